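#' Base composition and AT/GC strand skews
#'
#' Computes base fractions over unambiguous bases, the A+T content and the
#' two strand-asymmetry skews, AT-skew = (A - T)/(A + T) and GC-skew =
#' (G - C)/(G + C). A skew with a zero denominator is undefined and
#' reported as `NA` with the matching `*_defined` flag set to `FALSE`,
#' never as 0. IUPAC ambiguity codes are tolerated and excluded from all
#' denominators (their count is reported).
#'
#' @param seq nucleotide string (or [Biostrings::DNAString]).
#' @return list with `frac_a`, `frac_c`, `frac_g`, `frac_t`, `at_content`,
#'   `at_skew`, `gc_skew`, `at_skew_defined`, `gc_skew_defined`, `n_bases`,
#'   `n_excluded`.
#' @seealso [skewFromComposition()] for pre-tabulated percentages,
#'   [geneSkewProfiles()] for per-gene profiles.
#' @examples
#' baseComposition("ACGT")$at_skew   # 0
#' baseComposition("GGGG")$gc_skew   # 1 (AT-skew undefined)
#' @export
baseComposition <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nchar(seq)) stop("empty sequence")
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- bases[bases != "-"]
  cnt <- c(A = sum(bases == "A"), C = sum(bases == "C"),
           G = sum(bases == "G"), T = sum(bases %in% c("T", "U")))
  .skewStats(cnt, n_excluded = length(bases) - sum(cnt))
}

#' Skews from pre-tabulated composition
#'
#' Same statistics as [baseComposition()] but starting from printed
#' percentages or raw counts instead of a sequence. With
#' `asPercent = TRUE` the four values are taken as percentages of the
#' molecule and are not renormalised, so independently rounded percentages
#' (which may sum to slightly off 100) reproduce printed contents exactly:
#' `at_content = (a + t)/100`. The skews are ratios of the given values
#' either way.
#'
#' @param a,c,g,t counts, fractions or percentages of the four bases.
#' @param asPercent treat inputs as printed percentages (default FALSE).
#' @return as [baseComposition()].
#' @examples
#' s <- skewFromComposition(32.1, 19.1, 19.3, 29.6, asPercent = TRUE)
#' s$at_content       # 0.617
#' c(s$at_skew, s$gc_skew)
#' @export
skewFromComposition <- function(a, c, g, t, asPercent = FALSE) {
  out <- .skewStats(c(A = a, C = c, G = g, T = t), n_excluded = 0L)
  if (asPercent) {
    out$frac_a <- a / 100; out$frac_c <- c / 100
    out$frac_g <- g / 100; out$frac_t <- t / 100
    out$at_content <- (a + t) / 100
    out$n_bases <- NA_real_
  }
  out
}

.skewStats <- function(cnt, n_excluded) {
  tot <- sum(cnt)
  if (tot <= 0) stop("no unambiguous bases")
  fr <- cnt / tot
  at <- cnt[["A"]] + cnt[["T"]]
  gc <- cnt[["G"]] + cnt[["C"]]
  list(frac_a = fr[["A"]], frac_c = fr[["C"]], frac_g = fr[["G"]],
       frac_t = fr[["T"]],
       at_content = unname(at / tot),
       at_skew = if (at > 0) (cnt[["A"]] - cnt[["T"]]) / at else NA_real_,
       gc_skew = if (gc > 0) (cnt[["G"]] - cnt[["C"]]) / gc else NA_real_,
       at_skew_defined = at > 0, gc_skew_defined = gc > 0,
       n_bases = unname(tot), n_excluded = as.integer(n_excluded))
}

#' Per-gene composition and skew profiles
#'
#' One profile row per feature, computed on the feature's sense (reading)
#' strand: light-strand features are reverse-complemented before counting,
#' which is what makes the anti-A skew of the protein-coding genes visible
#' regardless of the strand they are encoded on. For protein-coding genes,
#' optional additional rows partition the sites into codon positions 1+2
#' and 3 (computed over complete codons; the 1-2 nt of a truncated terminal
#' stop are excluded from the partition rows).
#'
#' @param x a [MitoFeatureTable-class] carrying a sequence.
#' @param byCodonPosition also emit `pos12`/`pos3` rows for PCGs.
#' @return data.frame with columns `name`, `kind`, `partition`
#'   (`all`/`pos12`/`pos3`), `length` and the [baseComposition()] fields.
#' @export
geneSkewProfiles <- function(x, byCodonPosition = FALSE) {
  if (is.null(x@sequence)) stop("feature table carries no sequence")
  ft <- x@features
  rows <- list()
  for (i in seq_len(nrow(ft))) {
    s <- .senseSeq(x, i)
    rows[[length(rows) + 1L]] <-
      c(list(name = ft$name[i], kind = ft$kind[i], partition = "all",
             length = nchar(s)), baseComposition(s))
    if (byCodonPosition && ft$kind[i] == "PCG") {
      ncod <- nchar(s) %/% 3L
      if (ncod < 1L) stop("PCG frame error for '", ft$name[i], "'")
      ch <- strsplit(substr(s, 1L, 3L * ncod), "", fixed = TRUE)[[1L]]
      pos <- rep_len(1:3, 3L * ncod)
      p12 <- paste(ch[pos != 3L], collapse = "")
      p3 <- paste(ch[pos == 3L], collapse = "")
      rows[[length(rows) + 1L]] <-
        c(list(name = ft$name[i], kind = "PCG", partition = "pos12",
               length = nchar(p12)), baseComposition(p12))
      rows[[length(rows) + 1L]] <-
        c(list(name = ft$name[i], kind = "PCG", partition = "pos3",
               length = nchar(p3)), baseComposition(p3))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                        stringsAsFactors = FALSE)))
}

#' Codon usage of a set of coding sequences
#'
#' Pools codon counts over a set of in-frame CDSs and normalises to codons
#' per thousand. Stop codons are counted separately and excluded from the
#' per-thousand normalisation by default.
#'
#' @param cdsSet character vector (or [Biostrings::DNAStringSet]) of
#'   in-frame coding sequences; each length must be divisible by 3
#'   (complete the truncated stops first).
#' @param table codon table from [mitoGeneticCode()].
#' @param excludeStops exclude stop codons from per-thousand normalisation.
#' @return data.frame with columns `codon` (RNA alphabet), `aa`, `count`,
#'   `per_thousand`; attribute `total_codons` gives the normalisation
#'   denominator and `stop_counts` the per-stop tallies.
#' @examples
#' u <- codonUsage("TTTTTT")
#' u[u$count > 0, ]  # UUU 1000 per thousand
#' @export
codonUsage <- function(cdsSet, table = mitoGeneticCode(),
                       excludeStops = TRUE) {
  cdsSet <- as.character(cdsSet)
  if (any(nchar(cdsSet) %% 3L != 0L)) stop("frame violation")
  codons <- toupper(unlist(lapply(cdsSet, .splitCodons)))
  all64 <- names(table$code)
  cnt <- vapply(all64, function(cd) sum(codons == cd), integer(1L))
  isStop <- table$code == "*"
  denom <- if (excludeStops) sum(cnt[!isStop]) else sum(cnt)
  pt <- if (denom > 0) cnt * 1000 / denom else rep(NA_real_, 64L)
  if (excludeStops) pt[isStop] <- NA_real_
  out <- data.frame(codon = chartr("T", "U", all64),
                    aa = unname(table$code),
                    count = unname(cnt),
                    per_thousand = round(unname(pt), 3L),
                    stringsAsFactors = FALSE)
  attr(out, "total_codons") <- denom
  attr(out, "stop_counts") <- cnt[isStop]
  out
}

#' Correlation of genomic A+T content with fourfold-degenerate-site A+T
#'
#' Ordinary least squares of the A+T content at fourfold-degenerate
#' synonymous sites on the overall genomic A+T content across taxa,
#' reporting the coefficient of determination. A strong correlation is the
#' signature of mutation pressure driving composition.
#'
#' @param taxa data.frame with columns `taxon`, `overall_at`,
#'   `fourfold_at` (percentages or fractions, used as given).
#' @return list with `r_squared`, `slope`, `intercept`, `n_taxa`, `flags`
#'   (character vector; `"degenerate_fit"` for n = 2,
#'   `"zero_variance_predictor"` when the fit is undefined).
#' @export
atSynonymousCorrelation <- function(taxa) {
  n <- nrow(taxa)
  if (n < 2L) stop("need at least 2 taxa")
  flags <- character()
  if (n == 2L) flags <- c(flags, "degenerate_fit")
  if (var(taxa$overall_at) == 0) {
    return(list(r_squared = NA_real_, slope = NA_real_,
                intercept = NA_real_, n_taxa = n,
                flags = c(flags, "zero_variance_predictor")))
  }
  fit <- lm(fourfold_at ~ overall_at, data = taxa)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((taxa$fourfold_at - mean(taxa$fourfold_at))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(r_squared = r2, slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]), n_taxa = n, flags = flags)
}
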