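#' Pairwise p-distance between aligned sequences
#'
#' Uncorrected proportion of differing positions; columns where either
#' sequence has a gap (`-`) or an ambiguous state are excluded pairwise.
#'
#' @param a,b aligned sequences of equal length (nucleotide or amino acid).
#' @param mode `"nt"` or `"aa"` (controls which states count as unambiguous).
#' @return list with `distance`, `differences`, `compared` (number of
#'   comparable positions).
#' @examples
#' pairwiseDivergence("AAAA", "AAAT")$distance  # 0.25
#' @export
pairwiseDivergence <- function(a, b, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) stop("length mismatch")
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  ok <- if (mode == "nt") ca %in% c("A", "C", "G", "T") &
          cb %in% c("A", "C", "G", "T")
        else ca %in% c(LETTERS, "*") & cb %in% c(LETTERS, "*") &
          ca != "X" & cb != "X"
  n <- sum(ok)
  if (n == 0L) stop("zero comparable positions")
  d <- sum(ca[ok] != cb[ok])
  list(distance = d / n, differences = d, compared = n)
}

# per-codon synonymous site count (0..3): at each position, the fraction of
# the three possible single-base changes that are synonymous; a change to or
# from a stop codon is nonsynonymous by policy
.synSiteCache <- new.env(parent = emptyenv())

.synSiteTable <- function(code) {
  bases <- c("A", "C", "G", "T")
  sapply(names(code), function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1L]]
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, ch[p])) {
        mut <- ch; mut[p] <- b
        mcd <- paste(mut, collapse = "")
        if (code[[mcd]] != "*" && code[[cd]] != "*" &&
            code[[mcd]] == code[[cd]]) s <- s + 1 / 3
      }
    }
    s
  })
}

# memoised wrapper used by ng86
.synSites <- function(code) {
  key <- paste(names(code), code, sep = ":", collapse = ";")
  hit <- .synSiteCache[[key]]
  if (is.null(hit)) {
    hit <- .synSiteTable(code)
    .synSiteCache[[key]] <- hit
  }
  hit
}

.PERMS <- list(matrix(1L), rbind(c(1L, 2L), c(2L, 1L)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# average syn/nonsyn difference counts between two codons over all shortest
# substitution pathways (equal weighting; stop-codon steps count nonsyn)
.ngCodonDiff <- function(c1, c2, code) {
  ch1 <- strsplit(c1, "", fixed = TRUE)[[1L]]
  ch2 <- strsplit(c2, "", fixed = TRUE)[[1L]]
  dif <- which(ch1 != ch2)
  k <- length(dif)
  if (k == 0L) return(c(nd = 0, sd = 0))
  perms <- .PERMS[[k]]
  nd <- sd <- 0
  for (r in seq_len(nrow(perms))) {
    cur <- ch1
    for (p in dif[perms[r, ]]) {
      nxt <- cur; nxt[p] <- ch2[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa1 != "*" && aa2 != "*" && aa1 == aa2) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
  }
  c(nd = nd / nrow(perms), sd = sd / nrow(perms))
}

#' Nei-Gojobori (1986) dN/dS between two coding sequences
#'
#' Unweighted-pathway NG86 counting: per-codon synonymous site fractions
#' are averaged over the two sequences; observed differences in codons hit
#' more than once are averaged over all orderings of the single-base steps
#' (equal weighting); proportions are Jukes-Cantor corrected,
#' d = -3/4 log(1 - 4/3 p). Changes to or from stop codons are counted
#' nonsynonymous. Codons containing gaps or ambiguity codes are dropped
#' pairwise. The statistic is symmetric in its arguments.
#'
#' @param a,b aligned in-frame coding sequences of equal length.
#' @param table codon table from [mitoGeneticCode()].
#' @return list with `N`, `S` (site counts averaged over the pair), `Nd`,
#'   `Sd` (difference counts), `pN`, `pS`, `dN`, `dS` (`NA` with a flag
#'   when the correction is undefined, i.e. p >= 3/4), `omega` (`NA` when
#'   dS = 0 or undefined), `codons_compared`, `flags`.
#' @examples
#' ng86("TTT", "TTC")[c("Sd", "Nd", "dN")]  # one synonymous difference
#' @export
ng86 <- function(a, b, table = mitoGeneticCode()) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) stop("length mismatch")
  if (nchar(a) %% 3L != 0L) stop("frame violation")
  code <- table$code
  syn <- .synSites(code)
  ca <- .splitCodons(a); cb <- .splitCodons(b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  nc <- length(ca)
  if (nc == 0L) stop("no comparable codons")
  Sa <- sum(syn[ca]); Sb <- sum(syn[cb])
  S <- (Sa + Sb) / 2
  N <- 3 * nc - S
  nd <- sd <- 0
  for (i in seq_len(nc)) {
    if (ca[i] != cb[i]) {
      d <- .ngCodonDiff(ca[i], cb[i], code)
      nd <- nd + d[["nd"]]; sd <- sd + d[["sd"]]
    }
  }
  pN <- if (N > 0) nd / N else NA_real_
  pS <- if (S > 0) sd / S else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_
                    else -0.75 * log(1 - 4 * p / 3)
  dN <- jc(pN); dS <- jc(pS)
  flags <- character()
  if (!is.na(pN) && pN >= 0.75) flags <- c(flags, "dN_correction_undefined")
  if (!is.na(pS) && pS >= 0.75) flags <- c(flags, "dS_correction_undefined")
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  if (is.na(omega)) flags <- c(flags, "omega_undefined")
  list(N = N, S = S, Nd = nd, Sd = sd, pN = pN, pS = pS, dN = dN, dS = dS,
       omega = omega, codons_compared = nc, flags = flags)
}

# pooled NG86 over a set of sequence pairs: difference and site counts are
# summed before forming proportions
.pooledNg86 <- function(pairs, table) {
  N <- S <- Nd <- Sd <- 0
  for (p in pairs) {
    r <- ng86(p[[1L]], p[[2L]], table)
    N <- N + r$N; S <- S + r$S; Nd <- Nd + r$Nd; Sd <- Sd + r$Sd
  }
  pN <- if (N > 0) Nd / N else NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_
                    else -0.75 * log(1 - 4 * p / 3)
  dN <- jc(pN); dS <- jc(pS)
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  list(dN = dN, dS = dS, omega = omega)
}

.geneKind <- function(gene) {
  if (grepl("^(rrnS|rrnL)$", gene)) "rRNA"
  else if (grepl("^trn", gene)) "tRNA"
  else if (gene %in% .MITO_GENES) "PCG"
  else "other"
}

# amino-acid p-distance of two aligned CDSs (gap/ambiguous codons dropped
# pairwise, then translated; internal stops tolerated as a '*' state)
.aaDistance <- function(a, b, table) {
  ca <- .splitCodons(toupper(a)); cb <- .splitCodons(toupper(b))
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  if (!any(clean)) stop("zero comparable codons")
  aa1 <- unname(table$code[ca[clean]])
  aa2 <- unname(table$code[cb[clean]])
  list(distance = mean(aa1 != aa2), differences = sum(aa1 != aa2),
       compared = sum(clean))
}

#' Between-group and within-group divergence per gene
#'
#' Builds the per-gene divergence summary for a two-level design (e.g. five
#' copepod species vs 11 conspecific individuals): `DW` is the mean
#' nucleotide p-distance over within-group pairs; `DB` the mean between-group
#' divergence, computed on amino acids for protein-coding genes and on
#' nucleotides for structural RNA genes; `omegaW`/`omegaB` are pooled NG86
#' dN/dS over the within/between pair sets (PCGs only). An `overall` row
#' aggregates across genes by pooling difference and site counts.
#'
#' @param alignments named list (gene -> named character vector or
#'   [Biostrings::DNAStringSet] of aligned sequences; in-frame CDSs for
#'   PCGs).
#' @param groups named character vector mapping taxon names to group labels.
#' @param table codon table from [mitoGeneticCode()].
#' @return data.frame with columns `gene`, `DB`, `omegaB`, `DW`, `omegaW`;
#'   `NA` marks an undefined value (e.g. a group with fewer than 2 members,
#'   an RNA gene's omega, or dS = 0).
#' @export
groupDivergenceSummary <- function(alignments, groups,
                                   table = mitoGeneticCode()) {
  agg <- list(
    w_nt_d = 0, w_nt_n = 0, b_d = 0, b_n = 0,
    w_pairs = list(), b_pairs = list())
  rows <- list()
  for (gene in names(alignments)) {
    seqs <- alignments[[gene]]
    if (!is.character(seqs)) seqs <- as.character(seqs)
    taxa <- names(seqs)
    grp <- groups[taxa]
    if (anyNA(grp)) stop("taxa missing from group map: ",
                         paste(taxa[is.na(grp)], collapse = ", "))
    kind <- .geneKind(gene)
    idx <- utils::combn(seq_along(seqs), 2L)
    within <- grp[idx[1L, ]] == grp[idx[2L, ]]
    wl <- lapply(which(within), function(k)
      list(seqs[[idx[1L, k]]], seqs[[idx[2L, k]]]))
    bl <- lapply(which(!within), function(k)
      list(seqs[[idx[1L, k]]], seqs[[idx[2L, k]]]))

    DW <- NA_real_
    if (length(wl)) {
      dd <- vapply(wl, function(p) {
        r <- pairwiseDivergence(p[[1L]], p[[2L]], "nt")
        c(r$differences, r$compared)
      }, numeric(2L))
      DW <- mean(dd[1L, ] / dd[2L, ])
      agg$w_nt_d <- agg$w_nt_d + sum(dd[1L, ])
      agg$w_nt_n <- agg$w_nt_n + sum(dd[2L, ])
    }
    DB <- NA_real_
    if (length(bl)) {
      dd <- vapply(bl, function(p) {
        r <- if (kind == "PCG") .aaDistance(p[[1L]], p[[2L]], table)
             else pairwiseDivergence(p[[1L]], p[[2L]], "nt")
        c(r$differences, r$compared)
      }, numeric(2L))
      DB <- mean(dd[1L, ] / dd[2L, ])
      agg$b_d <- agg$b_d + sum(dd[1L, ])
      agg$b_n <- agg$b_n + sum(dd[2L, ])
    }
    omegaW <- omegaB <- NA_real_
    if (kind == "PCG") {
      if (length(wl)) omegaW <- .pooledNg86(wl, table)$omega
      if (length(bl)) omegaB <- .pooledNg86(bl, table)$omega
      agg$w_pairs <- c(agg$w_pairs, wl)
      agg$b_pairs <- c(agg$b_pairs, bl)
    }
    rows[[gene]] <- data.frame(gene = gene, DB = DB, omegaB = omegaB,
                               DW = DW, omegaW = omegaW,
                               stringsAsFactors = FALSE)
  }
  overall <- data.frame(
    gene = "overall",
    DB = if (agg$b_n > 0) agg$b_d / agg$b_n else NA_real_,
    omegaB = if (length(agg$b_pairs))
      .pooledNg86(agg$b_pairs, table)$omega else NA_real_,
    DW = if (agg$w_nt_n > 0) agg$w_nt_d / agg$w_nt_n else NA_real_,
    omegaW = if (length(agg$w_pairs))
      .pooledNg86(agg$w_pairs, table)$omega else NA_real_,
    stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), overall)
  rownames(out) <- NULL
  out
}

#' Ratio of within-group to between-group dN/dS
#'
#' @param rows data.frame shaped like [groupDivergenceSummary()] output
#'   (columns `gene`, `omegaB`, `omegaW`) with an `overall` row.
#' @return list with `overall_ratio` (omegaW/omegaB of the overall row;
#'   `NA` with a flag when omegaB is 0 or undefined) and `per_gene`
#'   (data.frame `gene`, `ratio`).
#' @examples
#' tab <- readDivergenceTable(system.file("extdata",
#'   "calanus_divergence_table.tsv", package = "mitocomparator"))
#' omegaRatioSummary(tab)$overall_ratio  # 4.14
#' @export
omegaRatioSummary <- function(rows) {
  ratio <- function(w, b) {
    if (is.na(w) || is.na(b) || b == 0) NA_real_ else w / b
  }
  ov <- rows[rows$gene == "overall", ]
  if (nrow(ov) != 1L) stop("overall row absent")
  overall <- ratio(ov$omegaW, ov$omegaB)
  flags <- character()
  if (is.na(overall)) flags <- "overall_ratio_undefined"
  pg <- rows[rows$gene != "overall", ]
  per_gene <- data.frame(
    gene = pg$gene,
    ratio = mapply(ratio, pg$omegaW, pg$omegaB),
    stringsAsFactors = FALSE)
  list(overall_ratio = overall, per_gene = per_gene, flags = flags)
}

#' Read a published per-gene divergence table
#'
#' Reads the TSV shape written by [groupDivergenceSummary()] (columns
#' `gene`, `DB`, `omegaB`, `DW`, `omegaW`; `#` comments; `NA` for
#' undefined cells).
#'
#' @param file path to the TSV.
#' @return data.frame.
#' @export
readDivergenceTable <- function(file) {
  read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}
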