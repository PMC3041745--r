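#' Invertebrate mitochondrial genetic code
#'
#' Returns the codon table used throughout the package: the invertebrate
#' mitochondrial code (NCBI translation table 5), in which ATA = Met and
#' TGA = Trp, with start-codon set ATD = \{ATA, ATT, ATG\} and stop set
#' \{TAA, TAG\}. Exposed as data so tests can inject toy codes.
#'
#' @return list with `code` (named character vector codon -> amino acid,
#'   `*` for stop), `starts`, `stops`.
#' @examples
#' mitoGeneticCode()$code[["ATA"]]  # "M"
#' @export
mitoGeneticCode <- function() {
  gc <- Biostrings::getGeneticCode("SGC4")
  names(gc) <- chartr("U", "T", names(gc))
  list(code = gc, starts = c("ATA", "ATT", "ATG"), stops = c("TAA", "TAG"))
}

#' Translate an in-frame coding sequence
#'
#' Translates under the invertebrate mitochondrial code. A terminal stop
#' codon is consumed (not reported in the protein). With
#' `truncated = TRUE`, a trailing 1-2 nt remainder is treated as an
#' incomplete stop (completed by polyadenylation in vivo) and dropped;
#' without the flag a length not divisible by three is a frame violation.
#' Internal stop codons are errors by default (a pseudogene guard).
#'
#' @param seq nucleotide string, sense strand, starting in frame.
#' @param table codon table from [mitoGeneticCode()].
#' @param truncated allow a 1-2 nt incomplete terminal stop.
#' @param allowInternalStops report internal stops as `*` instead of erroring.
#' @return amino-acid string.
#' @examples
#' translateCds("ATAATT")  # "MI"
#' translateCds("TGA", allowInternalStops = TRUE)  # "W" is not a stop here
#' @export
translateCds <- function(seq, table = mitoGeneticCode(), truncated = FALSE,
                         allowInternalStops = FALSE) {
  seq <- toupper(seq)
  r <- nchar(seq) %% 3L
  if (r != 0L) {
    if (!truncated)
      stop("sequence length not divisible by 3 (set truncated = TRUE for ",
           "an incomplete terminal stop)")
    seq <- substr(seq, 1L, nchar(seq) - r)
  }
  codons <- .splitCodons(seq)
  if (!length(codons)) return("")
  aa <- unname(table$code[codons])
  if (anyNA(aa)) stop("unknown codon: ",
                      paste(codons[is.na(aa)], collapse = ", "))
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]  # terminal stop consumed
  if (any(aa == "*") && !allowInternalStops)
    stop("internal stop codon at codon ", which(aa == "*")[1L])
  paste(aa, collapse = "")
}

#' Identify start and stop codons of an annotated protein-coding gene
#'
#' Start codons in these mitogenomes are drawn from ATD = \{ATA, ATT, ATG\};
#' where several in-frame candidates exist near the annotated 5' boundary the
#' convention is to pick the one that minimises overlap with the upstream
#' feature, with ties broken by the most conserved gene length (the
#' candidate closest to the annotated boundary) and then by the longer open
#' reading frame. The stop is TAA/TAG when the length permits,
#' otherwise a trailing `TA`/`T` abutting the downstream feature is annotated
#' as a truncated stop.
#'
#' @param x a [MitoFeatureTable-class] with sequence.
#' @param gene name of a PCG feature.
#' @param searchWindow nt searched on either side of the annotated 5'
#'   boundary for in-frame ATD candidates (default 9).
#' @param table codon table from [mitoGeneticCode()].
#' @return list with `gene`, `start_codon`, `stop_codon`, `truncated`
#'   (TRUE iff the stop is shorter than 3 nt), `start_offset` (signed nt
#'   shift of the chosen start relative to the annotation; 0 = annotated
#'   boundary) and `completed_stop_policy`.
#' @export
annotateStartStop <- function(x, gene, searchWindow = 9L,
                              table = mitoGeneticCode()) {
  i <- .featureRow(x, gene)
  ft <- x@features
  if (ft$kind[i] != "PCG") stop("'", gene, "' is not a protein-coding gene")
  if (is.null(x@sequence)) stop("feature table carries no sequence")
  s <- .senseSeq(x, i)
  n <- nchar(s)

  # stop codon: full TAA/TAG, else truncated TA/T remainder
  r <- n %% 3L
  stopc <- if (r == 0L) substr(s, n - 2L, n) else substr(s, n - r + 1L, n)
  truncated <- r != 0L
  if (!truncated && !stopc %in% table$stops)
    stop("no stop or truncated stop found for '", gene, "'")
  if (truncated && !stopc %in% c("TA", "T"))
    stop("trailing remainder '", stopc, "' is not a truncated stop")

  # in-frame ATD candidates within the search window around the 5' boundary;
  # offset o (multiple of 3, signed) shifts the reading start o nt into (+)
  # or upstream of (-) the annotated boundary
  readCodon <- function(o) {
    if (ft$strand[i] == "H") {
      from <- ft$start[i] + o
      if (from < 1L || from + 2L > x@totalLength) return(NA_character_)
      as.character(Biostrings::subseq(x@sequence, from, from + 2L))
    } else {
      to <- ft$end[i] - o
      if (to > x@totalLength || to - 2L < 1L) return(NA_character_)
      .revcomp(as.character(Biostrings::subseq(x@sequence, to - 2L, to)))
    }
  }
  offs <- seq(-searchWindow, min(searchWindow, n - 3L), by = 3L)
  codons5 <- vapply(offs, readCodon, character(1L))
  cand <- offs[!is.na(codons5) & codons5 %in% table$starts]
  if (!length(cand))
    stop("no ATD start candidate within ", searchWindow,
         " nt of the annotated boundary of '", gene, "'")
  # overlap (nt) of each candidate 5' boundary with the neighbouring feature
  # upstream in reading direction
  overlap <- if (ft$strand[i] == "H") {
    prevEnd <- if (i > 1L) ft$end[i - 1L] else 0L
    pmax(0L, prevEnd - (ft$start[i] + cand) + 1L)
  } else {
    nextStart <- if (i < nrow(ft)) ft$start[i + 1L] else x@totalLength + 1L
    pmax(0L, (ft$end[i] - cand) - nextStart + 1L)
  }
  # minimise overlap; among ties keep the length most conserved (offset
  # closest to the annotated boundary), then prefer the longer ORF
  tied <- cand[overlap == min(overlap)]
  tied <- tied[abs(tied) == min(abs(tied))]
  best <- min(tied)
  startc <- readCodon(best)
  list(gene = gene, start_codon = startc, stop_codon = stopc,
       truncated = truncated, start_offset = as.integer(best),
       completed_stop_policy = if (truncated)
         "incomplete terminator completed to TAA by polyadenylation"
       else "complete terminator")
}

#' Fourfold-degenerate third-codon positions
#'
#' A third position is fourfold degenerate iff all four bases there encode
#' the same amino acid (a change to a stop codon counts as nonsynonymous, so
#' such positions are excluded).
#'
#' @param cds in-frame coding sequence (sense strand, stop codon optional).
#' @param table codon table from [mitoGeneticCode()].
#' @return list with `positions` (nt positions within `cds` of the
#'   degenerate third sites), `codon_index`, and `baseCounts` (A/C/G/T counts
#'   at those sites).
#' @examples
#' fourfoldDegenerateSites("GGATTT")$codon_index  # GGN is 4-fold, TTN is not
#' @export
fourfoldDegenerateSites <- function(cds, table = mitoGeneticCode()) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("frame violation")
  codons <- .splitCodons(cds)
  code <- table$code
  is4d <- vapply(codons, function(cd) {
    stem <- substr(cd, 1L, 2L)
    aas <- code[paste0(stem, c("A", "C", "G", "T"))]
    !anyNA(aas) && length(unique(aas)) == 1L && aas[1L] != "*"
  }, logical(1L), USE.NAMES = FALSE)
  idx <- which(is4d)
  pos <- idx * 3L
  third <- if (length(pos)) substring(cds, pos, pos) else character()
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(third == b),
                   integer(1L))
  list(positions = pos, codon_index = idx, baseCounts = counts)
}
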