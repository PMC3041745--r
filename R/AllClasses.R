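#' @import methods
#' @importFrom stats lm coef quantile setNames prcomp binom.test var
#'   residuals
#' @importFrom utils read.delim write.table
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet subseq
NULL

setClassUnion("DNAString_OR_NULL", c("DNAString", "NULL"))

.MITO_GENES <- local({
  trn <- paste0("trn", c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                         "K", "M", "F", "P", "T", "W", "Y", "V",
                         "L1", "L2", "S1", "S2"))
  c(paste0("cox", 1:3), paste0("nad", 1:6), "nad4L", "atp6", "atp8", "cytb",
    "rrnS", "rrnL", trn)
})

.FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "NCR")

.validFeatureName <- function(name, kind) {
  ifelse(kind == "NCR", grepl("^(LNR[0-9]*|NCR[0-9]*|CR)$", name),
         name %in% .MITO_GENES)
}

#' MitoFeatureTable: ordered annotated features of one mitogenome
#'
#' Container for the annotation of a single mitochondrial genome: an ordered
#' table of features (protein-coding genes, tRNAs, rRNAs and labelled
#' non-coding regions) with 1-based inclusive coordinates on the reference
#' (heavy, H) strand, the molecule topology, the total length, and optionally
#' the H-strand nucleotide sequence.
#'
#' Feature names follow the standard mitochondrial vocabulary (`cox1`-`cox3`,
#' `nad1`-`nad6`, `nad4L`, `atp6`, `atp8`, `cytb`, `rrnS`, `rrnL`, `trnX`
#' with `trnL1` = CUN, `trnL2` = UUR, `trnS1` = AGN, `trnS2` = UCN).
#' Strands are `H`/`L` (heavy/light, as defined by molecular weight); `+`/`-`
#' are accepted on input and normalised. Protein-coding features carry start
#' and stop codons (truncated 1-2 nt stops allowed); other kinds carry none.
#'
#' @slot features data.frame with columns `name`, `kind`, `strand`, `start`,
#'   `end`, `start_codon`, `stop_codon`, ordered by strictly increasing start.
#' @slot topology `"linear"` or `"circular"`.
#' @slot totalLength total molecule length in nucleotides.
#' @slot sequence optional [Biostrings::DNAString] of the H strand.
#' @slot declared optional data.frame of declared per-row lengths/spacers kept
#'   for consistency auditing (see [validateFeatureTable()]).
#' @seealso [mitoFeatureTable()], [readFeatureTable()], [spacerTable()]
#' @exportClass MitoFeatureTable
setClass("MitoFeatureTable",
  representation(features = "data.frame", topology = "character",
                 totalLength = "integer", sequence = "DNAString_OR_NULL",
                 declared = "data.frame"),
  prototype(features = data.frame(), topology = "linear",
            totalLength = 0L, sequence = NULL, declared = data.frame()))

setValidity("MitoFeatureTable", function(object) {
  msg <- character()
  ft <- object@features
  need <- c("name", "kind", "strand", "start", "end", "start_codon",
            "stop_codon")
  if (!all(need %in% names(ft)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "topology must be 'linear' or 'circular'")
  if (length(object@totalLength) != 1L || is.na(object@totalLength) ||
      object@totalLength < 0L)
    msg <- c(msg, "totalLength must be a single non-negative integer")
  if (nrow(ft)) {
    if (anyDuplicated(ft$name))
      msg <- c(msg, "duplicate feature names")
    if (!all(ft$kind %in% .FEATURE_KINDS))
      msg <- c(msg, paste("unknown feature kind:",
                          paste(setdiff(ft$kind, .FEATURE_KINDS), collapse = ", ")))
    bad <- !.validFeatureName(ft$name, ft$kind)
    if (any(bad))
      msg <- c(msg, paste("unknown gene name:",
                          paste(ft$name[bad], collapse = ", ")))
    if (!all(ft$strand %in% c("H", "L")))
      msg <- c(msg, "strand must be 'H' or 'L'")
    if (any(ft$end < ft$start))
      msg <- c(msg, paste("end < start for:",
                          paste(ft$name[ft$end < ft$start], collapse = ", ")))
    if (any(ft$start < 1L) || any(ft$end > object@totalLength))
      msg <- c(msg, "feature coordinates outside [1, totalLength]")
    if (nrow(ft) > 1L && any(diff(ft$start) <= 0L))
      msg <- c(msg, "features must be strictly ordered by start")
    pcg <- ft$kind == "PCG"
    if (any(pcg & (is.na(ft$start_codon) | is.na(ft$stop_codon))))
      msg <- c(msg, "PCG features must carry start and stop codons")
    if (any(!pcg & (!is.na(ft$start_codon) | !is.na(ft$stop_codon))))
      msg <- c(msg, "non-PCG features must not carry start/stop codons")
  }
  if (!is.null(object@sequence) &&
      length(object@sequence) != object@totalLength)
    msg <- c(msg, "sequence length must equal totalLength")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a MitoFeatureTable
#'
#' @param features data.frame with columns `name`, `kind`, `strand`, `start`,
#'   `end` and optionally `start_codon`, `stop_codon`. Rows are sorted by
#'   start; strands `+`/`-` are normalised to `H`/`L`.
#' @param topology `"linear"` or `"circular"`.
#' @param totalLength molecule length (nt).
#' @param sequence optional H-strand sequence (character or
#'   [Biostrings::DNAString]).
#' @param declared optional data.frame (`name`, `length`, `intergenic`) of
#'   declared values for auditing.
#' @return a validated [MitoFeatureTable-class] object.
#' @examples
#' tab <- mitoFeatureTable(
#'   data.frame(name = c("cox1", "trnA"), kind = c("PCG", "tRNA"),
#'              strand = c("L", "H"), start = c(1L, 1551L), end = c(1548L, 1614L),
#'              start_codon = c("ATA", NA), stop_codon = c("TAA", NA)),
#'   topology = "linear", totalLength = 1700L)
#' totalLength(tab)
#' @export
mitoFeatureTable <- function(features, topology = c("linear", "circular"),
                             totalLength, sequence = NULL,
                             declared = data.frame()) {
  topology <- match.arg(topology)
  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(name = character(), kind = character(),
                           strand = character(), start = integer(),
                           end = integer(), start_codon = character(),
                           stop_codon = character(),
                           stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    if (is.null(features$start_codon)) features$start_codon <- NA_character_
    if (is.null(features$stop_codon)) features$stop_codon <- NA_character_
    features$strand <- c("+" = "H", "-" = "L", "H" = "H", "L" = "L")[
      as.character(features$strand)]
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    features$start_codon[features$start_codon %in% c("", ".")] <- NA_character_
    features$stop_codon[features$stop_codon %in% c("", ".")] <- NA_character_
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
  }
  if (!is.null(sequence) && !is(sequence, "DNAString"))
    sequence <- Biostrings::DNAString(as.character(sequence))
  new("MitoFeatureTable", features = features, topology = topology,
      totalLength = as.integer(totalLength), sequence = sequence,
      declared = declared)
}

#' HaplotypeAlignment: a multi-haplotype nucleotide alignment
#'
#' Rectangular alignment of intraspecific haplotypes (gaps allowed), with an
#' optional [MitoFeatureTable-class] annotation whose coordinates are taken to
#' be alignment columns (the reference haplotype is ungapped, so alignment
#' columns map one-to-one onto genome positions).
#'
#' @slot seqs [Biostrings::DNAStringSet] of equal widths (rows = haplotypes).
#' @slot annotation [MitoFeatureTable-class] or `NULL`.
#' @seealso [haplotypeAlignment()], [callVariableSites()],
#'   [slidingWindowScan()]
#' @exportClass HaplotypeAlignment
setClass("HaplotypeAlignment",
  representation(seqs = "DNAStringSet", annotation = "ANY"),
  prototype(seqs = Biostrings::DNAStringSet(), annotation = NULL))

setValidity("HaplotypeAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(w) && length(unique(w)) != 1L)
    return("all haplotypes must have equal aligned length")
  if (length(object@seqs) && is.null(names(object@seqs)))
    return("haplotypes must be named")
  if (!is.null(object@annotation)) {
    if (!is(object@annotation, "MitoFeatureTable"))
      return("annotation must be a MitoFeatureTable or NULL")
    if (length(w) && totalLength(object@annotation) != w[1L])
      return("annotation totalLength must equal alignment width")
  }
  TRUE
})

#' Construct a HaplotypeAlignment
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of aligned
#'   haplotypes (equal lengths, `-` for gaps).
#' @param annotation optional [MitoFeatureTable-class] mapped to alignment
#'   columns.
#' @return a [HaplotypeAlignment-class] object.
#' @export
haplotypeAlignment <- function(seqs, annotation = NULL) {
  if (!is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("hap", seq_along(seqs))
  new("HaplotypeAlignment", seqs = seqs, annotation = annotation)
}

#' SignedGeneOrder: a signed (oriented) gene order
#'
#' Circular or linear permutation of oriented genes, the substrate for
#' adjacency-retention, inversion-census and common-interval comparisons.
#' The linearised form starts at the anchor gene in + orientation (the whole
#' order is reflected and sign-flipped if the anchor is on -).
#'
#' @slot genes character vector of unique gene names in genomic order.
#' @slot orientation integer vector of +1/-1 (sense strand) parallel to
#'   `genes`.
#' @slot topology `"circular"` or `"linear"`.
#' @slot anchor gene used for linearisation.
#' @seealso [signedGeneOrder()], [commonIntervals()], [compareGeneOrders()]
#' @exportClass SignedGeneOrder
setClass("SignedGeneOrder",
  representation(genes = "character", orientation = "integer",
                 topology = "character", anchor = "character"))

setValidity("SignedGeneOrder", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes)) msg <- c(msg, "gene names must be unique")
  if (length(object@orientation) != length(object@genes))
    msg <- c(msg, "orientation must be parallel to genes")
  if (!all(object@orientation %in% c(-1L, 1L)))
    msg <- c(msg, "orientation entries must be +1 or -1")
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  if (length(object@genes) && !object@anchor %in% object@genes)
    msg <- c(msg, "anchor must be one of the genes")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a SignedGeneOrder
#'
#' @param genes gene names in genomic order; a leading `-` marks the opposite
#'   strand when `orientation` is not given (e.g. `c("cox1", "-nad2")`).
#' @param orientation optional vector of +1/-1 (or "+"/"-").
#' @param topology `"circular"` (default) or `"linear"`.
#' @param anchor linearisation anchor; defaults to `"cox1"` when present,
#'   else the first gene.
#' @return a [SignedGeneOrder-class] object.
#' @examples
#' o <- signedGeneOrder(c("cox1", "-nad2", "atp8", "atp6"))
#' orderGenes(o)
#' @export
signedGeneOrder <- function(genes, orientation = NULL,
                            topology = c("circular", "linear"),
                            anchor = NULL) {
  topology <- match.arg(topology)
  genes <- as.character(genes)
  if (is.null(orientation)) {
    orientation <- ifelse(startsWith(genes, "-"), -1L, 1L)
    genes <- sub("^[+-]", "", genes)
  } else if (is.character(orientation)) {
    orientation <- ifelse(orientation %in% c("-", "-1"), -1L, 1L)
  }
  if (is.null(anchor))
    anchor <- if ("cox1" %in% genes) "cox1" else genes[1L]
  new("SignedGeneOrder", genes = genes,
      orientation = as.integer(orientation), topology = topology,
      anchor = anchor)
}

#' ConcatDataset: a concatenated amino-acid supermatrix
#'
#' Concatenation of per-gene amino-acid alignments with per-gene column
#' partitions and optional per-column confidence scores (0-9 integers).
#'
#' @slot taxa taxon names (rows).
#' @slot mat character matrix (taxa x columns) of amino-acid states, `-` for
#'   gaps.
#' @slot partitions data.frame with columns `gene`, `start`, `end`; the
#'   partitions tile the matrix without overlap.
#' @slot scores integer vector of per-column scores, or zero-length when
#'   absent.
#' @seealso [buildConcatDataset()], [slowFastFilter()], [strandBiasFilter()]
#' @exportClass ConcatDataset
setClass("ConcatDataset",
  representation(taxa = "character", mat = "matrix",
                 partitions = "data.frame", scores = "integer"))

setValidity("ConcatDataset", function(object) {
  msg <- character()
  if (nrow(object@mat) != length(object@taxa))
    msg <- c(msg, "matrix rows must match taxa")
  p <- object@partitions
  if (nrow(p)) {
    cols <- unlist(mapply(seq.int, p$start, p$end, SIMPLIFY = FALSE))
    if (length(cols) != ncol(object@mat) || anyDuplicated(cols) ||
        !setequal(cols, seq_len(ncol(object@mat))))
      msg <- c(msg, "partitions must tile the matrix without overlap")
  }
  if (length(object@scores) && length(object@scores) != ncol(object@mat))
    msg <- c(msg, "scores must cover all columns")
  if (length(object@scores) &&
      (any(object@scores < 0L) || any(object@scores > 9L)))
    msg <- c(msg, "scores must be integers in 0..9")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
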