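#' Accessors for mitocomparator classes
#'
#' `features()` returns the ordered feature data.frame of a
#' [MitoFeatureTable-class]; `topology()` its molecule topology;
#' `totalLength()` its length in nt; `genomeSequence()` its H-strand
#' sequence (or `NULL`). `alnMatrix()` returns the character matrix of a
#' [HaplotypeAlignment-class]. `orderGenes()` and `orientations()` return the
#' gene names and +1/-1 orientations of a [SignedGeneOrder-class];
#' `datasetMatrix()` and `partitions()` the supermatrix and per-gene column
#' ranges of a [ConcatDataset-class].
#'
#' @param x an object of the corresponding class.
#' @return the slot value described above.
#' @name accessors
#' @aliases features topology totalLength genomeSequence alnMatrix
#'   orderGenes orientations datasetMatrix partitions
NULL

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))
#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname accessors
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))
#' @rdname accessors
#' @export
setGeneric("orderGenes", function(x) standardGeneric("orderGenes"))
#' @rdname accessors
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))
#' @rdname accessors
#' @export
setGeneric("datasetMatrix", function(x) standardGeneric("datasetMatrix"))
#' @rdname accessors
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

#' @rdname accessors
setMethod("features", "MitoFeatureTable", function(x) x@features)
#' @rdname accessors
setMethod("topology", "MitoFeatureTable", function(x) x@topology)
#' @rdname accessors
setMethod("totalLength", "MitoFeatureTable", function(x) x@totalLength)
#' @rdname accessors
setMethod("genomeSequence", "MitoFeatureTable", function(x) x@sequence)
#' @rdname accessors
setMethod("alnMatrix", "HaplotypeAlignment", function(x) {
  m <- as.matrix(x@seqs)
  rownames(m) <- names(x@seqs)
  m
})
#' @rdname accessors
setMethod("orderGenes", "SignedGeneOrder", function(x) x@genes)
#' @rdname accessors
setMethod("orientations", "SignedGeneOrder", function(x) x@orientation)
#' @rdname accessors
setMethod("datasetMatrix", "ConcatDataset", function(x) x@mat)
#' @rdname accessors
setMethod("partitions", "ConcatDataset", function(x) x@partitions)

setMethod("show", "MitoFeatureTable", function(object) {
  k <- table(factor(object@features$kind, levels = .FEATURE_KINDS))
  cat("MitoFeatureTable:", nrow(object@features), "features on a",
      object@topology, "molecule of", object@totalLength, "nt\n")
  cat("  ", paste(names(k), k, sep = ": ", collapse = ", "), "\n", sep = "")
  cat("  sequence:", if (is.null(object@sequence)) "absent" else "present",
      "\n")
})

setMethod("show", "HaplotypeAlignment", function(object) {
  cat("HaplotypeAlignment:", length(object@seqs), "haplotypes x",
      if (length(object@seqs)) Biostrings::width(object@seqs)[1L] else 0L,
      "columns;", if (is.null(object@annotation)) "unannotated"
      else "annotated", "\n")
})

setMethod("show", "SignedGeneOrder", function(object) {
  g <- paste0(ifelse(object@orientation < 0L, "-", ""), object@genes)
  cat("SignedGeneOrder (", object@topology, ", anchor ", object@anchor,
      "): ", paste(g, collapse = " "), "\n", sep = "")
})

setMethod("show", "ConcatDataset", function(object) {
  cat("ConcatDataset:", length(object@taxa), "taxa x", ncol(object@mat),
      "aa columns in", nrow(object@partitions), "gene partitions;",
      if (length(object@scores)) "scored" else "unscored", "\n")
})

setMethod("length", "SignedGeneOrder", function(x) length(x@genes))
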