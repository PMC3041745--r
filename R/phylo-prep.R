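#' Concatenate per-gene amino-acid alignments with confidence masking
#'
#' Builds a supermatrix from per-gene amino-acid alignments, keeping only
#' columns whose alignment-confidence score (0-9 integers, e.g. posterior
#' probabilities exported alongside the alignment) exceeds the threshold.
#' Taxa missing from a gene are padded with gaps and flagged. `atp8` is
#' excluded by default, the usual practice when it is absent from some
#' sampled taxa.
#'
#' @param geneAlignments named list (gene -> named character vector of
#'   aligned aa sequences, equal lengths within a gene).
#' @param scores optional named list (gene -> integer vector or digit
#'   string, one score per column).
#' @param threshold keep columns with score strictly above this (default 5).
#' @param exclude genes dropped before concatenation (default `"atp8"`).
#' @return a [ConcatDataset-class]; attribute `flags` lists padded taxa.
#' @export
buildConcatDataset <- function(geneAlignments, scores = NULL,
                               threshold = 5L, exclude = "atp8") {
  geneAlignments <- geneAlignments[setdiff(names(geneAlignments), exclude)]
  if (!length(geneAlignments)) stop("no genes left to concatenate")
  taxa <- sort(unique(unlist(lapply(geneAlignments, names))))
  flags <- character()
  blocks <- list(); parts <- list(); keptScores <- integer()
  at <- 0L
  for (gene in names(geneAlignments)) {
    seqs <- geneAlignments[[gene]]
    w <- unique(nchar(seqs))
    if (length(w) != 1L) stop("unequal alignment lengths in gene ", gene)
    missing <- setdiff(taxa, names(seqs))
    if (length(missing)) {
      flags <- c(flags, paste0(gene, ": padded ",
                               paste(missing, collapse = ",")))
      seqs[missing] <- strrep("-", w)
    }
    mat <- do.call(rbind, strsplit(toupper(seqs[taxa]), "", fixed = TRUE))
    rownames(mat) <- taxa
    keep <- seq_len(w)
    sc <- NULL
    if (!is.null(scores)) {
      sc <- scores[[gene]]
      if (is.null(sc)) stop("no scores for gene ", gene)
      if (is.character(sc) && length(sc) == 1L)
        sc <- as.integer(strsplit(sc, "", fixed = TRUE)[[1L]])
      sc <- as.integer(sc)
      if (length(sc) != w) stop("scores for gene ", gene,
                                " do not cover all columns")
      if (any(sc < 0L | sc > 9L)) stop("score out of range for gene ", gene)
      keep <- which(sc > threshold)
    }
    if (!length(keep)) next
    blocks[[gene]] <- mat[, keep, drop = FALSE]
    parts[[gene]] <- data.frame(gene = gene, start = at + 1L,
                                end = at + length(keep),
                                stringsAsFactors = FALSE)
    if (!is.null(sc)) keptScores <- c(keptScores, sc[keep])
    at <- at + length(keep)
  }
  if (!length(blocks)) stop("empty result after masking")
  d <- new("ConcatDataset", taxa = taxa, mat = do.call(cbind, blocks),
           partitions = do.call(rbind, c(parts, make.row.names = FALSE)),
           scores = if (is.null(scores)) integer() else keptScores)
  attr(d, "flags") <- flags
  d
}

# restrict a ConcatDataset to a column subset, recomputing partitions
.subsetColumns <- function(d, keep) {
  keep <- sort(keep)
  p <- d@partitions
  geneOf <- character(ncol(d@mat))
  for (i in seq_len(nrow(p))) geneOf[p$start[i]:p$end[i]] <- p$gene[i]
  g <- geneOf[keep]
  parts <- list(); at <- 0L
  for (gene in unique(g)) {
    nkeep <- sum(g == gene)
    parts[[gene]] <- data.frame(gene = gene, start = at + 1L,
                                end = at + nkeep, stringsAsFactors = FALSE)
    at <- at + nkeep
  }
  ord <- order(match(g, unique(g)))  # keep gene blocks contiguous
  keep <- keep[ord]
  new("ConcatDataset", taxa = d@taxa, mat = d@mat[, keep, drop = FALSE],
      partitions = do.call(rbind, c(parts, make.row.names = FALSE)),
      scores = if (length(d@scores)) d@scores[keep] else integer())
}

#' Exclude strand-biased genes from a concatenated dataset
#'
#' Concrete rendering of the "only proteins whose nucleotide composition
#' was not significantly strand-biased" criterion: for each gene and taxon,
#' a two-sided exact binomial test of G vs C counts at the
#' fourfold-degenerate third positions of that taxon's CDS; a gene is
#' excluded when it is biased (p < alpha) in more than half of the taxa
#' with testable sites. A gene with no degenerate sites is flagged and
#' retained. The per-gene decision table makes the rule auditable.
#'
#' @param d a [ConcatDataset-class].
#' @param nucleotideCds named list (gene -> named character vector of
#'   in-frame ungapped CDSs per taxon).
#' @param alpha significance level (default 0.05).
#' @param table codon table from [mitoGeneticCode()].
#' @return list with `dataset` (the restricted [ConcatDataset-class]) and
#'   `decisions` (data.frame `gene`, `n_tested`, `n_biased`, `excluded`,
#'   `flag`).
#' @export
strandBiasFilter <- function(d, nucleotideCds, alpha = 0.05,
                             table = mitoGeneticCode()) {
  genes <- unique(d@partitions$gene)
  dec <- lapply(genes, function(gene) {
    cds <- nucleotideCds[[gene]]
    if (is.null(cds)) stop("no CDS provided for gene ", gene)
    ps <- vapply(cds, function(s) {
      fd <- fourfoldDegenerateSites(s, table)
      g <- fd$baseCounts[["G"]]; c0 <- fd$baseCounts[["C"]]
      if (g + c0 == 0L) return(NA_real_)
      binom.test(g, g + c0, 0.5)$p.value
    }, numeric(1L))
    tested <- sum(!is.na(ps))
    biased <- sum(ps < alpha, na.rm = TRUE)
    flag <- if (tested == 0L) "no_degenerate_sites" else ""
    data.frame(gene = gene, n_tested = tested, n_biased = biased,
               excluded = tested > 0L && biased > tested / 2,
               flag = flag, stringsAsFactors = FALSE)
  })
  dec <- do.call(rbind, dec)
  keepGenes <- dec$gene[!dec$excluded]
  p <- d@partitions[d@partitions$gene %in% keepGenes, , drop = FALSE]
  cols <- unlist(mapply(seq.int, p$start, p$end, SIMPLIFY = FALSE))
  list(dataset = .subsetColumns(d, cols), decisions = dec)
}

#' Slow-fast filtering to moderate-rate sites
#'
#' Site rates are estimated as the summed within-group variability: for
#' each user-declared group, the number of distinct non-gap states minus
#' one, summed over groups (a parsimony-step lower bound requiring
#' predefined groups). Sites are ranked and split into four equal-count
#' quartiles; only the two internal quartiles are retained, with ties at
#' either boundary resolved towards inclusion (every site sharing a
#' boundary rate is kept), which is deterministic.
#'
#' @param d a [ConcatDataset-class].
#' @param groups named character vector (taxon -> group); every group needs
#'   at least 2 taxa.
#' @return list with `dataset` (moderate-rate [ConcatDataset-class]),
#'   `rates` (data.frame `column`, `rate`, `quartile`, `retained`).
#' @export
slowFastFilter <- function(d, groups) {
  grp <- groups[d@taxa]
  if (anyNA(grp)) stop("taxa missing from group map: ",
                       paste(d@taxa[is.na(grp)], collapse = ", "))
  if (any(table(grp) < 2L)) stop("every group needs at least 2 taxa")
  rates <- apply(d@mat, 2L, function(col) {
    sum(vapply(split(col, grp), function(s) {
      s <- s[s != "-"]
      max(0L, length(unique(s)) - 1L)
    }, integer(1L)))
  })
  n <- length(rates)
  srt <- sort(rates)
  a <- floor(n / 4); b <- ceiling(3 * n / 4)
  rlow <- srt[a + 1L]; rhigh <- srt[b]
  retained <- rates >= rlow & rates <= rhigh
  quart <- ifelse(rates < rlow, "Q1",
                  ifelse(rates > rhigh, "Q4",
                         ifelse(rates <= srt[ceiling(n / 2)], "Q2", "Q3")))
  list(dataset = .subsetColumns(d, which(retained)),
       rates = data.frame(column = seq_len(n), rate = as.integer(rates),
                          quartile = quart, retained = retained,
                          stringsAsFactors = FALSE))
}

#' Principal components of nucleotide composition across taxa
#'
#' Centred (unscaled) PCA of the four base proportions of concatenated
#' protein-coding genes, used to pick taxa with relatively homogeneous
#' composition before phylogenetic analysis (not an inference tool).
#'
#' @param taxaCompositions data.frame with columns `taxon`, `A`, `C`, `G`,
#'   `T` (proportions).
#' @return list with `loadings`, `scores` (per-taxon), `variance_explained`
#'   and `flags` (`"zero_variance"` when the components are undefined).
#' @export
compositionPca <- function(taxaCompositions) {
  if (nrow(taxaCompositions) < 3L) stop("need at least 3 taxa")
  x <- as.matrix(taxaCompositions[, c("A", "C", "G", "T")])
  rownames(x) <- taxaCompositions$taxon
  if (all(apply(x, 2L, function(cl) var(cl) == 0)))
    return(list(loadings = NULL, scores = NULL,
                variance_explained = NULL, flags = "zero_variance"))
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(loadings = p$rotation, scores = p$x, variance_explained = ve,
       flags = character())
}
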