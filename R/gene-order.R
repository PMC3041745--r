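#' Extract a signed gene order from a feature table
#'
#' Genes in genomic order with orientation +1 for H-strand features and -1
#' for L-strand features. Restricting `include` to `c("PCG", "rRNA")`
#' reproduces the usual major-gene arrangement comparison (tRNAs and
#' non-coding regions excluded for clarity).
#'
#' @param x a [MitoFeatureTable-class].
#' @param include feature kinds to keep (default everything except NCR).
#' @return a [SignedGeneOrder-class] with the table's topology.
#' @export
orderFromFeatures <- function(x, include = c("PCG", "rRNA", "tRNA")) {
  ft <- x@features[x@features$kind %in% include, , drop = FALSE]
  if (!nrow(ft)) stop("empty selection: no features of kind ",
                      paste(include, collapse = "/"))
  signedGeneOrder(ft$name,
                  orientation = ifelse(ft$strand == "H", 1L, -1L),
                  topology = x@topology)
}

#' The putative arthropod ground-pattern gene order
#'
#' The ancestral arthropod mitochondrial gene arrangement (the Limulus
#' polyphemus order) shipped as a named built-in signed order, used as the
#' rearrangement reference. Orientation + is the majority coding strand.
#'
#' @param includeTrn keep the 22 tRNA genes (default) or restrict to the 13
#'   protein-coding plus 2 rRNA genes.
#' @return a circular [SignedGeneOrder-class] anchored at `cox1`.
#' @export
arthropodGroundPattern <- function(includeTrn = TRUE) {
  g <- c("trnI", "-trnQ", "trnM", "nad2", "trnW", "-trnC", "-trnY",
         "cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6",
         "cox3", "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1",
         "trnE", "-trnF", "-nad5", "-trnH", "-nad4", "-nad4L", "trnT",
         "-trnP", "nad6", "cytb", "trnS2", "-nad1", "-trnL1", "-rrnL",
         "-trnV", "-rrnS")
  if (!includeTrn) g <- g[!grepl("trn", g)]
  signedGeneOrder(g, topology = "circular", anchor = "cox1")
}

# linearised (genes, orientation) starting at `anchor` with + orientation;
# a circular order is rotated, and reflected/sign-flipped when the anchor
# is on -; a linear order is only reflected when needed
.linearise <- function(o, anchor) {
  g <- o@genes; s <- o@orientation
  i <- match(anchor, g)
  if (is.na(i)) stop("anchor '", anchor, "' not in order")
  if (o@topology == "circular" && i > 1L) {
    idx <- c(i:length(g), seq_len(i - 1L))
    g <- g[idx]; s <- s[idx]
    i <- 1L
  }
  if (s[i] < 0L) {
    g <- rev(g); s <- rev(-s)
    if (o@topology == "circular") {
      i <- match(anchor, g)
      idx <- c(i:length(g), seq_len(i - 1L))
      g <- g[idx]; s <- s[idx]
    }
  }
  list(genes = g, orientation = s)
}

# unordered adjacency pairs of an order (wrap pair included when circular)
.adjacencies <- function(genes, circular) {
  n <- length(genes)
  if (n < 2L) return(character())
  a <- genes[-n]; b <- genes[-1L]
  if (circular && n > 2L) { a <- c(a, genes[n]); b <- c(b, genes[1L]) }
  unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

# restrict an order to a gene subset, preserving order and orientation
.restrict <- function(o, keep) {
  sel <- o@genes %in% keep
  signedGeneOrder(o@genes[sel], orientation = o@orientation[sel],
                  topology = o@topology,
                  anchor = if (o@anchor %in% o@genes[sel]) o@anchor
                           else o@genes[sel][1L])
}

#' Compare a gene order to a reference arrangement
#'
#' Compares two signed gene orders on their shared gene set: adjacency
#' retention (unordered neighbouring pairs present in both orders, the wrap
#' pair included on circular molecules), and the strand-inversion census
#' (genes whose orientation differs after anchoring both orders on the same
#' gene in + orientation).
#'
#' @param o a [SignedGeneOrder-class] (the query).
#' @param ref a [SignedGeneOrder-class] (the reference / ground pattern).
#' @param anchor gene used to align orientations; default `o`'s anchor if
#'   shared, else the first shared gene.
#' @return list with `shared_genes`, `dropped` (genes absent from one
#'   order), `retained_adjacencies` (data.frame `gene1`, `gene2`),
#'   `retained_count`, `inverted_genes`, `inverted_fraction`.
#' @examples
#' tab <- readFeatureTable(system.file("extdata",
#'   "calanus_sinicus_features.tsv", package = "mitocomparator"))
#' cmp <- compareGeneOrders(orderFromFeatures(tab, c("PCG", "rRNA")),
#'                          arthropodGroundPattern(includeTrn = FALSE))
#' cmp$retained_adjacencies  # atp6-atp8 and cytb-nad6 only
#' @export
compareGeneOrders <- function(o, ref, anchor = NULL) {
  shared <- intersect(o@genes, ref@genes)
  if (!length(shared)) stop("empty gene-set intersection")
  dropped <- union(setdiff(o@genes, shared), setdiff(ref@genes, shared))
  o2 <- .restrict(o, shared); r2 <- .restrict(ref, shared)
  if (is.null(anchor))
    anchor <- if (o@anchor %in% shared) o@anchor else shared[1L]

  a1 <- .adjacencies(o2@genes, o2@topology == "circular")
  a2 <- .adjacencies(r2@genes, r2@topology == "circular")
  kept <- intersect(a1, a2)
  parts <- strsplit(kept, "|", fixed = TRUE)
  retained <- data.frame(
    gene1 = vapply(parts, `[`, "", 1L),
    gene2 = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)

  l1 <- .linearise(o2, anchor); l2 <- .linearise(r2, anchor)
  s1 <- setNames(l1$orientation, l1$genes)
  s2 <- setNames(l2$orientation, l2$genes)
  inverted <- shared[s1[shared] != s2[shared]]

  list(shared_genes = shared, dropped = dropped,
       retained_adjacencies = retained, retained_count = nrow(retained),
       inverted_genes = inverted,
       inverted_fraction = length(inverted) / length(shared))
}

#' Common intervals of two gene orders
#'
#' Counts the gene sets of size 2 to n-1 that are contiguous (in any
#' internal order) in both orders -- the conserved-synteny measure used for
#' pairwise arrangement comparison. The comparison is unsigned
#' (orientations ignored); circular orders are linearised at the shared
#' anchor first, and by default intervals spanning the linearisation cut
#' are not counted (`circular = TRUE` toggles cyclic contiguity in both
#' orders).
#'
#' @param p,q [SignedGeneOrder-class] objects over the same gene set.
#' @param anchor linearisation anchor; default `p`'s anchor if shared, else
#'   the first gene of `p`.
#' @param circular count intervals across the linearisation cut as well.
#' @return list with `count` and `intervals` (list of gene-name vectors,
#'   for audit).
#' @examples
#' p <- signedGeneOrder(as.character(1:4), topology = "linear", anchor = "1")
#' q <- signedGeneOrder(c("2", "1", "4", "3"), topology = "linear",
#'                      anchor = "2")
#' commonIntervals(p, q)$count  # 2: {1,2} and {3,4}
#' @export
commonIntervals <- function(p, q, anchor = NULL, circular = FALSE) {
  if (!setequal(p@genes, q@genes)) stop("gene-set mismatch")
  if (is.null(anchor))
    anchor <- if (p@anchor %in% q@genes) p@anchor else p@genes[1L]
  gp <- .linearise(p, anchor)$genes
  gq <- .linearise(q, anchor)$genes
  n <- length(gp)
  if (n < 3L) return(list(count = 0L, intervals = list()))
  posq <- match(gp, gq)  # q-position of the gene at each p-position
  intervals <- list()
  starts <- seq_len(n)
  contigQ <- function(qs) {
    k <- length(qs)
    lin <- max(qs) - min(qs) == k - 1L
    if (lin || !circular) return(lin)
    comp <- setdiff(seq_len(n), qs)
    max(comp) - min(comp) == length(comp) - 1L
  }
  maxStart <- if (circular) n else n - 1L
  for (i in seq_len(maxStart)) {
    maxLen <- if (circular) n - 1L else n - i + 1L
    lo <- posq[i]; hi <- posq[i]
    for (len in 2:min(maxLen, n - 1L)) {
      j <- (i + len - 2L) %% n + 1L
      lo <- min(lo, posq[j]); hi <- max(hi, posq[j])
      idx <- ((i - 1L):(i + len - 2L)) %% n + 1L
      ok <- if (!circular) hi - lo == len - 1L else contigQ(posq[idx])
      if (ok) intervals[[length(intervals) + 1L]] <- gp[idx]
    }
  }
  if (circular) {
    key <- vapply(intervals, function(g) paste(sort(g), collapse = "|"), "")
    intervals <- intervals[!duplicated(key)]
  }
  list(count = length(intervals), intervals = intervals)
}

#' Read and write gene-order text files
#'
#' One genome per line: `name: gene1 -gene2 gene3 ...` where a leading `-`
#' marks the opposite strand. Orders read this way are circular by default.
#'
#' @param file path.
#' @param topology topology assigned to the orders read.
#' @return `readGeneOrders`: named list of [SignedGeneOrder-class].
#' @export
readGeneOrders <- function(file, topology = "circular") {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed gene-order line: ", ln)
    genes <- strsplit(trimws(parts[2L]), "\\s+")[[1L]]
    out[[trimws(parts[1L])]] <- signedGeneOrder(genes, topology = topology)
  }
  out
}

#' @rdname readGeneOrders
#' @param orders named list of [SignedGeneOrder-class] objects.
#' @export
writeGeneOrders <- function(orders, file) {
  lines <- vapply(names(orders), function(nm) {
    o <- orders[[nm]]
    paste0(nm, ": ", paste(paste0(ifelse(o@orientation < 0L, "-", ""),
                                  o@genes), collapse = " "))
  }, character(1L))
  writeLines(lines, file)
  invisible(file)
}
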