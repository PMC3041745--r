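aaAln <- function(...) {
  x <- list(...)
  vapply(x, paste, character(1), collapse = "")
}

test_that("confidence masking keeps columns strictly above threshold", {
  g <- list(cox1 = c(t1 = "MKLV", t2 = "MKIV", t3 = "MRLV"))
  sc <- list(cox1 = c(9L, 5L, 6L, 2L))
  d <- buildConcatDataset(g, sc, threshold = 5)
  expect_equal(ncol(datasetMatrix(d)), 2L)
  expect_equal(unname(datasetMatrix(d)["t1", ]), c("M", "L"))
  d0 <- buildConcatDataset(g, list(cox1 = c(1L, 3L, 2L, 9L)), threshold = 0)
  expect_equal(ncol(datasetMatrix(d0)), 4L)
  expect_error(buildConcatDataset(g, list(cox1 = c(9L, 5L, 6L, 12L))),
               "out of range")
  expect_error(buildConcatDataset(g, list(cox1 = c(0L, 0L, 0L, 0L)),
                                  threshold = 5), "empty result")
})

test_that("partitions tile the concatenated matrix", {
  g <- list(cox1 = c(t1 = strrep("M", 12), t2 = strrep("K", 12)),
            nad2 = c(t1 = strrep("L", 15), t2 = strrep("V", 15)))
  sc <- list(cox1 = rep(9L, 12), nad2 = rep(9L, 15))
  d <- buildConcatDataset(g, sc)
  p <- partitions(d)
  expect_equal(p$start, c(1L, 13L))
  expect_equal(p$end, c(12L, 27L))
})

test_that("atp8 is excluded by default and missing taxa are padded", {
  g <- list(atp8 = c(t1 = "MK"), cox1 = c(t1 = "ML", t2 = "MI"))
  d <- buildConcatDataset(g)
  expect_equal(unique(partitions(d)$gene), "cox1")
  expect_equal(unname(datasetMatrix(d)["t2", ]), c("M", "I"))
  g2 <- list(cox1 = c(t1 = "ML", t2 = "MI"), nad1 = c(t1 = "FF"))
  d2 <- buildConcatDataset(g2)
  expect_equal(unname(datasetMatrix(d2)["t2", 3:4]), c("-", "-"))
  expect_match(attr(d2, "flags"), "nad1")
})

test_that("masking commutes with concatenation", {
  set.seed(71)
  mkGene <- function(w) {
    seqs <- vapply(1:3, function(i)
      paste(sample(c("A", "R", "N", "D"), w, TRUE), collapse = ""),
      character(1))
    names(seqs) <- paste0("t", 1:3)
    seqs
  }
  g <- list(cox1 = mkGene(10), nad2 = mkGene(8))
  sc <- list(cox1 = sample(0:9, 10, TRUE), nad2 = sample(0:9, 8, TRUE))
  whole <- buildConcatDataset(g, sc, threshold = 5)
  perGene <- lapply(names(g), function(gene)
    buildConcatDataset(g[gene], sc[gene], threshold = 5, exclude = NULL))
  expect_equal(datasetMatrix(whole),
               do.call(cbind, lapply(perGene, datasetMatrix)))
})

test_that("strand-bias exclusion follows the binomial majority rule", {
  taxa <- paste0("t", 1:4)
  # balanced gene: equal G and C at every fourfold-degenerate site
  bal <- setNames(rep(paste(rep(c("GGA", "GGC", "GGG", "GGT"), 8),
                            collapse = ""), 4), taxa)
  # biased gene: degenerate third positions are 90% G
  mkBias <- function() paste(c(rep("GGG", 36), rep("GGC", 4)),
                             collapse = "")
  bias <- setNames(replicate(4, mkBias()), taxa)
  aa <- function(cds) setNames(vapply(cds, function(s)
    translateCds(s, allowInternalStops = TRUE), character(1)), names(cds))
  d <- buildConcatDataset(list(cox1 = aa(bal), nad2 = aa(bias)))
  r <- strandBiasFilter(d, list(cox1 = bal, nad2 = bias))
  expect_false(r$decisions$excluded[r$decisions$gene == "cox1"])
  expect_true(r$decisions$excluded[r$decisions$gene == "nad2"])
  expect_equal(unique(partitions(r$dataset)$gene), "cox1")
  # a gene with no degenerate sites is flagged and retained
  nodeg <- setNames(rep(strrep("TGG", 10), 4), taxa)  # Trp only
  d2 <- buildConcatDataset(list(cytb = aa(nodeg)))
  r2 <- strandBiasFilter(d2, list(cytb = nodeg))
  expect_equal(r2$decisions$flag, "no_degenerate_sites")
  expect_false(r2$decisions$excluded)
})

test_that("site rates count within-group states and quartiles keep the
           middle half", {
  g <- list(sim = c(a1 = "AAB", a2 = "ACB", b1 = "BDB", b2 = "BDB"))
  d <- buildConcatDataset(g)
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  sf <- slowFastFilter(d, groups)
  # col1: {A,A}|{B,B} -> 0; col2: {A,C}|{D,D} -> 1; col3: invariant -> 0
  expect_equal(sf$rates$rate, c(0L, 1L, 0L))
  expect_error(slowFastFilter(d, c(a1 = "A", a2 = "B", b1 = "B", b2 = "B")),
               "at least 2 taxa")
})

test_that("rank filtering keeps exactly the two internal quartiles", {
  # 8 columns with rates 0..7 over four 3-taxon groups: a column of rate r
  # gives r taxa (round-robin over groups, fresh taxon each time) a new
  # private state, so the summed within-group distinct-state excess is r
  taxa <- paste0("t", 1:12)
  groups <- setNames(rep(c("A", "B", "C", "D"), each = 3), taxa)
  states <- c("C", "D", "E", "F", "G", "H", "I", "K")
  cols <- lapply(0:7, function(r) {
    col <- rep("A", 12)
    slot <- integer(4)
    for (e in seq_len(r)) {
      grp <- (e - 1L) %% 4L
      slot[grp + 1L] <- slot[grp + 1L] + 1L
      col[3L * grp + 1L + slot[grp + 1L]] <- states[e]
    }
    col
  })
  mat <- do.call(cbind, cols)
  seqs <- setNames(apply(mat, 1, paste, collapse = ""), taxa)
  sf <- slowFastFilter(buildConcatDataset(list(sim = seqs)), groups)
  expect_equal(sf$rates$rate, 0:7)
  expect_equal(which(sf$rates$retained), 3:6)
  # untied continuous ranks retain exactly half
  expect_equal(mean(sf$rates$retained), 0.5)
})

test_that("a single rate class is wholly retained by the tie policy", {
  g <- list(sim = c(a1 = "AAAA", a2 = "AAAA", b1 = "AAAA", b2 = "AAAA"))
  sf <- slowFastFilter(buildConcatDataset(g),
                       c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_true(all(sf$rates$retained))
})

test_that("site rates ignore within-group taxon order", {
  rc <- genRateClassAlignment(simConfig(seed = 72))
  d <- buildConcatDataset(rc$alignments)
  sf1 <- slowFastFilter(d, rc$groups)
  seqs <- rc$alignments$sim
  perm <- names(seqs)
  perm[1:2] <- perm[2:1]  # swap two taxa of the same group
  d2 <- buildConcatDataset(list(sim = seqs[perm]))
  sf2 <- slowFastFilter(d2, rc$groups)
  expect_equal(sf1$rates$rate, sf2$rates$rate)
})

test_that("rate-class fixture retains the middle classes", {
  rc <- genRateClassAlignment(simConfig(seed = 73))
  sf <- slowFastFilter(buildConcatDataset(rc$alignments), rc$groups)
  ret <- sf$rates$retained
  cls <- rc$truth$rate_class
  expect_gte(mean(ret[cls %in% 1:2]), 0.9)
  expect_lte(mean(ret[cls %in% c(0, 3)]), 0.1)
  expect_equal(sf$rates$rate, cls)  # programmed rates recovered exactly
})

test_that("composition PCA handles rank-1 and degenerate data", {
  base <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  taxa <- data.frame(taxon = paste0("t", 1:6),
                     A = unname(base["A"]) + seq(-0.05, 0.05, length.out = 6),
                     C = unname(base["C"]), G = unname(base["G"]),
                     T = unname(base["T"]) - seq(-0.05, 0.05, length.out = 6))
  p <- compositionPca(taxa)
  expect_equal(p$variance_explained[1], 1.0, tolerance = 1e-12)
  flat <- data.frame(taxon = paste0("t", 1:4), A = 0.25, C = 0.25,
                     G = 0.25, T = 0.25)
  expect_equal(compositionPca(flat)$flags, "zero_variance")
  set.seed(74)
  rand <- data.frame(taxon = paste0("t", 1:10),
                     A = runif(10, 0.2, 0.4), C = runif(10, 0.1, 0.3),
                     G = runif(10, 0.1, 0.3), T = runif(10, 0.2, 0.4))
  pr <- compositionPca(rand)
  centred <- scale(as.matrix(rand[, c("A", "C", "G", "T")]), scale = FALSE)
  rebuilt <- pr$scores %*% t(pr$loadings)
  expect_equal(as.vector(rebuilt), as.vector(centred), tolerance = 1e-10)
  expect_true(all(pr$variance_explained >= 0))
  expect_lte(sum(pr$variance_explained), 1 + 1e-12)
})
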