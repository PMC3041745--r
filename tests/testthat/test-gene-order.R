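test_that("the major-gene order of the published table is extracted", {
  o <- orderFromFeatures(calanusTable(), include = c("PCG", "rRNA"))
  expect_length(o, 15L)
  expect_equal(orderGenes(o)[1:4], c("rrnL", "cox1", "nad4L", "cytb"))
  expect_equal(orientations(o)[1:4], c(1L, -1L, 1L, -1L))
  expect_equal(tail(orderGenes(o), 2), c("atp8", "atp6"))
  single <- mitoFeatureTable(
    data.frame(name = "cox1", kind = "PCG", strand = "H", start = 1L,
               end = 9L, start_codon = "ATG", stop_codon = "TAA"),
    topology = "linear", totalLength = 9L)
  expect_length(orderFromFeatures(single), 1L)
  expect_error(orderFromFeatures(single, include = "rRNA"),
               "empty selection")
})

test_that("comparison against the ground pattern finds the two famous
           retained borders", {
  cmp <- compareGeneOrders(orderFromFeatures(calanusTable()),
                           arthropodGroundPattern())
  keys <- with(cmp$retained_adjacencies, paste(gene1, gene2))
  expect_true("atp6 atp8" %in% keys)
  expect_true("cytb nad6" %in% keys)
  expect_length(cmp$shared_genes, 35L)  # trnR and trnC are unsequenced
  # the six major genes with flipped transcriptional polarity are found
  expect_true(all(c("atp6", "atp8", "nad3", "nad2", "nad1", "rrnS") %in%
                    cmp$inverted_genes))
  expect_true(cmp$inverted_fraction >= 0 && cmp$inverted_fraction <= 1)
})

test_that("an order compared to itself retains everything", {
  o <- orderFromFeatures(calanusTable(), include = c("PCG", "rRNA"))
  cmp <- compareGeneOrders(o, o)
  expect_equal(cmp$retained_count, 14L)  # 15 genes on a linear contig
  expect_length(cmp$inverted_genes, 0L)
  expect_equal(cmp$inverted_fraction, 0)
})

test_that("toy adjacency comparison matches hand enumeration", {
  p <- signedGeneOrder(c("a", "b", "c", "d"), topology = "circular",
                       anchor = "a")
  q <- signedGeneOrder(c("a", "c", "b", "d"), topology = "circular",
                       anchor = "a")
  cmp <- compareGeneOrders(p, q)
  keys <- sort(with(cmp$retained_adjacencies, paste(gene1, gene2)))
  # exhaustive listing: the d-a wrap border survives, and so does {b,c},
  # which stays adjacent (in swapped internal order) on both circles
  expect_equal(keys, c("a d", "b c"))
})

test_that("identical orders have the analytic common-interval count", {
  for (n in 3:8) {
    p <- signedGeneOrder(as.character(1:n), topology = "linear",
                         anchor = "1")
    expect_equal(commonIntervals(p, p)$count, (n + 1) * (n - 2) / 2)
  }
})

test_that("small worked examples of common intervals", {
  p <- signedGeneOrder(as.character(1:4), topology = "linear", anchor = "1")
  q <- signedGeneOrder(c("2", "1", "4", "3"), topology = "linear",
                       anchor = "2")
  r <- commonIntervals(p, q)
  expect_equal(r$count, 2L)
  got <- lapply(r$intervals, sort)
  expect_true(list(c("1", "2")) %in% got && list(c("3", "4")) %in% got)
  expect_error(
    commonIntervals(p, signedGeneOrder(c("1", "2", "9", "4"),
                                       topology = "linear", anchor = "1")),
    "gene-set mismatch")
})

test_that("common intervals equal the exhaustive subset oracle", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    p <- sample(letters[1:n])
    q <- sample(letters[1:n])
    po <- signedGeneOrder(p, topology = "linear", anchor = p[1])
    qo <- signedGeneOrder(q, topology = "linear", anchor = p[1])
    expect_equal(commonIntervals(po, qo)$count, oracleCommonIntervals(p, q))
  }
})

test_that("common intervals are symmetric and invariant under relabelling,
           rotation and reversal", {
  set.seed(52)
  n <- 7
  p <- sample(letters[1:n]); q <- sample(letters[1:n])
  po <- signedGeneOrder(p, topology = "linear", anchor = p[1])
  qo <- signedGeneOrder(q, topology = "linear", anchor = p[1])
  base <- commonIntervals(po, qo, anchor = p[1])$count
  expect_equal(commonIntervals(qo, po, anchor = p[1])$count, base)
  # relabelling
  map <- setNames(LETTERS[1:n], letters[1:n])
  expect_equal(commonIntervals(
    signedGeneOrder(unname(map[p]), topology = "linear", anchor = map[[p[1]]]),
    signedGeneOrder(unname(map[q]), topology = "linear", anchor = map[[p[1]]]))$count,
    base)
  # reversing one whole order
  qr <- signedGeneOrder(rev(q), topology = "linear", anchor = p[1])
  expect_equal(commonIntervals(po, qr, anchor = p[1])$count, base)
  # rotating circular orders does not change adjacency or interval counts
  pc <- signedGeneOrder(p, topology = "circular", anchor = p[1])
  qc <- signedGeneOrder(q, topology = "circular", anchor = p[1])
  c0 <- commonIntervals(pc, qc, anchor = p[1])$count
  rot <- function(v, k) c(v[-seq_len(k)], v[seq_len(k)])
  for (k in 1:3) {
    pr <- signedGeneOrder(rot(p, k), topology = "circular", anchor = p[1])
    expect_equal(commonIntervals(pr, qc, anchor = p[1])$count, c0)
    expect_equal(compareGeneOrders(pr, qc)$retained_count,
                 compareGeneOrders(pc, qc)$retained_count)
  }
})

test_that("gene-order text files round-trip", {
  orders <- list(
    calanus = signedGeneOrder(c("rrnL", "-cox1", "nad4L")),
    ground = signedGeneOrder(c("cox1", "cox2", "-nad5")))
  f <- tempfile(fileext = ".txt")
  writeGeneOrders(orders, f)
  back <- readGeneOrders(f)
  expect_equal(names(back), names(orders))
  for (nm in names(orders)) {
    expect_equal(orderGenes(back[[nm]]), orderGenes(orders[[nm]]))
    expect_equal(orientations(back[[nm]]), orientations(orders[[nm]]))
  }
})
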