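test_that("the published feature table parses into a validated container", {
  tab <- calanusTable()
  expect_s4_class(tab, "MitoFeatureTable")
  expect_equal(nrow(features(tab)), 35L)
  expect_equal(topology(tab), "linear")
  expect_equal(totalLength(tab), 20460L)
  expect_true(all(diff(features(tab)$start) > 0))
})

test_that("degenerate and malformed tables are handled", {
  empty <- mitoFeatureTable(NULL, topology = "linear", totalLength = 100L)
  expect_equal(nrow(features(empty)), 0L)
  expect_error(
    mitoFeatureTable(data.frame(name = "cox1", kind = "PCG", strand = "L",
                                start = 5207L, end = 3660L,
                                start_codon = "ATA", stop_codon = "TAA"),
                     topology = "linear", totalLength = 20460L),
    "end < start")
  expect_error(
    mitoFeatureTable(data.frame(name = c("cox1", "cox1"),
                                kind = "PCG", strand = "H",
                                start = c(1L, 100L), end = c(90L, 190L),
                                start_codon = "ATG", stop_codon = "TAA"),
                     topology = "linear", totalLength = 500L),
    "duplicate")
  expect_error(
    mitoFeatureTable(data.frame(name = "frobnitz", kind = "PCG",
                                strand = "H", start = 1L, end = 90L,
                                start_codon = "ATG", stop_codon = "TAA"),
                     topology = "linear", totalLength = 500L),
    "unknown gene name")
  expect_error(
    mitoFeatureTable(data.frame(name = "cox1", kind = "protein",
                                strand = "H", start = 1L, end = 90L,
                                start_codon = "ATG", stop_codon = "TAA"),
                     topology = "linear", totalLength = 500L),
    "unknown feature kind")
})

test_that("plus/minus strands are normalised to H/L", {
  tab <- mitoFeatureTable(
    data.frame(name = c("cox1", "nad2"), kind = "PCG",
               strand = c("+", "-"), start = c(1L, 200L),
               end = c(150L, 350L), start_codon = "ATG",
               stop_codon = "TAA"),
    topology = "linear", totalLength = 400L)
  expect_equal(features(tab)$strand, c("H", "L"))
})

test_that("spacer records reproduce the published intergenic arithmetic", {
  sp <- spacerTable(calanusTable())
  # trnH -> trnA is the 1770 nt control-region spacer, third LNR
  r <- sp[sp$upstream == "trnH" & sp$downstream == "trnA", ]
  expect_equal(r$spacer_nt, 1770L)
  expect_equal(r$lnr_label, "LNR3")
  # trnY/trnE is the largest overlap, 5 nt
  expect_equal(sp$spacer_nt[sp$upstream == "trnY"], -5L)
  # three overlapping borders in total, maximum 5 nt
  expect_equal(sum(sp$spacer_nt < 0), 3L)
  expect_equal(max(-sp$spacer_nt[sp$spacer_nt < 0]), 5L)
  # six long non-coding regions above the 100 nt threshold
  expect_equal(sum(!is.na(sp$lnr_label)), 6L)
  # the wrap record of the linear contig is open, never a plain spacer
  expect_true(sp$open[sp$lnr_label == "LNR1" & !is.na(sp$lnr_label)])
  expect_equal(sp$spacer_nt[!is.na(sp$lnr_label) & sp$lnr_label == "LNR1"],
               2959L)
})

test_that("abutting features have spacer 0 and single-feature tables none", {
  tab <- mitoFeatureTable(
    data.frame(name = c("cox1", "cox2"), kind = "PCG", strand = "H",
               start = c(1L, 11L), end = c(10L, 20L),
               start_codon = "ATG", stop_codon = "TAA"),
    topology = "linear", totalLength = 20L)
  sp <- spacerTable(tab)
  expect_equal(sp$spacer_nt[!sp$open], 0L)
  single <- mitoFeatureTable(
    data.frame(name = "cox1", kind = "PCG", strand = "H", start = 1L,
               end = 10L, start_codon = "ATG", stop_codon = "TAA"),
    topology = "linear", totalLength = 10L)
  expect_equal(nrow(spacerTable(single)), 0L)
})

test_that("on circular tables lengths plus spacers tile the molecule", {
  set.seed(42)
  for (i in 1:20) {
    tab <- randomFeatureTable(sample(3:8, 1L))
    if (topology(tab) != "circular") next
    sp <- spacerTable(tab)
    lens <- with(features(tab), end - start + 1L)
    expect_equal(sum(lens) + sum(sp$spacer_nt), totalLength(tab))
  }
})

test_that("per-kind length summary matches the published totals", {
  cls <- codingLengthSummary(calanusTable())
  bk <- cls$byKind
  expect_equal(bk$n[bk$kind == "PCG"], 13L)
  expect_equal(bk$total_nt[bk$kind == "PCG"], 11137L)
  pf <- cls$perFeature
  expect_equal(pf$length[pf$name == "rrnS"], 654L)
  expect_equal(pf$length[pf$name == "rrnL"], 1139L)
  empty <- mitoFeatureTable(NULL, topology = "linear", totalLength = 10L)
  expect_equal(codingLengthSummary(empty)$total_nt, 0L)
})

test_that("the validator flags declared-value inconsistencies only", {
  tab <- calanusTable()
  rep <- validateFeatureTable(tab)
  # the two alignment-estimated rRNA borders are the only declared
  # mismatches in the published profile
  expect_equal(sort(rep$name), c("trnG", "trnV"))
  expect_true(all(rep$check == "spacer_mismatch"))
  # the prose claim of a 762 nt spacer upstream of nad4 contradicts the
  # coordinates (771) and is flagged, not resolved
  claim <- validateFeatureTable(tab, data.frame(name = "nad4",
                                                intergenic = 762))
  expect_equal(claim$check, "spacer_mismatch")
  expect_equal(claim$computed, 771)
  # a declared length that disagrees with the coordinates is flagged
  bad <- validateFeatureTable(tab, data.frame(name = "trnV", length = 66))
  expect_true(any(bad$check == "length_mismatch"))
  # and a consistent row is not
  ok <- validateFeatureTable(tab, data.frame(name = "trnV", length = 65))
  expect_false(any(ok$check == "length_mismatch"))
})

test_that("TSV serialisation round-trips byte-identically and by value", {
  tab <- calanusTable()
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  writeFeatureTable(tab, f1)
  tab2 <- readFeatureTable(f1)
  writeFeatureTable(tab2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(features(tab2), features(tab))
  set.seed(99)
  for (i in 1:15) {
    t0 <- randomFeatureTable(sample(2:8, 1L))
    f <- tempfile(fileext = ".tsv")
    writeFeatureTable(t0, f)
    t1 <- readFeatureTable(f)
    expect_equal(features(t1), features(t0))
    expect_equal(topology(t1), topology(t0))
    expect_equal(totalLength(t1), totalLength(t0))
  }
})

test_that("GenBank and TSV dialects produce identical tables", {
  tab <- toyTable(sequence = {
    set.seed(1)
    s <- strsplit(randomDna(60), "")[[1]]
    cds <- paste0("ATG", paste(rep("GCA", 8), collapse = ""), "TAA")
    s[4:33] <- strsplit(cds, "")[[1]]
    paste(s, collapse = "")
  })
  gb <- tempfile(fileext = ".gb")
  seq <- as.character(genomeSequence(tab))
  writeLines(c(
    "LOCUS       SYNMITO                 60 bp    DNA     circular INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             4..33",
    '                     /gene="COX1"',
    "     tRNA            complement(41..50)",
    '                     /product="tRNA-Ala"',
    "ORIGIN",
    paste("        1", tolower(seq)),
    "//"), gb)
  got <- readGenBankFeatures(gb)
  expect_equal(features(got), features(tab))
  expect_equal(topology(got), "circular")
  expect_equal(totalLength(got), 60L)
  expect_equal(as.character(genomeSequence(got)), seq)
})
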