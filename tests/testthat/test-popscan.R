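test_that("variable-site calling classifies columns by definition", {
  same <- haplotypeAlignment(c(h1 = "ACGTACGT", h2 = "ACGTACGT"))
  expect_equal(callVariableSites(same)$summary$n_variable, 0L)
  aln <- haplotypeAlignment(c(h1 = "AAAA", h2 = "GCA-", h3 = "AAAA"))
  vs <- callVariableSites(aln)
  expect_equal(vs$sites$kind, c("substitution", "substitution", "indel"))
  expect_equal(vs$sites$transition[1], TRUE)    # A/G
  expect_equal(vs$sites$transition[2], FALSE)   # A/C
  expect_equal(vs$sites$column, c(1L, 2L, 4L))
  expect_error(callVariableSites(haplotypeAlignment(c(h1 = "ACGT"))),
               "at least 2")
})

test_that("parsimony-informative means two states in two haplotypes each", {
  aln <- haplotypeAlignment(c(h1 = "AG", h2 = "AG", h3 = "CG", h4 = "CA"))
  vs <- callVariableSites(aln)
  expect_equal(vs$sites$parsimony_informative, c(TRUE, FALSE))
})

test_that("annotated substitution sites get codon position and effect", {
  # one PCG on H covering columns 3..11 (ATG GGA TAA)
  ref <- "CCATGGGATAACC"
  tab <- mitoFeatureTable(
    data.frame(name = "nad3", kind = "PCG", strand = "H", start = 3L,
               end = 11L, start_codon = "ATG", stop_codon = "TAA"),
    topology = "linear", totalLength = nchar(ref))
  hap2 <- ref
  substr(hap2, 8, 8) <- "G"   # codon GGA (cols 6-8) -> GGG, synonymous
  hap3 <- ref
  substr(hap3, 9, 9) <- "G"   # TAA (cols 9-11) -> GAA, nonsynonymous
  aln <- haplotypeAlignment(c(h1 = ref, h2 = hap2, h3 = hap3),
                            annotation = tab)
  vs <- callVariableSites(aln)
  s8 <- vs$sites[vs$sites$column == 8, ]
  expect_equal(s8$codon_position, 3L)
  expect_equal(s8$effect, "synonymous")
  s9 <- vs$sites[vs$sites$column == 9, ]
  expect_equal(s9$codon_position, 1L)
  expect_equal(s9$effect, "nonsynonymous")
  expect_equal(s9$gene, "nad3")
})

test_that("light-strand genes are read in their own frame", {
  # L-strand PCG: H-strand slice is revcomp(ATGGGATAA) = TTATCCCAT
  ref <- "CCTTATCCCATCC"
  tab <- mitoFeatureTable(
    data.frame(name = "cox2", kind = "PCG", strand = "L", start = 3L,
               end = 11L, start_codon = "ATG", stop_codon = "TAA"),
    topology = "linear", totalLength = nchar(ref))
  # sense position p of the gene maps to genome column end - p + 1, so the
  # third position of sense codon GGA (sense pos 6) is column 6
  hap2 <- ref
  substr(hap2, 6, 6) <- "C"   # sense GGA -> GGG, synonymous
  aln <- haplotypeAlignment(c(h1 = ref, h2 = hap2), annotation = tab)
  vs <- callVariableSites(aln)
  s <- vs$sites[vs$sites$column == 6, ]
  expect_equal(s$codon_position, 3L)
  expect_equal(s$effect, "synonymous")
})

test_that("window scan frequencies are exact window counts", {
  rows <- rep(strrep("A", 400), 3)
  ch <- strsplit(rows[2], "")[[1]]; ch[250] <- "G"
  rows[2] <- paste(ch, collapse = "")
  aln <- haplotypeAlignment(setNames(rows, paste0("h", 1:3)))
  scan <- slidingWindowScan(aln, window = 200, step = 2)
  covering <- scan$starts <= 250 & scan$starts + 199 >= 250
  expect_true(all(scan$frequencies[covering] == 1 / 200))
  expect_true(all(scan$frequencies[!covering] == 0))
  expect_equal(scan$mean_frequency, 1 / 400)
  # zero variability
  quiet <- haplotypeAlignment(c(h1 = strrep("A", 300),
                                h2 = strrep("A", 300)))
  s2 <- slidingWindowScan(quiet, 200, 2)
  expect_true(all(s2$frequencies == 0))
  expect_equal(s2$mean_frequency, 0)
  expect_error(slidingWindowScan(quiet, 400), "window")
})

test_that("window track is invariant to haplotype order and mirrors
           under column reversal", {
  set.seed(61)
  g <- genAnnotatedGenome(simConfig(seed = 62))
  pop <- genPopulationAlignment(simConfig(seed = 62), g)
  m <- alnMatrix(pop$alignment)
  m <- m[, 1:2000]
  a1 <- haplotypeAlignment(apply(m, 1, paste, collapse = ""))
  a2 <- haplotypeAlignment(apply(m[sample(nrow(m)), ], 1, paste,
                                 collapse = ""))
  s1 <- slidingWindowScan(a1, 200, 2); s2 <- slidingWindowScan(a2, 200, 2)
  expect_equal(s1$frequencies, s2$frequencies)
  a3 <- haplotypeAlignment(apply(m[, ncol(m):1], 1, paste, collapse = ""))
  s3 <- slidingWindowScan(a3, 200, 2)
  expect_equal(s3$variable, rev(s1$variable))
})

test_that("hotspots merge qualifying windows and rank by density", {
  # uniform variability: no window exceeds the quantile threshold
  flat <- haplotypeAlignment(c(h1 = strrep("AC", 300),
                               h2 = strrep("GC", 300)))
  scanF <- slidingWindowScan(flat, 100, 10)
  expect_equal(nrow(hotspotRegions(scanF)), 0L)
  # one dense cluster stands out and is merged into a single region
  rows <- rep(strrep("A", 1000), 2)
  ch <- strsplit(rows[2], "")[[1]]; ch[500:540] <- "G"
  rows[2] <- paste(ch, collapse = "")
  aln <- haplotypeAlignment(setNames(rows, c("h1", "h2")))
  scan <- slidingWindowScan(aln, 100, 2)
  # threshold 0.9: the windows fully covering the cluster share the maximal
  # frequency, and a plateau wider than the quantile tail would otherwise
  # leave nothing strictly above the cut
  hs <- hotspotRegions(scan, 0.9)
  expect_equal(nrow(hs), 1L)
  expect_true(hs$start <= 500 && hs$end >= 540)
  expect_equal(hs$variable_sites, 41L)
  expect_equal(hs$bases_per_site, hs$span / 41)
})

test_that("hotspot density reproduces the published 'one in x' figures", {
  expect_equal(round(hotspotDensity(1045, 226), 1), 4.6)
  expect_equal(round(hotspotDensity(388, 22), 1), 17.6)
  expect_equal(round(hotspotDensity(214, 10), 1), 21.4)
})

test_that("microsatellite detection and allele typing work by definition", {
  ms <- findMicrosatellites(c(h1 = paste0("AAGG", "TCCTCCTCCTCC", "GGAA")),
                            motifLen = 3, minRepeats = c("3" = 4))
  expect_length(ms, 1L)
  expect_equal(ms[[1]]$motif, "TCC")
  expect_equal(ms[[1]]$per_haplotype$repeats, 4L)
  # repeat-number variation yields alleles; padding gaps are tolerated
  mk <- function(n, width) paste0(strrep("AT", n),
                                  strrep("-", width - 2 * n))
  aln <- haplotypeAlignment(c(h1 = mk(14, 60), h2 = mk(28, 60),
                              h3 = mk(14, 60)))
  loci <- findMicrosatellites(aln)
  expect_length(loci, 1L)
  expect_equal(loci[[1]]$n_alleles, 2L)
  expect_setequal(loci[[1]]$per_haplotype$repeats, c(14L, 28L))
})

test_that("homopolymer runs are not reported as higher-order motifs", {
  ms <- findMicrosatellites(c(h1 = paste0("GC", strrep("A", 12), "GC")),
                            motifLen = 1:6)
  expect_length(ms, 1L)
  expect_equal(ms[[1]]$motif, "A")
})

test_that("the generated population round-trips its programmed truth", {
  cfg <- simConfig(seed = 63)
  g <- genAnnotatedGenome(cfg)
  pop <- genPopulationAlignment(cfg, g)
  vs <- callVariableSites(pop$alignment)
  s <- vs$summary
  tr <- pop$truth
  expect_equal(s$n_substitution, tr$n_substitutions)
  expect_equal(s$n_indel, tr$n_indels)
  expect_equal(s$n_variable, tr$n_substitutions + tr$n_indels)
  expect_equal(s$n_transition_pairs, tr$n_transitions)
  expect_equal(s$n_transversion_pairs, tr$n_transversions)
  # called columns match the truth log exactly
  called <- vs$sites$column[vs$sites$kind == "substitution"]
  expect_equal(called, tr$substitution_columns$column)
  expect_equal(sort(vs$sites$column[vs$sites$kind == "indel"]),
               tr$indel_columns)
  # programmed microsatellite alleles are recovered
  loci <- findMicrosatellites(pop$alignment)
  spans <- vapply(tr$microsatellites, function(x) min(x$columns), integer(1))
  hit <- vapply(spans, function(sp)
    which(vapply(loci, function(l) l$span[1] <= sp && l$span[2] >= sp,
                 logical(1)))[1], integer(1))
  expect_false(anyNA(hit))
  expect_equal(sum(vapply(loci[hit], function(l) l$n_alleles, integer(1))),
               tr$n_alleles)
})

test_that("control-region motif scan finds poly-T runs and hairpins", {
  r <- scanControlRegionMotifs("AAAATTTTTTTTTTCCC")
  expect_equal(nrow(r$polyT), 1L)
  expect_equal(r$polyT$length, 10L)
  # constructed stem-loop: 8 bp Watson-Crick stem, 4 nt loop
  stem <- "GATTACAG"
  rc <- mitocomparator:::.revcomp(stem)
  seq <- paste0("CCCC", stem, "AAAA", rc, "CCCC")
  h <- scanControlRegionMotifs(seq)$hairpins
  expect_equal(nrow(h), 1L)
  expect_equal(h$stem, 8L)
  expect_equal(h$loop, 4L)
  expect_equal(h$start, 5L)
})

test_that("hairpin calls match a brute-force inverted-repeat search", {
  set.seed(64)
  for (i in 1:5) {
    s <- randomDna(300)
    got <- scanControlRegionMotifs(s, minStem = 5)$hairpins
    want <- oracleHairpins(s, minStem = 5)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      wantDf <- do.call(rbind, lapply(want, function(x)
        data.frame(start = x[["start"]], end = x[["end"]],
                   stem = x[["stem"]], loop = x[["loop"]])))
      o1 <- got[order(got$start, got$loop), ]
      o2 <- wantDf[order(wantDf$start, wantDf$loop), ]
      rownames(o1) <- rownames(o2) <- NULL
      expect_equal(o1, o2)
    }
  }
})
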