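.RUN_DEFAULTS <- list(
  seed = 1L,
  feature_table = NULL,    # path; NULL = synthetic genome
  alignment = NULL,        # FASTA path; NULL = synthetic population
  divergence_table = NULL, # published per-gene divergence TSV
  stages = list(genome = TRUE, skew = TRUE, codon_usage = TRUE,
                gene_order = TRUE, popscan = TRUE, divergence = TRUE),
  window = 200L, step = 2L, lnr_threshold = 100L,
  hotspot_quantile = 0.95, out_dir = "mitocomparator-report")

# write a TSV with a parameter-provenance comment header (deterministic;
# no timestamps)
.writeStamped <- function(df, file, params) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(params))
    writeLines(paste0("# ", nm, ": ", params[[nm]]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end comparative report
#'
#' Orchestrates the analysis stages over one configuration: genome
#' bookkeeping (per-kind lengths, spacers/overlaps/LNRs, validation),
#' composition and skew profiles, codon usage, gene-order comparison
#' against the arthropod ground pattern, the intraspecific polymorphism
#' scan (variable sites, window track, hotspots, microsatellites) and the
#' omega-ratio summary of a per-gene divergence table. Without input paths
#' the synthetic generators provide the data, so a complete report runs
#' from a bare seed. Re-running with an identical config produces
#' byte-identical tables.
#'
#' @param config list overriding any of: `seed`, `feature_table` (TSV
#'   path), `alignment` (FASTA path), `divergence_table` (TSV path),
#'   `stages` (named logical list), `window`, `step`, `lnr_threshold`,
#'   `hotspot_quantile`, `out_dir`. A path to a YAML file with those keys
#'   is also accepted (requires the yaml package). Unknown keys are
#'   rejected.
#' @param outDir output directory (overrides `config$out_dir`).
#' @return invisibly, the named vector of files written.
#' @export
runReport <- function(config = list(), outDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(.RUN_DEFAULTS))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.RUN_DEFAULTS, config)
  if (!is.null(outDir)) cfg$out_dir <- outDir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  put <- function(name, df, extra = list()) {
    f <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    .writeStamped(df, f, c(list(seed = cfg$seed), extra))
    out[[name]] <<- f
  }

  genome <- .stage("genome", {
    if (!is.null(cfg$feature_table)) readFeatureTable(cfg$feature_table)
    else genAnnotatedGenome(simConfig(seed = cfg$seed))
  })

  if (isTRUE(cfg$stages$genome)) .stage("genome", {
    cls <- codingLengthSummary(genome)
    put("genome_summary", cls$byKind)
    put("feature_lengths", cls$perFeature)
    put("spacers", spacerTable(genome, cfg$lnr_threshold),
        list(lnr_threshold = cfg$lnr_threshold))
    put("validation", validateFeatureTable(genome))
  })

  if (isTRUE(cfg$stages$skew) && !is.null(genomeSequence(genome)))
    .stage("skew", {
      put("skew_profiles", geneSkewProfiles(genome, byCodonPosition = TRUE))
    })

  if (isTRUE(cfg$stages$codon_usage) && !is.null(genomeSequence(genome)))
    .stage("codon_usage", {
      ft <- features(genome)
      pcg <- which(ft$kind == "PCG")
      cds <- vapply(pcg, function(i) {
        s <- .senseSeq(genome, i)
        substr(s, 1L, 3L * (nchar(s) %/% 3L))
      }, character(1L))
      put("codon_usage", codonUsage(cds))
    })

  if (isTRUE(cfg$stages$gene_order)) .stage("gene_order", {
    cmp <- compareGeneOrders(orderFromFeatures(genome, c("PCG", "rRNA")),
                             arthropodGroundPattern(includeTrn = FALSE))
    put("gene_order_comparison",
        data.frame(metric = c("shared_genes", "retained_adjacencies",
                              "inverted_genes", "inverted_fraction"),
                   value = c(length(cmp$shared_genes), cmp$retained_count,
                             length(cmp$inverted_genes),
                             cmp$inverted_fraction)))
    put("retained_adjacencies", cmp$retained_adjacencies)
  })

  if (isTRUE(cfg$stages$popscan)) .stage("popscan", {
    aln <- if (!is.null(cfg$alignment)) {
      if (!file.exists(cfg$alignment))
        stop("alignment file not found: ", cfg$alignment)
      haplotypeAlignment(Biostrings::readDNAStringSet(cfg$alignment))
    } else genPopulationAlignment(simConfig(seed = cfg$seed),
                                  reference = genome)$alignment
    vs <- callVariableSites(aln)
    put("variable_sites", vs$sites)
    put("variable_site_summary",
        data.frame(metric = names(unlist(vs$summary)),
                   value = unlist(vs$summary)))
    scan <- slidingWindowScan(aln, cfg$window, cfg$step)
    put("window_track",
        data.frame(start = scan$starts, frequency = scan$frequencies),
        list(window = cfg$window, step = cfg$step,
             mean_frequency = scan$mean_frequency))
    put("hotspots", hotspotRegions(scan, cfg$hotspot_quantile),
        list(quantile = cfg$hotspot_quantile,
             rule = "windows above the frequency quantile, merged"))
    ms <- findMicrosatellites(aln)
    put("microsatellites", if (length(ms)) do.call(rbind, lapply(ms,
      function(x) data.frame(motif = x$motif, start = x$span[1L],
                             end = x$span[2L], n_alleles = x$n_alleles)))
      else data.frame(motif = character(), start = integer(),
                      end = integer(), n_alleles = integer()))
  })

  if (isTRUE(cfg$stages$divergence) && !is.null(cfg$divergence_table))
    .stage("divergence", {
      tab <- readDivergenceTable(cfg$divergence_table)
      os <- omegaRatioSummary(tab)
      put("omega_ratios",
          rbind(os$per_gene,
                data.frame(gene = "overall", ratio = os$overall_ratio)))
    })

  invisible(out)
}
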