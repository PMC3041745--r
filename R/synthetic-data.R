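# run fn with a locally-seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fn()
}

#' Feature template of the Calanus sinicus-like synthetic genome
#'
#' The default generator template: the 35-feature annotation shape of the
#' C. sinicus mitochondrial contig (names, kinds, strands, coordinates,
#' start/stop codons), read from the packaged feature table.
#'
#' @return data.frame of features plus attributes `topology` and
#'   `total_length`.
#' @export
calanusFeatureTemplate <- function() {
  tab <- readFeatureTable(system.file("extdata",
                                      "calanus_sinicus_features.tsv",
                                      package = "mitocomparator"))
  ft <- features(tab)
  attr(ft, "topology") <- topology(tab)
  attr(ft, "total_length") <- totalLength(tab)
  ft
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Identical configs
#' and seeds give identical outputs (a single Mersenne-Twister stream per
#' generator call). Counts (substitutions, indel columns, transitions,
#' microsatellite repeat numbers) are placed deterministically to hit the
#' configured totals exactly, so downstream recovery tests are exact rather
#' than statistical.
#'
#' @param seed integer seed.
#' @param template feature template (default [calanusFeatureTemplate()]).
#' @param composition target base fractions of the H strand (default the
#'   C. sinicus composition A 0.321, C 0.191, G 0.193, T 0.296).
#' @param population list: `n_haplotypes` (11), `n_substitutions` (191),
#'   `n_indel_columns` (104, microsatellite gap padding included),
#'   `transition_fraction` (0.87), `microsatellites` (list of loci, each
#'   with `motif` and per-haplotype `repeats`).
#' @param divergence list: `omega` (target dN/dS), `codons` (CDS length in
#'   codons), `subs_per_codon` (total substitution density), `n_pairs`.
#' @param rates list for the rate-class alignment: `class_rates`,
#'   `sites_per_class`, `n_groups`, `taxa_per_group`.
#' @return list of class `mc_sim_config`.
#' @export
simConfig <- function(seed = 1L,
                      template = calanusFeatureTemplate(),
                      composition = c(A = 0.321, C = 0.191,
                                      G = 0.193, T = 0.296),
                      population = list(),
                      divergence = list(),
                      rates = list()) {
  # shallow by-name merge: nested defaults (e.g. the microsatellite list)
  # are replaced wholesale, never merged element-wise
  mergeCfg <- function(defaults, override) {
    stopifnot(is.list(override))
    defaults[names(override)] <- override
    defaults
  }
  pop <- mergeCfg(list(
    n_haplotypes = 11L, n_substitutions = 191L, n_indel_columns = 104L,
    transition_fraction = 0.87,
    microsatellites = list(
      list(motif = "TCC", repeats = c(4L, 4L, 4L, 5L, 5L, 4L, 4L, 4L, 4L,
                                      4L, 4L)),
      list(motif = "TA", repeats = c(14L, 28L, 14L, 20L, 28L, 14L, 14L,
                                     20L, 28L, 14L, 14L)),
      list(motif = "TA", repeats = c(10L, 12L, 10L, 10L, 12L, 10L, 10L,
                                     10L, 12L, 10L, 10L)))), population)
  div <- mergeCfg(list(omega = 0.2, codons = 300L,
                       subs_per_codon = 0.15, n_pairs = 1L), divergence)
  rts <- mergeCfg(list(class_rates = 0:3, sites_per_class = 50L,
                       n_groups = 2L, taxa_per_group = 4L), rates)
  structure(list(seed = as.integer(seed), template = template,
                 composition = composition, population = pop,
                 divergence = div, rates = rts),
            class = "mc_sim_config")
}

.sampleBases <- function(n, composition) {
  if (n <= 0L) return(character())
  sample(names(composition), n, replace = TRUE, prob = composition)
}

# random sense-strand CDS body codons avoiding stop codons
.sampleCodons <- function(n, composition, stops) {
  if (n <= 0L) return(character())
  out <- character(n)
  filled <- 0L
  while (filled < n) {
    cand <- paste0(.sampleBases(n - filled, composition),
                   .sampleBases(n - filled, composition),
                   .sampleBases(n - filled, composition))
    cand <- cand[!cand %in% stops]
    take <- utils::head(cand, n - filled)
    if (length(take)) out[filled + seq_along(take)] <- take
    filled <- filled + length(take)
  }
  out
}

#' Generate an annotated synthetic mitogenome
#'
#' Builds a genome whose annotation equals the template exactly and whose
#' sequence matches the target composition closely (within about 1% at the
#' default length): intergenic and RNA-gene regions are drawn from the
#' target composition; protein-coding regions carry the template's start
#' codon, stop-free random body codons and the template's (possibly
#' truncated) stop codon, written in reverse complement for light-strand
#' genes. The result passes [validateFeatureTable()] with no flags.
#'
#' @param cfg an [simConfig()] object.
#' @return a [MitoFeatureTable-class] with sequence.
#' @export
genAnnotatedGenome <- function(cfg) {
  .withSeed(cfg$seed, function() {
    ft <- cfg$template
    total <- attr(ft, "total_length")
    code <- mitoGeneticCode()
    genome <- .sampleBases(total, cfg$composition)
    for (i in seq_len(nrow(ft))) {
      if (ft$kind[i] != "PCG") next
      len <- ft$end[i] - ft$start[i] + 1L
      stopc <- ft$stop_codon[i]
      body <- (len - 3L - nchar(stopc)) / 3L
      if (body != floor(body)) stop("infeasible template: '", ft$name[i],
                                    "' length incompatible with its codons")
      cds <- paste0(ft$start_codon[i],
                    paste(.sampleCodons(body, cfg$composition, code$stops),
                          collapse = ""),
                    stopc)
      if (ft$strand[i] == "L") cds <- .revcomp(cds)
      genome[ft$start[i]:ft$end[i]] <- strsplit(cds, "", fixed = TRUE)[[1L]]
    }
    # repair pass: the stop-codon rejection inside PCG bodies biases the
    # realised composition slightly; flip non-PCG positions until the
    # genome-wide counts match the target (to rounding)
    pcg <- rep(FALSE, total)
    for (i in which(ft$kind == "PCG")) pcg[ft$start[i]:ft$end[i]] <- TRUE
    target <- round(cfg$composition / sum(cfg$composition) * total)
    repeat {
      realised <- vapply(names(target), function(b) sum(genome == b),
                         numeric(1L))
      delta <- target - realised
      need <- names(target)[delta >= 1]
      over <- names(target)[delta <= -1]
      if (!length(need) || !length(over)) break
      b <- need[which.max(delta[need])]
      d <- over[which.min(delta[over])]
      k <- min(delta[[b]], -delta[[d]])
      cand <- which(!pcg & genome == d)
      k <- min(k, length(cand))
      if (k < 1L) break
      genome[sample(cand, k)] <- b
    }
    mitoFeatureTable(ft, topology = attr(ft, "topology"),
                     totalLength = total,
                     sequence = paste(genome, collapse = ""))
  })
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSION <- c(A = "C", G = "T", C = "A", T = "G")

#' Generate a multi-haplotype population alignment with known truth
#'
#' Derives `n_haplotypes` rows from a reference genome: exactly
#' `n_substitutions` biallelic substitution columns (the first
#' `round(transition_fraction * n_substitutions)` of them transitions, the
#' rest transversions), exactly `n_indel_columns` gap-bearing columns
#' confined to non-coding regions (microsatellite repeat-number padding is
#' counted against this total first, plain gap columns make up the rest),
#' and the configured microsatellite loci with programmed per-haplotype
#' repeat numbers. The machine-readable ground truth is returned alongside
#' the alignment.
#'
#' @param cfg an [simConfig()] object.
#' @param reference a [MitoFeatureTable-class] with sequence (default
#'   `genAnnotatedGenome(cfg)`).
#' @return list with `alignment` (a [HaplotypeAlignment-class] annotated
#'   with `reference`) and `truth` (list: `substitution_columns` data.frame,
#'   `indel_columns`, `microsatellites`, `n_substitutions`, `n_indels`,
#'   `n_transitions`, `n_transversions`, `n_alleles`).
#' @export
genPopulationAlignment <- function(cfg, reference = genAnnotatedGenome(cfg)) {
  .withSeed(cfg$seed + 1L, function() {
    pop <- cfg$population
    n <- pop$n_haplotypes
    ft <- reference@features
    L <- reference@totalLength
    refseq <- strsplit(as.character(reference@sequence), "",
                       fixed = TRUE)[[1L]]
    m <- matrix(rep(refseq, each = n), nrow = n)
    rownames(m) <- sprintf("hap%02d", seq_len(n))

    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(ft))) covered[ft$start[i]:ft$end[i]] <- TRUE
    # non-coding columns, away from the unsequenced head/tail of the contig
    inner <- seq.int(min(ft$start), max(ft$end))
    ncrCols <- inner[!covered[inner]]

    # --- microsatellite loci, placed left-to-right in the largest NCR runs
    runs <- split(ncrCols, cumsum(c(1L, diff(ncrCols) != 1L)))
    runs <- runs[order(-vapply(runs, length, integer(1L)))]
    msTruth <- list()
    used <- logical(L)
    msGapCols <- integer()
    run <- runs[[1L]]
    offset <- 5L  # margin inside the run
    for (li in seq_along(pop$microsatellites)) {
      lc <- pop$microsatellites[[li]]
      k <- nchar(lc$motif)
      reps <- rep_len(lc$repeats, n)
      width <- max(reps) * k
      if (offset + width + 1L > length(run))
        stop("counts infeasible for region sizes: microsatellite locus ",
             li, " does not fit the largest non-coding run")
      cols <- run[offset + seq_len(width)]
      # guard columns: a base absent from the motif insulates the locus so
      # the programmed repeat number cannot be extended by its flanks
      guard <- setdiff(c("C", "G", "A", "T"),
                       strsplit(lc$motif, "", fixed = TRUE)[[1L]])[1L]
      gcols <- run[c(offset, offset + width + 1L)]
      m[, gcols] <- guard
      used[gcols] <- TRUE
      for (h in seq_len(n)) {
        s <- strrep(lc$motif, reps[h])
        filled <- nchar(s)
        m[h, cols] <- c(strsplit(s, "", fixed = TRUE)[[1L]],
                        rep("-", width - filled))
      }
      gapCols <- if (min(reps) < max(reps))
        cols[(min(reps) * k + 1L):width] else integer()
      msGapCols <- c(msGapCols, gapCols)
      used[cols] <- TRUE
      msTruth[[li]] <- list(motif = lc$motif, columns = cols,
                            repeats = reps,
                            alleles = unique(vapply(reps, function(r)
                              strrep(lc$motif, r), character(1L))))
      offset <- offset + width + 10L
    }

    # --- plain indel columns (gap in a random proper subset of haplotypes)
    remaining <- pop$n_indel_columns - length(msGapCols)
    if (remaining < 0L)
      stop("n_indel_columns smaller than the microsatellite gap padding (",
           length(msGapCols), ")")
    free <- setdiff(ncrCols, which(used))
    if (remaining > length(free))
      stop("counts infeasible for region sizes: not enough non-coding ",
           "columns for the requested indel columns")
    indelCols <- sort(sample(free, remaining))
    for (j in indelCols) {
      carriers <- sample(n, sample.int(n - 1L, 1L))
      m[carriers, j] <- "-"
    }
    used[indelCols] <- TRUE

    # --- substitution columns (biallelic, deterministic ts/tv split)
    candidates <- intersect(inner, which(!used))
    if (pop$n_substitutions > length(candidates))
      stop("counts infeasible: not enough columns for substitutions")
    subCols <- sort(sample(candidates, pop$n_substitutions))
    nTs <- round(pop$transition_fraction * pop$n_substitutions)
    isTs <- seq_along(subCols) %in% seq_len(nTs)
    subTruth <- data.frame(column = subCols,
                           ref = as.character(refseq[subCols]),
                           alt = rep(NA_character_, length(subCols)),
                           class = ifelse(isTs, "transition",
                                          "transversion"),
                           stringsAsFactors = FALSE)
    for (k in seq_along(subCols)) {
      j <- subCols[k]
      ref <- refseq[j]
      alt <- if (isTs[k]) .TRANSITION[[ref]] else .TRANSVERSION[[ref]]
      carriers <- sample(n, sample.int(n - 1L, 1L))
      m[carriers, j] <- alt
      subTruth$alt[k] <- alt
    }

    aln <- haplotypeAlignment(
      setNames(apply(m, 1L, paste, collapse = ""), rownames(m)),
      annotation = reference)
    truth <- list(
      substitution_columns = subTruth,
      indel_columns = sort(c(indelCols, msGapCols)),
      microsatellites = msTruth,
      n_substitutions = length(subCols),
      n_indels = length(indelCols) + length(msGapCols),
      n_transitions = sum(isTs), n_transversions = sum(!isTs),
      n_alleles = sum(vapply(msTruth, function(x) length(x$alleles),
                             integer(1L))))
    list(alignment = aln, truth = truth)
  })
}

#' Generate coding-sequence pairs evolved at a target dN/dS
#'
#' Builds an ancestor CDS (stop-free body) and a derived copy carrying
#' `round(subs_per_codon * codons)` single-base substitutions, at most one
#' per codon, accepted or rejected so that the realised
#' nonsynonymous:synonymous split matches the target omega relative to the
#' Nei-Gojobori site opportunities of the ancestor. A truth log with the
#' realised counts accompanies every pair.
#'
#' @param cfg an [simConfig()] object (see the `divergence` settings).
#' @return list of `cfg$divergence$n_pairs` elements, each with `a`, `b`
#'   (in-frame CDS strings) and `truth` (list `nd`, `sd`, `N`, `S`,
#'   `omega_target`, `omega_realised`).
#' @export
genCodonPairSet <- function(cfg) {
  div <- cfg$divergence
  if (div$omega < 0) stop("omega target must be >= 0")
  if (div$codons < 50L) stop("need at least 50 codons")
  code <- mitoGeneticCode()$code
  syn <- .synSites(code)
  bases <- c("A", "C", "G", "T")
  .withSeed(cfg$seed + 2L, function() {
    lapply(seq_len(div$n_pairs), function(rep) {
      anc <- .sampleCodons(div$codons, cfg$composition,
                          names(code)[code == "*"])
      S <- sum(syn[anc]); N <- 3 * div$codons - S
      if (S <= 0) stop("infeasible omega: zero synonymous opportunity")
      mTot <- round(div$subs_per_codon * div$codons)
      ndT <- round(mTot * div$omega * N / (div$omega * N + S))
      sdT <- mTot - ndT
      der <- anc
      nd <- sd <- 0L
      for (ci in sample(div$codons)) {
        if (nd >= ndT && sd >= sdT) break
        cd <- der[ci]
        ch <- strsplit(cd, "", fixed = TRUE)[[1L]]
        muts <- list()
        for (p in sample(3L)) for (b in sample(setdiff(bases, ch[p]))) {
          mut <- ch; mut[p] <- b
          muts[[length(muts) + 1L]] <- paste(mut, collapse = "")
        }
        for (mc in muts) {
          if (code[[mc]] == "*") next
          isSyn <- code[[mc]] == code[[cd]]
          if (isSyn && sd < sdT) { der[ci] <- mc; sd <- sd + 1L; break }
          if (!isSyn && nd < ndT) { der[ci] <- mc; nd <- nd + 1L; break }
        }
      }
      list(a = paste(anc, collapse = ""), b = paste(der, collapse = ""),
           truth = list(nd = nd, sd = sd, N = N, S = S,
                        omega_target = div$omega,
                        omega_realised = (nd / N) / (sd / S)))
    })
  })
}

#' Generate an amino-acid alignment with programmed site-rate classes
#'
#' Sites are drawn from the configured rate classes; a site of rate r
#' carries exactly r extra amino-acid states distributed round-robin over
#' the groups (each extra state given to a fresh taxon of the group), so
#' the summed within-group distinct-state count minus one equals r by
#' construction. Truth labels are attached.
#'
#' @param cfg an [simConfig()] object (see the `rates` settings).
#' @return list with `alignments` (named list with one gene, `sim`: named
#'   character vector of aa sequences), `groups` (taxon -> group map) and
#'   `truth` (data.frame `column`, `rate_class`).
#' @export
genRateClassAlignment <- function(cfg) {
  r <- cfg$rates
  if (r$n_groups < 2L || r$taxa_per_group < 2L)
    stop("need at least 2 groups with at least 2 taxa each")
  if (max(r$class_rates) > r$n_groups * (r$taxa_per_group - 1L))
    stop("infeasible class sizes: rate exceeds group capacity")
  .withSeed(cfg$seed + 3L, function() {
    taxa <- paste0("g", rep(seq_len(r$n_groups), each = r$taxa_per_group),
                   "_t", rep(seq_len(r$taxa_per_group), r$n_groups))
    groups <- setNames(rep(paste0("G", seq_len(r$n_groups)),
                           each = r$taxa_per_group), taxa)
    aaPool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    classes <- rep(r$class_rates, each = r$sites_per_class)
    classes <- sample(classes)  # shuffle site order
    m <- matrix("", nrow = length(taxa), ncol = length(classes),
                dimnames = list(taxa, NULL))
    for (j in seq_along(classes)) {
      base <- sample(aaPool, 1L)
      m[, j] <- base
      rate <- classes[j]
      if (rate > 0L) {
        extras <- sample(setdiff(aaPool, base), rate)
        grpIdx <- rep_len(seq_len(r$n_groups), rate)
        slot <- integer(r$n_groups)  # next fresh taxon per group
        for (e in seq_len(rate)) {
          g <- grpIdx[e]
          slot[g] <- slot[g] + 1L
          taxon <- (g - 1L) * r$taxa_per_group + 1L + slot[g]
          m[taxon, j] <- extras[e]
        }
      }
    }
    list(alignments = list(sim = setNames(apply(m, 1L, paste, collapse = ""),
                                          taxa)),
         groups = groups,
         truth = data.frame(column = seq_along(classes),
                            rate_class = classes))
  })
}
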