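# map alignment column -> feature row (PCG wins where annotations overlap)
.columnFeature <- function(anno, col) {
  ft <- anno@features
  hit <- which(ft$start <= col & ft$end >= col)
  if (!length(hit)) return(NA_integer_)
  pcg <- hit[ft$kind[hit] == "PCG"]
  if (length(pcg)) pcg[1L] else hit[1L]
}

# observed codon (sense strand) of haplotype row `h` covering column `col`
# of PCG row `i`; returns NA when the codon is incomplete or gapped
.observedCodon <- function(m, anno, i, col, h) {
  ft <- anno@features
  if (ft$strand[i] == "H") {
    off <- col - ft$start[i]
    ci <- off %/% 3L
    cols <- ft$start[i] + ci * 3L + 0:2
    if (cols[3L] > ft$end[i]) return(NA_character_)
    cd <- paste(m[h, cols], collapse = "")
  } else {
    off <- ft$end[i] - col
    ci <- off %/% 3L
    cols <- ft$end[i] - ci * 3L - (0:2)
    if (cols[3L] < ft$start[i]) return(NA_character_)
    cd <- .revcomp(paste(m[h, rev(cols)], collapse = ""))
  }
  if (grepl("^[ACGT]{3}$", cd)) cd else NA_character_
}

#' Call and classify variable sites in a haplotype alignment
#'
#' A column is variable iff it shows two or more distinct states (a gap
#' counts as a state). Columns where a gap participates are indel sites;
#' the others are substitutions, classified as transition/transversion when
#' biallelic (for multi-allelic columns the transition/transversion tally in
#' the summary counts every distinct unordered state pair). A site is
#' parsimony-informative when at least two states are each carried by at
#' least two haplotypes. When the alignment is annotated, substitution
#' sites inside protein-coding genes get their codon position and a
#' synonymous/nonsynonymous classification from the observed haplotype
#' codons (sites in overlapping annotations are resolved to the PCG).
#'
#' @param a a [HaplotypeAlignment-class] with at least 2 haplotypes.
#' @param table codon table from [mitoGeneticCode()].
#' @return list with `sites` (data.frame: `column`, `kind`, `states`,
#'   `transition`, `parsimony_informative`, `gene`, `codon_position`,
#'   `effect`) and `summary` (list of exact counts: `n_variable`,
#'   `n_substitution`, `n_indel`, `n_transition_pairs`,
#'   `n_transversion_pairs`, `transition_fraction`,
#'   `n_parsimony_informative`, `parsimony_informative_fraction`,
#'   `codon_position_counts`, `n_synonymous`, `n_nonsynonymous`).
#' @export
callVariableSites <- function(a, table = mitoGeneticCode()) {
  m <- alnMatrix(a)
  if (nrow(m) < 2L) stop("need at least 2 haplotypes")
  L <- ncol(m)
  anno <- a@annotation

  nStates <- apply(m, 2L, function(col) length(unique(col)))
  varCols <- which(nStates >= 2L)
  rows <- vector("list", length(varCols))
  tsPairs <- tvPairs <- 0L
  for (k in seq_along(varCols)) {
    j <- varCols[k]
    col <- m[, j]
    tab <- table(col)
    states <- names(tab)
    isIndel <- "-" %in% states
    kind <- if (isIndel) "indel" else "substitution"
    transition <- NA
    if (!isIndel) {
      prs <- utils::combn(states, 2L)
      ts <- .isTransition(prs[1L, ], prs[2L, ])
      tsPairs <- tsPairs + sum(ts)
      tvPairs <- tvPairs + sum(!ts)
      if (length(states) == 2L) transition <- ts[1L]
    }
    pi <- sum(tab >= 2L) >= 2L
    gene <- NA_character_; cpos <- NA_integer_; effect <- NA_character_
    if (!is.null(anno) && !isIndel) {
      i <- .columnFeature(anno, j)
      if (!is.na(i)) {
        gene <- anno@features$name[i]
        if (anno@features$kind[i] == "PCG") {
          ft <- anno@features
          off <- if (ft$strand[i] == "H") j - ft$start[i] else ft$end[i] - j
          cpos <- off %% 3L + 1L
          cods <- vapply(seq_len(nrow(m)), function(h)
            .observedCodon(m, anno, i, j, h), character(1L))
          cods <- unique(cods[!is.na(cods)])
          if (length(cods) >= 2L) {
            aas <- unique(unname(table$code[cods]))
            effect <- if (length(aas) == 1L) "synonymous" else "nonsynonymous"
          }
        }
      }
    }
    rows[[k]] <- data.frame(
      column = j, kind = kind, states = paste(states, collapse = "/"),
      transition = transition, parsimony_informative = pi, gene = gene,
      codon_position = cpos, effect = effect, stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, rows)
    else data.frame(column = integer(), kind = character(),
                    states = character(), transition = logical(),
                    parsimony_informative = logical(), gene = character(),
                    codon_position = integer(), effect = character(),
                    stringsAsFactors = FALSE)
  sub <- sites$kind == "substitution"
  summary <- list(
    n_variable = nrow(sites),
    n_substitution = sum(sub),
    n_indel = sum(!sub),
    n_transition_pairs = tsPairs,
    n_transversion_pairs = tvPairs,
    transition_fraction = if (tsPairs + tvPairs > 0)
      tsPairs / (tsPairs + tvPairs) else NA_real_,
    n_parsimony_informative = sum(sites$parsimony_informative[sub]),
    parsimony_informative_fraction = if (any(sub))
      mean(sites$parsimony_informative[sub]) else NA_real_,
    codon_position_counts = vapply(1:3, function(p)
      sum(sites$codon_position[sub] == p, na.rm = TRUE), integer(1L)),
    n_synonymous = sum(sites$effect[sub] == "synonymous", na.rm = TRUE),
    n_nonsynonymous = sum(sites$effect[sub] == "nonsynonymous",
                          na.rm = TRUE),
    alignment_length = L)
  list(sites = sites, summary = summary)
}

#' Sliding-window variable-site frequency track
#'
#' Window w covers columns [start, start + window - 1]; its frequency is
#' the number of variable columns in the window divided by the window
#' length. Windows advance by `step`; a final partial window is dropped.
#'
#' @param a a [HaplotypeAlignment-class].
#' @param window window length in columns (default 200).
#' @param step slide in columns (default 2).
#' @return list with `window`, `step`, `starts`, `frequencies`,
#'   `mean_frequency` (total variable sites / alignment length) and
#'   `variable` (per-column logical track).
#' @export
slidingWindowScan <- function(a, window = 200L, step = 2L) {
  m <- alnMatrix(a)
  L <- ncol(m)
  if (window > L) stop("window larger than alignment")
  v <- apply(m, 2L, function(col) length(unique(col)) >= 2L)
  cs <- c(0L, cumsum(v))
  starts <- seq.int(1L, L - window + 1L, by = step)
  freq <- (cs[starts + window] - cs[starts]) / window
  list(window = as.integer(window), step = as.integer(step),
       starts = starts, frequencies = freq,
       mean_frequency = sum(v) / L, variable = v)
}

#' Hotspot regions of a window scan
#'
#' Windows whose frequency exceeds the given quantile of all window
#' frequencies are merged when they overlap; each merged region reports its
#' span, the variable sites inside it, and the bases-per-variable-site
#' density (span length / variable sites). Regions are ranked densest
#' first. The quantile-threshold-plus-merge definition is this package's
#' operational rule for "hotspot"; reports carry it explicitly.
#'
#' @param scan result of [slidingWindowScan()].
#' @param threshold frequency quantile (default 0.95); windows strictly
#'   above it qualify.
#' @return data.frame with columns `start`, `end`, `span`,
#'   `variable_sites`, `bases_per_site`, ranked by increasing
#'   `bases_per_site`; zero rows when no window qualifies.
#' @seealso [hotspotDensity()]
#' @export
hotspotRegions <- function(scan, threshold = 0.95) {
  thr <- quantile(scan$frequencies, threshold, names = FALSE)
  hot <- which(scan$frequencies > thr)
  if (!length(hot))
    return(data.frame(start = integer(), end = integer(), span = integer(),
                      variable_sites = integer(), bases_per_site = numeric()))
  ws <- scan$starts[hot]
  we <- ws + scan$window - 1L
  ord <- order(ws)
  ws <- ws[ord]; we <- we[ord]
  # merge overlapping windows
  rs <- ws[1L]; re <- we[1L]; regions <- list()
  for (k in seq_along(ws)[-1L]) {
    if (ws[k] <= re + 1L) re <- max(re, we[k])
    else { regions[[length(regions) + 1L]] <- c(rs, re); rs <- ws[k]; re <- we[k] }
  }
  regions[[length(regions) + 1L]] <- c(rs, re)
  cs <- c(0L, cumsum(scan$variable))
  out <- do.call(rbind, lapply(regions, function(r) {
    n <- cs[r[2L] + 1L] - cs[r[1L]]
    data.frame(start = r[1L], end = r[2L], span = r[2L] - r[1L] + 1L,
               variable_sites = n,
               bases_per_site = if (n > 0) (r[2L] - r[1L] + 1L) / n
                                else NA_real_)
  }))
  out[order(out$bases_per_site), , drop = FALSE]
}

#' Bases per variable site of a region
#'
#' The density statistic reported for hotspot regions: region span in bases
#' divided by the variable sites it contains ("1 in x" notation).
#'
#' @param bases region span (nt).
#' @param sites variable sites within the region.
#' @return bases / sites.
#' @examples
#' hotspotDensity(1045, 226)  # 4.6
#' @export
hotspotDensity <- function(bases, sites) bases / sites

# maximal perfect tandem repeats in one ungapped sequence
.tandemRepeats <- function(seq, motifLen, minRepeats) {
  out <- list()
  for (k in motifLen) {
    minr <- minRepeats[[as.character(k)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, minr - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      motif <- substr(seq, m[j], m[j] + k - 1L)
      # reject motifs that are powers of a shorter unit (e.g. ATAT of AT)
      primitive <- all(vapply(seq_len(k - 1L), function(d)
        k %% d != 0L ||
          motif != paste(rep(substr(motif, 1L, d), k / d), collapse = ""),
        logical(1L)))
      if (!primitive) next
      reps <- len[j] %/% k
      out[[length(out) + 1L]] <- data.frame(
        start = m[j], end = m[j] + reps * k - 1L, motif = motif,
        repeats = reps, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), repeats = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Microsatellite loci and alleles across haplotypes
#'
#' Finds maximal perfect tandem repeats (motif length 1-6) in every
#' haplotype, maps them to alignment columns, merges hits whose alignment
#' spans overlap into loci, and types alleles as the distinct full locus
#' strings (capturing both repeat-number and internal variation).
#'
#' @param a a [HaplotypeAlignment-class] (or a plain named character vector
#'   of sequences, treated as ungapped).
#' @param motifLen motif lengths to scan (default 1:6).
#' @param minRepeats named vector of minimum repeat numbers per motif
#'   length; default `c("1"=8, "2"=5, "3"=4, "4"=3, "5"=3, "6"=3)`.
#' @return list of loci; each locus is a list with `motif` (most frequent
#'   motif), `span` (merged alignment columns `c(start, end)`),
#'   `per_haplotype` (data.frame `haplotype`, `start`, `end`, `repeats`,
#'   `allele`), `alleles` (distinct strings) and `n_alleles`.
#' @export
findMicrosatellites <- function(a, motifLen = 1:6,
                                minRepeats = c("1" = 8, "2" = 5, "3" = 4,
                                               "4" = 3, "5" = 3, "6" = 3)) {
  if (is(a, "HaplotypeAlignment")) {
    m <- alnMatrix(a)
    seqs <- apply(m, 1L, paste, collapse = "")
  } else seqs <- as.character(a)
  if (is.null(names(seqs))) names(seqs) <- paste0("hap", seq_along(seqs))
  hits <- list()
  for (h in names(seqs)) {
    gapped <- toupper(seqs[[h]])
    keep <- which(strsplit(gapped, "", fixed = TRUE)[[1L]] != "-")
    plain <- gsub("-", "", gapped, fixed = TRUE)
    tr <- .tandemRepeats(plain, motifLen, minRepeats)
    if (nrow(tr)) {
      tr$haplotype <- h
      tr$aln_start <- keep[tr$start]
      tr$aln_end <- keep[tr$end]
      tr$allele <- substring(plain, tr$start, tr$end)
      hits[[h]] <- tr
    }
  }
  if (!length(hits)) return(list())
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$aln_start), , drop = FALSE]
  # cluster hits by overlapping alignment spans
  cluster <- integer(nrow(hits))
  cur <- 0L; curEnd <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$aln_start[i] > curEnd) { cur <- cur + 1L; curEnd <- hits$aln_end[i] }
    else curEnd <- max(curEnd, hits$aln_end[i])
    cluster[i] <- cur
  }
  lapply(split(hits, cluster), function(g) {
    motif <- names(sort(table(g$motif), decreasing = TRUE))[1L]
    alleles <- unique(g$allele)
    list(motif = motif,
         span = c(min(g$aln_start), max(g$aln_end)),
         per_haplotype = data.frame(
           haplotype = g$haplotype, start = g$aln_start, end = g$aln_end,
           repeats = g$repeats, allele = g$allele, stringsAsFactors = FALSE),
         alleles = alleles, n_alleles = length(alleles))
  })
}

#' Scan a control-region sequence for regulatory motifs
#'
#' Reports the motifs used to recognise mitochondrial control regions:
#' poly-T stretches (candidate replication-origin signals), hairpins
#' (inverted repeats with a Watson-Crick-paired stem and a short loop) and
#' microsatellites.
#'
#' @param seq nucleotide string.
#' @param minPolyT minimum poly-T run length (default 8).
#' @param minStem minimum stem length in bp (default 8; A-T/G-C pairs only).
#' @param loopRange allowed loop lengths in nt (default 3-30).
#' @param ... passed to [findMicrosatellites()].
#' @return list with `polyT` (data.frame `start`, `end`, `length`),
#'   `hairpins` (data.frame `start`, `end`, `stem`, `loop`; maximal stems
#'   only) and `microsatellites`.
#' @export
scanControlRegionMotifs <- function(seq, minPolyT = 8L, minStem = 8L,
                                    loopRange = c(3L, 30L), ...) {
  seq <- toupper(as.character(seq))
  if (!nchar(seq)) stop("empty sequence")
  m <- gregexpr(sprintf("T{%d,}", minPolyT), seq)[[1L]]
  polyT <- if (m[1L] == -1L)
    data.frame(start = integer(), end = integer(), length = integer())
  else data.frame(start = as.integer(m),
                  end = as.integer(m) + attr(m, "match.length") - 1L,
                  length = attr(m, "match.length"))
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  paired <- function(i, j) !is.na(comp[ch[i]]) && comp[ch[i]] == ch[j]
  hp <- list()
  for (a in seq_len(L - 1L)) {
    for (l in loopRange[1L]:loopRange[2L]) {
      b <- a + l + 1L
      if (b > L) break
      if (!paired(a, b)) next
      s <- 1L
      while (a - s >= 1L && b + s <= L && paired(a - s, b + s)) s <- s + 1L
      if (s >= minStem)
        hp[[length(hp) + 1L]] <- data.frame(
          start = a - s + 1L, end = b + s - 1L, stem = s, loop = l)
    }
  }
  hairpins <- if (length(hp)) {
    hpd <- do.call(rbind, hp)
    hpd[!duplicated(hpd), , drop = FALSE]
  } else data.frame(start = integer(), end = integer(), stem = integer(),
                    loop = integer())
  list(polyT = polyT, hairpins = hairpins,
       microsatellites = findMicrosatellites(c(cr = seq), ...))
}
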