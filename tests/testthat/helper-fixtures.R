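# shared fixtures and independent oracles for the test suite

calanusTable <- function() {
  readFeatureTable(system.file("extdata", "calanus_sinicus_features.tsv",
                               package = "mitocomparator"))
}

toyTable <- function(sequence = NULL, totalLength = 60L) {
  mitoFeatureTable(
    data.frame(name = c("cox1", "trnA"), kind = c("PCG", "tRNA"),
               strand = c("H", "L"), start = c(4L, 41L), end = c(33L, 50L),
               start_codon = c("ATG", NA), stop_codon = c("TAA", NA),
               stringsAsFactors = FALSE),
    topology = "circular", totalLength = totalLength, sequence = sequence)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# random valid feature table for fuzz round-trips
randomFeatureTable <- function(nFeatures = 6L) {
  pool <- c("cox1", "cox2", "nad2", "nad5", "cytb", "atp6", "atp8",
            "rrnS", "trnA", "trnK", "trnL1", "trnS2")
  names <- sample(pool, nFeatures)
  lens <- sample(60:300, nFeatures, replace = TRUE)
  gaps <- sample(0:40, nFeatures, replace = TRUE)
  start <- cumsum(c(1L + gaps[1L],
                    if (nFeatures > 1L) lens[-nFeatures] + gaps[-1L] + 1L))
  end <- start + lens - 1L
  kind <- ifelse(grepl("^trn", names), "tRNA",
                 ifelse(grepl("^rrn", names), "rRNA", "PCG"))
  isP <- kind == "PCG"
  # PCG lengths must fit start + body codons + stop
  lens[isP] <- (lens[isP] %/% 3L) * 3L
  end <- start + lens - 1L
  mitoFeatureTable(
    data.frame(name = names, kind = kind, strand = sample(c("H", "L"),
               nFeatures, replace = TRUE), start = start, end = end,
               start_codon = ifelse(isP, "ATG", NA),
               stop_codon = ifelse(isP, "TAA", NA),
               stringsAsFactors = FALSE),
    topology = sample(c("linear", "circular"), 1L),
    totalLength = max(end) + sample(0:50, 1L))
}

# --- independent oracles -------------------------------------------------

# brute-force 3-mer tally for codon-usage checks
oracleCodonCounts <- function(cdsSet) {
  counts <- integer()
  for (s in cdsSet) {
    i <- seq(1L, nchar(s) - 2L, by = 3L)
    for (cd in substring(s, i, i + 2L))
      counts[cd] <- ifelse(is.na(counts[cd]), 1L, counts[cd] + 1L)
  }
  counts
}

# closed-form OLS slope/intercept/R2
oracleOls <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yh <- a + b * x
  r2 <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

# exhaustive common-interval oracle over all 2^n subsets
oracleCommonIntervals <- function(p, q) {
  n <- length(p)
  posP <- seq_len(n); names(posP) <- p
  posQ <- seq_len(n); names(posQ) <- q
  contig <- function(pos) max(pos) - min(pos) == length(pos) - 1L
  count <- 0L
  for (mask in 1:(2^n - 2L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(sel) < 2L || length(sel) > n - 1L) next
    genes <- p[sel]
    if (contig(posP[genes]) && contig(posQ[genes])) count <- count + 1L
  }
  count
}

# pathway-enumeration NG86 difference oracle for one codon pair
oracleNgPair <- function(c1, c2, code) {
  d <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (!length(d)) return(c(nd = 0, sd = 0))
  perms <- if (length(d) == 1L) list(d) else {
    prm <- function(v) if (length(v) <= 1L) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(prm(v[-i]), function(r) c(v[i], r))))
    prm(d)
  }
  nd <- sd <- 0
  for (ord in perms) {
    cur <- strsplit(c1, "")[[1L]]
    tgt <- strsplit(c2, "")[[1L]]
    for (p in ord) {
      nxt <- cur; nxt[p] <- tgt[p]
      a1 <- code[[paste(cur, collapse = "")]]
      a2 <- code[[paste(nxt, collapse = "")]]
      if (a1 != "*" && a2 != "*" && a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
  }
  c(nd = nd / length(perms), sd = sd / length(perms))
}

# brute-force inverted-repeat (hairpin) search
oracleHairpins <- function(seq, minStem = 8L, loopRange = c(3L, 30L)) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  L <- length(ch)
  found <- list()
  for (a in seq_len(L)) for (l in loopRange[1L]:loopRange[2L]) {
    b <- a + l + 1L
    if (b > L) next
    if (is.na(comp[ch[a]]) || comp[ch[a]] != ch[b]) next
    s <- 1L
    while (a - s >= 1L && b + s <= L && !is.na(comp[ch[a - s]]) &&
           comp[ch[a - s]] == ch[b + s]) s <- s + 1L
    if (s >= minStem)
      found[[length(found) + 1L]] <- c(start = a - s + 1L, end = b + s - 1L,
                                       stem = s, loop = l)
  }
  unique(found)
}
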