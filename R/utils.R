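# internal string helpers (character-vector based; Biostrings objects are
# converted at the boundary so tight per-codon loops stay cheap)

.revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTUacgtuNRYSWKMBDHVnryswkmbdhv",
                "TGCAAtgcaaNYRSWMKVHDBnyrswmkvhdb", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

.splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character())
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# sense-strand sequence of feature row i (reverse complement for L strand)
.senseSeq <- function(x, i) {
  stopifnot(!is.null(x@sequence))
  ft <- x@features
  s <- as.character(Biostrings::subseq(x@sequence, ft$start[i], ft$end[i]))
  if (ft$strand[i] == "L") .revcomp(s) else s
}

.featureRow <- function(x, gene) {
  i <- match(gene, x@features$name)
  if (is.na(i)) stop("no feature named '", gene, "'")
  i
}

.isPurine <- function(b) b %in% c("A", "G")

# TRUE iff the unordered base pair is a transition
.isTransition <- function(b1, b2) {
  (.isPurine(b1) & .isPurine(b2) & b1 != b2) |
    (!.isPurine(b1) & !.isPurine(b2) & b1 != b2 &
       b1 %in% c("C", "T") & b2 %in% c("C", "T"))
}
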