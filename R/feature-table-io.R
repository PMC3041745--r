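#' Read a feature table from TSV
#'
#' Reads the tab-separated feature-table dialect: comment lines start with
#' `#`; two directive comments declare the molecule (`# topology: linear`
#' and `# total_length: 20460`); the header line names the columns
#' `name`, `kind`, `strand`, `start`, `end` and optionally `start_codon`,
#' `stop_codon` (use `.` for none) plus declared `length`/`intergenic`
#' columns that are kept aside for [validateFeatureTable()].
#'
#' @param file path to the TSV file.
#' @param sequence optional H-strand sequence (character, [Biostrings::DNAString]
#'   or path to a single-record FASTA) attached to the table.
#' @return a validated [MitoFeatureTable-class].
#' @seealso [writeFeatureTable()], [readGenBankFeatures()]
#' @examples
#' tsv <- system.file("extdata", "calanus_sinicus_features.tsv",
#'                    package = "mitocomparator")
#' tab <- readFeatureTable(tsv)
#' tab
#' @export
readFeatureTable <- function(file, sequence = NULL) {
  lines <- readLines(file)
  com <- lines[startsWith(lines, "#")]
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*[:=]"), com, value = TRUE)
    if (!length(hit)) stop("feature table must declare '", key,
                           "' in a comment directive")
    trimws(sub(paste0("^#\\s*", key, "\\s*[:=]\\s*"), "", hit[1L]))
  }
  topo <- grab("topology")
  total <- as.integer(grab("total_length"))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) < 1L) stop("missing header line")
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA"))
  need <- c("name", "kind", "strand", "start", "end")
  if (!all(need %in% names(df)))
    stop("feature table needs columns: ", paste(need, collapse = ", "))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("malformed coordinates")
  declared <- df[intersect(c("name", "length", "intergenic"), names(df))]
  if (ncol(declared) < 2L) declared <- data.frame()
  if (is.character(sequence) && length(sequence) == 1L &&
      file.exists(sequence))
    sequence <- Biostrings::readDNAStringSet(sequence)[[1L]]
  mitoFeatureTable(df[c(need, intersect(c("start_codon", "stop_codon"),
                                        names(df)))],
                   topology = topo, totalLength = total,
                   sequence = sequence, declared = declared)
}

#' Write a feature table to TSV
#'
#' Serialises a [MitoFeatureTable-class] into the canonical TSV dialect read
#' by [readFeatureTable()]. Writing, re-reading and writing again is
#' byte-identical.
#'
#' @param x a [MitoFeatureTable-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeFeatureTable <- function(x, file) {
  ft <- x@features
  out <- c(paste0("# topology: ", x@topology),
           paste0("# total_length: ", x@totalLength))
  cols <- c("name", "kind", "strand", "start", "end", "start_codon",
            "stop_codon")
  df <- ft[cols]
  df$start_codon[is.na(df$start_codon)] <- "."
  df$stop_codon[is.na(df$stop_codon)] <- "."
  if (nrow(x@declared)) {
    m <- match(df$name, x@declared$name)
    for (col in setdiff(names(x@declared), "name"))
      df[[col]] <- x@declared[[col]][m]
  }
  out <- c(out, paste(names(df), collapse = "\t"))
  if (nrow(df))
    out <- c(out, do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(out, file)
  invisible(file)
}

.GB_ALIASES <- c(
  "cox1" = "cox1", "coi" = "cox1", "co1" = "cox1",
  "cox2" = "cox2", "coii" = "cox2", "co2" = "cox2",
  "cox3" = "cox3", "coiii" = "cox3", "co3" = "cox3",
  "nd1" = "nad1", "nd2" = "nad2", "nd3" = "nad3", "nd4" = "nad4",
  "nd4l" = "nad4L", "nd5" = "nad5", "nd6" = "nad6",
  "nad1" = "nad1", "nad2" = "nad2", "nad3" = "nad3", "nad4" = "nad4",
  "nad4l" = "nad4L", "nad5" = "nad5", "nad6" = "nad6",
  "atp6" = "atp6", "atp8" = "atp8", "cytb" = "cytb", "cob" = "cytb",
  "rrns" = "rrnS", "12s" = "rrnS", "s-rrna" = "rrnS",
  "rrnl" = "rrnL", "16s" = "rrnL", "l-rrna" = "rrnL")

.AA3_TO_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
               Glu = "E", Gln = "Q", Gly = "G", His = "H", Ile = "I",
               Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
               Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

.gbGeneName <- function(gene, product, type) {
  g <- tolower(gene)
  if (!is.na(g) && g %in% names(.GB_ALIASES)) return(.GB_ALIASES[[g]])
  if (!is.na(gene) && gene %in% .MITO_GENES) return(gene)
  if (type == "tRNA" && !is.na(product)) {
    aa <- sub("^tRNA-([A-Za-z]{3}).*$", "\\1", product)
    if (aa %in% names(.AA3_TO_1)) {
      letter <- .AA3_TO_1[[aa]]
      if (letter == "L")
        letter <- if (grepl("CUN", product)) "L1" else "L2"
      if (letter == "S")
        letter <- if (grepl("AGN", product)) "S1" else "S2"
      return(paste0("trn", letter))
    }
  }
  if (!is.na(product)) {
    p <- tolower(product)
    if (grepl("12s|small subunit", p)) return("rrnS")
    if (grepl("16s|large subunit", p)) return("rrnL")
  }
  NA_character_
}

#' Read mitogenome features from a GenBank flat file
#'
#' Minimal GenBank reader covering what annotated mitogenome records need:
#' the LOCUS line (length and circular/linear topology), `CDS`, `tRNA`,
#' `rRNA`, `misc_feature` and `D-loop` features with plain or
#' `complement(...)` spans, `/gene` and `/product` qualifiers, and the
#' ORIGIN sequence. CDS start/stop codons are derived from the sequence when
#' it is present (the trailing 1-2 nt of a gene whose length is not a
#' multiple of three are annotated as a truncated stop). A TSV table and a
#' GenBank record describing the same annotation parse to the same
#' [MitoFeatureTable-class].
#'
#' @param file path to a GenBank flat file.
#' @return a validated [MitoFeatureTable-class].
#' @export
readGenBankFeatures <- function(file) {
  lines <- readLines(file)
  locus <- grep("^LOCUS", lines, value = TRUE)[1L]
  if (is.na(locus)) stop("not a GenBank flat file (no LOCUS line)")
  total <- as.integer(sub("^.*?(\\d+)\\s+bp.*$", "\\1", locus))
  topo <- if (grepl("circular", locus)) "circular" else "linear"

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  fend <- if (length(ostart)) ostart[1L] - 1L else length(lines)
  feats <- list()
  cur <- NULL
  if (length(fstart)) {
    for (ln in lines[(fstart[1L] + 1L):fend]) {
      if (grepl("^ {5}\\S", ln)) {
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        type <- sub("^ {5}(\\S+).*$", "\\1", ln)
        loc <- trimws(sub("^ {5}\\S+\\s+", "", ln))
        cur <- list(type = type, loc = loc, gene = NA_character_,
                    product = NA_character_)
      } else if (!is.null(cur)) {
        q <- trimws(ln)
        if (grepl('^/gene="', q))
          cur$gene <- sub('^/gene="([^"]*)".*$', "\\1", q)
        else if (grepl('^/product="', q))
          cur$product <- sub('^/product="([^"]*)"?.*$', "\\1", q)
        else if (!grepl("^/", q) && !grepl("=", q))
          cur$loc <- paste0(cur$loc, q)  # continued location
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }

  seq <- NULL
  if (length(ostart)) {
    body <- lines[(ostart[1L] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    if (nchar(seq)) seq <- Biostrings::DNAString(seq)
  }

  kindOf <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
              misc_feature = "NCR", "D-loop" = "NCR")
  rows <- list()
  ncr <- 0L
  for (f in feats) {
    if (!f$type %in% names(kindOf)) next
    strand <- if (grepl("complement", f$loc)) "L" else "H"
    span <- regmatches(f$loc, regexpr("\\d+\\.\\.[<>]?\\d+", f$loc))[1]
    if (is.na(span)) stop("unsupported location: ", f$loc)
    coords <- as.integer(strsplit(gsub("[<>]", "", span), "..",
                                  fixed = TRUE)[[1L]])
    kind <- kindOf[[f$type]]
    name <- if (kind == "NCR") {
      ncr <- ncr + 1L
      if (!is.na(f$gene)) f$gene else paste0("NCR", ncr)
    } else .gbGeneName(f$gene, f$product, f$type)
    if (is.na(name)) stop("cannot resolve gene name for feature at ", f$loc)
    sc <- st <- NA_character_
    if (kind == "PCG" && !is.null(seq)) {
      s <- as.character(Biostrings::subseq(seq, coords[1L], coords[2L]))
      if (strand == "L") s <- .revcomp(s)
      n <- nchar(s)
      r <- n %% 3L
      sc <- substr(s, 1L, 3L)
      st <- if (r == 0L) substr(s, n - 2L, n) else substr(s, n - r + 1L, n)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, kind = kind, strand = strand,
      start = coords[1L], end = coords[2L],
      start_codon = sc, stop_codon = st, stringsAsFactors = FALSE)
  }
  mitoFeatureTable(do.call(rbind, rows), topology = topo,
                   totalLength = total, sequence = seq)
}
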