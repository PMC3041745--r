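#' Intergenic spacers, overlaps and long non-coding regions
#'
#' Computes one record per consecutive feature pair:
#' `spacer_nt = start(downstream) - end(upstream) - 1`, so a negative value
#' is an overlap. A wrap-around record (last feature back to the first) is
#' always included for tables with two or more features; on a circular
#' molecule its spacer is the unannotated run across the origin, on a linear
#' contig the same head+tail quantity is reported with `open = TRUE`
#' (the contig ends are unsequenced, so the value is a lower bound, never a
#' plain spacer). Records whose spacer exceeds `lnrThreshold` are labelled
#' `LNR1`, `LNR2`, ... in genome order (the wrap record, sitting at the
#' molecule head, is numbered first).
#'
#' @param x a [MitoFeatureTable-class] with at least 2 features (a smaller
#'   table returns an empty set of records).
#' @param lnrThreshold minimum spacer (nt) for a long-non-coding-region
#'   label; default 100 (regions "larger than 100 bp").
#' @return data.frame with columns `upstream`, `downstream`, `spacer_nt`,
#'   `open`, `lnr_label`.
#' @examples
#' tab <- readFeatureTable(system.file("extdata",
#'   "calanus_sinicus_features.tsv", package = "mitocomparator"))
#' sp <- spacerTable(tab)
#' sp[!is.na(sp$lnr_label), ]
#' sum(sp$spacer_nt < 0)  # overlapping gene borders
#' @export
spacerTable <- function(x, lnrThreshold = 100) {
  ft <- x@features
  n <- nrow(ft)
  if (n < 2L)
    return(data.frame(upstream = character(), downstream = character(),
                      spacer_nt = integer(), open = logical(),
                      lnr_label = character(), stringsAsFactors = FALSE))
  wrap <- data.frame(
    upstream = ft$name[n], downstream = ft$name[1L],
    spacer_nt = (ft$start[1L] - 1L) + (x@totalLength - ft$end[n]),
    open = x@topology == "linear", stringsAsFactors = FALSE)
  consec <- data.frame(
    upstream = ft$name[-n], downstream = ft$name[-1L],
    spacer_nt = ft$start[-1L] - ft$end[-n] - 1L,
    open = FALSE, stringsAsFactors = FALSE)
  rec <- rbind(wrap, consec)
  rec$lnr_label <- NA_character_
  big <- rec$spacer_nt > lnrThreshold
  rec$lnr_label[big] <- paste0("LNR", seq_len(sum(big)))
  rownames(rec) <- NULL
  rec
}

#' Per-kind feature counts and total lengths
#'
#' @param x a [MitoFeatureTable-class].
#' @return list with `byKind` (data.frame `kind`, `n`, `total_nt`),
#'   `perFeature` (data.frame `name`, `kind`, `length`) and `total_nt`
#'   (sum over all features).
#' @examples
#' tab <- readFeatureTable(system.file("extdata",
#'   "calanus_sinicus_features.tsv", package = "mitocomparator"))
#' codingLengthSummary(tab)$byKind   # PCG total is 11137 nt
#' @export
codingLengthSummary <- function(x) {
  ft <- x@features
  len <- ft$end - ft$start + 1L
  byKind <- data.frame(
    kind = .FEATURE_KINDS,
    n = vapply(.FEATURE_KINDS, function(k) sum(ft$kind == k), integer(1L)),
    total_nt = vapply(.FEATURE_KINDS,
                      function(k) sum(len[ft$kind == k]), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(byKind = byKind,
       perFeature = data.frame(name = ft$name, kind = ft$kind,
                               length = len, stringsAsFactors = FALSE),
       total_nt = sum(len))
}

#' Audit a feature table against declared lengths and spacers
#'
#' Compares declared per-row lengths with `end - start + 1` and declared
#' intergenic spacers with the values recomputed by [spacerTable()]
#' (a declared spacer on row i refers to the gap between row i and its
#' upstream neighbour). Out-of-range coordinates are also flagged. All
#' problems are report rows, never exceptions; an empty report means the
#' table is fully consistent.
#'
#' @param x a [MitoFeatureTable-class].
#' @param declared data.frame with column `name` plus any of `length`,
#'   `intergenic`; defaults to the declared values read alongside the table
#'   (e.g. the published profile columns kept by [readFeatureTable()]).
#' @return data.frame with columns `name`, `check`, `declared`, `computed`;
#'   zero rows iff consistent.
#' @examples
#' tab <- readFeatureTable(system.file("extdata",
#'   "calanus_sinicus_features.tsv", package = "mitocomparator"))
#' validateFeatureTable(tab)  # flags the two alignment-estimated rRNA borders
#' # auditing a free-text claim:
#' validateFeatureTable(tab, data.frame(name = "nad4", intergenic = 762))
#' @export
validateFeatureTable <- function(x, declared = NULL) {
  if (is.null(declared)) declared <- x@declared
  ft <- x@features
  flags <- list()
  add <- function(name, check, dec, comp)
    flags[[length(flags) + 1L]] <<- data.frame(
      name = name, check = check, declared = dec, computed = comp,
      stringsAsFactors = FALSE)
  oob <- ft$start < 1L | ft$end > x@totalLength
  for (i in which(oob))
    add(ft$name[i], "coordinates_out_of_range", NA_real_,
        as.numeric(ft$end[i]))
  if (!is.null(declared) && NROW(declared) && "name" %in% names(declared)) {
    sp <- spacerTable(x)
    for (i in seq_len(nrow(declared))) {
      nm <- declared$name[i]
      j <- match(nm, ft$name)
      if (!is.na(j) && "length" %in% names(declared) &&
          !is.na(declared$length[i])) {
        comp <- ft$end[j] - ft$start[j] + 1L
        if (declared$length[i] != comp)
          add(nm, "length_mismatch", declared$length[i], comp)
      }
      if ("intergenic" %in% names(declared) && !is.na(declared$intergenic[i])) {
        k <- match(nm, sp$downstream)
        if (!is.na(k) && !sp$open[k] && declared$intergenic[i] != sp$spacer_nt[k])
          add(nm, "spacer_mismatch", declared$intergenic[i], sp$spacer_nt[k])
      }
    }
  }
  if (!length(flags))
    return(data.frame(name = character(), check = character(),
                      declared = numeric(), computed = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}
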