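# Score and interval tracks backing the conservation, overlap-annotation and
# secondary-structure feature blocks. Per-base score tracks are held as
# dense per-chromosome numeric vectors (NA = missing) so window means over
# thousands of sites are a vector lookup; files are read through
# rtracklayer and densified against known chromosome lengths.

#' Construct a per-base score track
#'
#' @param values Named list of numeric vectors, one per chromosome, with NA
#'   at positions the track does not cover.
#' @return Object of class `score_track`.
#' @export
score_track <- function(values) {
  stopifnot(is.list(values), !is.null(names(values)))
  structure(list(values = values), class = "score_track")
}

#' Read a bedGraph score track
#'
#' @param path bedGraph file (0-based half-open intervals with a value
#'   column).
#' @param chrom_lengths Named integer vector of chromosome lengths used to
#'   densify the track.
#' @return A `score_track`.
#' @export
read_score_track <- function(path, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(chrom_lengths, function(n) rep(NA_real_, n))
  names(vals) <- names(chrom_lengths)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  sc <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) {
    cc <- chrom[i]
    if (!cc %in% names(vals)) next
    vals[[cc]][st[i]:en[i]] <- sc[i]
  }
  score_track(vals)
}

#' Write a score track as bedGraph
#'
#' Adjacent equal values are run-length collapsed; NA stretches are omitted.
#'
#' @param track A `score_track`.
#' @param path Output file.
#' @export
write_score_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cc in names(track$values)) {
    v <- track$values[[cc]]
    if (all(is.na(v))) next
    r <- rle(ifelse(is.na(v), NA, v))
    pos <- cumsum(c(0L, r$lengths))
    keep <- !is.na(r$values)
    if (!any(keep)) next
    lines <- sprintf("%s\t%d\t%d\t%g", cc, pos[-length(pos)][keep],
                     pos[-1][keep], r$values[keep])
    writeLines(lines, con)
  }
  invisible(path)
}

#' Look up per-base scores
#'
#' @param track A `score_track`.
#' @param chrom Chromosome of each query position.
#' @param pos 1-based genomic positions.
#' @return Numeric vector (NA where the track is missing or the chromosome
#'   unknown).
#' @export
track_values <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    v <- track$values[[cc]]
    if (is.null(v)) next
    p <- pos[idx]
    ok <- p >= 1L & p <= length(v)
    out[idx[ok]] <- v[p[ok]]
  }
  out
}

#' Read a BED6 interval track
#'
#' @param path BED file (0-based half-open; strand column respected when
#'   present).
#' @return A `GRanges` of the intervals.
#' @export
read_interval_track <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Make an interval track from a data frame
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `strand`.
#' @return A `GRanges`.
#' @export
interval_track <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

#' Does each site fall inside a track interval?
#'
#' Strand-aware: a site on strand s overlaps intervals on strand s or on the
#' unstranded `*`.
#'
#' @param track A `GRanges` interval track (or NULL for an empty track).
#' @param chrom,pos,strand Site coordinates (1-based genomic position of the
#'   methylated adenosine).
#' @return Integer 0/1 vector.
#' @export
interval_overlap_flag <- function(track, chrom, pos, strand) {
  n <- length(pos)
  if (is.null(track) || length(track) == 0L) return(integer(n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos), strand = strand)
  hits <- GenomicRanges::findOverlaps(q, track, ignore.strand = FALSE)
  out <- integer(n)
  out[unique(S4Vectors::queryHits(hits))] <- 1L
  out
}

overlap_track_names <- function() sprintf("slot_%d", 43:55)

#' Bundle the tracks backing the genomic feature blocks
#'
#' Holds the four conservation-role score tracks (two PhastCons-role, two
#' fitCons-role), the 13-slot registry of m6A-biology interval tracks, the
#' miRNA-target interval track, and the secondary-structure provider.
#' Unset slots behave as empty tracks (score lookups return missing,
#' overlap dummies return 0).
#'
#' @param score_tracks Named list of up to 4 `score_track` objects; names
#'   must be among `phastcons_primates`, `phastcons_vertebrates`,
#'   `fitcons_1`, `fitcons_2`.
#' @param interval_tracks Named list of `GRanges`, names among
#'   `slot_43` .. `slot_55` (a configurable registry standing in for the
#'   m6A-biology annotation set).
#' @param mirna_track `GRanges` of miRNA-target regions, or NULL.
#' @param structure Structure provider from [structure_provider()].
#' @return Object of class `track_bundle`.
#' @export
track_bundle <- function(score_tracks = list(), interval_tracks = list(),
                         mirna_track = NULL,
                         structure = structure_provider("nussinov")) {
  sc_names <- conservation_track_names()
  if (length(score_tracks) && !all(names(score_tracks) %in% sc_names)) {
    stop("score track names must be among: ", paste(sc_names, collapse = ", "),
         call. = FALSE)
  }
  if (length(interval_tracks) && !all(names(interval_tracks) %in% overlap_track_names())) {
    stop("interval track names must be among slot_43..slot_55", call. = FALSE)
  }
  structure(list(score_tracks = score_tracks,
                 interval_tracks = interval_tracks,
                 mirna_track = mirna_track,
                 structure = structure),
            class = "track_bundle")
}

conservation_track_names <- function() {
  c("phastcons_primates", "phastcons_vertebrates", "fitcons_1", "fitcons_2")
}

#' Secondary-structure provider
#'
#' Structure features come either from the built-in maximum base-pairing
#' folder (`type = "nussinov"`, see [nussinov_fold()]) or from precomputed
#' dot-bracket strings keyed by `"<transcript_id>:<window_start>"`
#' (`type = "precomputed"`).
#'
#' @param type `"nussinov"` or `"precomputed"`.
#' @param structures Named character vector of dot-bracket strings (required
#'   for `"precomputed"`).
#' @return Object of class `structure_provider`.
#' @export
structure_provider <- function(type = c("nussinov", "precomputed"),
                               structures = NULL) {
  type <- match.arg(type)
  if (type == "precomputed" && (is.null(structures) || is.null(names(structures)))) {
    stop("precomputed structures require a named character vector", call. = FALSE)
  }
  structure(list(type = type, structures = structures),
            class = "structure_provider")
}

#' Read precomputed dot-bracket structures
#'
#' Two-column tab-separated file: key (`transcript_id:window_start`) and
#' dot-bracket string.
#'
#' @param path File path.
#' @return A `"precomputed"` [structure_provider()].
#' @export
read_structures <- function(path) {
  tb <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("key", "structure"))
  structure_provider("precomputed", setNames(tb$structure, tb$key))
}
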