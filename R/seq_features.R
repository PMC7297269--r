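# Sequence-derived encodings of candidate m6A sites.
#
# Each nucleotide is represented by a 4-dimensional vector: three binary
# chemical-property indicators (ring number, amino/keto group, hydrogen-bond
# strength) plus the cumulative frequency of that base up to its position.
# A candidate site is the adenosine at the centre of a 21-nt window, giving
# an 84-dimensional sequence feature vector.

.CHEM <- matrix(
  c(1, 1, 1,   # A: purine, amino, weak H-bond
    0, 1, 0,   # C: pyrimidine, amino, strong H-bond
    1, 0, 0,   # G: purine, keto, strong H-bond
    0, 0, 1,   # U: pyrimidine, keto, weak H-bond
    0, 0, 0),  # N: padding for windows truncated at transcript ends
  ncol = 3, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "U", "N"), c("x", "y", "z"))
)

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Used by every sequence-facing entry point
#' so DNA input is accepted transparently.
#'
#' @param x Character vector of sequences.
#' @return Character vector over the RNA alphabet.
#' @export
as_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

check_rna_chars <- function(chars, allow_n = FALSE) {
  valid <- c("A", "C", "G", "U", if (allow_n) "N")
  bad <- which(!chars %in% valid)
  if (length(bad) > 0) {
    stop(sprintf("invalid nucleotide '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  invisible(chars)
}

#' Chemical-property code of a nucleotide
#'
#' Encodes a base as the binary triple (x, y, z): x = 1 for purines (A, G),
#' y = 1 for amino-group bases (A, C), z = 1 for weak hydrogen bonding (A, U).
#' The mapping is a bijection over \{A, C, G, U\}: A = (1,1,1), C = (0,1,0),
#' G = (1,0,0), U = (0,0,1). T is treated as U; the padding character N maps
#' to (0,0,0) and is only accepted when `allow_n = TRUE`.
#'
#' @param base Character vector of single nucleotides.
#' @param allow_n Accept the padding character N?
#' @return Numeric matrix with one row per base and columns x, y, z.
#' @examples
#' chemical_code(c("A", "C", "G", "U"))
#' @export
chemical_code <- function(base, allow_n = FALSE) {
  base <- as_rna(base)
  check_rna_chars(base, allow_n = allow_n)
  .CHEM[base, , drop = FALSE]
}

#' Cumulative base frequencies along a sequence
#'
#' For position i holding base b, returns d_i / i where d_i counts the
#' occurrences of b within positions 1..i. The first occurrence of any base
#' is always 1/1, so all values lie in (0, 1]. Positions holding the padding
#' character N are assigned frequency 0.
#'
#' @param sequence A single RNA (or DNA) string.
#' @param allow_n Accept the padding character N?
#' @return Numeric vector of per-position cumulative frequencies.
#' @examples
#' cumulative_frequencies("ACCUGAAUUG")  # A: 1/1, 2/5, 3/6 at positions 1, 5, 6
#' @export
cumulative_frequencies <- function(sequence, allow_n = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(as_rna(sequence), "", fixed = TRUE)[[1]]
  check_rna_chars(chars, allow_n = allow_n)
  counts <- c(A = 0, C = 0, G = 0, U = 0, N = 0)
  out <- numeric(length(chars))
  for (i in seq_along(chars)) {
    b <- chars[i]
    counts[b] <- counts[b] + 1
    out[i] <- if (b == "N") 0 else counts[[b]] / i
  }
  out
}

seq_feature_names <- function(window_length = 21L) {
  as.vector(t(outer(sprintf("seq_p%02d", seq_len(window_length)),
                    c("x", "y", "z", "f"), paste, sep = "_")))
}

#' Encode a site-centred window into the sequence feature vector
#'
#' Concatenates, position by position, the chemical-property triple and the
#' cumulative base frequency, yielding 4 values per position (84 for the
#' default 21-nt window). The window is expected to be centred on the
#' candidate adenosine with 10 nt of flank on each side; windows truncated at
#' transcript ends are padded with N, which encodes as (0,0,0) with
#' frequency 0. Cumulative frequencies are computed within the window.
#'
#' @param window A string of exactly `window_length` nucleotides (N allowed
#'   as padding).
#' @param window_length Expected window size in nt (default 21).
#' @return Named numeric vector of length `4 * window_length`.
#' @examples
#' v <- encode_window(strrep("A", 21))
#' all(v == 1)  # homopolymer: every position encodes (1,1,1,1)
#' @export
encode_window <- function(window, window_length = 21L) {
  stopifnot(is.character(window), length(window) == 1L)
  window <- as_rna(window)
  if (nchar(window) != window_length) {
    stop(sprintf("window has %d nt, expected %d", nchar(window), window_length),
         call. = FALSE)
  }
  drop(encode_windows(window, window_length = window_length))
}

#' Encode many windows at once
#'
#' Vectorised form of [encode_window()]: one row per window.
#'
#' @param windows Character vector of equal-length windows.
#' @inheritParams encode_window
#' @return Numeric matrix, `length(windows)` rows by `4 * window_length`
#'   columns, with the frozen sequence-feature column names.
#' @export
encode_windows <- function(windows, window_length = 21L) {
  stopifnot(is.character(windows))
  windows <- as_rna(windows)
  if (any(nchar(windows) != window_length)) {
    bad <- which(nchar(windows) != window_length)[1]
    stop(sprintf("window %d has %d nt, expected %d",
                 bad, nchar(windows[bad]), window_length), call. = FALSE)
  }
  n <- length(windows)
  out <- matrix(0, nrow = n, ncol = 4L * window_length,
                dimnames = list(NULL, seq_feature_names(window_length)))
  if (n == 0) return(out)
  # n x L character matrix of the windows
  cm <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  check_rna_chars(unique(as.vector(cm)), allow_n = TRUE)
  run <- matrix(0, nrow = n, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "U")))
  for (j in seq_len(window_length)) {
    b <- cm[, j]
    idx <- match(b, c("A", "C", "G", "U"))
    real <- !is.na(idx)
    run[cbind(which(real), idx[real])] <- run[cbind(which(real), idx[real])] + 1
    cols <- (j - 1L) * 4L
    out[, cols + 1L] <- .CHEM[b, "x"]
    out[, cols + 2L] <- .CHEM[b, "y"]
    out[, cols + 3L] <- .CHEM[b, "z"]
    f <- numeric(n)
    f[real] <- run[cbind(which(real), idx[real])] / j
    out[, cols + 4L] <- f
  }
  out
}

#' Extract the window around a position, padding at sequence ends
#'
#' @param sequence Transcript sequence (single string).
#' @param center 1-based positions of window centres.
#' @param flank Nucleotides of flank each side (window = 2*flank + 1).
#' @param warn Warn when any window is padded?
#' @return Character vector of windows, N-padded where they overrun the ends.
#' @export
site_window <- function(sequence, center, flank = 10L, warn = TRUE) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  stopifnot(all(center >= 1L), all(center <= n))
  lo <- center - flank
  hi <- center + flank
  pad_l <- pmax(0L, 1L - lo)
  pad_r <- pmax(0L, hi - n)
  if (warn && any(pad_l > 0 | pad_r > 0)) {
    warning(sprintf("%d window(s) truncated at transcript ends; padded with N",
                    sum(pad_l > 0 | pad_r > 0)), call. = FALSE)
  }
  core <- substring(sequence, pmax(lo, 1L), pmin(hi, n))
  paste0(strrep("N", pad_l), core, strrep("N", pad_r))
}

.D <- c("A", "G", "U")
.R <- c("A", "G")
.H <- c("A", "C", "U")

#' The 18 DRACH consensus 5-mers
#'
#' D = A/G/U, R = A/G, then the methylated A, C, H = A/C/U. The list is
#' lexicographically sorted and frozen; its order defines the motif one-hot
#' block of the genomic feature catalog.
#'
#' @return Character vector of the 18 motifs, sorted.
#' @export
drach_motifs <- function() {
  m <- as.vector(outer(outer(.D, .R, paste0), paste0("AC", .H), paste0))
  sort(m)
}

#' Scan a sequence for DRACH candidate adenosines
#'
#' Returns every position p (1-based) such that the 5-mer at p-2..p+2 matches
#' DRACH with the adenosine at p. Scanning is on the given (sense) strand
#' only.
#'
#' @param sequence RNA or DNA string.
#' @return Sorted integer vector of candidate centre positions (empty when
#'   there is no match).
#' @examples
#' scan_drach("GGACU")  # 3
#' @export
scan_drach <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  if (n < 5L) return(integer(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  check_rna_chars(chars, allow_n = TRUE)
  p <- 3:(n - 2L)
  keep <- chars[p] == "A" &
    chars[p - 2L] %in% .D &
    chars[p - 1L] %in% .R &
    chars[p + 1L] == "C" &
    chars[p + 2L] %in% .H
  p[keep]
}

#' Index of a DRACH 5-mer in the frozen motif catalog
#'
#' @param fivemer Character vector of DRACH 5-mers.
#' @return Integer index into [drach_motifs()] (1-based: "AAACA" is 1,
#'   "UGACU" is 18).
#' @export
motif_identity <- function(fivemer) {
  fivemer <- as_rna(fivemer)
  idx <- match(fivemer, drach_motifs())
  if (anyNA(idx)) {
    stop(sprintf("'%s' is not a DRACH 5-mer", fivemer[which(is.na(idx))[1]]),
         call. = FALSE)
  }
  idx
}

#' One-hot encoding of DRACH motif identity
#'
#' @inheritParams motif_identity
#' @return Numeric matrix, one row per 5-mer, 18 columns named
#'   `motif_<5-mer>`; each row sums to 1.
#' @export
motif_onehot <- function(fivemer) {
  idx <- motif_identity(fivemer)
  out <- matrix(0, nrow = length(idx), ncol = 18L,
                dimnames = list(NULL, paste0("motif_", drach_motifs())))
  out[cbind(seq_along(idx), idx)] <- 1
  out
}
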