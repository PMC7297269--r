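#' Maximum base-pairing RNA secondary structure
#'
#' Folds a short RNA by Nussinov-style dynamic programming, maximising the
#' number of base pairs under Watson-Crick (A-U, G-C) plus G-U wobble
#' pairing with a minimum hairpin loop of 3 unpaired bases. The traceback is
#' deterministic: whenever pairing the 5'-most base of an interval attains
#' the optimum it is paired with its 5'-most optimal partner.
#'
#' This is a deliberately coarse folder: the downstream structure features
#' only ask whether the site's base is paired and what fraction of the
#' window is paired, so a maximum-pairing model is sufficient. Precomputed
#' dot-bracket strings (e.g. from a thermodynamic folder) can be supplied
#' instead through [structure_provider()].
#'
#' @param sequence RNA/DNA string, at most `max_length` nt (the DP is cubic).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @param max_length Guard on input length.
#' @return Dot-bracket string of the same length as the input.
#' @examples
#' nussinov_fold("GGGAAACCC")
#' @export
nussinov_fold <- function(sequence, min_loop = 3L, max_length = 200L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- as_rna(sequence)
  if (nchar(sequence) > max_length) {
    stop(sprintf(paste0("sequence of %d nt exceeds the %d-nt folding guard; ",
                        "supply precomputed structures instead"),
                 nchar(sequence), max_length), call. = FALSE)
  }
  if (nchar(sequence) > 0) {
    check_rna_chars(strsplit(sequence, "", fixed = TRUE)[[1]], allow_n = TRUE)
  }
  .nussinov_cpp(sequence, as.integer(min_loop))
}

#' Number of base pairs in a dot-bracket string
#'
#' @param dotbracket Character vector of dot-bracket strings.
#' @return Integer vector of pair counts.
#' @export
pair_count <- function(dotbracket) {
  vapply(dotbracket,
         function(s) sum(strsplit(s, "", fixed = TRUE)[[1]] == "("),
         integer(1), USE.NAMES = FALSE)
}
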