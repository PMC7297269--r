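# The 60 genomic features computed per candidate site, grouped as:
#   1-10   transcript-topology dummies
#   11-12  splice-junction distances (capped at 2000 nt)
#   13-14  log2 region lengths (containing exon/intron; mature transcript)
#   15-32  DRACH motif identity one-hot
#   33-36  candidate clustering
#   37-40  evolutionary conservation (window means of 4 score tracks)
#   41-42  secondary structure (site paired; paired fraction of the window)
#   43-55  m6A-biology interval-overlap dummies (configurable registry)
#   56     miRNA-target dummy
#   57-60  gene-level z-scores (isoform count, exon count, gene GC, local GC)

#' The frozen genomic feature catalog
#'
#' @return Data frame with columns `index`, `name`, `group` describing the
#'   60 genomic features in their frozen order.
#' @export
genomic_feature_catalog <- function() {
  entries <- rbind(
    data.frame(name = region_flag_names(), group = "region_dummy"),
    data.frame(name = c("dist_sj_5_p2000", "dist_sj_3_p2000"),
               group = "splice_distance"),
    data.frame(name = c("length_region", "length_gene_ex"),
               group = "region_length"),
    data.frame(name = paste0("motif_", drach_motifs()), group = "motif_onehot"),
    data.frame(name = c("clust_50", "clust_500", "clust_2000",
                        "dist_nearest_p2000"), group = "clustering"),
    data.frame(name = conservation_track_names(), group = "conservation"),
    data.frame(name = c("struct_paired", "struct_paired_frac"),
               group = "structure"),
    data.frame(name = overlap_track_names(), group = "overlap_dummy"),
    data.frame(name = "mirna_target", group = "mirna"),
    data.frame(name = c("isoform_num", "exon_num", "gc_gene", "gc_local"),
               group = "zscore")
  )
  entries$index <- seq_len(nrow(entries))
  stopifnot(nrow(entries) == 60L, !anyDuplicated(entries$name))
  entries[c("index", "name", "group")]
}

#' The full 144-column feature catalog
#'
#' 84 sequence feature names (21 positions x chemical triple + cumulative
#' frequency) followed by the 60 genomic feature names.
#'
#' @return Character vector of 144 frozen column names.
#' @export
feature_catalog <- function() {
  c(seq_feature_names(), genomic_feature_catalog()$name)
}

#' Region-length features
#'
#' log2 of the length of the transcript region containing the site (exon,
#' or intron in full-transcript mode) and log2 of the mature transcript
#' length.
#'
#' @inheritParams splice_junction_distances
#' @return Matrix with columns `length_region`, `length_gene_ex`.
#' @export
region_length_features <- function(model, tx_pos, mode = "full_transcript") {
  rl <- containing_region_length(model, tx_pos, mode)
  cbind(length_region = log2(rl),
        length_gene_ex = rep(log2(model$mature_length), length(tx_pos)))
}

#' Candidate-clustering features
#'
#' Counts of other DRACH candidates within +/-50, +/-500 and +/-2000 nt of
#' the site (in the active mode's transcript coordinates) and the distance
#' to the nearest other candidate, capped at 2000. Candidate motifs, not
#' labelled sites, define the neighbourhood, so the features are computable
#' at prediction time.
#'
#' @param tx_pos Site position(s) in transcript coordinates.
#' @param all_pos Positions of every DRACH candidate on the same transcript
#'   (may include the sites themselves).
#' @param cap Distance cap.
#' @param windows Window half-widths for the three counts.
#' @return Matrix with columns `clust_50`, `clust_500`, `clust_2000`,
#'   `dist_nearest_p2000`.
#' @export
clustering_features <- function(tx_pos, all_pos, cap = 2000L,
                                windows = c(50L, 500L, 2000L)) {
  all_pos <- sort(unique(as.integer(all_pos)))
  n <- length(tx_pos)
  out <- matrix(0, nrow = n, ncol = 4L,
                dimnames = list(NULL, c("clust_50", "clust_500", "clust_2000",
                                        "dist_nearest_p2000")))
  for (i in seq_len(n)) {
    p <- tx_pos[i]
    others <- all_pos[all_pos != p]
    if (length(others) == 0L) {
      out[i, ] <- c(0, 0, 0, cap)
      next
    }
    d <- abs(others - p)
    out[i, 1:3] <- vapply(windows, function(w) sum(d <= w), numeric(1))
    out[i, 4L] <- min(cap, min(d))
  }
  out
}

#' Conservation features
#'
#' For each of the four conservation-role score tracks, the mean score over
#' the 21-nt window around the site's genomic position(s); in mature mode
#' the window follows the spliced transcript, so its genomic positions may
#' be discontiguous. Missing track values are imputed as 0 and the imputed
#' count is reported via a message.
#'
#' @param model A `transcript_model`.
#' @param tx_pos Site positions in the mode's transcript coordinates.
#' @param tracks A [track_bundle()].
#' @param mode Coordinate mode.
#' @param flank Window flank (window = 2*flank + 1 nt).
#' @param quiet Suppress the imputation message.
#' @return Matrix with one column per conservation track name.
#' @export
conservation_features <- function(model, tx_pos, tracks,
                                  mode = "full_transcript", flank = 10L,
                                  quiet = FALSE) {
  nm <- conservation_track_names()
  n <- length(tx_pos)
  len <- tx_length(model, mode)
  out <- matrix(0, nrow = n, ncol = 4L, dimnames = list(NULL, nm))
  # window positions in transcript coords, clipped at transcript ends
  wpos <- lapply(as.integer(tx_pos), function(p) {
    w <- (p - flank):(p + flank)
    w[w >= 1L & w <= len]
  })
  all_t <- unlist(wpos)
  gpos <- tx_project(model, all_t, "transcript", "genomic", mode)
  grp <- rep(seq_len(n), lengths(wpos))
  n_missing <- 0L
  for (k in nm) {
    tr <- tracks$score_tracks[[k]]
    v <- if (is.null(tr)) rep(NA_real_, length(gpos)) else {
      track_values(tr, rep(model$chrom, length(gpos)), gpos)
    }
    n_missing <- n_missing + sum(is.na(v))
    v[is.na(v)] <- 0
    out[, k] <- as.numeric(tapply(v, grp, mean))
  }
  if (!quiet && n_missing > 0L) {
    message(sprintf("conservation: %d missing track value(s) imputed as 0",
                    n_missing))
  }
  out
}

#' Structure features from a dot-bracket window
#'
#' @param dotbracket Dot-bracket string of the window.
#' @param center_index 1-based index of the site's base within the window.
#' @return Numeric vector `c(struct_paired, struct_paired_frac)`: 1 if the
#'   site's base is paired, and the fraction of paired bases in the window.
#' @export
structure_features <- function(dotbracket, center_index) {
  chars <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  stopifnot(center_index >= 1L, center_index <= length(chars))
  paired <- chars %in% c("(", ")")
  c(struct_paired = as.numeric(paired[center_index]),
    struct_paired_frac = mean(paired))
}

#' Site structure features via a structure provider
#'
#' Extracts the (up to) 101-nt window centred on each site from the
#' transcript sequence, obtains its dot-bracket string from the provider
#' (built-in folder, or precomputed keyed by
#' `"<transcript_id>:<window_start>"`), and computes the two structure
#' features.
#'
#' @param model A `transcript_model`.
#' @param tx_pos Site positions in the mode's transcript coordinates.
#' @param sequence Transcript sequence in the same mode.
#' @param provider A [structure_provider()].
#' @param flank Window flank (default 50, i.e. 101-nt windows).
#' @return Matrix with columns `struct_paired`, `struct_paired_frac`.
#' @export
site_structure_features <- function(model, tx_pos, sequence, provider,
                                    flank = 50L) {
  n <- length(tx_pos)
  len <- nchar(sequence)
  out <- matrix(0, nrow = n, ncol = 2L,
                dimnames = list(NULL, c("struct_paired", "struct_paired_frac")))
  for (i in seq_len(n)) {
    p <- as.integer(tx_pos[i])
    lo <- max(1L, p - flank); hi <- min(len, p + flank)
    db <- if (provider$type == "precomputed") {
      key <- sprintf("%s:%d", model$transcript_id, lo)
      s <- unname(provider$structures[key])
      if (is.na(s)) {
        stop(sprintf("no precomputed structure for window '%s'", key),
             call. = FALSE)
      }
      s
    } else {
      nussinov_fold(substr(sequence, lo, hi))
    }
    out[i, ] <- structure_features(db, p - lo + 1L)
  }
  out
}

#' GC fraction of a sequence
#'
#' Ambiguous bases (N) are excluded from both numerator and denominator.
#'
#' @param x Character vector of sequences.
#' @return Numeric vector of GC fractions (NaN for all-ambiguous input).
#' @export
gc_fraction <- function(x) {
  vapply(as_rna(x), function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars <- chars[chars %in% c("A", "C", "G", "U")]
    if (length(chars) == 0L) return(NaN)
    mean(chars %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Population z-score with the population-sd convention
#'
#' @param v Values to standardise.
#' @param population Reference population the mean and sd are taken over.
#' @return `(v - mean) / sd_pop`; 0 when the population sd is 0.
#' @export
zscore <- function(v, population) {
  m <- mean(population)
  s <- sqrt(mean((population - m)^2))
  if (s == 0) return(rep(0, length(v)))
  (v - m) / s
}

#' Gene-population statistics for the z-score features
#'
#' Computed once per dataset over its genes: isoform count (transcripts per
#' gene in the annotation), exon count of the selected transcript, and
#' gene-level GC fraction of the mature transcript.
#'
#' @param selected Named list of per-gene `transcript_model` (from
#'   [select_longest_transcript()]).
#' @param genome Genome sequences (named character vector or DNAStringSet).
#' @param isoform_counts Named integer vector of transcripts per gene; when
#'   NULL every gene is taken to have one annotated isoform.
#' @return Data frame (one row per gene) with columns `gene_id`,
#'   `isoform_num`, `exon_num`, `gc_gene`.
#' @export
gene_population <- function(selected, genome, isoform_counts = NULL) {
  gid <- vapply(selected, `[[`, character(1), "gene_id")
  iso <- if (is.null(isoform_counts)) rep(1L, length(selected)) else {
    as.integer(isoform_counts[gid])
  }
  data.frame(
    gene_id = gid,
    isoform_num = iso,
    exon_num = vapply(selected, `[[`, integer(1), "n_exons"),
    gc_gene = vapply(selected, function(m) {
      gc_fraction(tx_sequence(m, genome, "mature_rna"))
    }, numeric(1)),
    row.names = NULL
  )
}

#' Attribute-overlap dummy features
#'
#' The 13 m6A-biology interval-overlap dummies (registry order slot_43 ..
#' slot_55) plus the miRNA-target dummy. Unregistered slots yield 0.
#'
#' @param tracks A [track_bundle()].
#' @param chrom,pos,strand Site genomic coordinates.
#' @return Integer matrix, one row per site, 14 named 0/1 columns.
#' @export
attribute_overlap_flags <- function(tracks, chrom, pos, strand) {
  nm <- c(overlap_track_names(), "mirna_target")
  out <- matrix(0L, nrow = length(pos), ncol = 14L, dimnames = list(NULL, nm))
  for (k in overlap_track_names()) {
    out[, k] <- interval_overlap_flag(tracks$interval_tracks[[k]], chrom, pos,
                                      strand)
  }
  out[, "mirna_target"] <- interval_overlap_flag(tracks$mirna_track, chrom,
                                                 pos, strand)
  out
}
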