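# Assembly of the full 144-column feature matrix (84 sequence + 60 genomic
# values per candidate site). Sites are processed grouped by transcript so
# per-transcript work (sequence extraction, DRACH scanning for the
# clustering block) is done once.

#' Site table constructor
#'
#' A site is one adenosine under a DRACH motif, addressed both in genomic
#' and transcript coordinates.
#'
#' @param tx_id,gene_id Identifiers of the hosting (selected) transcript.
#' @param chrom,genomic_pos,strand Genomic coordinates (1-based position of
#'   the methylated A).
#' @param tx_pos Position in the active mode's transcript coordinates.
#' @param label Optional site labels (`"positive"`/`"negative"`).
#' @return Data frame with class `m6a_sites`.
#' @export
m6a_sites <- function(tx_id, gene_id, chrom, genomic_pos, strand, tx_pos,
                      label = NA_character_) {
  out <- data.frame(tx_id = as.character(tx_id),
                    gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    genomic_pos = as.integer(genomic_pos),
                    strand = as.character(strand),
                    tx_pos = as.integer(tx_pos),
                    label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("m6a_sites", "data.frame")
  out
}

#' Stable site keys
#'
#' @param sites An `m6a_sites` table.
#' @return Character vector `"<tx_id>:<tx_pos>:<strand>"`.
#' @export
site_key <- function(sites) {
  sprintf("%s:%d:%s", sites$tx_id, sites$tx_pos, sites$strand)
}

#' Sequence feature matrix for a site table
#'
#' Extracts the 21-nt window around each site from its transcript sequence
#' in the active mode and encodes it (see [encode_window()]).
#'
#' @param sites An `m6a_sites` table.
#' @param models Named list of `transcript_model` keyed by transcript id.
#' @param genome Genome sequences.
#' @param mode Coordinate mode.
#' @param flank Window flank (default 10, i.e. 21-nt windows).
#' @return Numeric matrix, one row per site, 84 named columns.
#' @export
sequence_feature_matrix <- function(sites, models, genome,
                                    mode = "full_transcript", flank = 10L) {
  mode <- match_mode(mode)
  n <- nrow(sites)
  out <- matrix(0, nrow = n, ncol = 4L * (2L * flank + 1L),
                dimnames = list(NULL, seq_feature_names(2L * flank + 1L)))
  for (t in unique(sites$tx_id)) {
    idx <- which(sites$tx_id == t)
    seqs <- tx_sequence(models[[t]], genome, mode)
    win <- site_window(seqs, sites$tx_pos[idx], flank = flank, warn = FALSE)
    out[idx, ] <- encode_windows(win, window_length = 2L * flank + 1L)
  }
  out
}

#' Genomic feature matrix for a site table
#'
#' Computes the 60 genomic features per site in frozen catalog order. The
#' z-score block is standardised against `gene_pop` (gene-level values) and
#' against the local GC of all sites in this call (population-sd
#' convention).
#'
#' @inheritParams sequence_feature_matrix
#' @param tracks A [track_bundle()].
#' @param gene_pop Data frame from [gene_population()].
#' @param quiet Suppress imputation messages.
#' @return Numeric matrix, one row per site, 60 named columns.
#' @export
genomic_feature_matrix <- function(sites, models, genome, tracks, gene_pop,
                                   mode = "full_transcript", quiet = FALSE) {
  mode <- match_mode(mode)
  cat60 <- genomic_feature_catalog()
  n <- nrow(sites)
  out <- matrix(0, nrow = n, ncol = 60L, dimnames = list(NULL, cat60$name))
  gc_local <- numeric(n)
  for (t in unique(sites$tx_id)) {
    idx <- which(sites$tx_id == t)
    model <- models[[t]]
    seqs <- tx_sequence(model, genome, mode)
    p <- sites$tx_pos[idx]
    out[idx, region_flag_names()] <- region_flags(model, p, mode)
    out[idx, c("dist_sj_5_p2000", "dist_sj_3_p2000")] <-
      splice_junction_distances(model, p, mode)
    out[idx, c("length_region", "length_gene_ex")] <-
      region_length_features(model, p, mode)
    # motif identity is a property of the site's genomic (pre-mRNA) context;
    # the spliced 5-mer can differ across an exon junction
    gseq <- if (mode == "full_transcript") seqs else {
      tx_sequence(model, genome, "full_transcript")
    }
    pfull <- if (mode == "full_transcript") p else {
      tx_project(model,
                 tx_project(model, p, "transcript", "genomic", "mature_rna"),
                 "genomic", "transcript", "full_transcript")
    }
    fivemers <- substring(gseq, pfull - 2L, pfull + 2L)
    out[idx, paste0("motif_", drach_motifs())] <- motif_onehot(fivemers)
    cand <- candidate_positions(model, genome, mode)
    out[idx, c("clust_50", "clust_500", "clust_2000", "dist_nearest_p2000")] <-
      clustering_features(p, cand)
    out[idx, conservation_track_names()] <-
      conservation_features(model, p, tracks, mode, quiet = quiet)
    out[idx, c("struct_paired", "struct_paired_frac")] <-
      site_structure_features(model, p, seqs, tracks$structure)
    gp <- gene_pop[match(model$gene_id, gene_pop$gene_id), ]
    out[idx, "isoform_num"] <- zscore(gp$isoform_num, gene_pop$isoform_num)
    out[idx, "exon_num"] <- zscore(gp$exon_num, gene_pop$exon_num)
    out[idx, "gc_gene"] <- zscore(gp$gc_gene, gene_pop$gc_gene)
    win101 <- site_window(seqs, p, flank = 50L, warn = FALSE)
    gc_local[idx] <- gc_fraction(gsub("N", "", win101))
  }
  out[, c(overlap_track_names(), "mirna_target")] <-
    attribute_overlap_flags(tracks, sites$chrom, sites$genomic_pos,
                            sites$strand)
  out[, "gc_local"] <- zscore(gc_local, gc_local)
  out
}

#' Genomic feature vector for a single site
#'
#' Convenience wrapper over [genomic_feature_matrix()] for one site; the
#' z-score populations must be supplied through `gene_pop` (the single
#' site's own local GC z-score is 0 by the population-sd convention).
#'
#' @param site One-row `m6a_sites` table.
#' @inheritParams genomic_feature_matrix
#' @return Named numeric vector of length 60.
#' @export
extract_genomic_vector <- function(site, models, genome, tracks, gene_pop,
                                   mode = "full_transcript") {
  stopifnot(nrow(site) == 1L)
  drop(genomic_feature_matrix(site, models, genome, tracks, gene_pop,
                              mode = mode, quiet = TRUE))
}

#' Full feature matrix for a site table
#'
#' Binds the 84 sequence features and the 60 genomic features into the
#' 144-column matrix in frozen catalog order, with site keys as row names.
#'
#' @inheritParams genomic_feature_matrix
#' @return List with `x` (n x 144 matrix), `y` (labels, possibly NA) and
#'   `sites`.
#' @export
build_feature_matrix <- function(sites, models, genome, tracks, gene_pop,
                                 mode = "full_transcript", quiet = TRUE) {
  xs <- sequence_feature_matrix(sites, models, genome, mode)
  xg <- genomic_feature_matrix(sites, models, genome, tracks, gene_pop,
                               mode = mode, quiet = quiet)
  x <- cbind(xs, xg)
  stopifnot(identical(colnames(x), feature_catalog()))
  rownames(x) <- site_key(sites)
  list(x = x, y = sites$label, sites = sites)
}

#' Write a feature matrix as TSV
#'
#' Tab-separated with a header of catalog names and a leading `site_key`
#' column.
#'
#' @param fm Result of [build_feature_matrix()].
#' @param path Output file.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(site_key = rownames(fm$x), fm$x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
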