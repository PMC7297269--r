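# Balanced labeled dataset construction from replicate base-resolution
# site-call sets: consensus positives (support in >= 2 replicates),
# negatives sampled uniformly from the remaining DRACH adenosines on the
# transcripts carrying positives, exclusion of sites mappable to more than
# one gene, and the 4/5 - 1/5 train/test split.

#' Read a site-call set from BED6
#'
#' Single-base intervals, 0-based half-open with mandatory strand; the
#' 1-based genomic position of the methylated adenosine is `start + 1`.
#'
#' @param path BED file.
#' @param experiment Experiment id recorded on the set.
#' @return Data frame of class `site_call_set` with columns `chrom`, `pos`,
#'   `strand` (unique rows).
#' @export
read_site_calls <- function(path, experiment = basename(path)) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop(sprintf("'%s' is not BED6 (strand required)", path),
                           call. = FALSE)
  site_call_set(data.frame(chrom = bed[[1]], pos = bed[[2]] + 1L,
                           strand = bed[[6]]), experiment)
}

#' Construct a site-call set
#'
#' @param df Data frame with columns `chrom`, `pos` (1-based genomic
#'   position of the A), `strand`.
#' @param experiment Experiment id.
#' @return Deduplicated data frame of class `site_call_set`.
#' @export
site_call_set <- function(df, experiment = "exp") {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(df)))
  out <- unique(df[c("chrom", "pos", "strand")])
  rownames(out) <- NULL
  attr(out, "experiment") <- experiment
  class(out) <- c("site_call_set", "data.frame")
  out
}

genomic_site_key <- function(df) sprintf("%s:%d:%s", df$chrom, df$pos, df$strand)

#' Write a site set as BED6
#'
#' @param df Data frame with `chrom`, `pos` (1-based), `strand`; optional
#'   `name` and `score` columns.
#' @param path Output BED file (0-based half-open single-base intervals).
#' @export
write_site_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, df$pos - 1L, df$pos,
                   name, format(score, trim = TRUE), df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Is a genomic position a DRACH-centred adenosine?
#'
#' Checks the strand-aware 5-mer context around each position against the
#' DRACH consensus.
#'
#' @param genome Genome sequences.
#' @param chrom,pos,strand Genomic coordinates.
#' @return Logical vector.
#' @export
is_drach_adenosine <- function(genome, chrom, pos, strand) {
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  vapply(seq_along(pos), function(i) {
    cs <- genome[[chrom[i]]]
    if (is.null(cs)) return(FALSE)
    if (pos[i] < 3L || pos[i] > nchar(cs) - 2L) return(FALSE)
    fm <- substr(cs, pos[i] - 2L, pos[i] + 2L)
    if (strand[i] == "-") fm <- revcomp(fm)
    length(scan_drach(fm)) == 1L && scan_drach(fm) == 3L
  }, logical(1))
}

#' Consensus positives across replicate call sets
#'
#' Sites present at the same genomic coordinate and strand in at least
#' `min_support` of the call sets, restricted to DRACH-centred adenosines.
#'
#' @param call_sets List of `site_call_set`.
#' @param min_support Minimum number of supporting replicates (default 2).
#' @param genome Genome sequences for the DRACH-context check; when NULL
#'   the check is skipped (inputs already guaranteed to be DRACH).
#' @return Data frame `chrom`, `pos`, `strand` with a `support` column.
#' @export
consensus_positives <- function(call_sets, min_support = 2L, genome = NULL) {
  if (length(call_sets) == 0L) stop("no call sets supplied", call. = FALSE)
  stopifnot(min_support >= 1L)
  keys <- unlist(lapply(call_sets, genomic_site_key))
  tab <- table(keys)
  keep <- names(tab)[tab >= min_support]
  all_sites <- unique(do.call(rbind, lapply(call_sets, function(s) {
    as.data.frame(s)[c("chrom", "pos", "strand")]
  })))
  out <- all_sites[genomic_site_key(all_sites) %in% keep, , drop = FALSE]
  out$support <- as.integer(tab[genomic_site_key(out)])
  if (!is.null(genome)) {
    ok <- is_drach_adenosine(genome, out$chrom, out$pos, out$strand)
    out <- out[ok, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map genomic sites to selected transcripts, excluding multi-gene sites
#'
#' Assigns each site to the selected (longest) transcript whose span
#' contains it on the same strand; sites falling inside the spans of more
#' than one gene are dropped, as are sites on no selected transcript.
#'
#' @param sites Data frame with `chrom`, `pos`, `strand`.
#' @param selected Named per-gene list of `transcript_model`.
#' @param mode Coordinate mode; in mature mode intronic sites are also
#'   dropped and `tx_pos` is a mature coordinate.
#' @return `m6a_sites` table.
#' @export
assign_sites_to_genes <- function(sites, selected, mode = "full_transcript") {
  mode <- match_mode(mode)
  tx_chrom <- vapply(selected, `[[`, character(1), "chrom")
  tx_strand <- vapply(selected, `[[`, character(1), "strand")
  tx_start <- vapply(selected, `[[`, integer(1), "span_start")
  tx_end <- vapply(selected, `[[`, integer(1), "span_end")
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- which(tx_chrom == sites$chrom[i] & tx_strand == sites$strand[i] &
                 tx_start <= sites$pos[i] & tx_end >= sites$pos[i])
    if (length(hit) != 1L) next  # unmapped or multi-gene: excluded
    m <- selected[[hit]]
    if (mode == "mature_rna" && !is_exonic(m, sites$pos[i])) next
    tp <- tx_project(m, sites$pos[i], "genomic", "transcript", mode)
    rows[[i]] <- data.frame(tx_id = m$transcript_id, gene_id = m$gene_id,
                            chrom = sites$chrom[i], genomic_pos = sites$pos[i],
                            strand = sites$strand[i], tx_pos = tp)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(m6a_sites(character(0), character(0), character(0), integer(0),
                     character(0), integer(0)))
  }
  df <- do.call(rbind, rows)
  m6a_sites(df$tx_id, df$gene_id, df$chrom, df$genomic_pos, df$strand,
            df$tx_pos)
}

#' Enumerate DRACH candidates on a set of transcripts
#'
#' The DRACH match is always evaluated on the pre-mRNA (full-transcript)
#' context, where base-resolution calls are anchored; under mature mode the
#' exonic candidates are kept and re-projected onto mature coordinates, so
#' junction-spanning spliced 5-mers never create or destroy candidates.
#'
#' @param selected Named per-gene list of `transcript_model`.
#' @param genome Genome sequences.
#' @param mode Coordinate mode.
#' @param tx_ids Restrict to these transcript ids (default all).
#' @return `m6a_sites` table of every DRACH-centred adenosine.
#' @export
enumerate_candidates <- function(selected, genome, mode = "full_transcript",
                                 tx_ids = NULL) {
  mode <- match_mode(mode)
  rows <- list()
  for (m in selected) {
    if (!is.null(tx_ids) && !(m$transcript_id %in% tx_ids)) next
    seqs <- tx_sequence(m, genome, "full_transcript")
    p <- scan_drach(seqs)
    if (length(p) == 0L) next
    g <- tx_project(m, p, "transcript", "genomic", "full_transcript")
    if (mode == "mature_rna") {
      keep <- is_exonic(m, g)
      if (!any(keep)) next
      g <- g[keep]
      p <- tx_project(m, g, "genomic", "transcript", "mature_rna")
    }
    rows[[m$transcript_id]] <- data.frame(
      tx_id = m$transcript_id, gene_id = m$gene_id, chrom = m$chrom,
      genomic_pos = g, strand = m$strand, tx_pos = p)
  }
  if (length(rows) == 0L) {
    return(m6a_sites(character(0), character(0), character(0), integer(0),
                     character(0), integer(0)))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  m6a_sites(df$tx_id, df$gene_id, df$chrom, df$genomic_pos, df$strand,
            df$tx_pos)
}

#' DRACH candidate positions on one transcript, in mode coordinates
#'
#' Matches [enumerate_candidates()] for a single model: the DRACH match is
#' evaluated on the pre-mRNA context, and mature mode keeps the exonic
#' candidates re-projected onto mature coordinates.
#'
#' @param model A `transcript_model`.
#' @param genome Genome sequences.
#' @param mode Coordinate mode.
#' @return Integer positions in the mode's transcript coordinates.
#' @export
candidate_positions <- function(model, genome, mode = "full_transcript") {
  mode <- match_mode(mode)
  p <- scan_drach(tx_sequence(model, genome, "full_transcript"))
  if (mode == "mature_rna" && length(p)) {
    g <- tx_project(model, p, "transcript", "genomic", "full_transcript")
    keep <- is_exonic(model, g)
    p <- if (any(keep)) {
      tx_project(model, g[keep], "genomic", "transcript", "mature_rna")
    } else integer(0)
  }
  p
}

#' Sample negative sites
#'
#' Uniform sample without replacement of size `n` from the candidate pool:
#' all DRACH adenosines on the transcripts containing positives, minus the
#' excluded coordinates (by default every site reported in any call set,
#' not only the consensus positives).
#'
#' @param pool `m6a_sites` table of candidate adenosines (e.g. from
#'   [enumerate_candidates()] restricted to positive-bearing transcripts).
#' @param exclude Data frame with `chrom`, `pos`, `strand` of coordinates
#'   that may not be sampled.
#' @param n Number of negatives (normally `|positives|`).
#' @param seed Integer seed.
#' @return `m6a_sites` table of `n` negatives.
#' @export
sample_negatives <- function(pool, exclude, n, seed = 20200609L) {
  ex_key <- sprintf("%s:%d:%s", exclude$chrom, exclude$pos, exclude$strand)
  pk <- sprintf("%s:%d:%s", pool$chrom, pool$genomic_pos, pool$strand)
  pool <- pool[!pk %in% ex_key, , drop = FALSE]
  if (nrow(pool) < n) {
    stop(sprintf("negative pool has %d candidates, %d needed (deficit %d)",
                 nrow(pool), n, n - nrow(pool)), call. = FALSE)
  }
  idx <- local({ set.seed(as.integer(seed)); sample(nrow(pool), n) })
  out <- pool[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' @param labels Site labels (`"positive"`/`"negative"` or 0/1).
#' @param fraction Training fraction (default 4/5).
#' @param seed Integer seed.
#' @return Character vector `"train"`/`"test"` aligned with `labels`.
#' @export
split_train_test <- function(labels, fraction = 0.8, seed = 20200609L) {
  y <- as_binary_labels(labels)
  out <- character(length(y))
  set.seed(as.integer(seed))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_train <- round(fraction * length(idx))
    tr <- sample(idx, n_train)
    out[tr] <- "train"
    out[setdiff(idx, tr)] <- "test"
  }
  out
}

#' Build a balanced labeled dataset from replicate call sets
#'
#' Full pipeline of the dataset rules: consensus positives (DRACH-checked,
#' support >= `min_support`), assignment to selected transcripts with
#' multi-gene exclusion, equal-size negative sampling from the
#' positive-bearing transcripts, and the stratified train/test split.
#' In mature mode the full-mode positives are filtered to exonic positions
#' and re-projected onto mature coordinates.
#'
#' @param call_sets List of `site_call_set`.
#' @param selected Named per-gene list of `transcript_model` (the gene set
#'   of one RNA class).
#' @param genome Genome sequences.
#' @param mode Coordinate mode.
#' @param rna_class Label recorded on the dataset (`"lncRNA"` or
#'   `"mRNA"`).
#' @param min_support Replicate support threshold for positives.
#' @param train_fraction Training fraction of the split.
#' @param seed Integer seed (negative sampling and split).
#' @param negative_exclude `"any_call"` (default: no site reported in any
#'   replicate may be a negative) or `"positives_only"`.
#' @return List of class `m6a_dataset` with `sites` (labels and split
#'   assignment), `mode`, `rna_class`, `seed`.
#' @export
build_labeled_dataset <- function(call_sets, selected, genome,
                                  mode = "full_transcript",
                                  rna_class = "lncRNA",
                                  min_support = 2L, train_fraction = 0.8,
                                  seed = 20200609L,
                                  negative_exclude = c("any_call",
                                                       "positives_only")) {
  mode <- match_mode(mode)
  negative_exclude <- match.arg(negative_exclude)
  cons <- consensus_positives(call_sets, min_support = min_support,
                              genome = genome)
  pos <- assign_sites_to_genes(cons, selected, mode = mode)
  if (nrow(pos) == 0L) stop("no consensus positives on the selected transcripts",
                            call. = FALSE)
  pos$label <- "positive"
  pool <- enumerate_candidates(selected, genome, mode = mode,
                               tx_ids = unique(pos$tx_id))
  exclude <- if (negative_exclude == "any_call") {
    unique(do.call(rbind, lapply(call_sets, function(s) {
      as.data.frame(s)[c("chrom", "pos", "strand")]
    })))
  } else {
    data.frame(chrom = pos$chrom, pos = pos$genomic_pos, strand = pos$strand)
  }
  neg <- sample_negatives(pool, exclude, n = nrow(pos), seed = seed)
  neg$label <- "negative"
  sites <- rbind(pos, neg)
  sites$split <- split_train_test(sites$label, fraction = train_fraction,
                                  seed = seed)
  structure(list(sites = sites, mode = mode, rna_class = rna_class,
                 min_support = min_support, seed = seed,
                 negative_exclude = negative_exclude),
            class = "m6a_dataset")
}

#' @export
print.m6a_dataset <- function(x, ...) {
  s <- x$sites
  cat(sprintf("<m6a_dataset> %s, %s mode: %d sites (%d+/%d-), %d train / %d test\n",
              x$rna_class, x$mode, nrow(s),
              sum(s$label == "positive"), sum(s$label == "negative"),
              sum(s$split == "train"), sum(s$split == "test")))
  invisible(x)
}

#' Write a dataset manifest
#'
#' Tab-separated manifest with columns `site_key`, `label`, `split`,
#' `mode`, `rna_class`.
#'
#' @param dataset An `m6a_dataset`.
#' @param path Output file.
#' @export
write_dataset_manifest <- function(dataset, path) {
  s <- dataset$sites
  df <- data.frame(site_key = site_key(s), label = s$label, split = s$split,
                   mode = dataset$mode, rna_class = dataset$rna_class)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
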