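# End-to-end driver: datasets -> feature matrices -> ensemble fit ->
# test-set prediction and evaluation, plus transcriptome-wide candidate
# scanning with a fitted model.

#' Run the full site-prediction pipeline on a fixture or file set
#'
#' Builds the lncRNA and mRNA balanced datasets from the replicate call
#' sets, extracts the 144-feature matrices under the requested coordinate
#' mode, fits the mRNA/lncRNA ensemble on the training splits (blend
#' weight by grid search on a validation subset of the lncRNA training
#' data), predicts the lncRNA test split and evaluates it.
#'
#' @param fixture An `m6a_fixture` (or a list with the same components:
#'   `genome`, `selected`, `gene_class`, `isoform_counts`, `tracks`,
#'   `call_sets`).
#' @param mode Coordinate mode.
#' @param seed Integer seed for dataset sampling, splitting and training.
#' @param trainer Trainer function (default 500-tree probability forest).
#' @param alpha Fixed blend weight, or NULL for grid search.
#' @param threshold Classification threshold for the binary calls.
#' @return List of class `m6a_pipeline` with the datasets, feature
#'   matrices, the `m6a_ensemble` fit, the test-set prediction table and
#'   the evaluation metrics.
#' @export
run_pipeline <- function(fixture, mode = "full_transcript", seed = 20200609L,
                         trainer = rf_trainer(), alpha = NULL,
                         threshold = 0.5) {
  mode <- match_mode(mode)
  sel_lnc <- fixture$selected[names(fixture$gene_class)[fixture$gene_class == "lncRNA"]]
  sel_m <- fixture$selected[names(fixture$gene_class)[fixture$gene_class == "mRNA"]]
  ds_lnc <- build_labeled_dataset(fixture$call_sets, sel_lnc, fixture$genome,
                                  mode = mode, rna_class = "lncRNA",
                                  seed = seed)
  ds_m <- build_labeled_dataset(fixture$call_sets, sel_m, fixture$genome,
                                mode = mode, rna_class = "mRNA", seed = seed)
  models_by_tx <- c(setNames(sel_lnc, vapply(sel_lnc, `[[`, character(1),
                                             "transcript_id")),
                    setNames(sel_m, vapply(sel_m, `[[`, character(1),
                                           "transcript_id")))
  pop_lnc <- gene_population(sel_lnc, fixture$genome,
                             fixture$isoform_counts)
  pop_m <- gene_population(sel_m, fixture$genome, fixture$isoform_counts)
  fm_lnc <- build_feature_matrix(ds_lnc$sites, models_by_tx, fixture$genome,
                                 fixture$tracks, pop_lnc, mode = mode)
  fm_m <- build_feature_matrix(ds_m$sites, models_by_tx, fixture$genome,
                               fixture$tracks, pop_m, mode = mode)
  tr_l <- ds_lnc$sites$split == "train"
  tr_m <- ds_m$sites$split == "train"
  fit <- m6a_ensemble(fm_lnc$x[tr_l, , drop = FALSE], fm_lnc$y[tr_l],
                      fm_m$x[tr_m, , drop = FALSE], fm_m$y[tr_m],
                      alpha = alpha, trainer = trainer, seed = seed,
                      mode = mode)
  x_test <- fm_lnc$x[!tr_l, , drop = FALSE]
  y_test <- fm_lnc$y[!tr_l]
  comp <- predict(fit, x_test, type = "components")
  pred <- cbind(ds_lnc$sites[!tr_l, c("tx_id", "chrom", "genomic_pos",
                                      "strand", "tx_pos", "label")],
                as.data.frame(comp))
  pred$call <- as.integer(comp[, "p_en"] > threshold)
  metrics <- evaluation_report(y_test, comp[, "p_en"], threshold)
  structure(list(dataset_lnc = ds_lnc, dataset_m = ds_m,
                 features_lnc = fm_lnc, features_m = fm_m,
                 fit = fit, predictions = pred, metrics = metrics,
                 mode = mode, seed = seed),
            class = "m6a_pipeline")
}

#' @export
print.m6a_pipeline <- function(x, ...) {
  cat(sprintf("<m6a_pipeline> %s mode, seed %d\n", x$mode, x$seed))
  print(x$dataset_lnc); print(x$dataset_m)
  cat(sprintf("  ensemble alpha = %.2f\n", x$fit$alpha))
  cat("  lncRNA test metrics:\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' Scan a transcriptome and score every DRACH candidate
#'
#' Enumerates every DRACH-centred adenosine on the selected transcripts,
#' extracts features, and scores each candidate with a fitted ensemble.
#'
#' @param fit An `m6a_ensemble`.
#' @param selected Named per-gene list of `transcript_model`.
#' @param genome Genome sequences.
#' @param tracks A [track_bundle()].
#' @param gene_pop Data frame from [gene_population()].
#' @param mode Coordinate mode.
#' @param threshold Call threshold (strictly greater than).
#' @return Data frame: one row per candidate with probability and binary
#'   call.
#' @export
scan_transcriptome <- function(fit, selected, genome, tracks, gene_pop,
                               mode = "full_transcript", threshold = 0.5) {
  cand <- enumerate_candidates(selected, genome, mode = mode)
  models_by_tx <- setNames(selected, vapply(selected, `[[`, character(1),
                                            "transcript_id"))
  fm <- build_feature_matrix(cand, models_by_tx, genome, tracks, gene_pop,
                             mode = mode)
  p <- predict(fit, fm$x, type = "prob")
  out <- as.data.frame(cand)
  out$probability <- p
  out$call <- as.integer(p > threshold)
  out
}

#' Write scored candidates as BED6 plus probability
#'
#' Genomic coordinates, 0-based half-open, score column = probability;
#' a companion transcript-coordinate TSV is written alongside.
#'
#' @param scored Result of [scan_transcriptome()].
#' @param path Output BED path.
#' @export
write_predictions_bed <- function(scored, path) {
  write_site_bed(data.frame(chrom = scored$chrom, pos = scored$genomic_pos,
                            name = sprintf("%s:%d", scored$tx_id,
                                           scored$tx_pos),
                            score = round(scored$probability, 4),
                            strand = scored$strand), path)
  write.table(scored, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
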