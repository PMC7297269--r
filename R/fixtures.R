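# Seeded synthetic fixtures: a small genome, gene annotation for an
# lncRNA-like and an mRNA-like gene class, conservation score tracks,
# interval tracks, and replicate base-resolution site-call sets with
# planted signal. The generator emulates the statistical structure of
# replicate single-base m6A experiments: true sites are DRACH adenosines
# sampled with configurable motif preference and 3'-end positional bias,
# conservation tracks are elevated around true sites, and each replicate
# observes the truth through dropout plus false calls at random DRACH
# positions. Effect sizes of zero yield label-independent features.

#' Fixture configuration
#'
#' Defaults define the study conditions used throughout the test-suite:
#' 6 replicate call sets with 15% per-replicate dropout and 5% false calls,
#' 2,000 planted positives per RNA class, class-specific DRACH motif
#' preferences, a 3'-end positional bias of strength 1, and a conservation
#' elevation of 0.35 around true sites. lncRNA-like genes carry few exons,
#' mRNA-like genes are longer with many exons, so topology and z-score
#' features genuinely differ between the classes.
#'
#' @param seed Master integer seed; all randomness derives from it.
#' @param n_genes Named vector: genes per class.
#' @param n_positives Named vector: planted true sites per class.
#' @param n_replicates Number of replicate call sets.
#' @param dropout Per-replicate probability a true site is missed.
#' @param false_call_rate False calls per replicate as a fraction of the
#'   truth size.
#' @param motif_weights Named list (per class) of sampling weights over the
#'   18 DRACH motifs; NULL entries mean uniform.
#' @param pos_bias Named vector: strength b of the 3'-end bias (weight
#'   multiplied by `exp(b * relpos)`).
#' @param conservation_effect Score elevation added to the conservation
#'   tracks within +/-10 nt of true sites (clipped at 1).
#' @param structure_pair_bias Extra weight multiplier for candidates whose
#'   base is paired under the built-in folder (0 disables the check, which
#'   is also the default).
#' @param chromosomes Chromosome names genes are distributed over.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(seed = 20200609L,
                           n_genes = c(lncRNA = 150L, mRNA = 150L),
                           n_positives = c(lncRNA = 2000L, mRNA = 2000L),
                           n_replicates = 6L,
                           dropout = 0.15,
                           false_call_rate = 0.05,
                           motif_weights = default_motif_weights(),
                           pos_bias = c(lncRNA = 1, mRNA = 1),
                           conservation_effect = 0.35,
                           structure_pair_bias = 0,
                           chromosomes = paste0("chr", 1:4)) {
  stopifnot(dropout >= 0, dropout <= 1, false_call_rate >= 0,
            false_call_rate <= 1, n_replicates >= 1)
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_positives = n_positives, n_replicates = n_replicates,
                 dropout = dropout, false_call_rate = false_call_rate,
                 motif_weights = motif_weights, pos_bias = pos_bias,
                 conservation_effect = conservation_effect,
                 structure_pair_bias = structure_pair_bias,
                 chromosomes = chromosomes),
            class = "fixture_config")
}

#' Default class-specific DRACH motif preferences
#'
#' Both classes prefer the canonical GGACU-type motifs, with the lncRNA
#' class shifted toward U-led motifs so the two classes carry genuinely
#' different sequence signal.
#'
#' @return Named list with `lncRNA` and `mRNA` weight vectors over
#'   [drach_motifs()].
#' @export
default_motif_weights <- function() {
  base <- setNames(rep(1, 18), drach_motifs())
  m <- base
  m[c("GGACU", "GAACU", "AGACU", "GGACA", "GGACC", "UGACU")] <-
    c(8, 4, 4, 3, 3, 2)
  l <- base
  l[c("GGACU", "UGACU", "UAACU", "GAACU", "AGACU")] <- c(6, 5, 3, 3, 2)
  list(lncRNA = l, mRNA = m)
}

#' Zero every planted effect in a fixture configuration
#'
#' With all effect sizes zeroed the planted sites are a uniform sample of
#' the DRACH candidates and the tracks carry no site-related elevation, so
#' every feature is label-independent.
#'
#' @param config A [fixture_config()].
#' @return The config with uniform motif weights, no positional bias, and
#'   no conservation elevation or structure bias.
#' @export
zero_effects <- function(config) {
  config$motif_weights <- list(lncRNA = NULL, mRNA = NULL)
  config$pos_bias[] <- 0
  config$conservation_effect <- 0
  config$structure_pair_bias <- 0
  config
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.gene_profiles <- list(
  lncRNA = list(exon_lambda = 1.5, exon_min = 1L, exon_max = 6L,
                exon_len = c(150L, 650L), intron_len = c(200L, 1500L)),
  mRNA = list(exon_lambda = 4, exon_min = 4L, exon_max = 14L,
              exon_len = c(100L, 300L), intron_len = c(300L, 2000L))
)

#' Generate a synthetic fixture
#'
#' Builds the genome, annotation (with extra shorter isoforms so
#' longest-transcript selection is exercised), conservation and interval
#' tracks, planted truth, and replicate call sets, all deterministically
#' from the config seed.
#'
#' @param config A [fixture_config()].
#' @return Object of class `m6a_fixture` with components `genome`,
#'   `models` (all isoforms), `selected` (longest transcript per gene),
#'   `isoform_counts`, `gene_class`, `tracks` (a [track_bundle()]),
#'   `call_sets`, `truth` (planted-site manifest) and `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  set.seed(config$seed)
  chroms <- config$chromosomes
  cursor <- setNames(rep(1L, length(chroms)), chroms)
  models <- list(); selected <- list()
  gene_class <- character(0); isoform_counts <- integer(0)
  gi <- 0L
  for (cls in names(config$n_genes)) {
    prof <- .gene_profiles[[cls]]
    for (g in seq_len(config$n_genes[[cls]])) {
      gi <- gi + 1L
      gene_id <- sprintf("G%s%04d", substr(cls, 1, 1), gi)
      n_ex <- min(prof$exon_max,
                  max(prof$exon_min, prof$exon_min + rpois(1, prof$exon_lambda)))
      ex_len <- sample(prof$exon_len[1]:prof$exon_len[2], n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) {
        sample(prof$intron_len[1]:prof$intron_len[2], n_ex - 1L, replace = TRUE)
      } else integer(0)
      cc <- chroms[(gi - 1L) %% length(chroms) + 1L]
      start <- cursor[[cc]] + 500L
      starts <- integer(n_ex); ends <- integer(n_ex)
      p <- start
      for (e in seq_len(n_ex)) {
        starts[e] <- p; ends[e] <- p + ex_len[e] - 1L
        p <- ends[e] + (if (e < n_ex) in_len[e] else 0L) + 1L
      }
      cursor[[cc]] <- ends[n_ex]
      strand <- sample(c("+", "-"), 1L)
      tx_main <- sprintf("%s.t1", gene_id)
      models[[tx_main]] <- transcript_model(tx_main, gene_id, cc, strand,
                                            starts, ends)
      n_iso <- 1L + rpois(1, 0.8)
      isoform_counts[gene_id] <- n_iso
      if (n_iso > 1L && n_ex > 1L) {
        for (k in seq_len(min(n_iso - 1L, n_ex - 1L))) {
          keep <- seq_len(n_ex - k)  # genomic-order prefix: shorter isoform
          tx_id <- sprintf("%s.t%d", gene_id, k + 1L)
          models[[tx_id]] <- transcript_model(tx_id, gene_id, cc, strand,
                                              starts[keep], ends[keep])
        }
      }
      selected[[gene_id]] <- models[[tx_main]]
      gene_class[gene_id] <- cls
    }
  }
  chrom_len <- setNames(cursor + 500L, chroms)
  genome <- setNames(vapply(chrom_len, .rand_seq, character(1)), chroms)

  # planted truth: weighted sample of full-transcript DRACH candidates
  truth <- list()
  for (cls in names(config$n_positives)) {
    sel_cls <- selected[names(gene_class)[gene_class == cls]]
    cand <- enumerate_candidates(sel_cls, genome, mode = "full_transcript")
    n_pos <- config$n_positives[[cls]]
    if (nrow(cand) < n_pos) {
      stop(sprintf("class %s: %d positives requested but only %d DRACH candidates",
                   cls, n_pos, nrow(cand)), call. = FALSE)
    }
    w <- rep(1, nrow(cand))
    mw <- config$motif_weights[[cls]]
    lens <- vapply(sel_cls, `[[`, integer(1), "span_length")
    names(lens) <- vapply(sel_cls, `[[`, character(1), "transcript_id")
    if (!is.null(mw)) {
      seqs <- vapply(sel_cls, tx_sequence, character(1), genome = genome,
                     mode = "full_transcript")
      names(seqs) <- names(lens)
      fm <- substring(seqs[cand$tx_id], cand$tx_pos - 2L, cand$tx_pos + 2L)
      w <- w * mw[fm]
    }
    b <- config$pos_bias[[cls]]
    if (b != 0) {
      relpos <- cand$tx_pos / lens[cand$tx_id]
      w <- w * exp(b * relpos)
    }
    if (config$structure_pair_bias > 0) {
      seqs <- vapply(sel_cls, tx_sequence, character(1), genome = genome,
                     mode = "full_transcript")
      names(seqs) <- names(lens)
      paired <- vapply(seq_len(nrow(cand)), function(i) {
        s <- seqs[[cand$tx_id[i]]]
        lo <- max(1L, cand$tx_pos[i] - 50L)
        hi <- min(nchar(s), cand$tx_pos[i] + 50L)
        db <- nussinov_fold(substr(s, lo, hi))
        substr(db, cand$tx_pos[i] - lo + 1L, cand$tx_pos[i] - lo + 1L) != "."
      }, logical(1))
      w <- w * (1 + config$structure_pair_bias * paired)
    }
    idx <- sample(nrow(cand), n_pos, prob = w)
    tr <- cand[sort(idx), , drop = FALSE]
    fm <- character(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      s <- tx_sequence(selected[[tr$gene_id[i]]], genome, "full_transcript")
      fm[i] <- substring(s, tr$tx_pos[i] - 2L, tr$tx_pos[i] + 2L)
    }
    tr$motif <- fm
    tr$rna_class <- cls
    truth[[cls]] <- tr
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  tracks <- .fixture_tracks(genome, chrom_len, truth, selected, gene_class,
                            config)
  call_sets <- .fixture_call_sets(truth, selected, genome, config)

  structure(list(genome = genome, chrom_lengths = chrom_len, models = models,
                 selected = selected, isoform_counts = isoform_counts,
                 gene_class = gene_class, tracks = tracks,
                 call_sets = call_sets, truth = truth, config = config),
            class = "m6a_fixture")
}

.fixture_tracks <- function(genome, chrom_len, truth, selected, gene_class,
                            config) {
  shapes <- list(phastcons_primates = c(1.5, 4),
                 phastcons_vertebrates = c(1.2, 4),
                 fitcons_1 = c(2, 6),
                 fitcons_2 = c(2, 7))
  mult <- c(phastcons_primates = 1, phastcons_vertebrates = 0.9,
            fitcons_1 = 0.7, fitcons_2 = 0.7)
  score_tracks <- list()
  for (nm in names(shapes)) {
    vals <- lapply(chrom_len, function(n) {
      round(rbeta(n, shapes[[nm]][1], shapes[[nm]][2]), 4)
    })
    if (config$conservation_effect > 0) {
      for (i in seq_len(nrow(truth))) {
        cc <- truth$chrom[i]
        lo <- max(1L, truth$genomic_pos[i] - 10L)
        hi <- min(chrom_len[[cc]], truth$genomic_pos[i] + 10L)
        vals[[cc]][lo:hi] <- pmin(1, vals[[cc]][lo:hi] +
                                    config$conservation_effect * mult[[nm]])
      }
    }
    score_tracks[[nm]] <- score_track(vals)
  }
  rand_intervals <- function(n, len) {
    cc <- sample(names(chrom_len), n, replace = TRUE)
    st <- vapply(cc, function(c) sample.int(max(1L, chrom_len[[c]] - len), 1L),
                 integer(1))
    interval_track(data.frame(chrom = cc, start = st, end = st + len - 1L,
                              strand = "*"))
  }
  interval_tracks <- list(slot_43 = rand_intervals(100L, 200L),
                          slot_44 = rand_intervals(100L, 500L))
  lnc_genes <- names(gene_class)[gene_class == "lncRNA"]
  pick <- sample(lnc_genes, max(1L, length(lnc_genes) %/% 4L))
  mirna <- interval_track(do.call(rbind, lapply(pick, function(g) {
    m <- selected[[g]]
    data.frame(chrom = m$chrom, start = m$span_start, end = m$span_end,
               strand = m$strand)
  })))
  track_bundle(score_tracks = score_tracks, interval_tracks = interval_tracks,
               mirna_track = mirna, structure = structure_provider("nussinov"))
}

.fixture_call_sets <- function(truth, selected, genome, config) {
  n_false <- round(config$false_call_rate * nrow(truth))
  false_pool <- NULL
  if (n_false > 0) {
    cand_all <- enumerate_candidates(selected, genome, "full_transcript")
    tk <- sprintf("%s:%d:%s", truth$chrom, truth$genomic_pos, truth$strand)
    ck <- sprintf("%s:%d:%s", cand_all$chrom, cand_all$genomic_pos,
                  cand_all$strand)
    false_pool <- cand_all[!ck %in% tk, , drop = FALSE]
  }
  lapply(seq_len(config$n_replicates), function(r) {
    set.seed(config$seed + 1000L * r)  # deterministic per-replicate sub-seed
    keep <- runif(nrow(truth)) >= config$dropout
    df <- data.frame(chrom = truth$chrom[keep], pos = truth$genomic_pos[keep],
                     strand = truth$strand[keep])
    if (n_false > 0 && nrow(false_pool) > 0) {
      fi <- sample(nrow(false_pool), min(n_false, nrow(false_pool)))
      df <- rbind(df, data.frame(chrom = false_pool$chrom[fi],
                                 pos = false_pool$genomic_pos[fi],
                                 strand = false_pool$strand[fi]))
    }
    site_call_set(df, experiment = sprintf("replicate_%d", r))
  })
}

#' @export
print.m6a_fixture <- function(x, ...) {
  cat(sprintf("<m6a_fixture> %d genes (%d lncRNA-like, %d mRNA-like), genome %.2f Mb\n",
              length(x$selected), sum(x$gene_class == "lncRNA"),
              sum(x$gene_class == "mRNA"),
              sum(nchar(x$genome)) / 1e6))
  cat(sprintf("  %d planted sites, %d replicate call sets (dropout %.0f%%, false %.0f%%)\n",
              nrow(x$truth), length(x$call_sets), 100 * x$config$dropout,
              100 * x$config$false_call_rate))
  invisible(x)
}

#' Configuration with a realistic lncRNA/mRNA class imbalance
#'
#' Sizes the fixture so the lncRNA class yields about 1,291 planted
#' positives while the mRNA class is at least 20-fold larger — the regime,
#' typical of base-resolution m6A compendia, whose scarcity of lncRNA sites
#' motivates the ensemble blend.
#'
#' @param seed Master seed.
#' @return A [fixture_config()].
#' @export
class_imbalance_config <- function(seed = 20200609L) {
  fixture_config(seed = seed,
                 n_genes = c(lncRNA = 120L, mRNA = 600L),
                 n_positives = c(lncRNA = 1291L, mRNA = 1291L * 25L))
}

#' Write a fixture to standard-format files
#'
#' Emits `genome.fa`, `annotation.gtf`, the four conservation tracks as
#' bedGraph, the interval tracks and replicate call sets as BED6, and the
#' truth manifest as TSV.
#'
#' @param fixture An `m6a_fixture`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fixture$genome),
                              file.path(dir, "genome.fa"))
  writeLines(format_gtf(fixture$models), file.path(dir, "annotation.gtf"))
  for (nm in names(fixture$tracks$score_tracks)) {
    write_score_track(fixture$tracks$score_tracks[[nm]],
                      file.path(dir, paste0(nm, ".bedGraph")))
  }
  for (nm in names(fixture$tracks$interval_tracks)) {
    rtracklayer::export(fixture$tracks$interval_tracks[[nm]],
                        file.path(dir, paste0(nm, ".bed")), format = "BED")
  }
  if (!is.null(fixture$tracks$mirna_track)) {
    rtracklayer::export(fixture$tracks$mirna_track,
                        file.path(dir, "mirna_targets.bed"), format = "BED")
  }
  for (r in seq_along(fixture$call_sets)) {
    s <- fixture$call_sets[[r]]
    write_site_bed(data.frame(chrom = s$chrom, pos = s$pos, strand = s$strand),
                   file.path(dir, sprintf("calls_rep%d.bed", r)))
  }
  write.table(fixture$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Format transcript models as GTF lines
#'
#' @param models Named list of `transcript_model`.
#' @return Character vector of GTF exon lines.
#' @export
format_gtf <- function(models) {
  unlist(lapply(models, function(m) {
    sprintf(paste0("%s\tlncm6A\texon\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\";"),
            m$chrom, m$exon_start, m$exon_end, m$strand,
            m$gene_id, m$transcript_id)
  }), use.names = FALSE)
}
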