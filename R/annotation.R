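# Transcript models: exon structure, coordinate projection between genomic
# and transcript systems, and topology queries under the two coordinate
# modes. Genomic coordinates are 1-based inclusive (GTF convention)
# throughout; BED output is converted to 0-based half-open at the boundary.

#' Build a transcript model from exon intervals
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Genomic exon intervals, 1-based inclusive.
#'   Exons must not overlap.
#' @return An object of class `transcript_model` with the exon table sorted
#'   in genomic order plus derived span and mature lengths.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L,
            all(exon_ends >= exon_starts),
            strand %in% c("+", "-"))
  o <- order(exon_starts)
  s <- as.integer(exon_starts[o]); e <- as.integer(exon_ends[o])
  if (length(s) > 1L && any(s[-1] <= e[-length(e)])) {
    stop(sprintf("overlapping exons in transcript '%s'", transcript_id),
         call. = FALSE)
  }
  m <- structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    exon_start = s,
    exon_end = e,
    span_start = s[1],
    span_end = e[length(e)],
    span_length = e[length(e)] - s[1] + 1L,
    mature_length = sum(e - s + 1L),
    n_exons = length(s)
  ), class = "transcript_model")
  m
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%d-%d(%s)\n",
              x$transcript_id, x$gene_id, x$chrom,
              x$span_start, x$span_end, x$strand))
  cat(sprintf("  %d exon(s); span %d nt, mature %d nt\n",
              x$n_exons, x$span_length, x$mature_length))
  invisible(x)
}

#' Mode-dependent transcript length
#'
#' @param model A `transcript_model`.
#' @param mode Coordinate mode (see [coordinate_modes()]).
#' @return Length in nt: the full genomic span (introns included) in
#'   full-transcript mode, the summed exon length in mature mode.
#' @export
tx_length <- function(model, mode = "full_transcript") {
  mode <- match_mode(mode)
  if (mode == "full_transcript") model$span_length else model$mature_length
}

# exon lengths and cumulative mature offsets in transcript (5'->3') order
.exons_tx_order <- function(model) {
  idx <- if (model$strand == "+") seq_len(model$n_exons) else rev(seq_len(model$n_exons))
  len <- (model$exon_end - model$exon_start + 1L)[idx]
  list(idx = idx, len = len, cum = cumsum(len))
}

#' Project positions between genomic and transcript coordinates
#'
#' Full-transcript mode is an offset map over the unspliced span; mature mode
#' maps through the exon chain and is a bijection between mature coordinates
#' and exonic genomic coordinates. Intronic genomic positions have no mature
#' image and raise an error in mature mode.
#'
#' @param model A `transcript_model`.
#' @param position Integer vector of positions in the source system.
#' @param from,to `"genomic"` or `"transcript"`.
#' @param mode Coordinate mode.
#' @return Integer vector of projected positions.
#' @export
tx_project <- function(model, position,
                       from = c("genomic", "transcript"),
                       to = c("transcript", "genomic"),
                       mode = "full_transcript") {
  from <- match.arg(from); to <- match.arg(to); mode <- match_mode(mode)
  position <- as.integer(position)
  if (from == to) return(position)
  minus <- model$strand == "-"
  if (mode == "full_transcript") {
    if (from == "genomic") {
      if (any(position < model$span_start | position > model$span_end)) {
        stop("genomic position outside transcript span", call. = FALSE)
      }
      return(if (minus) model$span_end - position + 1L
             else position - model$span_start + 1L)
    }
    if (any(position < 1L | position > model$span_length)) {
      stop("transcript position outside full-transcript range", call. = FALSE)
    }
    return(if (minus) model$span_end - position + 1L
           else model$span_start + position - 1L)
  }
  # mature mode
  ex <- .exons_tx_order(model)
  if (from == "transcript") {
    if (any(position < 1L | position > model$mature_length)) {
      stop("transcript position outside mature range", call. = FALSE)
    }
    k <- findInterval(position - 1L, c(0L, ex$cum), rightmost.closed = FALSE)
    off <- position - c(0L, ex$cum)[k] # 1-based offset within exon k
    gidx <- ex$idx[k]
    return(if (minus) model$exon_end[gidx] - off + 1L
           else model$exon_start[gidx] + off - 1L)
  }
  # genomic -> mature
  out <- integer(length(position))
  for (i in seq_along(position)) {
    p <- position[i]
    k <- which(p >= model$exon_start & p <= model$exon_end)
    if (length(k) != 1L) {
      stop(sprintf("genomic position %d has no mature image (intronic or off-transcript)", p),
           call. = FALSE)
    }
    j <- which(ex$idx == k)
    prev <- if (j > 1L) ex$cum[j - 1L] else 0L
    out[i] <- prev + (if (minus) model$exon_end[k] - p else p - model$exon_start[k]) + 1L
  }
  out
}

#' Is a genomic position exonic for a transcript?
#'
#' @inheritParams tx_project
#' @return Logical vector.
#' @export
is_exonic <- function(model, position) {
  vapply(as.integer(position), function(p) {
    any(p >= model$exon_start & p <= model$exon_end)
  }, logical(1))
}

# Junction coordinates in the mode's transcript system, under the
# "between bases" convention: a junction with coordinate j sits between
# transcript positions j and j+1. In mature mode the junctions are the
# exon-exon boundaries; in full-transcript mode both the donor (exon end)
# and acceptor (exon start) boundaries of every intron count.
.junctions <- function(model, mode) {
  if (model$n_exons < 2L) return(integer(0))
  if (mode == "mature_rna") {
    ex <- .exons_tx_order(model)
    return(ex$cum[-length(ex$cum)])
  }
  ex <- .exons_tx_order(model)
  jj <- integer(0)
  for (j in seq_len(model$n_exons - 1L)) {
    gidx <- ex$idx[j]
    # donor: last base of exon j (transcript orientation)
    don <- if (model$strand == "+") model$exon_end[gidx] else model$exon_start[gidx]
    don_t <- tx_project(model, don, "genomic", "transcript", "full_transcript")
    # acceptor: first base of exon j+1; junction is just before it
    gidx2 <- ex$idx[j + 1L]
    acc <- if (model$strand == "+") model$exon_start[gidx2] else model$exon_end[gidx2]
    acc_t <- tx_project(model, acc, "genomic", "transcript", "full_transcript")
    jj <- c(jj, don_t, acc_t - 1L)
  }
  sort(unique(jj))
}

#' Distances to the nearest splice junctions
#'
#' Nucleotide distances, in the active mode's coordinate system, from a site
#' to the nearest upstream (5') and downstream (3') splice junction, each
#' truncated at `cap`. A junction between transcript positions j and j+1 is
#' at distance `p - j` from a downstream site p and `j - p + 1` from an
#' upstream site. Single-exon transcripts (no junctions) return the cap for
#' both.
#'
#' @param model A `transcript_model`.
#' @param tx_pos Site position(s) in the mode's transcript coordinates.
#' @param mode Coordinate mode.
#' @param cap Truncation distance in nt (default 2000).
#' @return Matrix with columns `dist_sj_5_p2000`, `dist_sj_3_p2000`.
#' @export
splice_junction_distances <- function(model, tx_pos, mode = "full_transcript",
                                      cap = 2000L) {
  mode <- match_mode(mode)
  len <- tx_length(model, mode)
  tx_pos <- as.integer(tx_pos)
  if (any(tx_pos < 1L | tx_pos > len)) {
    stop("site position off transcript", call. = FALSE)
  }
  jj <- .junctions(model, mode)
  out <- matrix(as.numeric(cap), nrow = length(tx_pos), ncol = 2L,
                dimnames = list(NULL, c("dist_sj_5_p2000", "dist_sj_3_p2000")))
  if (length(jj) == 0L) return(out)
  for (i in seq_along(tx_pos)) {
    p <- tx_pos[i]
    up <- jj[jj < p]
    dn <- jj[jj >= p]
    if (length(up)) out[i, 1L] <- min(cap, p - max(up))
    if (length(dn)) out[i, 2L] <- min(cap, min(dn) - p + 1L)
  }
  out
}

region_flag_names <- function() {
  c("exon", "intron", "first_exon", "internal_exon", "last_exon",
    "five_prime_half", "three_prime_half", "tss_prox_100", "tes_prox_100",
    "long_exon_400")
}

#' Transcript-topology dummy variables for a site
#'
#' The 10 binary region features: overlap with any exon, with an intron
#' (always 0 in mature mode), with the first / an internal / the last exon
#' (in transcript orientation), location in the 5' or 3' half of the
#' transcript, proximity (within 100 nt) to the transcription start and end,
#' and containment in a long (>= 400 nt) exon.
#'
#' @inheritParams splice_junction_distances
#' @return Integer matrix, one row per site, 10 named 0/1 columns.
#' @export
region_flags <- function(model, tx_pos, mode = "full_transcript") {
  mode <- match_mode(mode)
  len <- tx_length(model, mode)
  tx_pos <- as.integer(tx_pos)
  if (any(tx_pos < 1L | tx_pos > len)) {
    stop("site position off transcript", call. = FALSE)
  }
  n <- length(tx_pos)
  out <- matrix(0L, nrow = n, ncol = 10L,
                dimnames = list(NULL, region_flag_names()))
  gpos <- tx_project(model, tx_pos, "transcript", "genomic", mode)
  ex <- .exons_tx_order(model)
  for (i in seq_len(n)) {
    g <- gpos[i]
    k <- which(g >= model$exon_start & g <= model$exon_end)  # genomic index
    exonic <- length(k) == 1L
    out[i, "exon"] <- as.integer(exonic)
    out[i, "intron"] <- as.integer(!exonic)
    if (exonic) {
      j <- which(ex$idx == k)  # transcript-order index
      out[i, "first_exon"] <- as.integer(j == 1L)
      out[i, "last_exon"] <- as.integer(j == model$n_exons)
      out[i, "internal_exon"] <- as.integer(j > 1L && j < model$n_exons)
      out[i, "long_exon_400"] <- as.integer(ex$len[j] >= 400L)
    }
    p <- tx_pos[i]
    out[i, "five_prime_half"] <- as.integer(p <= len / 2)
    out[i, "three_prime_half"] <- as.integer(p > len / 2)
    out[i, "tss_prox_100"] <- as.integer(p <= 100L)
    out[i, "tes_prox_100"] <- as.integer(len - p < 100L)
  }
  out
}

#' Length of the exon/intron containing a site
#'
#' @inheritParams splice_junction_distances
#' @return Integer vector: length in nt of the containing exon (or, in
#'   full-transcript mode, the containing intron for intronic sites).
#' @export
containing_region_length <- function(model, tx_pos, mode = "full_transcript") {
  mode <- match_mode(mode)
  gpos <- tx_project(model, as.integer(tx_pos), "transcript", "genomic", mode)
  vapply(gpos, function(g) {
    k <- which(g >= model$exon_start & g <= model$exon_end)
    if (length(k) == 1L) {
      model$exon_end[k] - model$exon_start[k] + 1L
    } else {
      # intron between genomic exons k0 and k0+1
      k0 <- max(which(model$exon_end < g))
      model$exon_start[k0 + 1L] - model$exon_end[k0] - 1L
    }
  }, integer(1))
}

#' Read gene annotation into transcript models
#'
#' Parses a GTF or GFF3 file (dispatched on extension by rtracklayer) and
#' builds one `transcript_model` per transcript from its exon records. Exon
#' records must carry `gene_id` and `transcript_id` attributes (for GFF3,
#' `Parent` is accepted in place of `transcript_id`). Transcripts whose gene
#' has no exon record are skipped with a warning.
#'
#' @param path GTF/GFF3 file.
#' @return Named list of `transcript_model` objects (names = transcript ids),
#'   with a `gene_index` attribute mapping gene id -> transcript ids.
#' @export
load_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  keep <- !is.na(type) & tolower(type) == "exon"
  if (!any(keep)) stop(sprintf("no exon records in '%s'", path), call. = FALSE)
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  tx <- if ("transcript_id" %in% colnames(md) && !all(is.na(md$transcript_id))) {
    as.character(md$transcript_id)
  } else if ("Parent" %in% colnames(md)) {
    as.character(unlist(lapply(md$Parent, `[`, 1L)))
  } else {
    stop(sprintf("exon records in '%s' lack transcript_id/Parent", path),
         call. = FALSE)
  }
  gid <- if ("gene_id" %in% colnames(md) && !all(is.na(md$gene_id))) {
    as.character(md$gene_id)
  } else {
    stop(sprintf("exon records in '%s' lack gene_id", path), call. = FALSE)
  }
  tx <- sub("^transcript:", "", tx)
  gid <- sub("^gene:", "", gid)
  if (anyNA(tx) || anyNA(gid)) {
    stop(sprintf("exon record %d in '%s' lacks gene_id or transcript_id",
                 which(is.na(tx) | is.na(gid))[1], path), call. = FALSE)
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  models <- list()
  for (t in unique(tx)) {
    idx <- which(tx == t)
    models[[t]] <- transcript_model(t, gid[idx[1]], chrom[idx[1]],
                                    strand[idx[1]], start[idx], end[idx])
  }
  gene_index <- split(names(models),
                      vapply(models, `[[`, character(1), "gene_id"))
  attr(models, "gene_index") <- gene_index
  models
}

#' Select the longest transcript of each gene
#'
#' Isoform effects are avoided by keeping, per gene, the transcript with the
#' greatest mature length; ties are broken by the lexicographically smallest
#' transcript id.
#'
#' @param models Named list of `transcript_model` (e.g. from
#'   [load_annotation()]).
#' @return Named list with one `transcript_model` per gene (names = gene
#'   ids).
#' @export
select_longest_transcript <- function(models) {
  if (length(models) == 0L) stop("no transcripts", call. = FALSE)
  genes <- vapply(models, `[[`, character(1), "gene_id")
  out <- lapply(split(models, genes), function(ms) {
    len <- vapply(ms, `[[`, integer(1), "mature_length")
    ids <- vapply(ms, `[[`, character(1), "transcript_id")
    best <- which(len == max(len))
    ms[[best[order(ids[best])[1]]]]
  })
  out[order(names(out))]
}

#' Extract a transcript's sequence from a genome
#'
#' Full-transcript mode returns the unspliced pre-RNA (genomic span),
#' mature mode the spliced exon chain; minus-strand transcripts are
#' reverse-complemented so the result reads 5'->3'. The sequence is returned
#' in the RNA alphabet.
#'
#' @param model A `transcript_model`.
#' @param genome Named character vector of chromosome sequences (DNA or
#'   RNA), or a `Biostrings::DNAStringSet`.
#' @param mode Coordinate mode.
#' @return Single RNA string.
#' @export
tx_sequence <- function(model, genome, mode = "full_transcript") {
  mode <- match_mode(mode)
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  chrom_seq <- genome[[model$chrom]]
  if (is.null(chrom_seq)) {
    stop(sprintf("chromosome '%s' absent from genome", model$chrom), call. = FALSE)
  }
  s <- if (mode == "full_transcript") {
    substr(chrom_seq, model$span_start, model$span_end)
  } else {
    paste(substring(chrom_seq, model$exon_start, model$exon_end), collapse = "")
  }
  if (model$strand == "-") s <- revcomp(s)
  as_rna(s)
}

#' Reverse complement
#'
#' @param x Character vector of DNA/RNA strings.
#' @return Reverse complement in the DNA alphabet (U is complemented to A;
#'   downstream sequence entry points convert back to RNA).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
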