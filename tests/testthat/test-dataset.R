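# Dataset-construction rules on hand-built toys and the shared fixture.

toy_genome_with_drach <- function() {
  # chr1: plant GGACU motifs at known positions inside a 300-nt sequence
  set.seed(122)
  s <- strsplit(random_rna(300, c("C", "G")), "")[[1]]  # no A: no stray DRACH
  plant <- function(s, at) {
    s[at:(at + 4)] <- c("G", "G", "A", "C", "U")
    s
  }
  for (at in c(21, 101, 151, 201, 251)) s <- plant(s, at)
  c(chr1 = paste(s, collapse = ""))
}

test_that("consensus positives require replicate support and DRACH context", {
  genome <- toy_genome_with_drach()
  mk <- function(pos) site_call_set(data.frame(chrom = "chr1", pos = pos,
                                               strand = "+"))
  sets <- list(mk(c(23, 103)), mk(c(23, 153)), mk(c(103, 60)))
  cons <- consensus_positives(sets, min_support = 2, genome = genome)
  expect_equal(cons$pos, c(23L, 103L))  # 153 and 60 seen once; 60 not DRACH
  expect_equal(cons$support, c(2L, 2L))
  u <- consensus_positives(sets, min_support = 1, genome = genome)
  expect_equal(u$pos, c(23L, 103L, 153L))  # union, DRACH-filtered (60 dropped)
  expect_error(consensus_positives(list()), "no call sets")
})

test_that("multi-gene sites are excluded and negatives never collide", {
  genome <- toy_genome_with_drach()
  g1 <- transcript_model("t1", "g1", "chr1", "+", 1L, 180L)
  g2 <- transcript_model("t2", "g2", "chr1", "+", 120L, 300L)
  selected <- list(g1 = g1, g2 = g2)
  sites <- data.frame(chrom = "chr1", pos = c(23L, 153L, 253L),
                      strand = c("+", "+", "+"))
  asg <- assign_sites_to_genes(sites, selected)
  # 153 lies in both spans -> excluded; 23 -> g1, 253 -> g2
  expect_equal(asg$gene_id, c("g1", "g2"))
  expect_equal(asg$genomic_pos, c(23L, 253L))
  pool <- enumerate_candidates(selected, genome)
  expect_true(all(is_drach_adenosine(genome, pool$chrom, pool$genomic_pos,
                                     pool$strand)))
  neg <- sample_negatives(pool, exclude = data.frame(chrom = "chr1",
                                                     pos = c(23L, 103L),
                                                     strand = "+"),
                          n = 2, seed = 1)
  expect_equal(nrow(neg), 2L)
  expect_false(any(neg$genomic_pos %in% c(23L, 103L)))
  expect_error(sample_negatives(pool, exclude = data.frame(chrom = character(0),
                                                           pos = integer(0),
                                                           strand = character(0)),
                                n = 100, seed = 1),
               "deficit")
  # determinism of the sample
  n1 <- sample_negatives(pool, data.frame(chrom = character(0), pos = integer(0),
                                          strand = character(0)), 3, seed = 7)
  n2 <- sample_negatives(pool, data.frame(chrom = character(0), pos = integer(0),
                                          strand = character(0)), 3, seed = 7)
  expect_identical(n1, n2)
})

test_that("train/test split is stratified, disjoint and seed-reproducible", {
  labels <- rep(c("positive", "negative"), each = 50)
  sp <- split_train_test(labels, fraction = 0.8, seed = 9)
  expect_equal(sum(sp == "train"), 80L)
  expect_equal(sum(sp == "test"), 20L)
  expect_equal(sum(sp == "train" & labels == "positive"), 40L)
  expect_equal(sum(sp == "test" & labels == "negative"), 10L)
  expect_identical(sp, split_train_test(labels, fraction = 0.8, seed = 9))
  expect_true(all(split_train_test(labels, fraction = 1, seed = 1) == "train"))
})

test_that("dataset construction is balanced with no duplicate or intronic leaks", {
  fx <- small_fixture()
  sel_lnc <- fx$selected[names(fx$gene_class)[fx$gene_class == "lncRNA"]]
  for (mode in coordinate_modes()) {
    ds <- build_labeled_dataset(fx$call_sets, sel_lnc, fx$genome, mode = mode,
                                seed = 31)
    s <- ds$sites
    expect_equal(sum(s$label == "positive"), sum(s$label == "negative"))
    expect_equal(anyDuplicated(site_key(s)), 0L)
    expect_equal(anyDuplicated(sprintf("%s:%d:%s", s$chrom, s$genomic_pos,
                                       s$strand)), 0L)
    # negatives never collide with positive coordinates
    pk <- with(s[s$label == "positive", ],
               sprintf("%s:%d:%s", chrom, genomic_pos, strand))
    nk <- with(s[s$label == "negative", ],
               sprintf("%s:%d:%s", chrom, genomic_pos, strand))
    expect_length(intersect(pk, nk), 0L)
    expect_equal(abs(sum(s$split == "train") - round(0.8 * nrow(s))) <= 1, TRUE)
    if (mode == "mature_rna") {
      # no intronic sites in mature mode
      for (i in sample(nrow(s), 30)) {
        m <- sel_lnc[[s$gene_id[i]]]
        expect_true(is_exonic(m, s$genomic_pos[i]))
      }
    }
  }
})

test_that("feature matrices are deterministic with frozen catalog columns", {
  fx <- small_fixture()
  sel_lnc <- fx$selected[names(fx$gene_class)[fx$gene_class == "lncRNA"]]
  ds <- build_labeled_dataset(fx$call_sets, sel_lnc, fx$genome, seed = 31)
  sub <- ds$sites[1:40, ]
  tx <- setNames(sel_lnc, vapply(sel_lnc, `[[`, character(1), "transcript_id"))
  pop <- gene_population(sel_lnc, fx$genome, fx$isoform_counts)
  fm <- build_feature_matrix(sub, tx, fx$genome, fx$tracks, pop)
  expect_equal(dim(fm$x), c(40L, 144L))
  expect_identical(colnames(fm$x), feature_catalog())
  # motif one-hot block sums to one per site
  oh <- fm$x[, paste0("motif_", drach_motifs())]
  expect_true(all(rowSums(oh) == 1))
  # dummies binary, distances within the cap
  dum <- fm$x[, c(region_flag_names(), overlap_track_names(), "mirna_target")]
  expect_true(all(dum %in% c(0, 1)))
  dst <- fm$x[, c("dist_sj_5_p2000", "dist_sj_3_p2000", "dist_nearest_p2000")]
  expect_true(all(dst >= 0 & dst <= 2000))
  # duplicated site gives an identical row; rebuild is identical
  dup <- build_feature_matrix(rbind(sub[5, ], sub[5, ]), tx, fx$genome,
                              fx$tracks, pop)
  expect_equal(dup$x[1, c(1:84, 85:140)], dup$x[2, c(1:84, 85:140)])
  fm2 <- build_feature_matrix(sub, tx, fx$genome, fx$tracks, pop)
  expect_identical(fm$x, fm2$x)
  # z-score blocks standardised against the gene population
  zg <- zscore(pop$exon_num, pop$exon_num)
  expect_equal(mean(zg), 0, tolerance = 1e-9)
  expect_equal(mean(zg^2), 1, tolerance = 1e-9)
  expect_equal(mean(fm$x[, "gc_local"]), 0, tolerance = 1e-9)
  expect_equal(mean(fm$x[, "gc_local"]^2), 1, tolerance = 1e-9)
  # single-site extraction agrees with the batch genomic block
  one <- extract_genomic_vector(sub[3, ], tx, fx$genome, fx$tracks, pop)
  batch <- genomic_feature_matrix(sub, tx, fx$genome, fx$tracks, pop,
                                  quiet = TRUE)
  same <- setdiff(genomic_feature_catalog()$name, "gc_local")
  expect_equal(one[same], batch[3, same])
})

test_that("manifests and site BEDs round-trip through files", {
  fx <- small_fixture()
  sel_lnc <- fx$selected[names(fx$gene_class)[fx$gene_class == "lncRNA"]]
  ds <- build_labeled_dataset(fx$call_sets, sel_lnc, fx$genome, seed = 31)
  p <- tempfile(fileext = ".tsv")
  write_dataset_manifest(ds, p)
  back <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(ds$sites))
  expect_equal(back$label, ds$sites$label)
  bed <- tempfile(fileext = ".bed")
  df <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = c("+", "-"))
  write_site_bed(df, bed)
  rs <- read_site_calls(bed)
  expect_equal(rs$pos, c(10L, 20L))
  expect_equal(rs$strand, c("+", "-"))
})
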