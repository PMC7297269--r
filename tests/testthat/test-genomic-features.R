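test_that("the genomic catalog has 60 frozen entries and the full catalog 144", {
  cat60 <- genomic_feature_catalog()
  expect_equal(nrow(cat60), 60L)
  expect_equal(anyDuplicated(cat60$name), 0L)
  expect_equal(cat60$index, 1:60)
  expect_equal(sum(cat60$group == "motif_onehot"), 18L)
  expect_length(feature_catalog(), 144L)
})

test_that("region length features are log2 of region and mature lengths", {
  single <- transcript_model("s", "g", "chr1", "+", 1L, 1024L)
  expect_equal(unname(region_length_features(single, 512L, "full_transcript")[1, ]),
               c(10, 10))
  m <- transcript_model("t", "g", "chr1", "+", c(1L, 501L), c(256L, 1268L))
  # site in the 256-nt exon of a 1024-nt mature transcript
  expect_equal(unname(region_length_features(m, 100L, "mature_rna")[1, ]),
               c(8, 10))
  one <- transcript_model("o", "g", "chr1", "+", 1L, 1L)
  expect_equal(unname(region_length_features(one, 1L, "mature_rna")[1, 1]), 0)
})

test_that("clustering features count candidate neighbours with capped distance", {
  lone <- clustering_features(100L, 100L)
  expect_equal(unname(lone[1, ]), c(0, 0, 0, 2000))
  two <- clustering_features(c(100L, 110L), c(100L, 110L))
  expect_equal(unname(two[1, ]), c(1, 1, 1, 10))
  expect_equal(unname(two[2, ]), c(1, 1, 1, 10))
  set.seed(104)
  pos <- sort(sample(10000L, 60L))
  cl <- clustering_features(pos, pos)
  expect_true(all(cl[, "clust_50"] <= cl[, "clust_500"]))
  expect_true(all(cl[, "clust_500"] <= cl[, "clust_2000"]))
  # brute force
  for (i in sample(60L, 10L)) {
    d <- abs(pos[-i] - pos[i])
    expect_equal(unname(cl[i, ]),
                 c(sum(d <= 50), sum(d <= 500), sum(d <= 2000),
                   min(2000, min(d))))
  }
})

test_that("conservation features are window means with zero imputation", {
  m <- transcript_model("t", "g", "chr1", "+", 1L, 200L)
  vals <- list(chr1 = rep(0.25, 200))
  tracks <- track_bundle(score_tracks = list(phastcons_primates = score_track(vals)))
  f <- conservation_features(m, 100L, tracks, quiet = TRUE)
  expect_equal(unname(f[1, "phastcons_primates"]), 0.25)
  expect_equal(unname(f[1, "fitcons_1"]), 0)  # absent track -> all imputed 0
  set.seed(105)
  rv <- runif(200)
  tracks2 <- track_bundle(score_tracks = list(fitcons_1 = score_track(list(chr1 = rv))))
  f2 <- conservation_features(m, 57L, tracks2, quiet = TRUE)
  expect_equal(unname(f2[1, "fitcons_1"]), mean(rv[47:67]))
  # all-missing window reports the imputation
  gap <- rv; gap[90:110] <- NA
  tracks3 <- track_bundle(score_tracks = list(fitcons_1 = score_track(list(chr1 = gap))))
  expect_message(f3 <- conservation_features(m, 100L, tracks3),
                 "imputed as 0")
  expect_equal(unname(f3[1, "fitcons_1"]), 0)
  # mature mode: the window follows the spliced transcript across the intron
  sp <- transcript_model("t2", "g", "chr1", "+", c(1L, 101L), c(50L, 150L))
  rv2 <- runif(150)
  tracks4 <- track_bundle(score_tracks = list(fitcons_2 = score_track(list(chr1 = rv2))))
  f4 <- conservation_features(sp, 50L, tracks4, mode = "mature_rna", quiet = TRUE)
  gwin <- c(40:50, 101:110)  # mature 40..60 spans the junction
  expect_equal(unname(f4[1, "fitcons_2"]), mean(rv2[gwin]))
})

test_that("structure features read pairing state from dot-bracket windows", {
  expect_equal(unname(structure_features(strrep(".", 101), 51L)), c(0, 0))
  db <- paste0(strrep("(", 20), strrep(".", 61), strrep(")", 20))
  expect_equal(unname(structure_features(db, 10L)), c(1, 40 / 101))
  expect_equal(unname(structure_features(db, 51L)), c(0, 40 / 101))
})

test_that("the built-in folder matches exhaustive maximum pairing", {
  expect_equal(nussinov_fold("AAAA"), "....")
  expect_equal(pair_count(nussinov_fold("GGGAAACCC")), 3L)
  expect_error(nussinov_fold(random_rna(300)), "folding guard")
  set.seed(106)
  for (r in 1:60) {
    s <- random_rna(sample(1:12, 1))
    db <- nussinov_fold(s)
    expect_true(check_structure_legal(s, db))
    expect_equal(pair_count(db), brute_max_pairs(s), info = s)
  }
  # longer sequences still emit legal structures
  for (r in 1:5) {
    s <- random_rna(80)
    expect_true(check_structure_legal(s, nussinov_fold(s)))
  }
})

test_that("site structure features accept precomputed structures", {
  genome <- c(chr1 = strrep("A", 200))
  m <- transcript_model("t", "g", "chr1", "+", 1L, 200L)
  seqs <- tx_sequence(m, genome)
  pre <- structure_provider("precomputed",
                            setNames(paste0("((((", strrep(".", 93), "))))"),
                                     "t:50"))
  f <- site_structure_features(m, 100L, seqs, pre)
  expect_equal(unname(f[1, ]), c(0, 8 / 101))
  expect_error(site_structure_features(m, 120L, seqs, pre), "no precomputed")
})

test_that("z-scores use the population-sd convention", {
  expect_equal(zscore(4, c(2, 4, 6)), 0)
  expect_equal(zscore(6, c(2, 4, 6)), sqrt(3 / 2))
  expect_equal(zscore(5, c(3, 3, 3)), 0)  # sd = 0 -> 0
  v <- c(1, 5, 9, 2)
  z <- zscore(v, v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
})

test_that("overlap flags are strand-aware with empty tracks giving zeros", {
  tb <- track_bundle()
  f <- attribute_overlap_flags(tb, "chr1", 100L, "+")
  expect_equal(unname(f[1, ]), rep(0L, 14))
  tr <- interval_track(data.frame(chrom = "chr1", start = 50L, end = 150L,
                                  strand = "+"))
  tb2 <- track_bundle(interval_tracks = list(slot_45 = tr))
  f2 <- attribute_overlap_flags(tb2, c("chr1", "chr1", "chr2"),
                                c(100L, 200L, 100L), c("+", "+", "+"))
  expect_equal(unname(f2[, "slot_45"]), c(1L, 0L, 0L))
  expect_equal(sum(f2), 1L)
  # opposite strand does not overlap
  f3 <- attribute_overlap_flags(tb2, "chr1", 100L, "-")
  expect_equal(unname(f3[1, "slot_45"]), 0L)
  # unstranded intervals overlap either strand
  tru <- interval_track(data.frame(chrom = "chr1", start = 50L, end = 150L))
  tb3 <- track_bundle(mirna_track = tru)
  expect_equal(unname(attribute_overlap_flags(tb3, "chr1", 100L, "-")[1, "mirna_target"]),
               1L)
})
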