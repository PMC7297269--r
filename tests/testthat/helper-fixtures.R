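# Shared toy objects and brute-force oracles for the test-suite.
# Fixtures are built in code; the small planted fixture is generated once
# per test run and cached.

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# two-exon plus-strand toy transcript: exons [1,100], [201,300]
toy_tx_plus <- function() {
  transcript_model("tplus", "gtoy", "chr1", "+", c(1L, 201L), c(100L, 300L))
}

# three-exon minus-strand toy transcript
toy_tx_minus <- function() {
  transcript_model("tminus", "gtoy2", "chr1", "-",
                   c(1001L, 1301L, 1601L), c(1100L, 1400L, 1700L))
}

small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- fixture_config(seed = 4242L,
                            n_genes = c(lncRNA = 30L, mRNA = 30L),
                            n_positives = c(lncRNA = 250L, mRNA = 250L))
      cache <<- generate_fixture(cfg)
    }
    cache
  }
})

# brute-force DRACH scan: test every 5-mer against the definition sets
brute_drach <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- integer(0)
  if (n < 5L) return(out)
  for (p in 3:(n - 2L)) {
    if (chars[p] == "A" &&
        chars[p - 2L] %in% c("A", "G", "U") &&
        chars[p - 1L] %in% c("A", "G") &&
        chars[p + 1L] == "C" &&
        chars[p + 2L] %in% c("A", "C", "U")) {
      out <- c(out, p)
    }
  }
  out
}

# exhaustive maximum base-pairing count by direct recursion (no memo):
# the 5'-most base is either unpaired or paired with every legal partner,
# splitting the interval into independent inside/outside halves
brute_max_pairs <- function(sequence, min_loop = 3L) {
  chars <- strsplit(chartr("T", "U", toupper(sequence)), "", fixed = TRUE)[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(chars[i], chars[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  n <- length(chars)
  if (n < min_loop + 2L) return(0L)
  rec(1L, n)
}

# dot-bracket legality: balanced, every pair a legal base pair, loop >= 3
check_structure_legal <- function(sequence, dotbracket, min_loop = 3L) {
  chars <- strsplit(chartr("T", "U", toupper(sequence)), "", fixed = TRUE)[[1]]
  db <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  if (length(chars) != length(db)) return(FALSE)
  stack <- integer(0)
  for (i in seq_along(db)) {
    if (db[i] == "(") stack <- c(stack, i)
    else if (db[i] == ")") {
      if (length(stack) == 0L) return(FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (i - j - 1L < min_loop) return(FALSE)
      if (!paste0(chars[j], chars[i]) %in%
          c("AU", "UA", "GC", "CG", "GU", "UG")) return(FALSE)
    }
  }
  length(stack) == 0L
}

# exhaustive AUC oracle: fraction of correctly ordered (pos, neg) pairs,
# ties counted 1/2
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# quick trainer for tests that only need a working classifier
fast_trainer <- function() rf_trainer(num_trees = 100L)
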