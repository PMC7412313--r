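# Independent oracles and shared fixtures for the test suite.

# All qualifying placements of `query` (given orientation) on `ref`:
# for every 0-based start, the edit distance is the minimum Levenshtein
# distance (utils::adist) between the query and reference segments starting
# there whose lengths are within max_edit of the query length.
oracle_placements_one_strand <- function(query, ref, max_edit) {
  L <- nchar(query)
  R <- nchar(ref)
  combos <- expand.grid(start = 0:(R - 1),
                        t = max(0, L - max_edit):(L + max_edit))
  combos <- combos[combos$start + combos$t <= R, , drop = FALSE]
  segs <- substr(rep(ref, nrow(combos)), combos$start + 1,
                 combos$start + combos$t)
  d <- as.integer(utils::adist(query, segs))
  dist <- tapply(d, combos$start, min)
  start <- as.integer(names(dist))
  keep <- dist <= max_edit
  data.frame(start = start[keep], edit = as.integer(dist[keep]))
}

# Both-strand oracle mirroring align_read's contract on a single reference.
oracle_placements <- function(read, ref, max_edit) {
  fw <- oracle_placements_one_strand(read, ref, max_edit)
  rv <- oracle_placements_one_strand(graftmobile::revcomp(read), ref, max_edit)
  out <- rbind(cbind(fw, strand = if (nrow(fw)) "+" else character(0)),
               cbind(rv, strand = if (nrow(rv)) "-" else character(0)))
  out[order(out$edit, out$start, out$strand), , drop = FALSE]
}

# Minimum Hamming distance of `read` over all offsets/strands of `refs`
# (Inf when the read is longer than every reference).
oracle_min_hamming <- function(read, refs) {
  best <- Inf
  for (q in c(read, graftmobile::revcomp(read))) {
    qv <- strsplit(q, "")[[1]]
    L <- length(qv)
    for (ref in refs) {
      rv <- strsplit(ref, "")[[1]]
      if (L > length(rv)) next
      for (s in 0:(length(rv) - L))
        best <- min(best, sum(qv != rv[s + seq_len(L)]))
    }
  }
  best
}

# Hypergeometric tails by explicit enumeration of all size-n draws.
oracle_hyper_tails <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)  # items 1..K are the marked ones
  c(p_over = mean(marked >= k), p_under = mean(marked <= k))
}

# Textbook Smith-Waterman with affine gaps (full 3-matrix DP, no tricks),
# returning the maximal local score.
oracle_sw_score <- function(a, b, mat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(E[i, j - 1] - gap_extend, H[i, j - 1] - gap_open - gap_extend)
    F[i, j] <- max(F[i - 1, j] - gap_extend, H[i - 1, j] - gap_open - gap_extend)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                   E[i, j], F[i, j])
  }
  max(H)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Apply `n_edits` random single-base edits (substitution/insertion/deletion).
mutate_read <- function(read, n_edits) {
  for (i in seq_len(n_edits)) {
    chars <- strsplit(read, "")[[1]]
    p <- sample(length(chars), 1)
    op <- sample(c("sub", "ins", "del"), 1)
    if (op == "sub") chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    else if (op == "ins") chars <- append(chars, sample(c("A", "C", "G", "T"), 1), p)
    else chars <- chars[-p]
    read <- paste(chars, collapse = "")
  }
  read
}

# Shared small simulated experiment, built once per test run.
.fixture_env <- new.env()
small_experiment <- function() {
  if (is.null(.fixture_env$exp)) {
    cfg <- sim_config(n_transcripts = 60, master_seed = 42)
    regions <- c("full+lowN+lowP+lowFe" = 6L, "full" = 1L, "lowN" = 4L,
                 "lowP" = 3L, "lowFe" = 3L, "full+lowN" = 1L)
    .fixture_env$exp <- simulate_experiment(cfg, regions)
  }
  .fixture_env$exp
}
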