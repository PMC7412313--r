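test_that("trimmed reads shorter than the minimum length are discarded", {
  q40 <- function(n) strrep("I", n)
  r40 <- random_dna(40)
  kept <- trim_read(r40, q40(40), adapter = "AGATCGGAAGAGC")
  expect_identical(kept$sequence, r40)

  r39 <- random_dna(39)
  expect_null(trim_read(r39, q40(39)))
  expect_null(trim_read("", ""))

  # 85-base read whose 3' half is adapter: 35-base remainder is too short
  adapter50 <- random_dna(50)
  read <- paste0(random_dna(35), adapter50)
  expect_null(trim_read(read, q40(85), adapter = adapter50))
  # same remainder above the threshold survives
  adapter40 <- substr(adapter50, 1, 40)
  read2 <- paste0(random_dna(45), adapter40)
  out <- trim_read(read2, q40(85), adapter = adapter40)
  expect_identical(nchar(out$sequence), 45L)
})

test_that("trimming matches a naive reference implementation on random reads", {
  naive_trim <- function(seq, qual, adapter, frac, min_ov, thr, win) {
    L <- nchar(seq)
    cut <- L
    for (p in seq_len(L - min_ov + 1)) {         # 1-based start of suffix
      ov <- min(L - p + 1, nchar(adapter))
      mm <- sum(strsplit(substr(seq, p, p + ov - 1), "")[[1]] !=
                  strsplit(substr(adapter, 1, ov), "")[[1]])
      if (mm <= floor(frac * ov)) { cut <- p - 1; break }
    }
    L <- cut
    q <- utf8ToInt(qual) - 33
    if (win > 0 && L >= win) {
      for (p in seq_len(L - win + 1)) {
        if (mean(q[p:(p + win - 1)]) < thr) { L <- p - 1; break }
      }
    }
    L
  }
  set.seed(31)
  adapter <- "AGATCGGAAGAGC"
  for (i in 1:150) {
    L <- sample(40:85, 1)
    seq <- random_dna(L)
    if (runif(1) < 0.4) {  # splice in an adapter suffix
      keep <- sample(10:(L - 5), 1)
      seq <- paste0(substr(seq, 1, keep), substr(adapter, 1, min(13, L - keep)),
                    substr(seq, keep + 14, L))
      seq <- substr(seq, 1, L)
    }
    qual <- intToUtf8(33 + sample(c(2, 11, 22, 37), L, replace = TRUE,
                                  prob = c(.1, .15, .25, .5)), multiple = FALSE)
    got <- trim_read(seq, qual, adapter, min_length = 1)
    want <- naive_trim(seq, qual, adapter, 0.1, 3, 20, 4)
    if (want == 0) {
      expect_true(is.null(got) || nchar(got$sequence) == 0)
    } else {
      expect_identical(nchar(got$sequence), as.integer(want))
      expect_identical(got$sequence, substr(seq, 1, want))
    }
  }
})

test_that("quality windows clip degraded 3' tails", {
  seq <- random_dna(85)
  qual <- paste0(strrep("I", 60), strrep("#", 25))  # Q40 then Q2
  out <- trim_read(seq, qual)
  # first window (width 4) with mean below 20 starts at base 60
  # (Q40, Q2, Q2, Q2 -> mean 11.5), so 59 bases are retained
  expect_identical(nchar(out$sequence), 59L)
  expect_identical(out$sequence, substr(seq, 1, 59))
})

test_that("rRNA filtering drops pairs within the mismatch cap, either strand", {
  set.seed(11)
  rrna <- transcript_set(c(r1 = random_dna(600), r2 = random_dna(500)), "rrna")
  exact <- substr(rrna$sequences[["r1"]], 101, 185)
  with3 <- mutate_read_subs_only <- local({
    chars <- strsplit(exact, "")[[1]]
    pos <- sample(85, 3)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    paste(chars, collapse = "")
  })
  far <- random_dna(85)
  stopifnot(oracle_min_hamming(far, rrna$sequences) > 3)
  mk <- function(s1) read_pairs(data.frame(
    pair_id = paste0("p", seq_along(s1)), seq1 = s1,
    qual1 = strrep("I", nchar(s1)), seq2 = revcomp(s1),
    qual2 = strrep("I", nchar(s1)), stringsAsFactors = FALSE))
  pr <- mk(c(exact, with3, revcomp(exact), far))
  res <- filter_rrna(pr, rrna, max_mismatch = 3)
  expect_identical(res$pairs$pair_id, "p4")
  expect_setequal(res$discards$pair_id, c("p1", "p2", "p3"))

  # 4 substitutions against the best placement: kept at the cap of 3
  with4 <- local({
    chars <- strsplit(exact, "")[[1]]
    for (p in c(5, 25, 50, 80))
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    paste(chars, collapse = "")
  })
  expect_identical(oracle_min_hamming(with4, rrna$sequences), 4)
  res4 <- filter_rrna(mk(with4), rrna, max_mismatch = 3)
  expect_identical(nrow(res4$pairs), 1L)

  # empty database is the identity filter
  res0 <- filter_rrna(pr, transcript_set(character(0), "rrna"))
  expect_identical(nrow(res0$pairs), nrow(pr))
})

test_that("seeded rRNA scan agrees with the brute-force Hamming oracle", {
  set.seed(21)
  rrna_seqs <- c(random_dna(400), random_dna(300))
  reads <- character(60)
  for (i in seq_len(60)) {
    L <- sample(c(40, 60, 85), 1)
    base <- if (i %% 2 == 0) {
      s <- sample(nchar(rrna_seqs[1]) - L, 1)
      substr(rrna_seqs[1], s, s + L - 1)
    } else random_dna(L)
    nmm <- sample(0:5, 1)
    chars <- strsplit(base, "")[[1]]
    if (nmm > 0) {
      for (p in sample(L, nmm))
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    if (runif(1) < 0.5) reads[i] <- paste(chars, collapse = "")
    else reads[i] <- revcomp(paste(chars, collapse = ""))
  }
  got <- graftmobile:::cpp_hamming_hits(reads, rrna_seqs, 3L)
  want <- vapply(reads, function(r) oracle_min_hamming(r, rrna_seqs) <= 3,
                 logical(1))
  expect_identical(unname(got), unname(want))
})

test_that("QC is idempotent, partitions its input, and removes all clean rRNA pairs", {
  cfg <- sim_config(n_transcripts = 20, error_rate = 0, rrna_fraction = 0.2,
                    lowq_fraction = 0, adapter_fraction = 0, master_seed = 17)
  refs <- diverge(generate_ancestor(cfg), cfg)
  rrna <- generate_rrna(cfg)
  truth <- assign_truth(refs$scion, c(full = 3L), seed = 1)
  s <- simulate_sample(refs$rootstock, refs$scion, truth, "full", 1, cfg,
                       rrna = rrna)
  res <- qc_pairs(s, rrna)
  expect_identical(sort(c(res$pairs$pair_id, res$discards$pair_id)),
                   sort(s$pair_id))
  expect_length(intersect(res$pairs$pair_id, res$discards$pair_id), 0)
  # error-free contaminants removed with recall 1.0
  org_kept <- parse_read_names(res$pairs$pair_id)$org
  expect_false(any(org_kept == "rrna"))
  rrna_ids <- s$pair_id[parse_read_names(s$pair_id)$org == "rrna"]
  expect_true(length(rrna_ids) > 0)
  expect_true(all(rrna_ids %in% res$discards$pair_id))
  # idempotence of the rRNA stage
  again <- filter_rrna(res$pairs, rrna, 3)
  expect_identical(nrow(again$pairs), nrow(res$pairs))
  # no survivor shorter than min_length
  expect_true(all(nchar(res$pairs$seq1) >= 40 & nchar(res$pairs$seq2) >= 40))
})
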