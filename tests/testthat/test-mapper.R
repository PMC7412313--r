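test_that("index postings enumerate stepped reference k-mers", {
  ts <- transcript_set(c(t1 = "ACGTACGT"), "demo")
  idx <- build_index(ts, k = 4, step = 4)
  post <- index_postings(idx)
  expect_identical(unique(post$kmer), "ACGT")
  expect_identical(post$offset, c(0L, 4L))
  expect_identical(post$target_id, c("t1", "t1"))

  empty <- build_index(transcript_set(character(0), "none"), k = 4)
  expect_identical(nrow(index_postings(empty)), 0L)

  idx2 <- build_index(ts, k = 4, step = 4)
  expect_identical(index_postings(idx), index_postings(idx2))

  expect_error(build_index(transcript_set(c(a = "ACGTACGT", b = "ACG"), "x"),
                           k = 4), "'b'")
})

test_that("exact and reverse-complement placements are found with edit 0", {
  set.seed(3)
  ts <- transcript_set(c(t1 = random_dna(400), t2 = random_dna(300)), "demo")
  idx <- build_index(ts)
  read <- substr(ts$sequences[["t2"]], 51, 135)
  hits <- align_read(read, idx, max_edit = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$target_id, "t2")
  expect_identical(hits$target_start, 50L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$edit_distance, 0L)
  expect_identical(hits$cigar, "85M")

  rc <- align_read(revcomp(read), idx, max_edit = 0)
  expect_identical(rc$strand, "-")
  expect_identical(rc$target_start, 50L)
  expect_identical(rc$edit_distance, 0L)
})

test_that("edit caps separate two-substitution reads", {
  set.seed(5)
  ts <- transcript_set(c(t1 = random_dna(500)), "demo")
  idx <- build_index(ts)
  read <- substr(ts$sequences[["t1"]], 101, 185)
  chars <- strsplit(read, "")[[1]]
  for (p in c(20, 60))
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  mutated <- paste(chars, collapse = "")
  or <- oracle_placements(mutated, ts$sequences[["t1"]], 2)
  expect_identical(min(or$edit), 2L)
  found2 <- align_read(mutated, idx, max_edit = 2)
  expect_true(any(found2$target_start == 100 & found2$edit_distance == 2))
  found1 <- align_read(mutated, idx, max_edit = 1)
  expect_identical(nrow(found1), 0L)
})

test_that("reads shorter than k yield an empty result with a warning", {
  ts <- transcript_set(c(t1 = random_dna(100)), "demo")
  idx <- build_index(ts)
  expect_warning(h <- align_read("ACGTACGT", idx), "shorter than k")
  expect_identical(nrow(h), 0L)
})

test_that("seeded alignment equals the all-placement Levenshtein oracle", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:300) {
    ref <- random_dna(sample(150:350, 1))
    ts <- transcript_set(c(t1 = ref), "demo")
    idx <- build_index(ts)
    s <- sample(nchar(ref) - 85, 1)
    read <- substr(ref, s, s + 84)
    read <- mutate_read(read, sample(0:2, 1))
    if (runif(1) < 0.5) read <- revcomp(read)
    if (nchar(read) < 15) next
    got <- align_read(read, idx, max_edit = 2, cigar = FALSE)
    want <- oracle_placements(read, ref, 2)
    got_key <- sort(paste(got$strand, got$target_start, got$edit_distance))
    want_key <- sort(paste(want$strand, want$start, want$edit))
    expect_identical(got_key, want_key)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 290)
})

test_that("strand symmetry: reverse complement flips strand, keeps edits", {
  set.seed(7)
  ts <- transcript_set(c(t1 = random_dna(300)), "demo")
  idx <- build_index(ts)
  for (i in 1:20) {
    s <- sample(200, 1)
    read <- mutate_read(substr(ts$sequences[["t1"]], s, s + 84), sample(0:2, 1))
    fw <- align_read(read, idx, max_edit = 2, cigar = FALSE)
    rv <- align_read(revcomp(read), idx, max_edit = 2, cigar = FALSE)
    flip <- c("+" = "-", "-" = "+")
    expect_identical(
      sort(paste(fw$strand, fw$target_start, fw$edit_distance)),
      sort(paste(unname(flip[rv$strand]), rv$target_start, rv$edit_distance)))
  }
})

test_that("proper pairs require one target, opposite strands and a sane insert", {
  set.seed(9)
  ts <- transcript_set(c(t1 = random_dna(600), t2 = random_dna(600)), "demo")
  idx <- build_index(ts)
  frag <- substr(ts$sequences[["t1"]], 101, 350)  # insert 250
  m1 <- substr(frag, 1, 85)
  m2 <- revcomp(substr(frag, 166, 250))
  ap <- align_pairs(m1, m2, idx, max_edit = 2, insert_bounds = c(150, 400))
  expect_true(ap$proper)
  expect_identical(ap$target_id, "t1")
  expect_identical(ap$summed_edit, 0L)

  # mates on different targets only: never proper
  m2b <- revcomp(substr(ts$sequences[["t2"]], 201, 285))
  ap2 <- align_pairs(m1, m2b, idx, max_edit = 2, insert_bounds = c(150, 400))
  expect_false(ap2$proper)

  # insert outside the bounds: not proper
  ap3 <- align_pairs(m1, m2, idx, max_edit = 2, insert_bounds = c(300, 400))
  expect_false(ap3$proper)

  # per-mate caps: edits 1 + 2 are proper at max_edit 2, not at 1
  m1e <- mutate_read(m1, 0); m1e <- local({
    chars <- strsplit(m1, "")[[1]]
    chars[30] <- setdiff(c("A", "C", "G", "T"), chars[30])[1]
    paste(chars, collapse = "")
  })
  m2e <- local({
    chars <- strsplit(m2, "")[[1]]
    for (p in c(20, 70)) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    paste(chars, collapse = "")
  })
  ap4 <- align_pairs(m1e, m2e, idx, max_edit = 2, insert_bounds = c(150, 400))
  expect_true(ap4$proper)
  expect_identical(ap4$summed_edit, 3L)
  ap5 <- align_pairs(m1e, m2e, idx, max_edit = 1, insert_bounds = c(150, 400))
  expect_false(ap5$proper)
})
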