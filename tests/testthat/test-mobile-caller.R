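test_that("control matching is exact full-length equality, either orientation", {
  set.seed(23)
  controls <- read_pairs(data.frame(
    pair_id = paste0("c", 1:5),
    seq1 = replicate(5, random_dna(85)), qual1 = strrep("I", 85),
    seq2 = replicate(5, random_dna(85)), qual2 = strrep("I", 85),
    stringsAsFactors = FALSE))
  cs <- control_read_set(controls)
  expect_length(cs, 10)
  expect_true(match_control(controls$seq1[3], cs))
  expect_true(match_control(revcomp(controls$seq2[4]), cs))
  # one base off from every control read: exhaustively verified, no match
  probe <- local({
    chars <- strsplit(controls$seq1[1], "")[[1]]
    chars[40] <- setdiff(c("A", "C", "G", "T"), chars[40])[1]
    paste(chars, collapse = "")
  })
  mism <- vapply(cs, function(s)
    s != probe && s != revcomp(probe), logical(1))
  expect_true(all(mism))
  expect_false(match_control(probe, cs))
  expect_false(match_control(probe, control_read_set(list())))
})

# hand-built references: scion differs from rootstock at every 20th base, so
# every 85-bp window carries >= 4 substitutions and escapes the rootstock stage
divergent_refs <- function(len = 800, seed = 29) {
  set.seed(seed)
  root <- random_dna(len)
  chars <- strsplit(root, "")[[1]]
  for (p in seq(10, len, by = 20))
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  list(rootstock = transcript_set(c(t1 = root), "rootstock"),
       scion = transcript_set(c(t1 = paste(chars, collapse = "")), "scion"))
}

make_pair <- function(ref, start = 101, insert = 250, id = "p1") {
  frag <- substr(ref, start, start + insert - 1)
  read_pairs(data.frame(
    pair_id = id, seq1 = substr(frag, 1, 85), qual1 = strrep("I", 85),
    seq2 = revcomp(substr(frag, insert - 84, insert)),
    qual2 = strrep("I", 85), stringsAsFactors = FALSE))
}

test_that("the cascade routes pairs by stage precedence", {
  refs <- divergent_refs()
  ridx <- build_index(refs$rootstock)
  sidx <- build_index(refs$scion)
  insert_bounds <- c(150, 400)

  root_pair <- make_pair(refs$rootstock$sequences[["t1"]])
  cl <- classify_pairs(root_pair, ridx, sidx, control_read_set(list()),
                       insert_bounds = insert_bounds)
  expect_identical(cl$label, "rootstock")
  expect_identical(cl$targets, "t1")

  scion_pair <- make_pair(refs$scion$sequences[["t1"]])
  cl2 <- classify_pairs(scion_pair, ridx, sidx, control_read_set(list()),
                        insert_bounds = insert_bounds)
  expect_identical(cl2$label, "transmitted")
  expect_identical(cl2$targets, "t1")
  expect_identical(cl2$summed_edit, 0L)

  # a perfect control match is removed before the scion stage sees it
  ctl <- control_read_set(scion_pair)
  cl3 <- classify_pairs(scion_pair, ridx, sidx, ctl,
                        insert_bounds = insert_bounds)
  expect_identical(cl3$label, "control_match")

  # garbage reaches no stage
  junk <- make_pair(paste(rep("ACGT", 200), collapse = ""))
  cl4 <- classify_pairs(junk, ridx, sidx, control_read_set(list()),
                        insert_bounds = insert_bounds)
  expect_identical(cl4$label, "unassigned")
})

test_that("labels are exhaustive and exclusive and caps act monotonically", {
  exp <- small_experiment()
  s <- exp$samples[["full.1"]]
  qc <- qc_pairs(s, exp$rrna)
  ridx <- build_index(exp$rootstock)
  sidx <- build_index(exp$scion)
  ctl <- control_read_set(lapply(exp$controls, function(x)
    qc_pairs(x, exp$rrna)$pairs))
  cl <- classify_pairs(qc$pairs, ridx, sidx, ctl)
  expect_identical(nrow(cl), nrow(qc$pairs))
  expect_true(all(cl$label %in% c("rootstock", "control_match", "transmitted",
                                  "unassigned")))
  tx <- function(root_cap, scion_cap)
    sum(classify_pairs(qc$pairs, ridx, sidx, ctl, root_max_edit = root_cap,
                       scion_max_edit = scion_cap)$label == "transmitted")
  # raising the rootstock cap never increases transmitted calls
  expect_gte(tx(1, 1), tx(2, 1))
  expect_gte(tx(2, 1), tx(3, 1))
  # raising the scion cap never decreases them
  expect_lte(tx(2, 0), tx(2, 1))
  expect_lte(tx(2, 1), tx(2, 2))
  # transmitted targets are scion ids
  tt <- cl$targets[cl$label == "transmitted"]
  expect_true(all(unlist(strsplit(tt, ",")) %in% transcript_ids(exp$scion)))
})

test_that("the replicate rule calls mobile at >= 2 of 3 detections", {
  classified <- data.frame(
    pair_id = paste0("p", 1:7),
    label = "transmitted",
    targets = c("A", "A", "B", "C", "C", "C", "A,B"),
    condition = "full",
    replicate = c(1L, 2L, 2L, 1L, 2L, 3L, 3L),
    stringsAsFactors = FALSE)
  # pad totals so rpkm denominators exist
  lengths <- c(A = 1000L, B = 2000L, C = 500L)
  tab <- call_mobile(classified, lengths, n_replicates = 3,
                     min_replicates = 2, min_pairs = 1)
  calls <- tab$calls
  get <- function(id) calls[calls$transcript_id == id, ]
  expect_true(get("A")$mobile)              # replicates {1,2,3}
  expect_identical(get("A")$n_detected, 3L)
  expect_true(get("B")$mobile)              # {2,3} via the ambiguous pair
  expect_true(get("C")$mobile)              # {1,2,3}

  single <- data.frame(pair_id = "q1", label = "transmitted", targets = "D",
                       condition = "full", replicate = 2L,
                       stringsAsFactors = FALSE)
  tab2 <- call_mobile(single, c(D = 800L), n_replicates = 3)
  expect_false(tab2$calls$mobile)           # one replicate only: never mobile

  expect_error(call_mobile(single, c(D = 800L), n_replicates = 3,
                           min_replicates = 4), "exceeds")
})

test_that("RPKM follows its closed form and guards its denominators", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(7, 350, 2e6), 10)
  expect_error(rpkm(1, 0, 10), "transcript_length")
  expect_error(rpkm(1, 10, 0), "total_mapped_pairs")
})

test_that("condition sets mirror the call table and its union", {
  empty <- call_mobile(data.frame(pair_id = character(0), label = character(0),
                                  targets = character(0),
                                  condition = character(0),
                                  replicate = integer(0)),
                       c(A = 100L), n_replicates = 3)
  cs0 <- condition_sets(empty)
  expect_length(cs0$union, 0)

  classified <- data.frame(
    pair_id = paste0("p", 1:8),
    label = "transmitted",
    targets = rep(c("A", "B"), each = 4),
    condition = rep(c("full", "full", "lowN", "lowN"), 2),
    replicate = rep(c(1L, 2L), 4), stringsAsFactors = FALSE)
  tab <- call_mobile(classified, c(A = 100L, B = 100L), n_replicates = 3)
  cs <- condition_sets(tab)
  expect_setequal(cs$full, c("A", "B"))
  expect_setequal(cs$lowN, c("A", "B"))
  expect_identical(cs$union,
                   sort(unique(unlist(cs[setdiff(names(cs), "union")]))))
})

test_that("the pipeline recovers the simulated truth on the small experiment", {
  exp <- small_experiment()
  res <- run_pipeline(exp$rootstock, exp$scion, exp$samples, exp$controls,
                      exp$rrna)
  for (cond in exp$truth$conditions) {
    truth <- exp$truth$mobile_by_condition[[cond]]
    called <- res$condition_sets[[cond]]
    tp <- length(intersect(called, truth))
    expect_gte(tp / length(truth), 0.90)
    expect_gte(tp / max(length(called), 1), 0.95)
  }
  # control purity: no rootstock-origin pair is ever transmitted
  tx <- res$classifications[res$classifications$label == "transmitted", ]
  expect_true(all(parse_read_names(tx$pair_id)$org == "scion"))
})
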