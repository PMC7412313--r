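test_that("ancestor generation respects size, bounds and determinism", {
  cfg0 <- sim_config(n_transcripts = 0)
  expect_length(generate_ancestor(cfg0), 0)

  cfg <- sim_config(n_transcripts = 100, length_range = c(500, 2000),
                    master_seed = 1)
  a1 <- generate_ancestor(cfg)
  a2 <- generate_ancestor(cfg)
  expect_identical(a1, a2)
  lens <- transcript_lengths(a1)
  expect_true(all(lens >= 500 & lens <= 2000))
  expect_length(a1, 100)
  # coding mode: ORF structure, no internal stops
  codons <- lapply(a1$sequences, function(s)
    substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3)))
  expect_true(all(vapply(codons, function(cc)
    cc[1] == "ATG" && !any(cc[-length(cc)] %in% c("TAA", "TAG", "TGA")) &&
      cc[length(cc)] %in% c("TAA", "TAG", "TGA"), logical(1))))
})

test_that("divergence of zero and indel rate of zero are identities", {
  cfg <- sim_config(n_transcripts = 10, divergence = 0, indel_rate = 0,
                    master_seed = 5)
  anc <- generate_ancestor(cfg)
  refs <- diverge(anc, cfg)
  expect_identical(refs$scion$sequences, anc$sequences)
  expect_identical(refs$rootstock$sequences, anc$sequences)

  cfg2 <- sim_config(n_transcripts = 10, divergence = 0.04, indel_rate = 0,
                     master_seed = 5)
  refs2 <- diverge(generate_ancestor(cfg2), cfg2)
  expect_identical(nchar(refs2$scion$sequences),
                   nchar(refs2$rootstock$sequences))
})

test_that("realized between-lineage divergence matches the configured rate", {
  cfg <- sim_config(n_transcripts = 50, divergence = 0.04, indel_rate = 0,
                    master_seed = 7)
  refs <- diverge(generate_ancestor(cfg), cfg)
  diffs <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                  refs$scion$sequences, refs$rootstock$sequences)
  sites <- sum(nchar(refs$scion$sequences))
  p_hat <- sum(diffs) / sites
  se <- sqrt(0.04 * 0.96 / sites)
  expect_lt(abs(p_hat - 0.04), 3 * se)
})

test_that("truth assignment does exclusive-region set arithmetic", {
  cfg <- sim_config(n_transcripts = 30, master_seed = 2)
  scion <- diverge(generate_ancestor(cfg), cfg)$scion
  empty <- assign_truth(scion, integer(0), seed = 3)
  expect_true(all(lengths(empty$mobile_by_condition) == 0))

  tr <- assign_truth(scion, c("full+lowN+lowP+lowFe" = 5L, "lowN" = 3L),
                     seed = 3)
  expect_length(tr$mobile_by_condition$lowN, 8)
  expect_length(tr$mobile_by_condition$lowP, 5)
  expect_length(tr$mobile_by_condition$full, 5)
  expect_length(intersect(tr$mobile_by_condition$lowN,
                          tr$mobile_by_condition$lowP), 5)
  expect_identical(tr, assign_truth(scion, c("full+lowN+lowP+lowFe" = 5L,
                                             "lowN" = 3L), seed = 3))
  expect_error(assign_truth(scion, c(full = 31L)), "exceed")
  expect_error(assign_truth(scion, c(bogus = 1L)), "unknown condition")
})

test_that("non-grafted controls contain no scion-origin reads", {
  exp <- small_experiment()
  for (ctl in exp$controls) {
    org <- parse_read_names(ctl$pair_id)$org
    expect_false(any(org == "scion"))
    expect_true(all(org %in% c("rootstock", "rrna")))
  }
})

test_that("error-free reads are exact (reverse-complemented) source substrings", {
  cfg <- sim_config(n_transcripts = 15, error_rate = 0, adapter_fraction = 0,
                    rrna_fraction = 0, lowq_fraction = 0, master_seed = 9)
  refs <- diverge(generate_ancestor(cfg), cfg)
  truth <- assign_truth(refs$scion, c(full = 4L), seed = 1)
  s <- simulate_sample(refs$rootstock, refs$scion, truth, "full", 1, cfg)
  info <- parse_read_names(s$pair_id)
  for (i in seq_len(nrow(s))) {
    src <- if (info$org[i] == "scion") refs$scion$sequences[[info$src[i]]]
           else refs$rootstock$sequences[[info$src[i]]]
    expect_true(grepl(s$seq1[i], src, fixed = TRUE))
    expect_true(grepl(revcomp(s$seq2[i]), src, fixed = TRUE))
  }
})

test_that("sample depth follows the Poisson expectation", {
  cfg <- sim_config(n_transcripts = 50, depth = 30, adapter_fraction = 0,
                    rrna_fraction = 0, master_seed = 13)
  refs <- diverge(generate_ancestor(cfg), cfg)
  truth <- assign_truth(refs$scion, integer(0), seed = 1)
  s <- simulate_sample(refs$rootstock, refs$scion, truth, "full", 1, cfg,
                       grafted = FALSE)
  expected <- 50 * 30
  expect_lt(abs(nrow(s) - expected), 3 * sqrt(expected))
})

test_that("samples are reproducible and read names reconcile with sources", {
  exp <- small_experiment()
  cfg <- exp$config
  s1 <- simulate_sample(exp$rootstock, exp$scion, exp$truth, "lowN", 2, cfg,
                        rrna = exp$rrna)
  s2 <- simulate_sample(exp$rootstock, exp$scion, exp$truth, "lowN", 2, cfg,
                        rrna = exp$rrna)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  info <- parse_read_names(s1$pair_id)
  expect_false(anyNA(info$src))
  known <- c(transcript_ids(exp$rootstock), transcript_ids(exp$scion),
             transcript_ids(exp$rrna))
  expect_true(all(info$src %in% known))
  # scion-origin reads come only from the condition's truth set
  scion_src <- unique(info$src[info$org == "scion"])
  expect_true(all(scion_src %in% exp$truth$mobile_by_condition$lowN))
})

test_that("naive translation truncates at the first stop codon", {
  expect_identical(unname(translate_naive(c(x = "ATGGCTTAA"))), "MA")
  expect_identical(unname(translate_naive(c(x = "ATGGCTTAAGGG"))), "MA")
  expect_identical(unname(translate_naive(c(x = "ATGGCTG"))), "MA")

  cfg <- sim_config(n_transcripts = 8, divergence = 0, indel_rate = 0,
                    master_seed = 4)
  refs <- diverge(generate_ancestor(cfg), cfg)
  prot <- generate_proteomes(refs$scion, refs$rootstock)
  expect_identical(prot$scion, prot$rootstock)
  expect_identical(names(prot$scion), transcript_ids(refs$scion))
})

test_that("configuration domains are validated", {
  expect_error(sim_config(divergence = 0.6), "divergence")
  expect_error(sim_config(read_length = 30), "read_length")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  expect_error(sim_config(error_rate = -0.1), "rates")
})
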