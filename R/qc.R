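#' Adapter and quality trimming of a single mate
#'
#' Removes a 3' adapter occurrence (leftmost position where the read suffix
#' matches a prefix of the adapter within `mismatch_frac`, overlap at least
#' `min_overlap`), then applies a sliding-window quality clip (the read is
#' cut at the start of the first window whose mean Phred quality falls below
#' `quality_threshold`). A result shorter than `min_length` is a discard.
#'
#' @param sequence nucleotide string.
#' @param qualities Phred+33 quality string of the same length.
#' @param adapter adapter sequence ("" disables adapter trimming).
#' @param quality_threshold mean window quality below which the read is cut.
#' @param window sliding window size in bases (0 disables quality trimming).
#' @param min_length minimum surviving length (default 40).
#' @param mismatch_frac allowed adapter mismatch fraction.
#' @param min_overlap minimum read/adapter overlap to trigger trimming.
#' @return list `(sequence, qualities)` or `NULL` as the discard signal.
#' @export
trim_read <- function(sequence, qualities, adapter = "AGATCGGAAGAGC",
                      quality_threshold = 20, window = 4, min_length = 40,
                      mismatch_frac = 0.1, min_overlap = 3) {
  stopifnot(length(sequence) == 1, nchar(sequence) == nchar(qualities))
  if (nchar(sequence) == 0) return(NULL)
  len <- cpp_trim_lengths(sequence, qualities, adapter, mismatch_frac,
                          as.integer(min_overlap),
                          as.integer(quality_threshold), as.integer(window))
  if (len < min_length) return(NULL)
  list(sequence = substr(sequence, 1, len),
       qualities = substr(qualities, 1, len))
}

#' Trim a read-pair set; discard pairs with a too-short mate
#'
#' Applies [trim_read()] to both mates of every pair. If either trimmed mate
#' is shorter than `min_length` the whole pair is discarded, preserving pair
#' integrity for the paired alignment stages.
#'
#' @param pairs a `read_pairs` data frame.
#' @inheritParams trim_read
#' @return list with `pairs` (trimmed survivors, original order) and
#'   `discards` (data frame pair_id, reason).
#' @export
trim_pairs <- function(pairs, adapter = "AGATCGGAAGAGC", quality_threshold = 20,
                       window = 4, min_length = 40, mismatch_frac = 0.1,
                       min_overlap = 3) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (nrow(pairs) == 0)
    return(list(pairs = pairs,
                discards = data.frame(pair_id = character(0),
                                      reason = character(0))))
  l1 <- cpp_trim_lengths(pairs$seq1, pairs$qual1, adapter, mismatch_frac,
                         as.integer(min_overlap),
                         as.integer(quality_threshold), as.integer(window))
  l2 <- cpp_trim_lengths(pairs$seq2, pairs$qual2, adapter, mismatch_frac,
                         as.integer(min_overlap),
                         as.integer(quality_threshold), as.integer(window))
  keep <- l1 >= min_length & l2 >= min_length
  out <- pairs[keep, , drop = FALSE]
  out$seq1 <- substr(out$seq1, 1, l1[keep])
  out$qual1 <- substr(out$qual1, 1, l1[keep])
  out$seq2 <- substr(out$seq2, 1, l2[keep])
  out$qual2 <- substr(out$qual2, 1, l2[keep])
  list(pairs = read_pairs(out, attr(pairs, "condition"),
                          attr(pairs, "replicate"), attr(pairs, "grafted")),
       discards = data.frame(pair_id = pairs$pair_id[!keep],
                             reason = rep("short", sum(!keep)),
                             stringsAsFactors = FALSE))
}

#' Remove read pairs matching a ribosomal RNA reference
#'
#' A pair is discarded when either mate aligns end-to-end, gap-free
#' (Hamming distance over the full read), on either strand at any offset of
#' any rRNA reference sequence with at most `max_mismatch` mismatches.
#' Survivor order is preserved; an empty rRNA set is the identity filter.
#'
#' @param pairs a `read_pairs` data frame.
#' @param rrna_refs rRNA [transcript_set()].
#' @param max_mismatch maximum tolerated substitutions (default 3).
#' @return list with `pairs` (survivors) and `discards` (pair_id, reason).
#' @export
filter_rrna <- function(pairs, rrna_refs, max_mismatch = 3) {
  stopifnot(inherits(pairs, "read_pairs"), inherits(rrna_refs, "transcript_set"))
  if (nrow(pairs) == 0 || length(rrna_refs) == 0)
    return(list(pairs = pairs,
                discards = data.frame(pair_id = character(0),
                                      reason = character(0))))
  hit <- cpp_hamming_hits(pairs$seq1, rrna_refs$sequences, as.integer(max_mismatch)) |
         cpp_hamming_hits(pairs$seq2, rrna_refs$sequences, as.integer(max_mismatch))
  list(pairs = read_pairs(pairs[!hit, , drop = FALSE],
                          attr(pairs, "condition"), attr(pairs, "replicate"),
                          attr(pairs, "grafted")),
       discards = data.frame(pair_id = pairs$pair_id[hit],
                             reason = rep("rrna", sum(hit)),
                             stringsAsFactors = FALSE))
}

#' Full read QC: trim, length filter, rRNA filter
#'
#' @param pairs a `read_pairs` data frame.
#' @param rrna_refs optional rRNA [transcript_set()].
#' @param params a [pipeline_params()] list.
#' @return list with `pairs` (survivors) and `discards` (pair_id, reason).
#' @export
qc_pairs <- function(pairs, rrna_refs = NULL, params = pipeline_params()) {
  tr <- trim_pairs(pairs, adapter = params$adapter,
                   quality_threshold = params$quality_threshold,
                   window = params$window, min_length = params$min_length,
                   mismatch_frac = params$adapter_mismatch_frac,
                   min_overlap = params$adapter_min_overlap)
  if (is.null(rrna_refs) || length(rrna_refs) == 0)
    return(list(pairs = tr$pairs, discards = tr$discards))
  rr <- filter_rrna(tr$pairs, rrna_refs, params$rrna_max_mismatch)
  list(pairs = rr$pairs, discards = rbind(tr$discards, rr$discards))
}
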