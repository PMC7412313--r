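#' Build the control read set from non-grafted samples
#'
#' Collects every mate sequence of every non-grafted control sample into a
#' lookup set used for perfect-match subtraction.
#'
#' @param controls list of `read_pairs` from non-grafted samples.
#' @return character vector of unique control read sequences (class
#'   `control_set`).
#' @export
control_read_set <- function(controls) {
  if (inherits(controls, "read_pairs")) controls <- list(controls)
  seqs <- unlist(lapply(controls, function(p) c(p$seq1, p$seq2)),
                 use.names = FALSE)
  if (is.null(seqs)) seqs <- character(0)
  structure(unique(seqs), class = "control_set")
}

#' Perfect-match test against the control read set
#'
#' `TRUE` for a mate whose full sequence, or its reverse complement, occurs
#' verbatim among the control reads. No alignment is involved: "perfect
#' match" is exact full-length string equality.
#'
#' @param sequences character vector of mate sequences.
#' @param control_set a `control_set` from [control_read_set()].
#' @return logical vector.
#' @export
match_control <- function(sequences, control_set) {
  if (length(control_set) == 0) return(rep(FALSE, length(sequences)))
  sequences %in% control_set | revcomp(sequences) %in% control_set
}

#' Classify read pairs through the rootstock/control/scion cascade
#'
#' The sequential decision the whole analysis rests on, applied to every
#' QC-passing pair of a rootstock sample:
#' \enumerate{
#'   \item pairs aligning properly to the rootstock transcriptome within
#'     `root_max_edit` edits per mate are labelled `rootstock`;
#'   \item of the escapees, pairs with either mate perfectly matching a
#'     non-grafted control read (either orientation) are `control_match`;
#'   \item the remainder aligning properly to the scion transcriptome within
#'     `scion_max_edit` edits per mate are `transmitted`, assigned to the
#'     minimal-summed-edit scion target(s) (ties recorded, flagged
#'     ambiguous);
#'   \item everything else is `unassigned`.
#' }
#' Labels are exhaustive and exclusive.
#'
#' @param pairs a `read_pairs` data frame.
#' @param rootstock_index,scion_index `kmer_index` objects over the two
#'   references.
#' @param control_set a `control_set` (may be empty).
#' @param root_max_edit per-mate edit cap for the rootstock stage (default 2).
#' @param scion_max_edit per-mate edit cap for the scion stage (default 1).
#' @param insert_bounds proper-pair insert size range.
#' @return data frame with columns `pair_id`, `label`, `targets`
#'   (comma-joined assigned transcript ids or `NA`), `ambiguous`,
#'   `summed_edit`.
#' @export
classify_pairs <- function(pairs, rootstock_index, scion_index, control_set,
                           root_max_edit = 2, scion_max_edit = 1,
                           insert_bounds = c(50, 600)) {
  stopifnot(inherits(pairs, "read_pairs"))
  n <- nrow(pairs)
  label <- rep("unassigned", n)
  targets <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n)
  summed <- rep(NA_integer_, n)
  if (n > 0) {
    st1 <- align_pairs(pairs$seq1, pairs$seq2, rootstock_index,
                       max_edit = root_max_edit, insert_bounds = insert_bounds)
    root <- st1$proper
    label[root] <- "rootstock"
    targets[root] <- st1$tied_targets[root]
    ambiguous[root] <- st1$ambiguous[root]
    summed[root] <- st1$summed_edit[root]
    esc <- which(!root)
    if (length(esc) > 0) {
      ctl <- match_control(pairs$seq1[esc], control_set) |
             match_control(pairs$seq2[esc], control_set)
      label[esc[ctl]] <- "control_match"
      rem <- esc[!ctl]
      if (length(rem) > 0) {
        st3 <- align_pairs(pairs$seq1[rem], pairs$seq2[rem], scion_index,
                           max_edit = scion_max_edit,
                           insert_bounds = insert_bounds)
        tx <- st3$proper
        label[rem[tx]] <- "transmitted"
        targets[rem[tx]] <- st3$tied_targets[tx]
        ambiguous[rem[tx]] <- st3$ambiguous[tx]
        summed[rem[tx]] <- st3$summed_edit[tx]
      }
    }
  }
  data.frame(pair_id = pairs$pair_id, label = label, targets = targets,
             ambiguous = ambiguous, summed_edit = summed,
             stringsAsFactors = FALSE)
}

#' Call graft-mobile transcripts across replicates
#'
#' A scion transcript is detected in a replicate when at least `min_pairs`
#' transmitted pairs are assigned to it, and called mobile under a condition
#' when detected in at least `min_replicates` of the condition's replicates.
#' Ambiguous multi-target pairs count toward every tied target. RPKM is
#' computed per detected replicate from the transmitted pair count, the
#' transcript length, and the replicate's total properly mapped pairs
#' (rootstock + transmitted).
#'
#' @param classified data frame binding [classify_pairs()] outputs for all
#'   grafted samples, with added columns `condition` and `replicate`.
#' @param scion_lengths named vector of scion transcript lengths (bp), e.g.
#'   [transcript_lengths()] of the scion reference.
#' @param n_replicates replicates per condition.
#' @param min_replicates minimum replicates supporting a mobile call
#'   (default 2, the "two out of three" rule).
#' @param min_pairs minimum transmitted pairs for detection in a replicate.
#' @return object of class `mobile_call_table`: list with `calls` (one row
#'   per transcript x condition: `n_detected`, `detected_replicates`,
#'   `mobile`) and `detections` (transcript x condition x replicate pair
#'   counts and RPKM).
#' @export
call_mobile <- function(classified, scion_lengths, n_replicates = 3,
                        min_replicates = 2, min_pairs = 1) {
  stopifnot(all(c("pair_id", "label", "targets", "condition", "replicate")
                %in% names(classified)))
  if (min_replicates > n_replicates)
    stop("min_replicates (", min_replicates, ") exceeds n_replicates (",
         n_replicates, ")")
  tx <- classified[classified$label == "transmitted", , drop = FALSE]
  mapped <- classified[classified$label %in% c("rootstock", "transmitted"), ,
                       drop = FALSE]
  totals <- if (nrow(mapped) == 0) {
    data.frame(condition = character(0), replicate = integer(0),
               total = integer(0))
  } else {
    stats::aggregate(list(total = mapped$pair_id),
                     by = list(condition = mapped$condition,
                               replicate = mapped$replicate),
                     FUN = length)
  }
  if (nrow(tx) == 0) {
    det <- data.frame(transcript_id = character(0), condition = character(0),
                      replicate = integer(0), pairs = integer(0),
                      rpkm = numeric(0))
  } else {
    tgt <- strsplit(tx$targets, ",", fixed = TRUE)
    reps <- lengths(tgt)
    long <- data.frame(transcript_id = unlist(tgt, use.names = FALSE),
                       condition = rep(tx$condition, reps),
                       replicate = rep(tx$replicate, reps),
                       stringsAsFactors = FALSE)
    det <- stats::aggregate(list(pairs = rep(1L, nrow(long))),
                            by = long[c("transcript_id", "condition",
                                        "replicate")], FUN = sum)
    det <- merge(det, totals, by = c("condition", "replicate"), all.x = TRUE)
    unknown <- setdiff(det$transcript_id, names(scion_lengths))
    if (length(unknown) > 0)
      stop("transmitted targets missing from scion_lengths: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    det$rpkm <- mapply(rpkm, det$pairs,
                       scion_lengths[det$transcript_id], det$total)
    det <- det[det$pairs >= min_pairs,
               c("transcript_id", "condition", "replicate", "pairs", "rpkm")]
    det <- det[order(det$transcript_id, det$condition, det$replicate), ,
               drop = FALSE]
    rownames(det) <- NULL
  }
  if (nrow(det) == 0) {
    calls <- data.frame(transcript_id = character(0), condition = character(0),
                        n_detected = integer(0),
                        detected_replicates = character(0),
                        mobile = logical(0), stringsAsFactors = FALSE)
  } else {
    calls <- stats::aggregate(
      list(n_detected = det$replicate),
      by = det[c("transcript_id", "condition")],
      FUN = function(r) length(unique(r)))
    reps_str <- stats::aggregate(
      list(detected_replicates = det$replicate),
      by = det[c("transcript_id", "condition")],
      FUN = function(r) paste(sort(unique(r)), collapse = ","))
    calls <- merge(calls, reps_str, by = c("transcript_id", "condition"))
    calls$mobile <- calls$n_detected >= min_replicates
    calls <- calls[order(calls$transcript_id, calls$condition),
                   c("transcript_id", "condition", "n_detected",
                     "detected_replicates", "mobile")]
    rownames(calls) <- NULL
  }
  structure(list(calls = calls, detections = det,
                 n_replicates = as.integer(n_replicates),
                 min_replicates = as.integer(min_replicates),
                 min_pairs = as.integer(min_pairs)),
            class = "mobile_call_table")
}

#' @export
print.mobile_call_table <- function(x, ...) {
  cat(sprintf("mobile_call_table: %d transcript x condition rows, %d mobile (>=%d/%d replicates)\n",
              nrow(x$calls), sum(x$calls$mobile), x$min_replicates,
              x$n_replicates))
  invisible(x)
}

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped fragments:
#' `1e9 * count / (length * total)`.
#'
#' @param pair_count fragments assigned to the transcript.
#' @param transcript_length transcript length in bp (> 0).
#' @param total_mapped_pairs library-wide mapped fragments (> 0).
#' @return RPKM value.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(pair_count, transcript_length, total_mapped_pairs) {
  if (any(transcript_length <= 0)) stop("transcript_length must be > 0")
  if (any(total_mapped_pairs <= 0)) stop("total_mapped_pairs must be > 0")
  1e9 * pair_count / (transcript_length * total_mapped_pairs)
}

#' Per-condition mobile transcript id sets
#'
#' @param table a `mobile_call_table`.
#' @return named list: one sorted id vector per condition, plus `union`
#'   across all conditions.
#' @export
condition_sets <- function(table) {
  stopifnot(inherits(table, "mobile_call_table"))
  calls <- table$calls[table$calls$mobile, , drop = FALSE]
  conds <- unique(table$calls$condition)
  sets <- lapply(conds, function(cc)
    sort(calls$transcript_id[calls$condition == cc]))
  names(sets) <- conds
  sets$union <- sort(unique(unlist(sets, use.names = FALSE)))
  sets
}
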