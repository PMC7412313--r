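#' Build a k-mer index over a transcript set
#'
#' Every reference position congruent to 0 modulo `step` contributes its
#' k-mer to the postings table. The index is the seeding structure of the
#' banded edit-distance aligner: with `k = 15` and `step = 5`, any 85-bp
#' read placement with at most two edits is guaranteed to share an indexed
#' exact k-mer with its reference (pigeonhole over the read's clean
#' segments), so seeding loses no qualifying hit at the caps the
#' classification cascade uses.
#'
#' @param refs a [transcript_set()].
#' @param k k-mer size (default 15).
#' @param step reference sampling stride (default 5).
#' @return object of class `kmer_index`.
#' @export
build_index <- function(refs, k = 15, step = 5) {
  stopifnot(inherits(refs, "transcript_set"), k >= 1, k <= 31, step >= 1)
  if (length(refs) > 0) {
    lens <- transcript_lengths(refs)
    if (any(lens < k)) {
      short <- names(lens)[which.min(lens)]
      stop("k (", k, ") exceeds the length of transcript '", short, "' (",
           min(lens), " bp)")
    }
  }
  post <- cpp_build_postings(refs$sequences, as.integer(k), as.integer(step))
  structure(list(k = as.integer(k), step = as.integer(step),
                 keys = post$keys, key_start = post$key_start,
                 post_target = post$post_target,
                 post_offset = post$post_offset,
                 ref_names = transcript_ids(refs),
                 ref_seqs = unname(refs$sequences)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d step=%d, %d keys, %d postings over %d targets\n",
              x$k, x$step, length(x$keys), length(x$post_target),
              length(x$ref_names)))
  invisible(x)
}

#' Postings of a k-mer index as a data frame
#'
#' @param index a `kmer_index`.
#' @return data frame with columns `kmer`, `target_id`, `offset` (0-based).
#' @export
index_postings <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  n <- length(index$post_target)
  if (n == 0)
    return(data.frame(kmer = character(0), target_id = character(0),
                      offset = integer(0)))
  counts <- diff(index$key_start)
  data.frame(kmer = rep(index$keys, counts),
             target_id = index$ref_names[index$post_target + 1L],
             offset = index$post_offset, stringsAsFactors = FALSE)
}

#' Align a read against an indexed transcript set
#'
#' Seed-and-verify alignment: exact k-mer seeds on both strands are
#' clustered by implied diagonal, each candidate placement is verified with
#' banded dynamic programming (band half-width = `max_edit`), and every
#' placement with Levenshtein edit distance at most `max_edit` is reported.
#' A hit on strand `-` means the reverse complement of the read matches the
#' reference forward strand at the reported position. End-to-end in the
#' read: the edit count covers the whole read, not a local fragment.
#'
#' @param sequence read sequence (one string).
#' @param index a `kmer_index` from [build_index()].
#' @param max_edit maximum Levenshtein distance (substitutions + indels).
#' @param cigar whether to compute CIGAR strings.
#' @return data frame of alignment records (`target_id`, `target_start`
#'   0-based, `strand`, `edit_distance`, `cigar`) sorted by
#'   (edit_distance, target_id, target_start).
#' @export
align_read <- function(sequence, index, max_edit = 2, cigar = TRUE) {
  stopifnot(inherits(index, "kmer_index"), length(sequence) == 1)
  if (nchar(sequence) < index$k) {
    warning("read shorter than k (", index$k, "); no alignment attempted")
    return(empty_alignments())
  }
  hits <- cpp_align_reads(sequence, index$keys, index$key_start,
                          index$post_target, index$post_offset,
                          index$ref_seqs, index$k, as.integer(max_edit),
                          isTRUE(cigar))
  format_alignments(hits, index)
}

#' Align many reads (batch version of [align_read()])
#'
#' @param sequences character vector of reads.
#' @inheritParams align_read
#' @return data frame as in [align_read()] plus a `read` index column.
#' @export
align_reads <- function(sequences, index, max_edit = 2, cigar = FALSE) {
  stopifnot(inherits(index, "kmer_index"))
  ok <- nchar(sequences) >= index$k
  if (!all(ok)) warning(sum(!ok), " read(s) shorter than k skipped")
  hits <- cpp_align_reads(sequences[ok], index$keys, index$key_start,
                          index$post_target, index$post_offset,
                          index$ref_seqs, index$k, as.integer(max_edit),
                          isTRUE(cigar))
  hits$read <- which(ok)[hits$read]
  out <- format_alignments(hits, index, keep_read = TRUE)
  out[order(out$read, out$edit_distance, out$target_id, out$target_start), ,
      drop = FALSE]
}

empty_alignments <- function() {
  data.frame(target_id = character(0), target_start = integer(0),
             strand = character(0), edit_distance = integer(0),
             cigar = character(0), stringsAsFactors = FALSE)
}

format_alignments <- function(hits, index, keep_read = FALSE) {
  out <- data.frame(target_id = index$ref_names[hits$target],
                    target_start = hits$tstart, strand = hits$strand,
                    edit_distance = hits$edit, cigar = hits$cigar,
                    stringsAsFactors = FALSE)
  if (keep_read) out$read <- hits$read
  out <- out[order(out$edit_distance, out$target_id, out$target_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proper-pair alignment of mate pairs
#'
#' A pair is proper when both mates hit the same target on opposite strands
#' with an implied insert (outermost span of the two placements) inside
#' `insert_bounds`, each mate within `max_edit`. Among qualifying placements
#' the minimal summed edit wins; remaining ties are broken by target id and
#' leftmost start. All targets tied at the minimal summed edit are reported
#' (`tied_targets`), with `ambiguous = TRUE` when more than one.
#'
#' @param mate1,mate2 character vectors of mate sequences.
#' @param index a `kmer_index`.
#' @param max_edit per-mate Levenshtein cap.
#' @param insert_bounds numeric length-2: allowed insert size range in bp.
#' @return data frame with one row per pair: `proper`, `target_id`,
#'   `summed_edit`, `edit1`, `edit2`, `start1`, `start2`, `strand1`,
#'   `tied_targets` (comma-joined), `ambiguous`.
#' @export
align_pairs <- function(mate1, mate2, index, max_edit = 2,
                        insert_bounds = c(50, 600)) {
  stopifnot(inherits(index, "kmer_index"), length(mate1) == length(mate2))
  res <- cpp_align_pairs(mate1, mate2, index$keys, index$key_start,
                         index$post_target, index$post_offset,
                         index$ref_seqs, index$ref_names,
                         index$k, as.integer(max_edit),
                         as.integer(insert_bounds[1]),
                         as.integer(insert_bounds[2]))
  data.frame(proper = res$proper,
             target_id = ifelse(is.na(res$target), NA_character_,
                                index$ref_names[res$target]),
             summed_edit = res$summed_edit, edit1 = res$edit1,
             edit2 = res$edit2, start1 = res$start1, start2 = res$start2,
             strand1 = res$strand1, tied_targets = res$tied_targets,
             ambiguous = res$ambiguous, stringsAsFactors = FALSE)
}

#' Export alignment records as a SAM-like TSV
#'
#' Minimal SAM-flavoured table: read id, target, 1-based position, strand,
#' CIGAR, and an NM-style edit distance column.
#'
#' @param records data frame from [align_read()]/[align_reads()].
#' @param read_ids optional read id vector indexed by `records$read`.
#' @param path output file path.
#' @return invisibly, the written data frame.
#' @export
write_alignments_tsv <- function(records, path, read_ids = NULL) {
  out <- data.frame(
    read_id = if (!is.null(read_ids) && !is.null(records$read))
      read_ids[records$read] else records$read %||% NA,
    target = records$target_id,
    pos = records$target_start + 1L,
    strand = records$strand,
    cigar = records$cigar,
    NM = records$edit_distance, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
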