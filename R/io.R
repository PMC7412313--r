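#' Read a FASTA file into a transcript set
#'
#' @param path FASTA path (gzip handled transparently).
#' @param species_id species label for the resulting set.
#' @return a [transcript_set()].
#' @export
read_fasta <- function(path, species_id = basename(path)) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  transcript_set(stats::setNames(as.character(x), ids), species_id)
}

#' Write a transcript set (or named sequences) as FASTA
#'
#' @param x a [transcript_set()] or named character vector (nucleotide or
#'   amino acid).
#' @param path output path (`.gz` suffix compresses).
#' @param protein treat sequences as amino acids.
#' @export
write_fasta <- function(x, path, protein = FALSE) {
  seqs <- if (inherits(x, "transcript_set")) x$sequences else x
  set <- if (protein) Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a paired FASTQ sample
#'
#' @param path1,path2 mate FASTQ paths (Phred+33; gzip transparent).
#' @param condition,replicate,grafted sample metadata.
#' @return a `read_pairs` data frame.
#' @export
read_pairs_fastq <- function(path1, path2, condition = NA, replicate = NA,
                             grafted = NA) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("mate files differ in record count: ", path1, " vs ", path2)
  ids1 <- sub("\\s.*$", "", names(r1))
  ids2 <- sub("\\s.*$", "", names(r2))
  ids1 <- sub("/1$", "", ids1); ids2 <- sub("/2$", "", ids2)
  if (!identical(ids1, ids2)) stop("mate files are not name-synchronized")
  read_pairs(data.frame(pair_id = ids1,
                        seq1 = as.character(r1),
                        qual1 = as.character(S4Vectors::mcols(r1)$qualities),
                        seq2 = as.character(r2),
                        qual2 = as.character(S4Vectors::mcols(r2)$qualities),
                        stringsAsFactors = FALSE),
             condition, replicate, grafted)
}

#' Write a paired sample as two FASTQ files
#'
#' @param pairs a `read_pairs` data frame.
#' @param path1,path2 output FASTQ paths (`.gz` suffix compresses).
#' @export
write_pairs_fastq <- function(pairs, path1, path2) {
  stopifnot(inherits(pairs, "read_pairs"))
  w <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path))
  }
  w(pairs$seq1, pairs$qual1, pairs$pair_id, path1)
  w(pairs$seq2, pairs$qual2, pairs$pair_id, path2)
  invisible(c(path1, path2))
}

#' Read / write one-id-per-line list files
#' @param path file path.
#' @return character vector of ids.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' @rdname read_id_list
#' @param ids character vector to write.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Pipeline parameter bundle
#'
#' Collects every analysis threshold in one validated place. The defaults
#' are the published criteria of the classification cascade: trimmed reads
#' shorter than 40 bases discarded; rRNA matches within 3 mismatches
#' removed; rootstock mapping within 2 edits; perfect-match control
#' subtraction; scion mapping within 1 edit; mobile calls requiring
#' detection in at least 2 of 3 replicates.
#'
#' @param min_length minimum trimmed read length (bp).
#' @param quality_threshold sliding-window mean quality threshold.
#' @param window sliding window width (bases).
#' @param adapter 3' adapter sequence.
#' @param adapter_mismatch_frac allowed adapter mismatch fraction.
#' @param adapter_min_overlap minimum adapter overlap (bases).
#' @param rrna_max_mismatch rRNA filter mismatch cap.
#' @param root_max_edit rootstock-stage per-mate edit cap.
#' @param scion_max_edit scion-stage per-mate edit cap.
#' @param min_replicates replicates required for a mobile call.
#' @param min_pairs transmitted pairs required for per-replicate detection.
#' @param evalue_cutoff orthology e-value bound (strict).
#' @param k,step k-mer index parameters.
#' @param insert_bounds proper-pair insert range (bp).
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(min_length = 40, quality_threshold = 20,
                            window = 4, adapter = "AGATCGGAAGAGC",
                            adapter_mismatch_frac = 0.1,
                            adapter_min_overlap = 3,
                            rrna_max_mismatch = 3, root_max_edit = 2,
                            scion_max_edit = 1, min_replicates = 2,
                            min_pairs = 1, evalue_cutoff = 1e-5,
                            k = 15, step = 5, insert_bounds = c(50, 600)) {
  p <- list(min_length = min_length, quality_threshold = quality_threshold,
            window = window, adapter = adapter,
            adapter_mismatch_frac = adapter_mismatch_frac,
            adapter_min_overlap = adapter_min_overlap,
            rrna_max_mismatch = rrna_max_mismatch,
            root_max_edit = root_max_edit, scion_max_edit = scion_max_edit,
            min_replicates = min_replicates, min_pairs = min_pairs,
            evalue_cutoff = evalue_cutoff, k = k, step = step,
            insert_bounds = insert_bounds)
  stopifnot(p$min_length >= 1, p$rrna_max_mismatch >= 0,
            p$root_max_edit >= 0, p$scion_max_edit >= 0,
            p$min_replicates >= 1, p$min_pairs >= 1, p$k >= 1, p$step >= 1,
            length(p$insert_bounds) == 2,
            p$insert_bounds[1] <= p$insert_bounds[2])
  class(p) <- "pipeline_params"
  p
}

#' Run the full mobile-mRNA discovery pipeline
#'
#' Executes the fixed stage order on every grafted sample: adapter/quality
#' trimming with short-read discard, rRNA filtering, rootstock alignment,
#' non-grafted control subtraction, scion alignment, and the
#' replicate-supported mobile call. Control samples pass through the same
#' QC before their reads form the perfect-match subtraction set. Rerunning
#' with identical inputs reproduces identical outputs.
#'
#' @param rootstock,scion [transcript_set()] references.
#' @param samples named list of grafted `read_pairs` (names
#'   `condition.replicate`, as produced by [simulate_experiment()]).
#' @param controls list of non-grafted `read_pairs`.
#' @param rrna optional rRNA [transcript_set()].
#' @param params a [pipeline_params()].
#' @param outdir optional directory; when given, per-stage TSV artifacts,
#'   per-condition mobile id lists and a run manifest are written there.
#' @return list with `call_table` (a `mobile_call_table`), `condition_sets`,
#'   `classifications` (per-pair labels with condition/replicate),
#'   `qc_discards`, `stage_counts` (per-sample reconciliation of input,
#'   discarded and labelled pair counts), and `params`.
#' @export
run_pipeline <- function(rootstock, scion, samples, controls, rrna = NULL,
                         params = pipeline_params(), outdir = NULL) {
  stopifnot(inherits(rootstock, "transcript_set"),
            inherits(scion, "transcript_set"),
            is.list(samples), length(samples) > 0)
  root_idx <- build_index(rootstock, params$k, params$step)
  scion_idx <- build_index(scion, params$k, params$step)
  ctl_qc <- lapply(controls, qc_pairs, rrna_refs = rrna, params = params)
  ctl_set <- control_read_set(lapply(ctl_qc, `[[`, "pairs"))
  class_list <- list()
  qc_list <- list()
  counts <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    cond <- attr(s, "condition")
    repl <- attr(s, "replicate")
    qc <- qc_pairs(s, rrna_refs = rrna, params = params)
    cl <- classify_pairs(qc$pairs, root_idx, scion_idx, ctl_set,
                         root_max_edit = params$root_max_edit,
                         scion_max_edit = params$scion_max_edit,
                         insert_bounds = params$insert_bounds)
    cl$condition <- cond
    cl$replicate <- repl
    class_list[[nm]] <- cl
    if (nrow(qc$discards) > 0) {
      qc$discards$sample <- nm
      qc_list[[nm]] <- qc$discards
    }
    counts[[nm]] <- data.frame(
      sample = nm, condition = cond, replicate = repl,
      input = nrow(s), discarded_short = sum(qc$discards$reason == "short"),
      discarded_rrna = sum(qc$discards$reason == "rrna"),
      classified = nrow(cl),
      rootstock = sum(cl$label == "rootstock"),
      control_match = sum(cl$label == "control_match"),
      transmitted = sum(cl$label == "transmitted"),
      unassigned = sum(cl$label == "unassigned"),
      stringsAsFactors = FALSE)
  }
  classifications <- do.call(rbind, class_list)
  rownames(classifications) <- NULL
  stage_counts <- do.call(rbind, counts)
  rownames(stage_counts) <- NULL
  bad <- with(stage_counts,
              input != discarded_short + discarded_rrna + classified)
  if (any(bad))
    stop("pair accounting does not reconcile for sample(s): ",
         paste(stage_counts$sample[bad], collapse = ", "))
  n_reps <- max(stage_counts$replicate)
  table <- call_mobile(classifications, transcript_lengths(scion),
                       n_replicates = n_reps,
                       min_replicates = params$min_replicates,
                       min_pairs = params$min_pairs)
  sets <- condition_sets(table)
  result <- list(call_table = table, condition_sets = sets,
                 classifications = classifications,
                 qc_discards = if (length(qc_list) > 0)
                   do.call(rbind, qc_list) else NULL,
                 stage_counts = stage_counts, params = params)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(result$classifications, "classifications.tsv")
  wt(result$call_table$calls, "mobile_calls.tsv")
  wt(result$call_table$detections, "detections.tsv")
  wt(result$stage_counts, "stage_counts.tsv")
  for (cond in setdiff(names(result$condition_sets), "union"))
    write_id_list(result$condition_sets[[cond]],
                  file.path(outdir, paste0("mobile_", cond, ".txt")))
  write_id_list(result$condition_sets$union,
                file.path(outdir, "mobile_union.txt"))
  manifest <- c(
    paste0("package: graftmobile ",
           as.character(utils::packageVersion("graftmobile"))),
    paste0("params: ", paste(names(result$params), "=",
                             vapply(result$params, function(x)
                               paste(format(x), collapse = ","),
                               character(1)), collapse = "; ")),
    paste0("samples: ", nrow(result$stage_counts)),
    paste0("total_pairs: ", sum(result$stage_counts$input)))
  writeLines(manifest, file.path(outdir, "run_manifest.txt"))
  invisible(outdir)
}
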