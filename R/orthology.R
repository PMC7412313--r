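# Karlin-Altschul ungapped constants for BLOSUM62; the internal e-value is
# an approximation (documented) sufficient for reciprocal-best-hit ranking.
KA_LAMBDA_BLOSUM62 <- 0.3176
KA_K_BLOSUM62 <- 0.134

#' Load a 12-column tabular similarity hit file
#'
#' Reads the standard tab-separated hit format (query, subject, %identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore) and reduces multiple HSPs per (query, subject) pair to
#' the single best record (max bit score, then min e-value).
#'
#' @param path file path.
#' @return data frame of hit records, one row per (query, subject).
#' @export
load_hits <- function(path) {
  cols <- c("query_id", "subject_id", "identity_pct", "length", "mismatches",
            "gapopens", "qstart", "qend", "sstart", "send", "evalue",
            "bit_score")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
    for (nm in cols[3:12]) out[[nm]] <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12)
  if (length(bad) > 0)
    stop("malformed hit row (expected 12 tab-separated columns) at line ",
         bad[1])
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- cols
  for (nm in cols[3:12]) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v))
      stop("non-numeric value in column '", nm, "' at line ",
           which(is.na(v))[1])
    df[[nm]] <- v
  }
  if (any(df$evalue < 0)) stop("negative e-value at line ",
                               which(df$evalue < 0)[1])
  # best-HSP reduction
  df <- df[order(df$query_id, df$subject_id, -df$bit_score, df$evalue), ,
           drop = FALSE]
  df <- df[!duplicated(df[c("query_id", "subject_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write hit records in 12-column tabular format
#' @param hits data frame as returned by [load_hits()].
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(format(hits, scientific = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(hits)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  storage.mode(m) <- "integer"
  m
}

#' Score a protein pair with local alignment
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap of
#' length g costs `gap_open + g * gap_extend`). The bit score uses the
#' published ungapped Karlin-Altschul constants for BLOSUM62 and the
#' e-value is the approximate `m * db_size * 2^(-bitscore)`; both are
#' surrogate statistics intended for hit ranking on synthetic proteomes,
#' not for reproducing a search engine's exact numbers.
#'
#' @param protein_a,protein_b amino-acid strings.
#' @param matrix substitution matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend gap penalties (defaults 11, 1).
#' @param db_size total residues in the subject database (defaults to
#'   `nchar(protein_b)`).
#' @return one-row data frame: `raw_score`, `bit_score`, `evalue`,
#'   `identity_pct`, `align_length`.
#' @export
score_pair <- function(protein_a, protein_b, matrix = NULL, gap_open = 11,
                       gap_extend = 1, db_size = NULL) {
  if (nchar(protein_a) == 0 || nchar(protein_b) == 0)
    stop("empty protein sequence")
  if (is.null(matrix)) matrix <- blosum62_matrix()
  res <- cpp_sw_pair(protein_a, protein_b, matrix, rownames(matrix),
                     as.integer(gap_open), as.integer(gap_extend))
  bit <- (KA_LAMBDA_BLOSUM62 * res$score - log(KA_K_BLOSUM62)) / log(2)
  if (is.null(db_size)) db_size <- nchar(protein_b)
  data.frame(raw_score = res$score, bit_score = bit,
             evalue = nchar(protein_a) * db_size * 2^(-bit),
             identity_pct = if (res$align_length > 0)
               100 * res$identities / res$align_length else 0,
             align_length = res$align_length)
}

#' All-vs-all similarity hits between two proteomes
#'
#' Scores every query against every subject with the internal
#' Smith-Waterman scorer and returns hit records (one per pair) with bit
#' scores and approximate e-values, ready for [best_hits()].
#'
#' @param queries,subjects named character vectors of protein sequences.
#' @inheritParams score_pair
#' @param evalue_max drop hits above this e-value to keep the table small.
#' @return data frame: `query_id`, `subject_id`, `raw_score`, `bit_score`,
#'   `evalue`.
#' @export
score_proteomes <- function(queries, subjects, matrix = NULL, gap_open = 11,
                            gap_extend = 1, evalue_max = 10) {
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  if (is.null(matrix)) matrix <- blosum62_matrix()
  keepq <- nchar(queries) > 0
  keeps <- nchar(subjects) > 0
  sc <- cpp_sw_matrix(queries[keepq], subjects[keeps], matrix,
                      rownames(matrix), as.integer(gap_open),
                      as.integer(gap_extend))
  db_size <- sum(nchar(subjects[keeps]))
  bit <- (KA_LAMBDA_BLOSUM62 * sc - log(KA_K_BLOSUM62)) / log(2)
  ev <- outer(nchar(queries[keepq]), rep(db_size, sum(keeps))) * 2^(-bit)
  keep <- which(ev <= evalue_max, arr.ind = TRUE)
  out <- data.frame(query_id = names(queries[keepq])[keep[, 1]],
                    subject_id = names(subjects[keeps])[keep[, 2]],
                    raw_score = sc[keep], bit_score = bit[keep],
                    evalue = ev[keep], stringsAsFactors = FALSE)
  out <- out[order(out$query_id, -out$bit_score, out$evalue, out$subject_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best hit per query under an e-value cutoff
#'
#' Hits with e-value greater than or equal to the cutoff are removed (the
#' criterion is strictly `E < cutoff`); per query the maximum bit score
#' wins, ties broken by minimum e-value, then by lexicographically smallest
#' subject id.
#'
#' @param hits data frame with `query_id`, `subject_id`, `bit_score`,
#'   `evalue` (reduced to one row per pair).
#' @param evalue_cutoff strict upper bound on e-value (default 1e-5).
#' @return named character vector: query id -> best subject id.
#' @export
best_hits <- function(hits, evalue_cutoff = 1e-5) {
  h <- hits[hits$evalue < evalue_cutoff, , drop = FALSE]
  if (nrow(h) == 0) return(stats::setNames(character(0), character(0)))
  h <- h[order(h$query_id, -h$bit_score, h$evalue, h$subject_id), ,
         drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  stats::setNames(h$subject_id, h$query_id)
}

#' Reciprocal best hits
#'
#' Ortholog pairs: `a` and `b` are paired exactly when `b` is `a`'s best
#' hit and `a` is `b`'s best hit. The result is a partial matching (each id
#' appears in at most one pair) and is symmetric in its two arguments.
#'
#' @param best_ab named vector from [best_hits()] (A queries -> B subjects).
#' @param best_ba named vector for the reverse direction.
#' @return data frame with columns `id_a`, `id_b`, sorted by `id_a`.
#' @export
reciprocal_best <- function(best_ab, best_ba) {
  a <- names(best_ab)
  b <- unname(best_ab)
  ok <- !is.na(best_ba[b]) & best_ba[b] == a
  ok[is.na(ok)] <- FALSE
  out <- data.frame(id_a = a[ok], id_b = b[ok], stringsAsFactors = FALSE)
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal-best-hit orthology between two proteomes
#'
#' Convenience wrapper: scores both directions with [score_proteomes()],
#' takes [best_hits()] under the e-value cutoff, and intersects them with
#' [reciprocal_best()].
#'
#' @param proteome_a,proteome_b named character vectors of proteins.
#' @param evalue_cutoff strict e-value bound (default 1e-5).
#' @inheritParams score_pair
#' @return data frame of ortholog pairs (`id_a`, `id_b`).
#' @export
rbh_orthologs <- function(proteome_a, proteome_b, evalue_cutoff = 1e-5,
                          matrix = NULL, gap_open = 11, gap_extend = 1) {
  stopifnot(!is.null(names(proteome_a)), !is.null(names(proteome_b)))
  if (is.null(matrix)) matrix <- blosum62_matrix()
  pa <- proteome_a[nchar(proteome_a) > 0]
  pb <- proteome_b[nchar(proteome_b) > 0]
  # raw local-alignment scores are symmetric: score the matrix once and
  # derive the two directional e-values from it
  sc <- cpp_sw_matrix(pa, pb, matrix, rownames(matrix),
                      as.integer(gap_open), as.integer(gap_extend))
  bit <- (KA_LAMBDA_BLOSUM62 * sc - log(KA_K_BLOSUM62)) / log(2)
  ev_ab <- nchar(pa) * sum(nchar(pb)) * 2^(-bit)
  ev_ba <- t(2^(-bit) * rep(sum(nchar(pa)), nrow(bit))) * nchar(pb)
  hits_from <- function(ev, bitm, qnames, snames) {
    keep <- which(ev < evalue_cutoff, arr.ind = TRUE)
    data.frame(query_id = qnames[keep[, 1]], subject_id = snames[keep[, 2]],
               bit_score = bitm[keep], evalue = ev[keep],
               stringsAsFactors = FALSE)
  }
  hits_ab <- hits_from(ev_ab, bit, names(pa), names(pb))
  hits_ba <- hits_from(ev_ba, t(bit), names(pb), names(pa))
  reciprocal_best(best_hits(hits_ab, evalue_cutoff),
                  best_hits(hits_ba, evalue_cutoff))
}

#' Strip isoform suffixes from transcript ids
#'
#' Optional id normalization (off by default everywhere): removes the final
#' dot-separated suffix, mapping e.g. `"g02007.1"` to `"g02007"`.
#'
#' @param ids character vector of transcript ids.
#' @return character vector.
#' @export
strip_isoform_suffix <- function(ids) sub("\\.[^.]*$", "", ids)
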