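#' Reference transcript set
#'
#' A lightweight container for a species' reference transcriptome: a named
#' vector of nucleotide sequences plus a species label. Used as the reference
#' for every alignment stage and as the substrate of the simulator.
#'
#' @param sequences named character vector of nucleotide sequences (A/C/G/T).
#' @param species_id single label for the species the set belongs to.
#' @return an object of class `transcript_set`.
#' @examples
#' ts <- transcript_set(c(t1 = "ACGTACGT", t2 = "GGGTTTAA"), "demo")
#' length(ts)
#' @export
transcript_set <- function(sequences, species_id = "unknown") {
  stopifnot(is.character(sequences), length(species_id) == 1)
  ids <- names(sequences)
  if (length(sequences) > 0) {
    if (is.null(ids) || any(ids == "" | is.na(ids)))
      stop("all sequences must be named with a transcript id")
    if (anyDuplicated(ids))
      stop("duplicate transcript ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (any(nchar(sequences) == 0)) stop("empty sequences are not allowed")
    if (any(grepl("[^ACGT]", sequences)))
      stop("sequences must use the alphabet A,C,G,T only")
  }
  structure(list(species_id = as.character(species_id),
                 sequences = sequences),
            class = "transcript_set")
}

#' @export
length.transcript_set <- function(x) length(x$sequences)

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set '%s': %d transcripts", x$species_id, length(x)))
  if (length(x) > 0)
    cat(sprintf(", lengths %d-%d bp", min(nchar(x$sequences)),
                max(nchar(x$sequences))))
  cat("\n")
  invisible(x)
}

#' Transcript ids of a transcript set
#' @param x a `transcript_set`.
#' @return character vector of ids.
#' @export
transcript_ids <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  names(x$sequences)
}

#' Transcript lengths (bp)
#' @param x a `transcript_set`.
#' @return named integer vector of sequence lengths.
#' @export
transcript_lengths <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  stats::setNames(nchar(x$sequences), names(x$sequences))
}
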