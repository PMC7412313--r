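#' Overlap between a mobile set and a previously published set
#'
#' Optionally translates mobile ids through an ortholog map (columns `id_a`,
#' `id_b`; mobile ids are matched on the `id_a` side) before intersecting.
#'
#' @param mobile_ids character vector of mobile transcript ids.
#' @param previous_ids character vector from a published study.
#' @param ortholog_map optional data frame (`id_a`, `id_b`) from
#'   [reciprocal_best()].
#' @return integer overlap count.
#' @export
overlap <- function(mobile_ids, previous_ids, ortholog_map = NULL) {
  ids <- unique(mobile_ids)
  if (!is.null(ortholog_map)) {
    stopifnot(all(c("id_a", "id_b") %in% names(ortholog_map)))
    ids <- ortholog_map$id_b[ortholog_map$id_a %in% ids]
  }
  length(intersect(ids, previous_ids))
}

#' Covered percentage of a published set
#'
#' `100 * k / K`, rounded half-up to two decimals: the fraction of a
#' previously published transcript set recovered by a mobile set.
#'
#' @param k overlap count.
#' @param K published set size (> 0).
#' @return percentage in `[0, 100]` with two decimals.
#' @examples
#' covered_percent(1, 3)  # 33.33
#' @export
covered_percent <- function(k, K) {
  if (any(K <= 0)) stop("K must be > 0")
  if (any(k < 0 | k > K)) stop("k must lie in [0, K]")
  floor(100 * k / K * 100 + 0.5) / 100
}

#' Hypergeometric over-/under-enrichment test of a set overlap
#'
#' Exact tail probabilities of drawing `k` marked items when `n` items are
#' drawn without replacement from a universe of `N` containing `K` marked
#' items. The pmf is computed by log-factorial accumulation;
#' `p_over = P(X >= k)` and `p_under = P(X <= k)` share the point mass at
#' `k`, the reported direction is the smaller tail, and the reported p-value
#' is `min(p_over, p_under)`.
#'
#' @param k observed overlap.
#' @param K marked items in the universe (e.g. a published set's size).
#' @param n draws (e.g. the mobile set's size).
#' @param N universe size. The universe is an explicit modelling choice:
#'   e.g. the scion reference size for within-system tests, or the number of
#'   ortholog pairs for cross-system tests.
#' @return object of class `enrichment_result`: list with `k`, `K`, `n`,
#'   `N`, `p_over`, `p_under`, `p`, `direction` (over/under/none),
#'   `covered_pct`.
#' @export
hypergeom_test <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n) || k < 0) stop("k must lie in [0, min(K, n)]")
  if (k < max(0, n - (N - K))) stop("k below the support: n - (N - K) draws are forced successes")
  support <- max(0, n - (N - K)):min(K, n)
  lpmf <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  pmf <- exp(lpmf)
  p_over <- sum(pmf[support >= k])
  p_under <- sum(pmf[support <= k])
  direction <- if (p_over < p_under) "over"
               else if (p_under < p_over) "under" else "none"
  structure(list(k = k, K = K, n = n, N = N, p_over = p_over,
                 p_under = p_under, p = min(p_over, p_under),
                 direction = direction,
                 covered_pct = if (K > 0) covered_percent(k, K)
                               else NA_real_),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "overlap %d of K=%d (covered %.2f%%), n=%d drawn from N=%d: %s-enrichment, p=%.4g\n",
    x$k, x$K, x$covered_pct, x$n, x$N, x$direction, x$p))
  invisible(x)
}

#' Exclusive Venn partition of 2-4 named sets
#'
#' @param sets named list of 2 to 4 character vectors.
#' @return data frame with one row per non-empty region signature
#'   (`&`-joined set names), its `count`, and a list column `members`;
#'   counts sum to the union size.
#' @export
venn_partition <- function(sets) {
  m <- length(sets)
  if (m < 2 || m > 4) stop("venn_partition expects between 2 and 4 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) {
    sig <- character(0)
  } else {
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
    sig <- apply(membership, 1, function(row)
      paste(names(sets)[row], collapse = "&"))
  }
  regions <- lapply(seq_len(2^m - 1), function(mask) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    paste(names(sets)[inset], collapse = "&")
  })
  counts <- vapply(regions, function(r) sum(sig == r), integer(1))
  members <- lapply(regions, function(r) universe[sig == r])
  out <- data.frame(region = unlist(regions), count = counts,
                    stringsAsFactors = FALSE)
  out$members <- members
  out
}

#' Enrichment report over several published sets
#'
#' One row per published set plus an `All Sets` union row: overlap, covered
#' percentage, enrichment direction, and hypergeometric p-value. Mirrors
#' the layout of cross-study comparison tables; direction and p-value are
#' `NA` when the overlap is zero (degenerate under-enrichment cells).
#'
#' @param mobile_ids mobile transcript id vector (translated through
#'   `ortholog_map` when given).
#' @param previous_sets named list of published id vectors.
#' @param N universe size for the hypergeometric test (must be supplied;
#'   there is no defensible default for cross-system comparisons).
#' @param ortholog_map optional (`id_a`, `id_b`) data frame.
#' @param add_union whether to append the union ("All Sets") row.
#' @return data frame: `set`, `K`, `n`, `k`, `covered_pct`, `direction`,
#'   `p_value`.
#' @export
enrichment_report <- function(mobile_ids, previous_sets, N,
                              ortholog_map = NULL, add_union = TRUE) {
  stopifnot(is.list(previous_sets), !is.null(names(previous_sets)))
  sets <- previous_sets
  if (add_union)
    sets <- c(sets, list("All Sets" = sort(unique(unlist(previous_sets,
                                                         use.names = FALSE)))))
  ids <- unique(mobile_ids)
  if (!is.null(ortholog_map))
    ids <- unique(ortholog_map$id_b[ortholog_map$id_a %in% ids])
  rows <- lapply(names(sets), function(nm) {
    K <- length(unique(sets[[nm]]))
    k <- length(intersect(ids, sets[[nm]]))
    ht <- hypergeom_test(k, K, length(ids), N)
    data.frame(set = nm, K = K, n = length(ids), k = k,
               covered_pct = ht$covered_pct,
               direction = if (k == 0) NA_character_ else ht$direction,
               p_value = if (k == 0) NA_real_ else ht$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
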