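#' Count pairwise disease co-occurrence
#'
#' Enumerates every unordered pair of ICD-10 codes that appears together in at
#' least one record and counts, against the cohort size `N = n_records(rs)`,
#' the records carrying each code (`n_a`, `n_b`) and both (`k`). Pairs that
#' never co-occur are not enumerated: they would only add `p = 1` entries to
#' the multiple-testing family.
#'
#' @param rs A `record_set`.
#' @return Tibble with columns `code_a`, `code_b` (with `code_a < code_b`),
#'   `n_a`, `n_b`, `k`, `N`, plus attribute `prevalence` (tibble `code`, `n`).
#' @export
count_pairs <- function(rs) {
  if (nrow(rs) == 0L) abort("Record set is empty.")
  long <- tibble(record_id = rep(rs$record_id, lengths(rs$codes)),
                 code = unlist(rs$codes, use.names = FALSE))
  prevalence <- dplyr::count(long, .data$code, name = "n") |>
    dplyr::arrange(.data$code)

  multi <- rs[lengths(rs$codes) >= 2L, ]
  if (nrow(multi) == 0L) {
    pairs <- tibble(code_a = character(), code_b = character(),
                    n_a = integer(), n_b = integer(),
                    k = integer(), N = integer())
  } else {
    # codes are stored sorted within each record, so combn emits code_a < code_b
    pair_mat <- do.call(cbind, lapply(multi$codes, combn, 2L))
    pairs <- tibble(code_a = pair_mat[1, ], code_b = pair_mat[2, ]) |>
      dplyr::count(.data$code_a, .data$code_b, name = "k")
    prev <- setNames(prevalence$n, prevalence$code)
    pairs$n_a <- unname(prev[pairs$code_a])
    pairs$n_b <- unname(prev[pairs$code_b])
    pairs$N <- nrow(rs)
    pairs <- pairs[, c("code_a", "code_b", "n_a", "n_b", "k", "N")]
  }
  attr(pairs, "prevalence") <- prevalence
  pairs
}

#' Upper-tail hypergeometric co-occurrence p-value
#'
#' Probability of observing `k` or more records carrying both diseases when
#' `n_a` and `n_b` records carry each independently in a cohort of `N`:
#' `P(X >= k)` with `X ~ Hypergeometric(N, n_a, n_b)`. The test is one-sided
#' (enrichment only: co-occurrence "more often than by chance"), symmetric in
#' `(n_a, n_b)`, and computed through the survival function of
#' [stats::phyper()] for numerical stability. All arguments recycle.
#'
#' @param N Cohort size.
#' @param n_a,n_b Records carrying each disease.
#' @param k Records carrying both.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' hypergeom_upper_tail(N = 10, n_a = 5, n_b = 4, k = 4)  # 5/210
#' @export
hypergeom_upper_tail <- function(N, n_a, n_b, k) {
  df <- tibble(N = N, n_a = n_a, n_b = n_b, k = k)  # recycle & length-check
  with(df, {
    bad <- is.na(N) | is.na(n_a) | is.na(n_b) | is.na(k) |
      n_a > N | n_b > N | k > pmin(n_a, n_b) | k < 0 | n_a < 0 | n_b < 0
    if (any(bad)) {
      abort(sprintf("Inconsistent counts at position(s) %s: need 0 <= k <= min(n_a, n_b) and n_a, n_b <= N.",
                    paste(which(bad), collapse = ", ")))
    }
    phyper(k - 1, m = n_a, n = N - n_a, k = n_b, lower.tail = FALSE)
  })
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order. One
#' adjustment family corresponds to one network: all tested pairs of one
#' cohort (or one age bracket) are adjusted together.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Full co-occurrence evidence table for a cohort
#'
#' [count_pairs()] plus the hypergeometric p-value and BH q-value for every
#' co-occurring pair; this is the complete tested family from which
#' [build_comorbidity_network()] thresholds its edges, and the
#' machine-readable analogue of a searchable comorbidity table.
#'
#' @param rs A `record_set`.
#' @return Tibble `code_a`, `code_b`, `n_a`, `n_b`, `k`, `N`, `p`, `q`, with
#'   the `prevalence` attribute of [count_pairs()].
#' @export
pair_stats <- function(rs) {
  pairs <- count_pairs(rs)
  pairs$p <- if (nrow(pairs)) {
    hypergeom_upper_tail(pairs$N, pairs$n_a, pairs$n_b, pairs$k)
  } else {
    numeric()
  }
  pairs$q <- bh_adjust(pairs$p)
  pairs
}
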