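# Independent oracles and small fixtures shared across the suite.

# Upper-tail hypergeometric probability by brute-force enumeration of all
# C(N, n_b) equally likely draw sets; the successes are taken to be 1..n_a.
enum_hypergeom_upper <- function(N, n_a, n_b, k) {
  draws <- utils::combn(N, n_b)
  hits <- apply(draws, 2L, function(d) sum(d <= n_a))
  mean(hits >= k)
}

# BH step-up computed literally from the definition.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Dense linear solve of the PageRank system (I - d P^T) x = (1-d)/n e, with
# dangling nodes teleporting uniformly.
dense_pagerank <- function(g, damping = 0.85) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  deg <- rowSums(A)
  P <- matrix(1 / n, n, n)
  ok <- deg > 0
  P[ok, ] <- A[ok, , drop = FALSE] / deg[ok]
  x <- solve(diag(n) - damping * t(P), rep((1 - damping) / n, n))
  x / sum(x)
}

# All set partitions of 1..n (Bell-number enumeration, restricted growth
# strings), as a list of integer membership vectors.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, next_id) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (m in seq_len(next_id)) {
      recurse(c(assign, m), next_id + (m == next_id))
    }
  }
  recurse(integer(0), 1L)
  out
}

# Minimum two-level codelength over every partition of the graph's nodes.
exhaustive_best_codelength <- function(g, damping = 0.85) {
  codes <- igraph::V(g)$name
  flow <- comorbnet::pagerank_flow(g, damping = damping)
  parts <- all_partitions(length(codes))
  vals <- vapply(parts, function(m) {
    comorbnet::map_equation(g, stats::setNames(m, codes), flow)$codelength
  }, numeric(1))
  list(codelength = min(vals),
       partition = stats::setNames(parts[[which.min(vals)]], codes))
}

# Adjusted Rand Index between two labelings (closed form on the
# contingency table).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Tiny long-format cohort used by several record tests.
tiny_cohort_df <- function() {
  data.frame(
    record_id = c("r1", "r1", "r2", "r3", "r3", "r4"),
    age = c(63, 63, 41, 5, 5, 78),
    sex = c("F", "F", "M", "F", "F", "M"),
    icd10 = c("I10.X", "N18.9", "I25.8", "Q24.8", "I10.X", "N18.9"),
    stringsAsFactors = FALSE
  )
}

# Named igraph builders for small, known-topology fixtures.
named_graph <- function(g, prefix = "v") {
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(igraph::vcount(g)))
  g
}

two_cliques_bridge <- function(size = 4L) {
  g <- igraph::disjoint_union(igraph::make_full_graph(size),
                              igraph::make_full_graph(size))
  g <- named_graph(g)
  igraph::add_edges(g, c(1L, size + 1L))
}
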