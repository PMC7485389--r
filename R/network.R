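#' Build a significance-filtered comorbidity network
#'
#' Nodes are ICD-10 codes and an undirected edge links two diseases whose
#' co-occurrence is significant after FDR control: the edge set is all tested
#' pairs with `q < alpha` (strict, per the conventional `FDR < 0.05`
#' criterion) and `k >= min_k`. The graph is simple (no self-loops or
#' multi-edges) and unweighted; the co-occurrence evidence (`k`, `p`, `q`) is
#' kept as edge metadata. By default only edge-incident codes become nodes;
#' `include_isolates = TRUE` also keeps prevalent codes with no significant
#' partner.
#'
#' @param rs A `record_set`.
#' @param alpha FDR threshold in (0, 1); default 0.05.
#' @param min_k Minimum co-occurrence count for an edge (default 1; the
#'   significance test is the only filter).
#' @param include_isolates Keep codes with no significant edge as isolated
#'   nodes? Default `FALSE`.
#' @return A `comorbidity_network` object: list with elements `graph` (an
#'   igraph with node attributes `name`, `prevalence` and edge attributes
#'   `k`, `p`, `q`), `pairs` (the full tested family from [pair_stats()]),
#'   `alpha`, `min_k`, `n_records`.
#' @seealso [topology()], [top_hubs()], [detect_modules()],
#'   [tidy.comorbidity_network()], [glance.comorbidity_network()]
#' @export
build_comorbidity_network <- function(rs, alpha = 0.05, min_k = 1L,
                                      include_isolates = FALSE) {
  stopifnot_scalar_prob(alpha, "alpha")
  pairs <- pair_stats(rs)
  prevalence <- attr(pairs, "prevalence")
  edges <- pairs[pairs$q < alpha & pairs$k >= min_k, , drop = FALSE]

  node_codes <- if (include_isolates) {
    prevalence$code
  } else {
    sort(unique(c(edges$code_a, edges$code_b)))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("code_a", "code_b", "k", "p", "q")],
    directed = FALSE,
    vertices = prevalence[prevalence$code %in% node_codes, , drop = FALSE]
  )
  igraph::V(g)$prevalence <- igraph::V(g)$n

  structure(
    list(graph = g, pairs = pairs, alpha = alpha, min_k = as.integer(min_k),
         n_records = nrow(rs)),
    class = "comorbidity_network"
  )
}

as_igraph <- function(net) {
  if (inherits(net, "comorbidity_network")) net$graph
  else if (inherits(net, "igraph")) net
  else abort("Expected a comorbidity_network or igraph object.")
}

#' @export
print.comorbidity_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf(
    "<comorbidity_network> %d nodes, %d edges (FDR < %g, k >= %d; N = %d records, %d pairs tested)\n",
    igraph::vcount(g), igraph::ecount(g), x$alpha, x$min_k,
    x$n_records, nrow(x$pairs)))
  invisible(x)
}

#' Edge table of a comorbidity network
#'
#' @param x A `comorbidity_network`.
#' @param ... Unused.
#' @return Tibble of retained edges: `code_a`, `code_b`, `n_a`, `n_b`, `k`,
#'   `p`, `q`.
#' @export
tidy.comorbidity_network <- function(x, ...) {
  p <- x$pairs
  out <- p[p$q < x$alpha & p$k >= x$min_k,
           c("code_a", "code_b", "n_a", "n_b", "k", "p", "q"), drop = FALSE]
  as_tibble(out)
}

#' Topology summary of a comorbidity network
#'
#' Graph-level metrics in one row: density `2E / (n(n-1))`, average degree
#' `2E / n`, Freeman degree centralization
#' `sum_i (k_max - k_i) / ((n-1)(n-2))` (0 for a regular graph, 1 for a
#' star), and mean local clustering coefficient (nodes of degree < 2
#' contribute 0). Metrics whose denominators are degenerate (`n < 2` for
#' density, `n < 3` for centralization) are `NA`.
#'
#' @param net A `comorbidity_network` or igraph.
#' @return One-row tibble: `n_nodes`, `n_edges`, `density`, `average_degree`,
#'   `centralization`, `avg_clustering`.
#' @export
topology <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  cc <- if (n > 0) {
    loc <- igraph::transitivity(g, type = "local", isolates = "zero")
    loc[!is.finite(loc)] <- 0
    mean(loc)
  } else {
    NA_real_
  }
  tibble(
    n_nodes = n,
    n_edges = e,
    density = if (n >= 2) 2 * e / (n * (n - 1)) else NA_real_,
    average_degree = if (n >= 1) 2 * e / n else NA_real_,
    centralization = if (n >= 3) sum(max(deg) - deg) / ((n - 1) * (n - 2))
                     else NA_real_,
    avg_clustering = cc
  )
}

#' Topology identities from published counts
#'
#' Recomputes the closed-form topology columns from node/edge counts alone,
#' for checking a reported summary table: density and average degree need
#' only `(n, E)`; Freeman centralization additionally needs the maximum
#' degree. Useful when the underlying cohort is not available but its summary
#' counts are.
#'
#' @param n_nodes,n_edges Integer counts.
#' @param k_max Maximum degree (optional; `NA` centralization without it).
#' @return One-row tibble: `n_nodes`, `n_edges`, `density`, `average_degree`,
#'   `centralization`.
#' @examples
#' topology_from_counts(1473, 20543, k_max = 707)
#' @export
topology_from_counts <- function(n_nodes, n_edges, k_max = NA_real_) {
  n <- as.numeric(n_nodes)
  e <- as.numeric(n_edges)
  tibble(
    n_nodes = n,
    n_edges = e,
    density = ifelse(n >= 2, 2 * e / (n * (n - 1)), NA_real_),
    average_degree = ifelse(n >= 1, 2 * e / n, NA_real_),
    # sum_i (k_max - k_i) = n * k_max - 2E since degrees sum to 2E
    centralization = ifelse(n >= 3 & !is.na(k_max),
                            (n * k_max - 2 * e) / ((n - 1) * (n - 2)),
                            NA_real_)
  )
}

#' @rdname topology
#' @param x A `comorbidity_network`.
#' @param ... Unused.
#' @export
glance.comorbidity_network <- function(x, ...) {
  topology(x)
}

#' Most connected diseases
#'
#' The diseases with the largest number of significant comorbidities (highest
#' degree), e.g. for a "top 20 connected comorbidities" panel. Ties are broken
#' lexicographically by code.
#'
#' @param net A `comorbidity_network` or igraph.
#' @param k How many to return (default 20); truncated to the node count.
#' @return Tibble `code`, `degree`, sorted by descending degree.
#' @export
top_hubs <- function(net, k = 20L) {
  if (k < 1L) abort("`k` must be at least 1.")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  out <- tibble(code = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$code)
  head(out, k)
}

#' Write the network as GraphML
#'
#' Node attributes: code (`name`), `prevalence`, `degree`, and `module` when
#' a partition is supplied; edge attributes `k`, `p`, `q`.
#'
#' @param net A `comorbidity_network`.
#' @param path Output file.
#' @param partition Optional `module_partition` from [detect_modules()].
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, partition = NULL) {
  g <- as_igraph(net)
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(partition)) {
    m <- setNames(partition$module, partition$code)
    igraph::V(g)$module <- as.integer(m[igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the significant-edge table as TSV
#'
#' @param net A `comorbidity_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(net, path) {
  readr::write_tsv(tidy(net), path)
  invisible(path)
}
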