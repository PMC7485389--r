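test_that("edges require q strictly below alpha and k >= min_k", {
  sim <- generate_cohort(sim_config(n_records = 600L), seed = 2L)
  rs <- sim$records
  ps <- pair_stats(rs)
  q_attained <- sort(unique(ps$q))
  q_mid <- q_attained[ceiling(length(q_attained) / 2)]
  net <- build_comorbidity_network(rs, alpha = q_mid)
  edges <- tidy(net)
  # the pair whose q equals alpha exactly is excluded (strict inequality)
  expect_true(all(edges$q < q_mid))
  expect_false(any(ps$q[ps$q == q_mid] %in% edges$q))
  # raising min_k prunes low-count edges only
  net2 <- build_comorbidity_network(rs, alpha = q_mid, min_k = 3L)
  expect_true(all(tidy(net2)$k >= 3L))
  expect_true(nrow(tidy(net2)) <= nrow(edges))
})

test_that("nodes default to edge-incident codes; isolates are opt-in", {
  sim <- generate_cohort(sim_config(n_records = 500L), seed = 3L)
  net <- build_comorbidity_network(sim$records)
  edges <- tidy(net)
  expect_setequal(igraph::V(net$graph)$name,
                  unique(c(edges$code_a, edges$code_b)))
  net_iso <- build_comorbidity_network(sim$records, include_isolates = TRUE)
  prev <- attr(net$pairs, "prevalence")
  expect_equal(igraph::vcount(net_iso$graph), nrow(prev))
})

test_that("topology metrics match closed forms on canonical graphs", {
  tri <- named_graph(igraph::make_full_graph(3))
  t_tri <- topology(tri)
  expect_equal(t_tri$density, 1)
  expect_equal(t_tri$centralization, 0)
  expect_equal(t_tri$avg_clustering, 1)

  star <- named_graph(igraph::make_star(7, mode = "undirected"))
  t_star <- topology(star)
  expect_equal(t_star$centralization, 1)
  expect_equal(t_star$average_degree, 2 * 6 / 7)
  expect_equal(t_star$avg_clustering, 0)  # degree-1 leaves contribute 0

  # degenerate sizes report NA, not errors
  single <- named_graph(igraph::make_empty_graph(1, directed = FALSE))
  t1 <- topology(single)
  expect_true(is.na(t1$density))
  expect_true(is.na(t1$centralization))
})

test_that("published-counts identities reproduce a full summary row", {
  row <- topology_from_counts(1473, 20543, k_max = 707)
  expect_equal(row$density, 0.019, tolerance = 0.0005 / 0.019)
  expect_equal(row$average_degree, 27.893, tolerance = 0.0005 / 27.893)
  expect_equal(row$centralization, 0.462, tolerance = 0.0005 / 0.462)
})

test_that("hub ranking is by degree with lexicographic ties", {
  g <- igraph::graph_from_literal(B - A, B - C, A - C, D - A)
  # A and B tie at degree 3? degrees: A:3, B:2, C:2, D:1
  hubs <- top_hubs(g, k = 4)
  expect_equal(hubs$code[1], "A")
  expect_equal(hubs$code[2:3], c("B", "C"))  # tie broken lexicographically
  expect_equal(nrow(top_hubs(g, k = 10)), 4L)
  star <- named_graph(igraph::make_star(5, mode = "undirected"))
  expect_equal(top_hubs(star, 1)$degree, 4L)
})

test_that("planted within-module pairs are recovered as edges", {
  sim <- generate_cohort(sim_config(), seed = 17L)
  net <- build_comorbidity_network(sim$records)
  edges <- tidy(net)
  truth <- sim$truth$disease_modules
  mod <- stats::setNames(truth$module, truth$code)
  planted <- utils::combn(truth$code, 2)
  same <- mod[planted[1, ]] == mod[planted[2, ]]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  got <- key(edges$code_a, edges$code_b)
  recovery <- mean(key(planted[1, same], planted[2, same]) %in% got)
  expect_gte(recovery, 0.95)
  # each planted hub tops the degree ranking of its own module subgraph
  for (m in unique(truth$module)) {
    members <- intersect(truth$code[truth$module == m],
                         igraph::V(net$graph)$name)
    sub <- igraph::induced_subgraph(net$graph, members)
    expect_equal(top_hubs(sub, 1)$code, truth$code[truth$module == m & truth$hub])
  }
})

test_that("exports write readable GraphML and TSV", {
  sim <- generate_cohort(sim_config(n_records = 500L), seed = 4L)
  net <- build_comorbidity_network(sim$records)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_table(net, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tidy(net)))
  part <- detect_modules(net, seed = 1)
  write_graphml(net, gml, partition = part)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(net$graph))
  expect_true("module" %in% igraph::vertex_attr_names(g2))
})
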