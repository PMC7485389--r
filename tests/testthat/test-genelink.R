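test_that("annotation tables group into uppercase gene sets with a drop tally", {
  df <- data.frame(
    icd10 = c("I25.8", "I25.8", "i25.8", "bogus", "N18.9", "N18.9"),
    gene = c("GENE1", "GENE2", "gene1", "GENE3", "", "ACE")
  )
  ann <- as_gene_annotation_map(df)
  sets <- annotation_sets(ann)
  expect_equal(sets[["I25.8"]], c("GENE1", "GENE2"))  # duplicates collapse
  expect_equal(sets[["N18.9"]], "ACE")
  dropped <- attr(ann, "dropped")
  expect_equal(unname(dropped["invalid_code"]), 1L)
  expect_equal(unname(dropped["blank_gene"]), 1L)
  expect_error(as_gene_annotation_map(data.frame(icd10 = "I10.X")), "gene")

  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  expect_equal(annotation_sets(read_gene_annotations(path)), sets)
})

test_that("jaccard index matches set arithmetic and its boundary identities", {
  expect_equal(jaccard_index(c("A", "B"), c("B", "A")), 1)
  expect_equal(jaccard_index(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard_index(c("A", "B", "C"), c("B", "C", "D")), 2 / 4)
  expect_warning(j0 <- jaccard_index(character(), character()), "undefined")
  expect_equal(j0, 0)
  # a shared-gene count of 437 over a union of 528 reproduces the reported
  # nine-decimal similarity
  a <- c(sprintf("S%03d", 1:437), sprintf("A%02d", 1:60))
  b <- c(sprintf("S%03d", 1:437), sprintf("B%02d", 1:31))
  expect_equal(length(intersect(a, b)), 437L)
  expect_equal(length(union(a, b)), 528L)
  expect_equal(jaccard_index(a, b), 0.827651515, tolerance = 5e-10 / 0.8276)
})

test_that("jaccard responds monotonically to shared and unshared genes", {
  set.seed(31)
  for (i in 1:20) {
    a <- sample(sprintf("G%02d", 1:30), sample(3:12, 1))
    b <- sample(sprintf("G%02d", 1:30), sample(3:12, 1))
    j <- jaccard_index(a, b)
    oracle <- length(intersect(a, b)) / length(union(a, b))
    expect_equal(j, oracle, tolerance = 1e-15)
    expect_gte(jaccard_index(c(a, "NEW1"), c(b, "NEW1")), j)
    expect_lte(jaccard_index(c(a, "ONLYA"), b), j)
    expect_equal(j, jaccard_index(b, a))
    expect_true(j >= 0 && j <= 1)
  }
})

test_that("pair overlaps exclude unannotated endpoints and rank by similarity", {
  ann <- as_gene_annotation_map(data.frame(
    icd10 = c(rep("A01.X", 4), rep("B01.X", 4), rep("C01.X", 2)),
    gene = c(paste0("G", 1:4), paste0("G", c(1:3, 9)), paste0("G", 1:2))
  ))
  edges <- tibble::tibble(code_a = c("A01.X", "A01.X", "B01.X"),
                          code_b = c("B01.X", "C01.X", "D01.X"))
  ov <- gene_overlap(edges, ann)
  expect_equal(nrow(ov), 2L)  # D01.X unannotated -> pair excluded
  expect_equal(ov$jaccard, sort(ov$jaccard, decreasing = TRUE))
  row_ab <- ov[ov$code_a == "A01.X" & ov$code_b == "B01.X", ]
  expect_equal(row_ab$n_shared, 3L)
  expect_equal(row_ab$n_union, 5L)
  expect_equal(row_ab$jaccard, 3 / 5)
  top <- rank_pairs_by_jaccard(edges, ann, top_n = 1)
  expect_equal(nrow(top), 1L)
  expect_equal(top$jaccard, max(ov$jaccard))
})

test_that("hub coverage counts annotated comorbidity partners", {
  g <- igraph::make_star(11, mode = "undirected")
  igraph::V(g)$name <- sprintf("Z%02d.X", 1:11)
  hub <- igraph::V(g)$name[1]
  partners <- igraph::V(g)$name[-1]
  ann <- as_gene_annotation_map(data.frame(icd10 = partners[1:4],
                                           gene = "GENE1"))
  cov <- module_gene_coverage(g, hub, ann)
  expect_equal(cov$n_neighbors, 10L)
  expect_equal(cov$n_annotated, 4L)
  expect_equal(cov$percent, 40)
  expect_error(module_gene_coverage(g, "X99.X", ann), "not a node")
})

test_that("simulated annotation coverage tracks the configured probability", {
  cfg <- sim_config(n_records = 2500L)
  sim <- simulate_comorbidity_study(cfg, seed = 41L)
  net <- build_comorbidity_network(sim$records)
  hub <- sim$truth$hubs[1]
  cov <- module_gene_coverage(net, hub, sim$annotations)
  # direct counting oracle on the generator's own ground truth
  partners <- igraph::V(net$graph)$name[as.integer(
    igraph::neighbors(net$graph, hub))]
  expect_equal(cov$n_annotated, sum(partners %in% sim$truth$annotated))
  # binomial error around the planted 40% annotation rate
  expect_lt(abs(cov$fraction - cfg$annotation_probability), 0.2)
})

test_that("within-module gene similarity exceeds between-module similarity", {
  sim <- simulate_comorbidity_study(sim_config(n_records = 2500L), seed = 13L)
  net <- build_comorbidity_network(sim$records)
  edges <- tidy(net)
  mod <- stats::setNames(sim$truth$disease_modules$module,
                         sim$truth$disease_modules$code)
  ov <- gene_overlap(edges, sim$annotations)
  same <- mod[ov$code_a] == mod[ov$code_b]
  between <- if (any(!same)) mean(ov$jaccard[!same]) else 0
  expect_gt(mean(ov$jaccard[same]), between)
  expect_gt(mean(ov$jaccard[same]), 0.5)
})
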