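empty_comorbidity_network <- function(alpha, min_k, n_records) {
  pairs <- tibble(code_a = character(), code_b = character(),
                  n_a = integer(), n_b = integer(), k = integer(),
                  N = integer(), p = numeric(), q = numeric())
  attr(pairs, "prevalence") <- tibble(code = character(), n = integer())
  structure(
    list(graph = igraph::make_empty_graph(0, directed = FALSE),
         pairs = pairs, alpha = alpha, min_k = as.integer(min_k),
         n_records = n_records),
    class = "comorbidity_network"
  )
}

#' Build the full-cohort and per-age-bracket comorbidity networks
#'
#' One network per age bracket plus an `all_ages` network, each with its own
#' FDR family (every bracket is a standalone analysis with its own tested
#' pairs and its own BH adjustment). Brackets with fewer than two
#' multi-diagnosis records yield an empty network with a warning.
#'
#' @param rs A `record_set`.
#' @param brackets Bracket table as from [default_age_brackets()].
#' @param alpha,min_k,include_isolates As in [build_comorbidity_network()].
#' @return Named list of `comorbidity_network`s: `all_ages` first, then one
#'   per bracket label.
#' @export
age_stratified_networks <- function(rs, brackets = default_age_brackets(),
                                    alpha = 0.05, min_k = 1L,
                                    include_isolates = FALSE) {
  strata <- c(list(all_ages = rs), stratify_by_age(rs, brackets))
  purrr::imap(strata, function(sub, label) {
    n_multi <- sum(lengths(sub$codes) >= 2L)
    if (n_multi < 2L) {
      warn(sprintf("Bracket '%s' has %d multi-diagnosis record(s); emitting an empty network.",
                   label, n_multi))
      return(empty_comorbidity_network(alpha, min_k, nrow(sub)))
    }
    build_comorbidity_network(sub, alpha = alpha, min_k = min_k,
                              include_isolates = include_isolates)
  })
}

#' Run the comorbidity analysis pipeline end to end
#'
#' Records to networks (full cohort and per age bracket, each its own FDR
#' family), topology summaries, top hubs per bracket, map-equation modules of
#' the full-cohort network with PageRank labels, and — when annotations are
#' supplied — per-module shared-gene overlaps and pathway enrichment of the
#' top Jaccard pairs. Deterministic given `seed`. When `out_dir` is given,
#' the standard artifacts (edge tables, GraphML, topology JSON, module /
#' overlap / enrichment TSVs and a markdown report) are written there.
#'
#' @param records A `record_set`.
#' @param annotations Optional `gene_annotation_map`.
#' @param pathways Optional `pathway_collection`.
#' @param alpha FDR threshold for edges and enrichment (default 0.05).
#' @param min_k Minimum co-occurrence count for an edge.
#' @param brackets Age brackets (default [default_age_brackets()]).
#' @param seed,n_restarts Module-detection reproducibility controls.
#' @param n_top_hubs Hubs listed per bracket (default 20).
#' @param n_top_pairs Shared-gene pairs taken forward to enrichment
#'   (default 4).
#' @param out_dir Optional output directory.
#' @return A `comorbidity_analysis` list: `networks`, `topology` (tibble with
#'   a `bracket` column), `hubs`, `partition`, `modules`, `overlap`,
#'   `top_pairs`, `enrichment` (named list of `enrichment_result`s),
#'   `alpha`, `seed`.
#' @export
run_comorbidity_pipeline <- function(records, annotations = NULL,
                                     pathways = NULL,
                                     alpha = 0.05, min_k = 1L,
                                     brackets = default_age_brackets(),
                                     seed = 1L, n_restarts = 10L,
                                     n_top_hubs = 20L, n_top_pairs = 4L,
                                     out_dir = NULL) {
  networks <- age_stratified_networks(records, brackets,
                                      alpha = alpha, min_k = min_k)
  topo <- purrr::imap_dfr(networks, function(net, label) {
    dplyr::bind_cols(tibble(bracket = label), topology(net))
  })
  hubs <- purrr::imap_dfr(networks, function(net, label) {
    if (igraph::vcount(net$graph) == 0L) return(NULL)
    dplyr::bind_cols(tibble(bracket = label), top_hubs(net, n_top_hubs))
  })

  main <- networks$all_ages
  partition <- NULL
  modules <- NULL
  if (igraph::vcount(main$graph) > 0L) {
    partition <- detect_modules(main, seed = seed, n_restarts = n_restarts)
    modules <- attr(partition, "modules")
  }

  overlap <- NULL
  top_pairs <- NULL
  enrichment <- NULL
  if (!is.null(annotations) && !is.null(partition)) {
    edges <- tidy(main)
    assign <- setNames(partition$module, partition$code)
    within <- edges[assign[edges$code_a] == assign[edges$code_b], ]
    within$module <- unname(assign[within$code_a])
    overlap <- gene_overlap(within, annotations)
    if (nrow(overlap) > 0L) {
      mod_of <- setNames(within$module,
                         paste(within$code_a, within$code_b))
      overlap$module <- unname(mod_of[paste(overlap$code_a, overlap$code_b)])
      top_pairs <- head(overlap, n_top_pairs)
      if (!is.null(pathways) && nrow(top_pairs) > 0L) {
        enrichment <- purrr::pmap(
          list(top_pairs$code_a, top_pairs$code_b, top_pairs$shared),
          function(a, b, shared) {
            if (length(intersect(toupper(shared), pathways$universe)) == 0L) {
              return(NULL)
            }
            enrich_pathways(shared, pathways, alpha = alpha)
          })
        names(enrichment) <- paste(top_pairs$code_a, top_pairs$code_b,
                                   sep = "--")
      }
    }
  }

  out <- structure(
    list(networks = networks, topology = topo, hubs = hubs,
         partition = partition, modules = modules,
         overlap = overlap, top_pairs = top_pairs, enrichment = enrichment,
         alpha = alpha, seed = seed),
    class = "comorbidity_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' @export
print.comorbidity_analysis <- function(x, ...) {
  main <- x$networks$all_ages
  cat(sprintf("<comorbidity_analysis> %d bracket networks + all ages (%d nodes, %d edges); %s modules\n",
              length(x$networks) - 1L,
              igraph::vcount(main$graph), igraph::ecount(main$graph),
              if (is.null(x$partition)) "no"
              else length(unique(x$partition$module))))
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Edge table and GraphML per bracket, `topology.json`, `modules.tsv`,
#' `overlap.tsv`, `enrichment_<pair>.tsv` and `report.md`.
#'
#' @param analysis A `comorbidity_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  safe <- function(label) gsub("[^A-Za-z0-9_]+", "_", label)
  purrr::iwalk(analysis$networks, function(net, label) {
    write_edge_table(net, file.path(dir, sprintf("edges_%s.tsv", safe(label))))
    if (igraph::vcount(net$graph) > 0L) {
      part <- if (label == "all_ages") analysis$partition else NULL
      write_graphml(net, file.path(dir, sprintf("network_%s.graphml",
                                                safe(label))), part)
    }
  })
  jsonlite::write_json(analysis$topology,
                       file.path(dir, "topology.json"), digits = NA)
  if (!is.null(analysis$partition)) {
    write_module_table(analysis$partition, file.path(dir, "modules.tsv"))
  }
  if (!is.null(analysis$overlap)) {
    write_overlap_table(analysis$overlap, file.path(dir, "overlap.tsv"))
  }
  purrr::iwalk(analysis$enrichment %||% list(), function(res, pair) {
    if (!is.null(res)) {
      write_enrichment_table(res, file.path(dir, sprintf("enrichment_%s.tsv",
                                                         safe(pair))))
    }
  })
  comorbidity_report(analysis, file.path(dir, "report.md"))
  invisible(dir)
}

#' Render a markdown summary report
#'
#' Topology table for every bracket, top hubs per bracket, module table with
#' PageRank labels, and the top shared-gene pairs with their leading
#' enrichment hits.
#'
#' @param analysis A `comorbidity_analysis`.
#' @param path Output markdown file.
#' @return `path`, invisibly.
#' @export
comorbidity_report <- function(analysis, path) {
  fmt_tbl <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return("(none)")
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    paste(c(header, sep, body), collapse = "\n")
  }
  lines <- c(
    "# Comorbidity network analysis report", "",
    sprintf("FDR threshold: %g; module-detection seed: %s.",
            analysis$alpha, format(analysis$seed)), "",
    "## Network topology by age bracket", "",
    fmt_tbl(analysis$topology), "",
    "## Top connected diseases per bracket", ""
  )
  for (label in unique(analysis$hubs$bracket)) {
    lines <- c(lines, sprintf("### %s", label), "",
               fmt_tbl(analysis$hubs[analysis$hubs$bracket == label,
                                     c("code", "degree")]), "")
  }
  lines <- c(lines, "## Modules (map equation, PageRank labels)", "",
             fmt_tbl(analysis$modules), "")
  if (!is.null(analysis$top_pairs) && nrow(analysis$top_pairs) > 0L) {
    tp <- as_tibble(analysis$top_pairs)
    tp$shared <- NULL
    lines <- c(lines, "## Top shared-gene comorbidity pairs", "",
               fmt_tbl(tp), "")
    for (pair in names(analysis$enrichment %||% list())) {
      res <- analysis$enrichment[[pair]]
      if (is.null(res)) next
      lines <- c(lines, sprintf("### Enrichment: %s", pair), "",
                 fmt_tbl(head(as_tibble(res), 5L)), "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
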