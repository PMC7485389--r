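#' Read a disease-gene annotation table
#'
#' A TSV with columns `icd10`, `gene`, one association per row — the format
#' of a curated ClinVar-style extract mapping disease codes to the gene
#' symbols of their reported variants. Rows are grouped into per-disease gene
#' sets; gene symbols are uppercased, duplicates collapse, rows with
#' syntactically invalid codes or blank genes are dropped and tallied.
#'
#' @param path TSV file path.
#' @return A `gene_annotation_map`: tibble `icd10`, `genes` (list column of
#'   sorted unique symbols) with attribute `dropped` (named tally of
#'   discarded rows). Use [annotation_sets()] for a plain named list.
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  as_gene_annotation_map(df)
}

#' @rdname read_gene_annotations
#' @param x Data frame with columns `icd10`, `gene`.
#' @export
as_gene_annotation_map <- function(x) {
  missing_cols <- setdiff(c("icd10", "gene"), names(x))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Annotation table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  x$code <- icd10_clean(x$icd10)
  x$gene <- toupper(trimws(as.character(x$gene)))
  bad_code <- is.na(x$code)
  bad_gene <- !bad_code & (is.na(x$gene) | x$gene == "")
  keep <- !bad_code & !bad_gene
  out <- x[keep, ] |>
    dplyr::distinct(.data$code, .data$gene) |>
    dplyr::group_by(icd10 = .data$code) |>
    dplyr::summarise(genes = list(sort(.data$gene)), .groups = "drop")
  structure(out,
            dropped = c(invalid_code = sum(bad_code), blank_gene = sum(bad_gene)),
            class = c("gene_annotation_map", class(tibble())))
}

#' @rdname read_gene_annotations
#' @param ann A `gene_annotation_map`.
#' @export
annotation_sets <- function(ann) {
  setNames(ann$genes, ann$icd10)
}

#' Jaccard similarity of two gene sets
#'
#' `|A intersect B| / |A union B|`: 1 for identical non-empty sets, 0 for
#' disjoint sets. Two empty sets have no defined overlap; the value is
#' reported as 0 with a warning.
#'
#' @param a,b Character vectors (treated as sets).
#' @return A single number in `[0, 1]`.
#' @examples
#' jaccard_index(c("ACE", "NOS3"), c("ACE", "MTHFR"))
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  n_union <- length(union(a, b))
  if (n_union == 0L) {
    warn("Jaccard index of two empty sets is undefined; returning 0.")
    return(0)
  }
  length(intersect(a, b)) / n_union
}

#' Shared genes and Jaccard index for comorbid disease pairs
#'
#' For every significant comorbidity edge whose two endpoints both carry a
#' gene annotation, the shared gene set, its size, the union size and the
#' Jaccard index. Pairs with an unannotated endpoint are excluded (their
#' genetic overlap is unobserved, not zero).
#'
#' @param edges A `comorbidity_network`, or an edge tibble with columns
#'   `code_a`, `code_b` (e.g. [tidy.comorbidity_network()] filtered to one
#'   module).
#' @param ann A `gene_annotation_map`.
#' @return A `gene_overlap` tibble: `code_a`, `code_b`, `n_a_genes`,
#'   `n_b_genes`, `n_shared`, `n_union`, `jaccard`, `shared` (list column),
#'   sorted by descending `jaccard` (ties: `n_shared` desc, then codes).
#' @export
gene_overlap <- function(edges, ann) {
  if (inherits(edges, "comorbidity_network")) edges <- tidy(edges)
  if (!all(c("code_a", "code_b") %in% names(edges))) {
    abort("`edges` needs columns code_a and code_b.")
  }
  sets <- annotation_sets(ann)
  keep <- edges$code_a %in% names(sets) & edges$code_b %in% names(sets)
  e <- edges[keep, c("code_a", "code_b")]
  if (nrow(e) == 0L) {
    return(structure(tibble(code_a = character(), code_b = character(),
                            n_a_genes = integer(), n_b_genes = integer(),
                            n_shared = integer(), n_union = integer(),
                            jaccard = numeric(), shared = list()),
                     class = c("gene_overlap", class(tibble()))))
  }
  rows <- purrr::map2(e$code_a, e$code_b, function(a, b) {
    ga <- sets[[a]]; gb <- sets[[b]]
    shared <- intersect(ga, gb)
    tibble(code_a = a, code_b = b,
           n_a_genes = length(ga), n_b_genes = length(gb),
           n_shared = length(shared),
           n_union = length(union(ga, gb)),
           jaccard = jaccard_index(ga, gb),
           shared = list(sort(shared)))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$jaccard), dplyr::desc(.data$n_shared),
                   .data$code_a, .data$code_b)
  structure(out, class = c("gene_overlap", class(tibble())))
}

#' Top comorbidity pairs by genetic similarity
#'
#' @param edges,ann As in [gene_overlap()].
#' @param top_n How many pairs to keep (default all).
#' @return The first `top_n` rows of [gene_overlap()].
#' @export
rank_pairs_by_jaccard <- function(edges, ann, top_n = Inf) {
  out <- gene_overlap(edges, ann)
  head(out, min(top_n, nrow(out)))
}

#' Annotation coverage of a hub's comorbidities
#'
#' How many of a hub disease's significant comorbidity partners carry a gene
#' annotation — e.g. "307 of the 714 comorbidities in this module (43%) have
#' associated genes".
#'
#' @param net A `comorbidity_network` or igraph.
#' @param hub ICD-10 code of the hub disease.
#' @param ann A `gene_annotation_map`.
#' @return One-row tibble: `hub`, `n_neighbors`, `n_annotated`, `fraction`
#'   (in \[0, 1\]), `percent` (rounded to whole percent).
#' @export
module_gene_coverage <- function(net, hub, ann) {
  g <- as_igraph(net)
  if (!hub %in% igraph::V(g)$name) {
    abort(sprintf("Hub code %s is not a node of the network.", hub))
  }
  partners <- igraph::V(g)$name[as.integer(
    igraph::neighbors(g, hub, mode = "all"))]
  annotated <- sum(partners %in% ann$icd10[lengths(ann$genes) > 0])
  frac <- if (length(partners) > 0) annotated / length(partners) else NA_real_
  tibble(hub = hub,
         n_neighbors = length(partners),
         n_annotated = annotated,
         fraction = frac,
         percent = round(100 * frac))
}

#' Write a gene-overlap table as TSV
#'
#' The `shared` list column is serialised as a semicolon-joined string.
#'
#' @param overlap A `gene_overlap` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_overlap_table <- function(overlap, path) {
  out <- as_tibble(overlap)
  out$shared_genes <- purrr::map_chr(out$shared, paste, collapse = ";")
  out$shared <- NULL
  readr::write_tsv(out, path)
  invisible(path)
}
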