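#' Read a GMT pathway collection
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines with fewer than three
#' fields and duplicated pathway names are fatal (with the offending line
#' number / name). The gene universe defaults to the union of all pathway
#' genes and can be overridden, e.g. with the full annotated-gene universe.
#'
#' @param path GMT file path.
#' @param universe Optional character vector overriding the universe;
#'   pathways are intersected with it.
#' @return A `pathway_collection`: list with `pathways` (named list of gene
#'   sets), `universe` (character vector), `descriptions` (named character).
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("GMT file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    abort(sprintf("Malformed GMT line %d: fewer than 3 tab-separated fields.",
                  short[1]))
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  dup <- names_[duplicated(names_)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate pathway name in GMT: %s.", dup[1]))
  }
  descriptions <- setNames(vapply(fields, `[[`, character(1), 2L), names_)
  pathways <- setNames(
    lapply(fields, function(f) sort(unique(toupper(f[-(1:2)])))), names_)
  pathway_collection(pathways, universe = universe,
                     descriptions = descriptions)
}

#' @rdname read_gmt
#' @param pathways Named list of character gene sets.
#' @param descriptions Optional named character vector.
#' @export
pathway_collection <- function(pathways, universe = NULL,
                               descriptions = NULL) {
  if (is.null(names(pathways)) || anyDuplicated(names(pathways))) {
    abort("Pathways must have unique names.")
  }
  pathways <- lapply(pathways, function(g) sort(unique(toupper(g))))
  universe <- if (is.null(universe)) {
    sort(unique(unlist(pathways, use.names = FALSE)))
  } else {
    sort(unique(toupper(universe)))
  }
  pathways <- lapply(pathways, intersect, y = universe)
  structure(list(pathways = pathways, universe = universe,
                 descriptions = descriptions),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways over a universe of %d genes\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Pathway over-representation analysis of a gene list
#'
#' For each pathway, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap `k` between the gene list (size `n`, after
#' restriction to the universe of size `U`) and the pathway (size `K`),
#' BH-adjusted across all pathways of the collection; a pathway is flagged
#' significant when `q < alpha`. This is the in-package equivalent of a
#' web-based enrichment run on the shared-gene list of a comorbidity pair.
#'
#' @param genes Character vector of gene symbols (a shared-gene list).
#' @param coll A `pathway_collection`.
#' @param alpha Significance threshold on `q` (default 0.05).
#' @return An `enrichment_result` tibble sorted by `q` then `p`:
#'   `pathway`, `k`, `n`, `K`, `U`, `p`, `q`, `significant`, with attribute
#'   `n_outside_universe` (genes dropped before testing).
#' @export
enrich_pathways <- function(genes, coll, alpha = 0.05) {
  if (!inherits(coll, "pathway_collection")) {
    abort("`coll` must be a pathway_collection.")
  }
  stopifnot_scalar_prob(alpha, "alpha")
  genes <- unique(toupper(genes))
  eff <- intersect(genes, coll$universe)
  n_dropped <- length(genes) - length(eff)
  if (n_dropped > 0L) {
    inform(sprintf("%d gene(s) outside the universe dropped before testing.",
                   n_dropped))
  }
  if (length(eff) == 0L) {
    abort("No genes of the list are in the universe; nothing to test.")
  }
  U <- length(coll$universe)
  n <- length(eff)
  k <- vapply(coll$pathways, function(p) length(intersect(p, eff)), integer(1))
  K <- lengths(coll$pathways)
  p <- hypergeom_upper_tail(N = U, n_a = K, n_b = n, k = k)
  q <- bh_adjust(p)
  out <- tibble(pathway = names(coll$pathways),
                k = unname(k), n = n, K = unname(K), U = U,
                p = unname(p), q = unname(q),
                significant = unname(q) < alpha) |>
    dplyr::arrange(.data$q, .data$p, .data$pathway)
  structure(out, n_outside_universe = n_dropped,
            class = c("enrichment_result", class(tibble())))
}

#' Write an enrichment table as TSV
#'
#' @param res An `enrichment_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(res, path) {
  readr::write_tsv(as_tibble(res), path)
  invisible(path)
}
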