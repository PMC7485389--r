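#' PageRank visit rates on the comorbidity network
#'
#' Stationary distribution of a damped random walk on the undirected graph:
#' with probability `damping` the walker follows a uniformly chosen edge, and
#' with probability `1 - damping` (plus the full mass of isolated nodes) it
#' teleports uniformly. Computed by power iteration until the L1 change drops
#' below `tol`, so the result is deterministic for a given graph. These visit
#' rates are the flow distribution that both the map equation and the
#' module-labelling rule ("the disease the walk visits most") consume.
#'
#' @param net A `comorbidity_network` or igraph.
#' @param damping Damping factor in (0, 1]; default 0.85.
#' @param tol L1 convergence tolerance; default 1e-12.
#' @param max_iter Iteration cap (default 100000).
#' @return A `flow_distribution`: tibble `code`, `visit_rate` (summing to 1)
#'   with attributes `damping` and `tol`.
#' @export
pagerank_flow <- function(net, damping = 0.85, tol = 1e-12,
                          max_iter = 100000L) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) abort("Cannot compute visit rates on an empty graph.")
  if (!is.numeric(damping) || damping <= 0 || damping > 1) {
    abort("`damping` must lie in (0, 1].")
  }
  adj <- igraph::as_adj_list(g, mode = "all")
  deg <- lengths(adj)
  nbr <- lapply(adj, as.integer)

  x <- rep(1 / n, n)
  dangling <- deg == 0L
  for (iter in seq_len(max_iter)) {
    spread <- ifelse(deg > 0L, x / pmax(deg, 1L), 0)
    x_new <- rep((1 - damping) / n, n) +
      damping * sum(x[dangling]) / n
    inflow <- numeric(n)
    for (i in seq_len(n)) {
      if (deg[i] > 0L) {
        s <- spread[i]
        inflow[nbr[[i]]] <- inflow[nbr[[i]]] + s
      }
    }
    x_new <- x_new + damping * inflow
    if (sum(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x <- x / sum(x)
  structure(
    tibble(code = igraph::V(g)$name %||% as.character(seq_len(n)),
           visit_rate = x),
    damping = damping, tol = tol,
    class = c("flow_distribution", class(tibble()))
  )
}

as_flow_vector <- function(flow) {
  if (is.data.frame(flow)) setNames(flow$visit_rate, flow$code)
  else if (is.numeric(flow) && !is.null(names(flow))) flow
  else abort("`flow` must be a flow_distribution or a named numeric vector.")
}

as_membership_vector <- function(partition, codes) {
  m <- if (is.data.frame(partition)) {
    setNames(partition$module, partition$code)
  } else if (!is.null(names(partition))) {
    partition
  } else {
    abort("`partition` must be a module_partition tibble or a named vector.")
  }
  if (!setequal(names(m), codes)) {
    abort("Partition must cover exactly the network's nodes.")
  }
  m[codes]
}

#' Two-level map-equation codelength of a partition
#'
#' Description length, in bits, of a random walk on the network encoded with
#' a two-level codebook: an index codebook for entering modules and one
#' codebook per module for within-module steps and exits,
#' `L(M) = q * H(Q) + sum_m p_m * H(P_m)`. Module exit/entry flow is the walk
#' flow crossing module boundaries along edges; teleportation steps are not
#' encoded ("unrecorded teleportation"), so a partition into disconnected
#' components has a zero index term even with damping < 1. A one-module
#' partition has codelength equal to the Shannon entropy of the visit rates.
#'
#' @param net A `comorbidity_network` or igraph.
#' @param partition A `module_partition`, a tibble with columns
#'   `code`, `module`, or a named membership vector.
#' @param flow Visit rates from [pagerank_flow()] on the same network;
#'   computed if omitted.
#' @return A `map_equation_score`: list with `codelength`, `index_term`,
#'   `module_terms` (named numeric; `codelength = index_term +
#'   sum(module_terms)` exactly).
#' @export
map_equation <- function(net, partition, flow = NULL) {
  g <- as_igraph(net)
  codes <- igraph::V(g)$name
  flow <- flow %||% pagerank_flow(net)
  damping <- attr(flow, "damping") %||% 0.85
  p <- as_flow_vector(flow)[codes]
  m <- as_membership_vector(partition, codes)
  mod_ids <- sort(unique(m))

  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  exit <- setNames(numeric(length(mod_ids)), mod_ids)
  if (nrow(el) > 0) {
    ma <- as.character(m[el[, 1]])
    mb <- as.character(m[el[, 2]])
    cross <- ma != mb
    if (any(cross)) {
      fa <- damping * p[el[cross, 1]] / deg[el[cross, 1]]
      fb <- damping * p[el[cross, 2]] / deg[el[cross, 2]]
      exit_a <- tapply(fa, ma[cross], sum)
      exit_b <- tapply(fb, mb[cross], sum)
      exit[names(exit_a)] <- exit[names(exit_a)] + exit_a
      exit[names(exit_b)] <- exit[names(exit_b)] + exit_b
    }
  }

  p_mod <- tapply(p, factor(m, levels = mod_ids), sum)
  q_tot <- sum(exit)
  index_term <- plogp(q_tot) - sum(plogp(exit))
  module_terms <- vapply(seq_along(mod_ids), function(i) {
    members <- p[m == mod_ids[i]]
    plogp(exit[i] + p_mod[i]) - plogp(exit[i]) - sum(plogp(members))
  }, numeric(1))
  names(module_terms) <- mod_ids

  structure(
    list(codelength = index_term + sum(module_terms),
         index_term = index_term,
         module_terms = module_terms,
         exit_flow = exit,
         module_flow = setNames(as.numeric(p_mod), mod_ids)),
    class = "map_equation_score"
  )
}

#' @export
print.map_equation_score <- function(x, ...) {
  cat(sprintf("<map_equation_score> L = %.6f bits (index %.6f + %d module terms)\n",
              x$codelength, x$index_term, length(x$module_terms)))
  invisible(x)
}

# ---- greedy map-equation minimisation ---------------------------------------

# Codelength from module aggregates, dropping the constant -sum(plogp(p_i)).
reduced_codelength <- function(Q, P) {
  plogp(sum(Q)) - 2 * sum(plogp(Q)) + sum(plogp(Q + P))
}

#' Detect flow modules by greedy map-equation minimisation
#'
#' Infomap-style community detection: every node starts in its own module and
#' single-node moves that decrease the two-level codelength are applied
#' greedily (each node may join a neighbouring module, or split off on its
#' own) until no move helps; the sweep order is reshuffled on each of
#' `n_restarts` restarts and the lowest-codelength partition wins.
#' Deterministic given `(seed, n_restarts)`; the result never has a higher
#' codelength than the one-module partition. Modules are numbered by
#' decreasing total flow and labelled with the member disease of highest
#' PageRank visit rate (ties broken lexicographically).
#'
#' @param net A `comorbidity_network` or igraph.
#' @param seed Integer RNG seed for the restart shuffles.
#' @param n_restarts Number of restarts (default 10).
#' @param damping,tol Passed to [pagerank_flow()].
#' @param name_table Optional data frame `code`, `name` for human-readable
#'   module labels.
#' @return A `module_partition`: tibble `code`, `module`, `visit_rate` with
#'   attributes `codelength`, `index_term`, `modules` (per-module tibble:
#'   `module`, `n_nodes`, `flow`, `exit_flow`, `label`, and `label_name` when
#'   `name_table` is given), `seed`, `n_restarts`.
#' @export
detect_modules <- function(net, seed = 1L, n_restarts = 10L,
                           damping = 0.85, tol = 1e-12, name_table = NULL) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) abort("Cannot partition an empty graph.")
  codes <- igraph::V(g)$name %||% as.character(seq_len(n))
  flow <- pagerank_flow(g, damping = damping, tol = tol)
  p <- as_flow_vector(flow)[codes]

  adj <- igraph::as_adj_list(g, mode = "all")
  nbr <- lapply(adj, as.integer)
  deg <- lengths(nbr)
  # walk flow node -> each neighbour; out[i] = total edge out-flow of i
  w_out <- ifelse(deg > 0L, damping * p / pmax(deg, 1L), 0)
  out_tot <- ifelse(deg > 0L, damping * p, 0)

  el_idx <- igraph::as_edgelist(g, names = FALSE)
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(max(1L, n_restarts))) {
      order_r <- sample.int(n)
      res <- greedy_sweeps(n, nbr, deg, p, w_out, out_tot, order_r, el_idx)
      if (is.null(best) || res$L < best$L - 1e-12) best <- res
    }
  })

  membership <- best$membership
  # renumber modules by decreasing flow, ties by smallest member code
  mod_flow <- tapply(p, membership, sum)
  first_code <- tapply(codes, membership, min)
  ord <- order(-mod_flow, first_code)
  renum <- setNames(seq_along(ord), names(mod_flow)[ord])
  membership <- unname(renum[as.character(membership)])

  part <- structure(
    tibble(code = codes, module = membership, visit_rate = unname(p)),
    seed = seed, n_restarts = n_restarts,
    class = c("module_partition", class(tibble()))
  )
  score <- map_equation(g, part, flow = flow)
  attr(part, "codelength") <- score$codelength
  attr(part, "index_term") <- score$index_term
  modules <- module_summary(part, p)
  modules$exit_flow <- unname(score$exit_flow[as.character(modules$module)])
  if (!is.null(name_table)) {
    nm <- setNames(as.character(name_table$name), name_table$code)
    modules$label_name <- unname(nm[modules$label])
  }
  attr(part, "modules") <- modules
  part
}

module_summary <- function(part, p) {
  ids <- sort(unique(part$module))
  purrr::map_dfr(ids, function(id) {
    members <- part$code[part$module == id]
    rates <- p[members]
    lab <- members[rates == max(rates)]
    tibble(module = id,
           n_nodes = length(members),
           flow = sum(rates),
           label = sort(lab)[1])
  })
}

greedy_sweeps <- function(n, nbr, deg, p, w_out, out_tot, order_r, el_idx) {
  membership <- seq_len(n)
  Q <- numeric(n); P <- p  # per-module exit flow and node flow
  # initial singleton exits: all edge out-flow leaves the module
  Q[] <- out_tot
  free_ids <- integer(0)

  # single best-improving merge of two connected modules, or FALSE;
  # single-node moves alone cannot fuse two multi-node modules, so the
  # search alternates node sweeps with module merges
  try_merge <- function() {
    if (nrow(el_idx) == 0L) return(FALSE)
    ma <- membership[el_idx[, 1]]
    mb <- membership[el_idx[, 2]]
    cross <- ma != mb
    if (!any(cross)) return(FALSE)
    i <- el_idx[cross, 1]; j <- el_idx[cross, 2]
    a <- pmin(ma[cross], mb[cross]); b <- pmax(ma[cross], mb[cross])
    keyf <- factor(paste(a, b))
    # walk flow crossing each module pair, in both directions
    fl <- tapply(w_out[i] + w_out[j], keyf, sum)
    pair_a <- as.integer(sub(" .*", "", names(fl)))
    pair_b <- as.integer(sub(".* ", "", names(fl)))
    q_tot <- sum(Q)
    best_delta <- 0; best_idx <- 0L; best_QC <- NA_real_
    for (idx in seq_along(fl)) {
      A <- pair_a[idx]; B <- pair_b[idx]
      QC <- Q[A] + Q[B] - fl[[idx]]
      PC <- P[A] + P[B]
      delta <- (-2 * plogp(QC) + plogp(QC + PC) +
                  plogp(q_tot - Q[A] - Q[B] + QC)) -
        (-2 * plogp(Q[A]) + plogp(Q[A] + P[A]) -
           2 * plogp(Q[B]) + plogp(Q[B] + P[B]) + plogp(q_tot))
      if (delta < best_delta - 1e-12) {
        best_delta <- delta; best_idx <- idx; best_QC <- QC
      }
    }
    if (best_idx == 0L) return(FALSE)
    A <- pair_a[best_idx]; B <- pair_b[best_idx]
    membership[membership == B] <<- A
    Q[A] <<- best_QC; P[A] <<- P[A] + P[B]
    Q[B] <<- 0; P[B] <<- 0
    free_ids <<- c(free_ids, B)
    TRUE
  }

  repeat {
    moved <- FALSE
    for (v in order_r) {
      cur <- membership[v]
      nbrs <- nbr[[v]]
      if (length(nbrs) == 0L) next
      nbr_mods <- membership[nbrs]
      # flow v -> each candidate module, and candidate module -> v
      f_to <- tapply(rep(w_out[v], length(nbrs)), nbr_mods, sum)
      f_from <- tapply(w_out[nbrs], nbr_mods, sum)
      cand <- unique(nbr_mods)
      cand <- cand[cand != cur]
      a_out <- if (as.character(cur) %in% names(f_to)) f_to[[as.character(cur)]] else 0
      a_in <- if (as.character(cur) %in% names(f_from)) f_from[[as.character(cur)]] else 0

      QA_new <- Q[cur] - (out_tot[v] - a_out) + a_in
      PA_new <- P[cur] - p[v]
      base_old <- -2 * plogp(Q[cur]) + plogp(Q[cur] + P[cur])
      base_A_new <- -2 * plogp(QA_new) + plogp(QA_new + PA_new)

      best_delta <- 0
      best_target <- cur
      best_QB <- NA_real_
      consider <- cand
      alone <- P[cur] > p[v] + 1e-300  # currently sharing a module?
      for (tgt in consider) {
        b_out <- f_to[[as.character(tgt)]]
        b_in <- f_from[[as.character(tgt)]]
        QB_new <- Q[tgt] + (out_tot[v] - b_out) - b_in
        PB_new <- P[tgt] + p[v]
        old_terms <- base_old - 2 * plogp(Q[tgt]) + plogp(Q[tgt] + P[tgt])
        new_terms <- base_A_new - 2 * plogp(QB_new) + plogp(QB_new + PB_new)
        q_tot_old <- sum(Q)
        q_tot_new <- q_tot_old - Q[cur] - Q[tgt] + QA_new + QB_new
        delta <- (new_terms + plogp(q_tot_new)) - (old_terms + plogp(q_tot_old))
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_target <- tgt
          best_QB <- QB_new
        }
      }
      if (alone) {
        # moving v to a fresh singleton module
        QB_new <- out_tot[v]
        PB_new <- p[v]
        new_terms <- base_A_new - 2 * plogp(QB_new) + plogp(QB_new + PB_new)
        q_tot_old <- sum(Q)
        q_tot_new <- q_tot_old - Q[cur] + QA_new + QB_new
        delta <- (new_terms + plogp(q_tot_new)) - (base_old + plogp(q_tot_old))
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          # a shared module implies some id was emptied earlier, so a free
          # id always exists here
          best_target <- free_ids[1]
          best_QB <- QB_new
        }
      }
      if (best_target != cur) {
        if (best_target %in% free_ids) free_ids <- setdiff(free_ids, best_target)
        Q[cur] <- QA_new; P[cur] <- PA_new
        Q[best_target] <- best_QB
        P[best_target] <- P[best_target] + p[v]
        membership[v] <- best_target
        if (PA_new <= 1e-300) {
          Q[cur] <- 0; P[cur] <- 0
          free_ids <- c(free_ids, cur)
        }
        moved <- TRUE
      }
    }
    if (!moved && !try_merge()) break
  }
  active <- P > 0
  list(membership = membership,
       L = reduced_codelength(Q[active], P[active]))
}

#' Label modules by their highest-flow disease
#'
#' Each module is labelled with the ICD-10 code of its member with the
#' highest PageRank visit rate (exact ties go to the lexicographically
#' smallest code); optionally joined to human-readable disease names.
#'
#' @param partition A `module_partition` (or tibble `code`, `module`).
#' @param flow Visit rates from [pagerank_flow()]; taken from the partition's
#'   `visit_rate` column if omitted.
#' @param name_table Optional data frame `code`, `name`.
#' @return Tibble `module`, `n_nodes`, `flow`, `label` (+ `label_name`).
#' @export
label_modules <- function(partition, flow = NULL, name_table = NULL) {
  p <- if (!is.null(flow)) {
    as_flow_vector(flow)[partition$code]
  } else if ("visit_rate" %in% names(partition)) {
    setNames(partition$visit_rate, partition$code)
  } else {
    abort("Supply `flow` or a partition with a visit_rate column.")
  }
  modules <- module_summary(partition, p)
  if (!is.null(name_table)) {
    nm <- setNames(as.character(name_table$name), name_table$code)
    modules$label_name <- unname(nm[modules$label])
  }
  modules
}

#' @export
print.module_partition <- function(x, ...) {
  mods <- attr(x, "modules")
  cat(sprintf("<module_partition> %d nodes in %d modules, L = %.4f bits (seed %s)\n",
              nrow(x), length(unique(x$module)),
              attr(x, "codelength"), format(attr(x, "seed"))))
  if (!is.null(mods)) print(as_tibble(mods))
  invisible(x)
}

#' @export
#' @rdname detect_modules
#' @param x A `module_partition`.
#' @param ... Unused.
tidy.module_partition <- function(x, ...) {
  mods <- attr(x, "modules")
  lab <- setNames(mods$label, mods$module)
  out <- as_tibble(x)
  out$module_label <- unname(lab[as.character(out$module)])
  out[, c("code", "module", "module_label", "visit_rate")]
}

#' @export
#' @rdname detect_modules
glance.module_partition <- function(x, ...) {
  tibble(n_nodes = nrow(x),
         n_modules = length(unique(x$module)),
         codelength = attr(x, "codelength"),
         index_term = attr(x, "index_term"),
         seed = attr(x, "seed") %||% NA_integer_)
}

#' Write the module assignment table as TSV
#'
#' @param partition A `module_partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_module_table <- function(partition, path) {
  readr::write_tsv(tidy(partition), path)
  invisible(path)
}
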