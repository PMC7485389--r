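#' Configuration for the synthetic comorbidity study generator
#'
#' Describes a cohort of discharge records with planted comorbidity
#' structure: each record has a latent disease module (a physiopathological
#' cluster such as congenital, ischemic or renal disease), draws most of its
#' ICD-10 codes from that module's diseases — hub diseases oversampled — and
#' an age from the module's age profile (the congenital-style module
#' concentrates in the 0-10 bracket, the chronic modules in later life).
#' Disease-gene annotations mirror the same modules: each module owns a gene
#' pool and annotated diseases sample most of it, so within-module comorbid
#' pairs share many genes (high Jaccard index) while between-module pairs
#' share almost none; pathway sets mirror the module pools.
#'
#' The within-module preference is an odds boost: a code is drawn from the
#' record's latent module with probability
#' `boost * s / (boost * s + (D - s))` (module size `s`, `D` diseases), so
#' `within_boost = 1` is the structureless null in which all diseases are
#' exchangeable and the significance-filtered network should be empty.
#'
#' @param n_records Number of discharge records (default 5000).
#' @param n_diseases Number of distinct ICD-10 codes (default 60, split
#'   evenly across modules).
#' @param n_modules Number of planted modules (default 3).
#' @param within_boost Odds multiplier >= 1 for drawing a code from the
#'   record's latent module (default 25).
#' @param max_codes_per_record Maximum diagnoses per record (default 6: a
#'   principal diagnosis plus up to five comorbidities).
#' @param codes_weights Sampling weights for the number of diagnoses
#'   `1:max_codes_per_record`.
#' @param hub_per_module Plant one oversampled hub disease per module?
#' @param hub_weight Sampling weight of the hub relative to other module
#'   members (default 3).
#' @param age_profiles Optional `n_modules x 10` matrix of age-bracket
#'   weights (rows = modules, columns = the [default_age_brackets()]).
#' @param annotation_probability Fraction of diseases that carry a gene
#'   annotation (default 0.4, matching the roughly 40% coverage of curated
#'   clinical-variant extracts).
#' @param genes_per_module_pool Size of each module's gene pool (default 150).
#' @param gene_sample_rate Probability that an annotated disease carries each
#'   gene of its module pool (default 0.8).
#' @param noise_genes Size of the shared background gene pool (default 300).
#' @param noise_gene_rate Per-gene probability of background genes (default
#'   0.02).
#' @param pathway_alignment Emit one pathway per module mirroring its gene
#'   pool? (default TRUE).
#' @param n_distractor_pathways Random gene-set pathways added to the
#'   collection (default 12).
#' @param distractor_size Genes per distractor pathway (default 150).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_records = 5000L,
                       n_diseases = 60L,
                       n_modules = 3L,
                       within_boost = 25,
                       max_codes_per_record = 6L,
                       codes_weights = c(0.05, 0.10, 0.20, 0.25, 0.25, 0.15),
                       hub_per_module = TRUE,
                       hub_weight = 3,
                       age_profiles = NULL,
                       annotation_probability = 0.4,
                       genes_per_module_pool = 150L,
                       gene_sample_rate = 0.8,
                       noise_genes = 300L,
                       noise_gene_rate = 0.02,
                       pathway_alignment = TRUE,
                       n_distractor_pathways = 12L,
                       distractor_size = 150L) {
  if (n_modules > n_diseases) abort("Need n_modules <= n_diseases.")
  if (max_codes_per_record > n_diseases) {
    abort("Need max_codes_per_record <= n_diseases.")
  }
  if (within_boost < 1) abort("`within_boost` must be >= 1.")
  if (length(codes_weights) != max_codes_per_record) {
    abort("`codes_weights` must have one weight per possible code count.")
  }
  for (pr in c(annotation_probability, gene_sample_rate, noise_gene_rate)) {
    if (pr < 0 || pr > 1) abort("Probabilities must lie in [0, 1].")
  }
  if (is.null(age_profiles)) {
    age_profiles <- default_age_profiles(n_modules)
  }
  if (!is.matrix(age_profiles) || nrow(age_profiles) != n_modules ||
      ncol(age_profiles) != nrow(default_age_brackets())) {
    abort("`age_profiles` must be an n_modules x 10 weight matrix.")
  }
  structure(list(
    n_records = as.integer(n_records),
    n_diseases = as.integer(n_diseases),
    n_modules = as.integer(n_modules),
    within_boost = within_boost,
    max_codes_per_record = as.integer(max_codes_per_record),
    codes_weights = codes_weights / sum(codes_weights),
    hub_per_module = isTRUE(hub_per_module),
    hub_weight = hub_weight,
    age_profiles = age_profiles,
    annotation_probability = annotation_probability,
    genes_per_module_pool = as.integer(genes_per_module_pool),
    gene_sample_rate = gene_sample_rate,
    noise_genes = as.integer(noise_genes),
    noise_gene_rate = noise_gene_rate,
    pathway_alignment = isTRUE(pathway_alignment),
    n_distractor_pathways = as.integer(n_distractor_pathways),
    distractor_size = as.integer(distractor_size)
  ), class = "sim_config")
}

# Module 1: congenital-like, concentrated in 0-10; later modules shift to
# mid-life and old age. Extra modules recycle the chronic profile.
default_age_profiles <- function(n_modules) {
  base <- rbind(
    c(60, 15, 8, 5, 4, 3, 2, 1, 1, 1),
    c(1, 3, 6, 12, 20, 25, 18, 9, 4, 2),
    c(1, 1, 2, 4, 8, 14, 22, 24, 16, 8)
  )
  m <- base[rep_len(seq_len(nrow(base)), n_modules), , drop = FALSE]
  m / rowSums(m)
}

module_code_table <- function(cfg) {
  sizes <- diff(floor(seq(0, cfg$n_diseases, length.out = cfg$n_modules + 1)))
  letters_pool <- c("Q", "I", "N", "E", "J", "K", "G", "M", "D", "C")
  letter <- rep_len(letters_pool, cfg$n_modules)
  purrr::map_dfr(seq_len(cfg$n_modules), function(mod) {
    idx <- seq_len(sizes[mod])
    tibble(code = sprintf("%s%02d.X", letter[mod], idx - 1L),
           module = mod,
           hub = cfg$hub_per_module & idx == 1L)
  })
}

#' Generate a synthetic discharge cohort with planted modules
#'
#' See [sim_config()] for the generative model. Deterministic given `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer RNG seed.
#' @return List with `records` (a `record_set`) and `truth`: a list holding
#'   `disease_modules` (tibble `code`, `module`, `hub`), `hubs`,
#'   `record_modules` (latent module per emitted record), and the effective
#'   within-module draw probability `p_within`.
#' @export
generate_cohort <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  codes <- module_code_table(cfg)
  D <- cfg$n_diseases
  with_local_seed(seed, {
    n <- cfg$n_records
    z <- sample.int(cfg$n_modules, n, replace = TRUE)
    brackets <- default_age_brackets()
    age <- integer(n)
    for (mod in seq_len(cfg$n_modules)) {
      idx <- which(z == mod)
      if (length(idx) == 0L) next
      br <- sample.int(nrow(brackets), length(idx), replace = TRUE,
                       prob = cfg$age_profiles[mod, ])
      lo <- brackets$lo[br]
      hi <- pmin(brackets$hi[br], 100)
      age[idx] <- lo + floor(runif(length(idx)) * (hi - lo + 1))
    }
    sex <- sample(c("F", "M"), n, replace = TRUE)
    n_codes <- sample.int(cfg$max_codes_per_record, n, replace = TRUE,
                          prob = cfg$codes_weights)

    sizes <- table(factor(codes$module, levels = seq_len(cfg$n_modules)))
    rec <- rep.int(seq_len(n), n_codes)
    mod_of_draw <- z[rec]
    s <- as.numeric(sizes[mod_of_draw])
    p_within_vec <- cfg$within_boost * s / (cfg$within_boost * s + (D - s))
    within <- runif(length(rec)) < p_within_vec

    disease <- integer(length(rec))
    # uniform background draws over all diseases
    disease[!within] <- sample.int(D, sum(!within), replace = TRUE)
    # within-module draws, hub oversampled
    for (mod in seq_len(cfg$n_modules)) {
      sel <- which(within & mod_of_draw == mod)
      if (length(sel) == 0L) next
      members <- which(codes$module == mod)
      wts <- ifelse(codes$hub[members], cfg$hub_weight, 1)
      disease[sel] <- members[sample.int(length(members), length(sel),
                                         replace = TRUE, prob = wts)]
    }

    long <- tibble(
      record_id = sprintf("r%05d", rec),
      age = age[rec],
      sex = sex[rec],
      icd10 = codes$code[disease]
    )
    rs <- suppressWarnings(
      as_record_set(long, max_codes = cfg$max_codes_per_record,
                    provenance = sprintf("synthetic cohort (seed %d)", seed)))
    truth <- list(
      disease_modules = codes,
      hubs = codes$code[codes$hub],
      record_modules = tibble(record_id = sprintf("r%05d", seq_len(n)),
                              module = z),
      p_within = unique(round(p_within_vec, 10)),
      seed = seed
    )
    list(records = rs, truth = truth)
  })
}

#' Generate module-aligned gene annotations and pathways
#'
#' Each planted module owns a disjoint gene pool; each annotated disease
#' receives most of its module's pool (per-gene probability
#' `gene_sample_rate`) plus a sprinkle of shared background genes, so
#' within-module disease pairs have high Jaccard similarity and
#' between-module pairs near zero. When `pathway_alignment` is on, the
#' collection contains one pathway per module (its full gene pool) plus
#' random distractor gene sets.
#'
#' @param cfg A [sim_config()].
#' @param truth Ground truth from [generate_cohort()].
#' @param seed Integer RNG seed.
#' @return List with `annotations` (a `gene_annotation_map`), `pathways`
#'   (a `pathway_collection`) and `truth` extended with `module_pools`,
#'   `module_pathways` and `annotated` codes.
#' @export
generate_annotations <- function(cfg, truth, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  codes <- truth$disease_modules
  pools <- lapply(seq_len(cfg$n_modules), function(mod) {
    sprintf("M%dGENE%03d", mod, seq_len(cfg$genes_per_module_pool))
  })
  noise_pool <- sprintf("NOISE%03d", seq_len(cfg$noise_genes))

  with_local_seed(seed + 1000003L, {
    annotated <- runif(nrow(codes)) < cfg$annotation_probability
    rows <- purrr::map(which(annotated), function(i) {
      pool <- pools[[codes$module[i]]]
      keep <- pool[runif(length(pool)) < cfg$gene_sample_rate]
      noise <- noise_pool[runif(length(noise_pool)) < cfg$noise_gene_rate]
      genes <- c(keep, noise)
      if (length(genes) == 0L) genes <- pool[sample.int(length(pool), 1L)]
      tibble(icd10 = codes$code[i], gene = genes)
    })
    ann <- as_gene_annotation_map(dplyr::bind_rows(
      rows, tibble(icd10 = character(), gene = character())))

    pw <- list()
    if (cfg$pathway_alignment) {
      pw <- setNames(pools, sprintf("MODULE_%d_PATHWAY", seq_len(cfg$n_modules)))
    }
    gene_space <- c(unlist(pools, use.names = FALSE), noise_pool)
    distract <- lapply(seq_len(cfg$n_distractor_pathways), function(i) {
      sample(gene_space, min(cfg$distractor_size, length(gene_space)))
    })
    names(distract) <- sprintf("RANDOM_SET_%02d",
                               seq_len(cfg$n_distractor_pathways))
    coll <- pathway_collection(c(pw, distract))

    truth$module_pools <- setNames(pools,
                                   sprintf("module_%d", seq_len(cfg$n_modules)))
    truth$module_pathways <- names(pw)
    truth$annotated <- codes$code[annotated]
    list(annotations = ann, pathways = coll, truth = truth)
  })
}

#' Generate a complete synthetic comorbidity study
#'
#' Cohort plus module-aligned annotations and pathways in one call;
#' deterministic given `seed`.
#'
#' @inheritParams generate_cohort
#' @return A `comorbidity_simulation`: list with `records`, `annotations`,
#'   `pathways`, `truth`, `config`.
#' @export
simulate_comorbidity_study <- function(cfg = sim_config(), seed = 1L) {
  cohort <- generate_cohort(cfg, seed = seed)
  ann <- generate_annotations(cfg, cohort$truth, seed = seed)
  structure(list(records = cohort$records,
                 annotations = ann$annotations,
                 pathways = ann$pathways,
                 truth = ann$truth,
                 config = cfg),
            class = "comorbidity_simulation")
}

#' @export
print.comorbidity_simulation <- function(x, ...) {
  cat(sprintf(
    "<comorbidity_simulation> %d records, %d diseases in %d planted modules (seed %d)\n",
    nrow(x$records), x$config$n_diseases, x$config$n_modules, x$truth$seed))
  invisible(x)
}

#' Write a simulated study to disk in the pipeline's file dialects
#'
#' Emits `records.tsv` (long format: record_id, age, sex, icd10),
#' `annotations.tsv` (icd10, gene), `pathways.gmt` and `truth.json`.
#'
#' @param sim A `comorbidity_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "comorbidity_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "records.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "truth.json"))

  long <- tibble(record_id = rep(sim$records$record_id,
                                 lengths(sim$records$codes)),
                 age = rep(sim$records$age, lengths(sim$records$codes)),
                 sex = rep(sim$records$sex, lengths(sim$records$codes)),
                 icd10 = unlist(sim$records$codes, use.names = FALSE))
  readr::write_tsv(long, paths[["records"]])

  ann_long <- tibble(icd10 = rep(sim$annotations$icd10,
                                 lengths(sim$annotations$genes)),
                     gene = unlist(sim$annotations$genes, use.names = FALSE))
  readr::write_tsv(ann_long, paths[["annotations"]])

  gmt <- vapply(names(sim$pathways$pathways), function(nm) {
    paste(c(nm, "synthetic", sim$pathways$pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, paths[["pathways"]])

  truth <- sim$truth
  jsonlite::write_json(
    list(disease_modules = truth$disease_modules,
         hubs = truth$hubs,
         module_pathways = truth$module_pathways,
         annotated = truth$annotated,
         p_within = truth$p_within,
         seed = truth$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
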