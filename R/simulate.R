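#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate a merged immunotherapy-treated NSCLC discovery
#' cohort: 106 patients; a latent "responder-like" subgroup (45\% of
#' patients) whose pathway genes mutate at a multiplied rate, yielding
#' roughly 35-40\% NOTCH+/co-DDR+ (GoodBenefit) samples; whole-exome-scale
#' background mutation counts so TMB is coupled to the latent group;
#' exponential progression-free survival with baseline hazard log(2)/3.6
#' per month (median 3.6 months in BadBenefit) and a planted hazard ratio
#' of 0.34 for GoodBenefit; independent exponential censoring plus an
#' administrative cutoff; and durable-clinical-benefit probabilities of
#' 0.70 (GoodBenefit) vs 0.35 (BadBenefit).
#'
#' @param n_samples Number of patients.
#' @param catalog Pathway catalog the mutations are structured around.
#' @param p_gene Baseline per-gene mutation probability for pathway genes.
#' @param enrich_mult Multiplier on `p_gene` in the latent responder-like
#'   subgroup.
#' @param p_latent Probability a patient belongs to the latent subgroup.
#' @param lambda_bg Poisson mean of background (non-pathway) mutations.
#' @param bg_mult_latent Multiplier on `lambda_bg` in the latent subgroup
#'   (couples TMB to the responder-like phenotype).
#' @param n_bg_genes Size of the background dummy-gene pool.
#' @param planted_hr Hazard ratio of GoodBenefit vs BadBenefit (> 0).
#' @param baseline_hazard Events per month in BadBenefit.
#' @param censor_rate Rate of the independent exponential censoring process.
#' @param admin_cutoff Administrative censoring time in months.
#' @param dcb_prob Named vector: probability of DCB per binary stratum.
#' @param tnb_ratio Mean neoantigens per non-synonymous mutation.
#' @param n_genes Number of genes in the generated expression matrix.
#' @param delta Planted immune-signature shift in SD units.
#' @param up_signatures Immune signatures shifted `+delta` in GoodBenefit.
#' @param down_genes Genes shifted `-delta` in GoodBenefit.
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the config.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 106,
                              catalog = default_catalog(),
                              p_gene = 0.01,
                              enrich_mult = 5,
                              p_latent = 0.45,
                              lambda_bg = 80,
                              bg_mult_latent = 1.6,
                              n_bg_genes = 2000,
                              planted_hr = 0.34,
                              baseline_hazard = log(2) / 3.6,
                              censor_rate = 0.02,
                              admin_cutoff = 40,
                              dcb_prob = c(GoodBenefit = 0.70,
                                           BadBenefit = 0.35),
                              tnb_ratio = 0.1,
                              n_genes = 1200,
                              delta = 1.5,
                              up_signatures = c("Activated_CD4_T_cell",
                                                "Activated_CD8_T_cell"),
                              down_genes = c("IL4", "TNFSF15"),
                              seed = 42) {
  cfg <- list(n_samples = n_samples, catalog = catalog, p_gene = p_gene,
              enrich_mult = enrich_mult, p_latent = p_latent,
              lambda_bg = lambda_bg, bg_mult_latent = bg_mult_latent,
              n_bg_genes = n_bg_genes, planted_hr = planted_hr,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              admin_cutoff = admin_cutoff, dcb_prob = dcb_prob,
              tnb_ratio = tnb_ratio, n_genes = n_genes, delta = delta,
              up_signatures = up_signatures, down_genes = down_genes,
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_gene, cfg$p_latent, cfg$dcb_prob, cfg$tnb_ratio)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (cfg$p_gene * cfg$enrich_mult > 1)
    stop("p_gene * enrich_mult exceeds 1")
  if (cfg$planted_hr <= 0) stop("planted_hr must be positive")
  if (cfg$lambda_bg < 0) stop("lambda_bg must be non-negative")
  if (cfg$n_samples < 1) stop("n_samples must be >= 1")
  if (!all(c("GoodBenefit", "BadBenefit") %in% names(cfg$dcb_prob)))
    stop("dcb_prob needs GoodBenefit and BadBenefit entries")
  if (!inherits(cfg$catalog, "pathway_catalog"))
    stop("catalog must be a pathway_catalog")
  invisible(cfg)
}

#' Read a simulation scenario from YAML
#'
#' Scalar fields of [simulation_config()] can be given in a YAML file;
#' unspecified fields keep their defaults. The catalog itself is configured
#' separately (fields `pathways_gmt` / `categories_tsv` name a GMT plus
#' sidecar category map).
#'
#' @param path Path to the YAML scenario.
#' @return A `simulation_config`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$pathways_gmt)) {
    cats <- if (!is.null(y$categories_tsv)) read_category_map(y$categories_tsv)
            else NULL
    y$catalog <- pathway_catalog(read_gmt(y$pathways_gmt, categories = cats),
                                 provenance = paste("scenario catalog:",
                                                    y$pathways_gmt))
    y$pathways_gmt <- NULL
    y$categories_tsv <- NULL
  }
  if (!is.null(y$dcb_prob)) y$dcb_prob <- unlist(y$dcb_prob)
  do.call(simulation_config, y)
}

#' Generate a synthetic cohort bundle
#'
#' Draws per-sample mutations (pathway genes at their per-gene rates, the
#' latent subgroup at the multiplied rate, plus Poisson background
#' mutations on dummy genes), derives the GoodBenefit/BadBenefit strata by
#' the same public [assign_strata()] rule the pipeline uses (generator and
#' pipeline can never drift), then draws exponential PFS/OS with the
#' planted hazard ratio, independent censoring, response per stratum, and
#' TMB/TNB. Files are written in the package's MAF / clinical / truth
#' schemas.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Object of class `fixture_bundle`: list with `paths` (maf,
#'   clinical, truth), `strata`, `truth`, `config`.
#' @export
generate_cohort <- function(config, dir = tempfile("cohort")) {
  .validate_sim_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  pathway_genes <- sort(unique(unlist(lapply(config$catalog$sets,
                                             `[[`, "genes"))))
  latent <- stats::rbinom(n, 1, config$p_latent) == 1
  classes <- nonsynonymous_classes()
  class_wts <- c(0.70, 0.08, 0.01, 0.05, 0.04, 0.03, 0.02, 0.06, 0.01)
  # one uniform per (sample, pathway gene), drawn up front: under a fixed
  # seed the realized hit sets are nested in p_gene, so stratum counts
  # respond monotonically to the mutation rate
  u <- matrix(stats::runif(n * length(pathway_genes)), nrow = n)
  n_bg_draw <- stats::rpois(n, config$lambda_bg *
                              ifelse(latent, config$bg_mult_latent, 1))
  mut_list <- vector("list", n)
  for (i in seq_len(n)) {
    p <- config$p_gene * if (latent[i]) config$enrich_mult else 1
    hit <- pathway_genes[u[i, ] < p]
    n_bg <- n_bg_draw[i]
    bg <- if (n_bg > 0)
      sprintf("BG%04d", sample.int(config$n_bg_genes, n_bg, replace = TRUE))
    else character(0)
    genes <- c(hit, bg)
    n_mut <- length(genes)
    if (n_mut == 0) next
    mut_list[[i]] <- data.frame(
      sample_id = rep(ids[i], n_mut),
      gene = genes,
      variant_class = sample(classes, n_mut, replace = TRUE,
                             prob = class_wts),
      protein_change = NA_character_,
      stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, mut_list[!vapply(mut_list, is.null,
                                               logical(1))])
  if (is.null(mutations))
    mutations <- data.frame(sample_id = character(0), gene = character(0),
                            variant_class = character(0),
                            protein_change = character(0),
                            stringsAsFactors = FALSE)

  # strata via the public rule on a clinical skeleton
  skeleton <- data.frame(sample_id = ids, response = "unknown",
                         pfs_months = 0, pfs_event = 0,
                         stringsAsFactors = FALSE)
  co <- cohort(skeleton, mutations, name = "synthetic-skeleton")
  amat <- build_alteration_matrix(co, config$catalog)
  strata <- assign_strata(amat)
  good <- strata$binary_label == "GoodBenefit"

  hazard <- config$baseline_hazard * ifelse(good, config$planted_hr, 1)
  pfs_true <- stats::rexp(n, rate = hazard)
  cens <- pmin(stats::rexp(n, rate = max(config$censor_rate, 1e-12)),
               config$admin_cutoff)
  pfs <- pmin(pfs_true, cens)
  pfs_event <- as.integer(pfs_true <= cens)
  os_true <- pfs_true + stats::rexp(n, rate = hazard * 1.5)
  os_cens <- pmin(stats::rexp(n, rate = max(config$censor_rate, 1e-12)),
                  config$admin_cutoff)
  os <- pmin(os_true, os_cens)
  os_event <- as.integer(os_true <= os_cens)

  p_dcb <- unname(config$dcb_prob[ifelse(good, "GoodBenefit",
                                         "BadBenefit")])
  dcb <- stats::runif(n) < p_dcb
  response <- ifelse(dcb, "DCB", "NDB")
  best <- character(n)
  best[dcb] <- ifelse(stats::runif(sum(dcb)) < 0.5, "CR/PR", "SD")
  best[!dcb] <- ifelse(stats::runif(sum(!dcb)) < 0.65, "PD/NE", "SD")

  tmb <- as.integer(table(factor(
    mutations$sample_id[is_nonsynonymous(mutations$variant_class)],
    levels = ids)))
  tnb <- stats::rbinom(n, tmb, config$tnb_ratio)

  clinical <- data.frame(
    sample_id = ids, response = response, best_response = best,
    pfs_months = round(pfs, 3), pfs_event = pfs_event,
    os_months = round(os, 3), os_event = os_event,
    histology = ifelse(stats::runif(n) < 0.82, "Squamous", "Non-squamous"),
    sex = ifelse(stats::runif(n) < 0.51, "Female", "Male"),
    smoking = ifelse(stats::runif(n) < 0.80, "Current/Former", "Never"),
    pdl1 = sample(c("Strong", "Weak", "Negative", "Unknown"), n,
                  replace = TRUE, prob = c(0.17, 0.45, 0.29, 0.09)),
    treatment = ifelse(stats::runif(n) < 0.29, "PD-1",
                       "PD-1 plus CTLA-4"),
    tmb = tmb, tnb = tnb, stringsAsFactors = FALSE)

  truth <- data.frame(
    sample_id = ids, latent = as.integer(latent),
    binary_label = as.character(strata$binary_label),
    three_group_label = as.character(strata$three_group_label),
    hazard = hazard, planted_hr = config$planted_hr,
    baseline_hazard = config$baseline_hazard, stringsAsFactors = FALSE)

  paths <- list(maf = file.path(dir, "mutations.maf.tsv"),
                clinical = file.path(dir, "clinical.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_maf(mutations, paths$maf)
  write_clinical(clinical, paths$clinical)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  structure(list(paths = paths, strata = strata, truth = truth,
                 config = config, dir = dir),
            class = "fixture_bundle")
}

#' Generate a synthetic expression matrix with planted immune signal
#'
#' Baseline Normal(0, 1) per gene and sample; genes of the configured "up"
#' immune signatures are shifted `+delta` in GoodBenefit samples, the
#' configured "down" genes `-delta`. The gene universe is the union of all
#' signature genes padded with dummy genes up to `n_genes`.
#'
#' @param config A [simulation_config()].
#' @param strata Output of [assign_strata()] (from [generate_cohort()]).
#' @param path Output TSV path.
#' @param signatures Signature collection defining the planted sets;
#'   defaults to the packaged immune signatures.
#' @return `path`, invisibly; the written matrix as attribute `"matrix"`.
#' @export
generate_expression <- function(config, strata,
                                path = tempfile(fileext = ".tsv"),
                                signatures = default_immune_signatures()) {
  sig_union <- sort(unique(c(unlist(lapply(signatures, `[[`, "genes")),
                             toupper(config$down_genes))))
  if (config$n_genes < length(sig_union))
    stop("n_genes (", config$n_genes, ") smaller than the signature gene ",
         "union (", length(sig_union), ")")
  n_dummy <- config$n_genes - length(sig_union)
  genes <- c(sig_union, sprintf("EXPR%04d", seq_len(n_dummy)))
  samples <- strata$sample_id
  set.seed(config$seed + 1L)
  m <- matrix(stats::rnorm(length(genes) * length(samples)),
              nrow = length(genes),
              dimnames = list(genes, samples))
  good <- strata$binary_label == "GoodBenefit"
  up_genes <- unique(unlist(lapply(config$up_signatures, function(nm) {
    if (!nm %in% names(signatures))
      stop("unknown up signature: ", nm)
    signatures[[nm]]$genes
  })))
  up_genes <- setdiff(up_genes, toupper(config$down_genes))
  m[up_genes, good] <- m[up_genes, good] + config$delta
  down <- intersect(toupper(config$down_genes), genes)
  m[down, good] <- m[down, good] - config$delta
  write_expression(round(m, 5), path)
  out <- path
  attr(out, "matrix") <- m
  invisible(out)
}

#' Write a fixture-bundle manifest
#'
#' @param bundle A `fixture_bundle` from [generate_cohort()]; an
#'   `expression` path may be attached as `bundle$paths$expression`.
#' @param dir Directory for `manifest.json` (default the bundle directory).
#' @return Path to the manifest, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir = bundle$dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  paths <- bundle$paths
  missing <- names(paths)[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("bundle incomplete; missing file(s): ",
         paste(missing, collapse = ", "))
  cfg <- bundle$config
  cfg_echo <- cfg[setdiff(names(cfg), "catalog")]
  cfg_echo$catalog_provenance <- cfg$catalog$provenance
  manifest <- list(
    files = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    seed = cfg$seed,
    config = cfg_echo)
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
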