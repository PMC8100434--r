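.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full pathway co-occurrence pipeline
#'
#' Sequences the whole analysis on one cohort: read and validate inputs,
#' build the alteration matrix, assign NOTCH+/co-DDR+ strata, compute
#' prevalence and co-occurrence enrichment, run the survival arm
#' (Kaplan-Meier per stratum, log-rank, univariate Cox forest, TMB/TNB
#' contrasts) and, when an expression matrix is supplied, the immune arm
#' (ssGSEA scoring, 3-group Ward clustering, pre-ranked GSEA and per-gene
#' contrasts). Every table is written as TSV with deterministic column
#' order, plus a JSON run manifest (seed, config echo, stage counts,
#' warnings). One message per stage reports counts in/out so attrition is
#' auditable.
#'
#' @param maf Path to the MAF-style mutation TSV.
#' @param clinical Path to the clinical TSV.
#' @param expression Optional path to the expression TSV; the immune arm is
#'   skipped with a logged notice when absent.
#' @param out_dir Output directory.
#' @param pathways_gmt,categories_tsv Optional catalog override (GMT +
#'   category sidecar); the packaged default catalog otherwise.
#' @param signatures_gmt Optional immune signature GMT override.
#' @param panel Optional character vector of assayed genes; the catalog is
#'   restricted to it (targeted-panel mode).
#' @param endpoint `"PFS"` or `"OS"` for the survival arm.
#' @param adjust Optional covariates for the multivariable Cox fit.
#' @param enrichment_construction Passed to
#'   [notch_cooccurrence_enrichment()].
#' @param alpha ssGSEA rank-weight exponent.
#' @param n_perm Permutations for the pre-ranked GSEA.
#' @param compare_genes Genes for the per-gene expression contrast.
#' @param seed Seed for the permutation null.
#' @return Invisible list of class `copath_run`: all result tables, paths,
#'   and the manifest.
#' @export
run_pipeline <- function(maf, clinical, expression = NULL,
                         out_dir = "copath_run",
                         pathways_gmt = NULL, categories_tsv = NULL,
                         signatures_gmt = NULL, panel = NULL,
                         endpoint = "PFS", adjust = NULL,
                         enrichment_construction = "joint_vs_response",
                         alpha = 0.25, n_perm = 1000,
                         compare_genes = c("IL4", "TNFRSF18", "TNFSF15"),
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message("[copath] ", msg)
    msg
  }
  stages <- character(0)

  catalog <- if (is.null(pathways_gmt)) default_catalog()
  else pathway_catalog(
    read_gmt(pathways_gmt,
             categories = if (!is.null(categories_tsv))
               read_category_map(categories_tsv) else NULL),
    provenance = paste("user catalog:", pathways_gmt))
  if (!is.null(panel)) catalog <- restrict_catalog(catalog, panel)
  stages <- c(stages, note("catalog: %d sets (%d ddr)", length(catalog),
                           length(ddr_names(catalog))))

  cl <- read_clinical(clinical)
  mut <- read_maf(maf)
  co <- withCallingHandlers(
    cohort(cl, mut, name = basename(out_dir)),
    message = function(m) {
      warnings_log <<- c(warnings_log, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  stages <- c(stages, note("cohort: %d patients, %d mutation rows",
                           nrow(co$clinical), nrow(co$mutations)))

  amat <- build_alteration_matrix(co, catalog)
  strata <- assign_strata(amat)
  stages <- c(stages, note("strata: %d GoodBenefit / %d BadBenefit",
                           sum(strata$binary_label == "GoodBenefit"),
                           sum(strata$binary_label == "BadBenefit")))

  tmb <- compute_tmb(co)
  prevalence <- pathway_prevalence_by_response(amat, co$clinical)
  enrichment <- notch_cooccurrence_enrichment(
    amat, co$clinical, construction = enrichment_construction)
  gene_freq <- gene_mutation_frequency(co)

  good_id <- strata$sample_id[strata$binary_label == "GoodBenefit"]
  cl2 <- co$clinical
  is_good <- cl2$sample_id %in% good_id
  times <- if (endpoint == "PFS") cl2$pfs_months else cl2$os_months
  events <- if (endpoint == "PFS") cl2$pfs_event else cl2$os_event
  ok <- !is.na(times) & !is.na(events)
  km_tables <- NULL
  logrank <- NULL
  km_good <- km_bad <- NULL
  if (any(is_good[ok]) && any(!is_good[ok])) {
    km_good <- km_fit(times[ok & is_good], events[ok & is_good])
    km_bad <- km_fit(times[ok & !is_good], events[ok & !is_good])
    logrank <- logrank_test(times[ok & is_good], events[ok & is_good],
                            times[ok & !is_good], events[ok & !is_good])
    km_tables <- rbind(
      data.frame(group = "GoodBenefit", time = km_good$times,
                 survival = km_good$survival, at_risk = km_good$at_risk),
      data.frame(group = "BadBenefit", time = km_bad$times,
                 survival = km_bad$survival, at_risk = km_bad$at_risk))
    stages <- c(stages, note(
      "survival (%s): median %s vs %s months, log-rank p = %.3g", endpoint,
      format(km_good$median), format(km_bad$median), logrank$p_value))
  } else {
    warnings_log <- c(warnings_log,
                      "one stratum empty; stratum survival arm skipped")
  }
  forest <- pathway_forest(amat, co$clinical, endpoint = endpoint,
                           adjust = adjust, strata = strata)

  tmb_obs <- ifelse(is.na(cl2$tmb), tmb[cl2$sample_id], cl2$tmb)
  burden_tests <- data.frame(
    quantity = "TMB",
    mean_good = mean(tmb_obs[is_good]),
    mean_bad = mean(tmb_obs[!is_good]),
    p_value = rank_sum_test(tmb_obs[is_good], tmb_obs[!is_good])$p_value,
    stringsAsFactors = FALSE)
  if (any(!is.na(cl2$tnb))) {
    tnb_ok <- !is.na(cl2$tnb)
    burden_tests <- rbind(burden_tests, data.frame(
      quantity = "TNB",
      mean_good = mean(cl2$tnb[tnb_ok & is_good]),
      mean_bad = mean(cl2$tnb[tnb_ok & !is_good]),
      p_value = rank_sum_test(cl2$tnb[tnb_ok & is_good],
                              cl2$tnb[tnb_ok & !is_good])$p_value))
  }
  summary_tab <- tryCatch(cohort_summary_table(co$clinical),
                          error = function(e) NULL)

  immune <- NULL
  if (!is.null(expression)) {
    expr <- read_expression(expression)
    signatures <- if (is.null(signatures_gmt)) default_immune_signatures()
                  else read_gmt(signatures_gmt)
    scores <- score_cohort(expr, signatures, alpha = alpha)
    clusters <- cluster_immune(scores, k = 3)
    ranked <- group_rank_list(expr, strata)
    gsea <- preranked_gsea(ranked, signatures, n_perm = n_perm, seed = seed)
    genes_tab <- compare_gene_expression(expr, strata, compare_genes)
    immune <- list(scores = scores, clusters = clusters, ranked = ranked,
                   gsea = gsea, gene_contrasts = genes_tab)
    stages <- c(stages, note(
      "immune: %d samples scored, %d signatures, %d enriched / %d depleted",
      nrow(scores), nrow(gsea), sum(gsea$call == "enriched"),
      sum(gsea$call == "depleted")))
  } else {
    stages <- c(stages, note("immune arm skipped: no expression input"))
  }

  paths <- list(
    alteration_matrix = .write_tsv(
      data.frame(sample_id = rownames(amat), 1L * amat, check.names = FALSE),
      file.path(out_dir, "alteration_matrix.tsv")),
    strata = .write_tsv(strata, file.path(out_dir, "strata.tsv")),
    prevalence = .write_tsv(prevalence,
                            file.path(out_dir, "prevalence.tsv")),
    enrichment = .write_tsv(enrichment,
                            file.path(out_dir, "enrichment.tsv")),
    gene_frequency = .write_tsv(gene_freq,
                                file.path(out_dir, "gene_frequency.tsv")),
    tmb = .write_tsv(data.frame(sample_id = names(tmb), tmb = tmb),
                     file.path(out_dir, "tmb.tsv")),
    forest = .write_tsv(forest, file.path(out_dir, "cox_forest.tsv")),
    burden_tests = .write_tsv(burden_tests,
                              file.path(out_dir, "burden_tests.tsv")))
  if (!is.null(km_tables))
    paths$km <- .write_tsv(km_tables, file.path(out_dir, "km_curves.tsv"))
  if (!is.null(summary_tab))
    paths$summary_table <- .write_tsv(summary_tab,
                                      file.path(out_dir,
                                                "cohort_summary.tsv"))
  if (!is.null(immune)) {
    paths$ssgsea <- .write_tsv(
      data.frame(sample_id = rownames(immune$scores), immune$scores,
                 check.names = FALSE),
      file.path(out_dir, "ssgsea_scores.tsv"))
    paths$clusters <- .write_tsv(immune$clusters,
                                 file.path(out_dir, "immune_clusters.tsv"))
    paths$gsea <- .write_tsv(immune$gsea,
                             file.path(out_dir, "gsea_results.tsv"))
    paths$gene_contrasts <- .write_tsv(
      immune$gene_contrasts, file.path(out_dir, "gene_contrasts.tsv"))
  }

  manifest <- list(seed = seed, endpoint = endpoint,
                   n_patients = nrow(co$clinical),
                   n_mutations = nrow(co$mutations),
                   n_pathways = ncol(amat),
                   n_good = sum(strata$binary_label == "GoodBenefit"),
                   n_bad = sum(strata$binary_label == "BadBenefit"),
                   immune_arm = !is.null(immune),
                   stages = stages, warnings = warnings_log,
                   catalog_provenance = catalog$provenance)
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(structure(
    list(cohort = co, alteration = amat, strata = strata, tmb = tmb,
         prevalence = prevalence, enrichment = enrichment,
         gene_frequency = gene_freq, km_good = km_good, km_bad = km_bad,
         logrank = logrank, forest = forest, burden_tests = burden_tests,
         summary_table = summary_tab, immune = immune, paths = paths,
         manifest = manifest, manifest_path = manifest_path,
         out_dir = out_dir),
    class = "copath_run"))
}

#' Consolidate a pipeline run into one summary
#'
#' Pulls the headline numbers (group sizes, KM medians, log-rank p, the
#' GoodBenefit hazard ratio, top co-occurrence enrichments, burden
#' contrasts, immune cluster sizes and calls) from the run's own tables —
#' no report-only arithmetic — and writes one machine-readable JSON and one
#' human-readable TSV. Absent arms are reported as null fields.
#'
#' @param run A `copath_run` from [run_pipeline()].
#' @return The summary as a list, invisibly; files `report_summary.json`
#'   and `report_summary.tsv` are written into the run directory.
#' @export
render_report <- function(run) {
  stopifnot(inherits(run, "copath_run"))
  gb_row <- run$forest[run$forest$term == "GoodBenefit" &
                         run$forest$model == "univariate", ]
  top_enrich <- run$enrichment[order(run$enrichment$p_value), ][1, ]
  summary <- list(
    n_patients = run$manifest$n_patients,
    n_good = run$manifest$n_good,
    n_bad = run$manifest$n_bad,
    km_median_good = if (!is.null(run$km_good)) run$km_good$median else NULL,
    km_median_bad = if (!is.null(run$km_bad)) run$km_bad$median else NULL,
    logrank_p = if (!is.null(run$logrank)) run$logrank$p_value else NULL,
    goodbenefit_hr = if (nrow(gb_row)) gb_row$hr else NULL,
    goodbenefit_hr_ci = if (nrow(gb_row)) c(gb_row$ci_low, gb_row$ci_high)
                        else NULL,
    goodbenefit_hr_p = if (nrow(gb_row)) gb_row$p else NULL,
    notch_pct_dcb = run$prevalence$pct_dcb[
      run$prevalence$pathway == "NOTCH"],
    notch_pct_ndb = run$prevalence$pct_ndb[
      run$prevalence$pathway == "NOTCH"],
    top_enrichment_pathway = top_enrich$pathway,
    top_enrichment_log2_or = top_enrich$log2_odds_ratio,
    tmb_p = run$burden_tests$p_value[run$burden_tests$quantity == "TMB"],
    immune = if (!is.null(run$immune)) list(
      cluster_sizes = as.list(table(run$immune$clusters$cluster)),
      n_enriched = sum(run$immune$gsea$call == "enriched"),
      n_depleted = sum(run$immune$gsea$call == "depleted")
    ) else NULL)
  json_path <- file.path(run$out_dir, "report_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  flat <- data.frame(
    key = c("n_patients", "n_good", "n_bad", "km_median_good",
            "km_median_bad", "logrank_p", "goodbenefit_hr",
            "notch_pct_dcb", "notch_pct_ndb", "tmb_p"),
    value = c(summary$n_patients, summary$n_good, summary$n_bad,
              if (is.null(summary$km_median_good)) NA else
                summary$km_median_good,
              if (is.null(summary$km_median_bad)) NA else
                summary$km_median_bad,
              if (is.null(summary$logrank_p)) NA else summary$logrank_p,
              if (is.null(summary$goodbenefit_hr)) NA else
                summary$goodbenefit_hr,
              summary$notch_pct_dcb, summary$notch_pct_ndb, summary$tmb_p),
    stringsAsFactors = FALSE)
  .write_tsv(flat, file.path(run$out_dir, "report_summary.tsv"))
  invisible(summary)
}
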