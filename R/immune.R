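#' Read a gene-by-sample expression matrix
#'
#' TSV with a header of sample IDs; first column gene symbols (uppercased,
#' must be unique). Values are assumed log-scale normalized abundance.
#'
#' @param path Path to the expression TSV.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  genes <- toupper(as.character(df[[1]]))
  if (anyDuplicated(genes))
    stop("duplicate gene symbols in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  rownames(m) <- genes
  m
}

#' Write an expression matrix to TSV
#' @param expression Numeric matrix, genes in rows.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged 28 immune-cell-type signature collection
#'
#' Marker-gene signatures for 28 immune cell types, shipped as a GMT
#' fixture with representative (curated stand-in) marker genes; pass any
#' other GMT to the scoring functions to override.
#'
#' @return Named list of `gene_set` objects.
#' @export
default_immune_signatures <- function() {
  gmt <- system.file("extdata", "immune_signatures_28.gmt",
                     package = "copath")
  if (!nzchar(gmt))
    stop("packaged immune signature fixture is missing")
  read_gmt(gmt)
}

#' Single-sample GSEA enrichment score
#'
#' Rank-based enrichment of a signature in one sample: genes are ordered by
#' decreasing expression (ties broken by gene name), the in-set cumulative
#' uses weights `rank^alpha` (rank N for the top gene) normalized over
#' in-set genes, the out-of-set cumulative steps by `1/(N - Nh)`, and the
#' score is the sum over all ranks of the difference of the two cumulatives.
#' The score depends only on within-sample ranks, so it is invariant under
#' any strictly monotone transform of the expression values. A signature
#' covering every gene has no out-of-set mass; the degenerate score is 0 by
#' convention.
#'
#' @param values Named numeric vector: one sample's expression by gene.
#' @param signature Character vector of signature genes (or a `gene_set`).
#' @param alpha Rank-weight exponent, >= 0 (0 = unweighted KS running sum).
#' @return Scalar enrichment score, or `NA` with a warning when fewer than
#'   2 signature genes are present in the sample.
#' @export
ssgsea_score <- function(values, signature, alpha = 0.25) {
  if (inherits(signature, "gene_set")) signature <- signature$genes
  stopifnot(alpha >= 0, !is.null(names(values)))
  genes <- toupper(names(values))
  signature <- toupper(signature)
  in_set <- genes %in% signature
  if (sum(in_set) < 2L) {
    warning("signature overlap < 2 genes; score undefined")
    return(NA_real_)
  }
  n <- length(values)
  if (all(in_set)) return(0)
  ord <- order(-values, genes)
  in_ord <- in_set[ord]
  rank_value <- n:1
  w <- rank_value^alpha
  hit <- ifelse(in_ord, w, 0)
  hit <- hit / sum(hit)
  miss <- ifelse(in_ord, 0, 1 / (n - sum(in_ord)))
  sum(cumsum(hit) - cumsum(miss))
}

#' ssGSEA scores for a whole cohort
#'
#' @param expression Genes-by-samples matrix ([read_expression()]).
#' @param signatures Named list of gene vectors or `gene_set` objects;
#'   defaults to the packaged 28 immune-cell signatures.
#' @param alpha Rank-weight exponent.
#' @param rescale If `TRUE`, min-max rescale each signature's scores across
#'   samples to `[0, 1]`.
#' @return Samples-by-signatures numeric matrix; signatures with fewer than
#'   2 genes in the matrix are skipped with one aggregated warning.
#' @export
score_cohort <- function(expression, signatures = default_immune_signatures(),
                         alpha = 0.25, rescale = FALSE) {
  stopifnot(is.matrix(expression))
  sig_genes <- lapply(signatures, function(s)
    if (inherits(s, "gene_set")) s$genes else toupper(s))
  if (is.null(names(sig_genes)) &&
      all(vapply(signatures, inherits, logical(1), "gene_set")))
    names(sig_genes) <- vapply(signatures, function(s) s$name, character(1))
  overlap <- vapply(sig_genes, function(g)
    sum(rownames(expression) %in% g), integer(1))
  skipped <- names(sig_genes)[overlap < 2L]
  if (length(skipped) == length(sig_genes))
    stop("every signature has < 2 genes in the expression matrix")
  if (length(skipped))
    warning("skipped signature(s) with < 2 matrix genes: ",
            paste(skipped, collapse = ", "))
  sig_genes <- sig_genes[overlap >= 2L]
  scores <- sapply(sig_genes, function(g)
    apply(expression, 2, function(col)
      ssgsea_score(stats::setNames(col, rownames(expression)), g,
                   alpha = alpha)))
  scores <- matrix(scores, nrow = ncol(expression),
                   dimnames = list(colnames(expression), names(sig_genes)))
  if (rescale) {
    scores <- apply(scores, 2, function(x) {
      r <- range(x)
      if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
    })
    rownames(scores) <- colnames(expression)
  }
  scores
}

#' Cluster samples into immune-infiltration groups
#'
#' Agglomerative hierarchical clustering of the ssGSEA score profiles with
#' the "ward.D" linkage (Lance-Williams Ward update on unsquared Euclidean
#' distances) and the tree cut at `k`. Clusters are labeled by descending
#' cluster-mean score: for `k = 3` the labels are immune-high,
#' immune-intermediate, immune-low.
#'
#' @param scores Samples-by-signatures score matrix ([score_cohort()]).
#' @param k Number of clusters (default 3).
#' @return Data frame `sample_id`, `cluster` (factor ordered high to low);
#'   attributes `linkage` and `hclust` carry provenance.
#' @export
cluster_immune <- function(scores, k = 3) {
  stopifnot(is.matrix(scores))
  if (k > nrow(scores)) stop("k exceeds the number of samples")
  hc <- stats::hclust(stats::dist(scores, method = "euclidean"),
                      method = "ward.D")
  raw <- stats::cutree(hc, k = k)
  cluster_mean <- vapply(seq_len(k), function(i)
    mean(scores[raw == i, , drop = FALSE]), numeric(1))
  ord <- order(-cluster_mean)
  labels <- if (k == 3) c("immune-high", "immune-intermediate", "immune-low")
            else paste0("immune-C", seq_len(k))
  lab_of_raw <- character(k)
  lab_of_raw[ord] <- labels
  out <- data.frame(sample_id = rownames(scores),
                    cluster = factor(lab_of_raw[raw], levels = labels),
                    stringsAsFactors = FALSE)
  attr(out, "linkage") <- "ward.D/euclidean"
  attr(out, "hclust") <- hc
  out
}

# Population z-score per gene (denominator n); constant genes -> 0.
.zscore_rows <- function(expression) {
  mu <- rowMeans(expression)
  sd_pop <- sqrt(rowMeans((expression - mu)^2))
  flat <- sd_pop == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s); z-scores set to 0")
    sd_pop[flat] <- 1
  }
  z <- (expression - mu) / sd_pop
  z[flat, ] <- 0
  z
}

#' Ranked gene list for a stratum contrast
#'
#' Expression is z-scored per gene across all samples (population SD); the
#' rank metric is the mean z within the focal stratum, sorted descending
#' with ties broken by gene name. A positive metric therefore means higher
#' expression in the focal (GoodBenefit) stratum.
#'
#' @param expression Genes-by-samples matrix.
#' @param strata Output of [assign_strata()] (needs `sample_id`,
#'   `binary_label`).
#' @param focal Focal stratum label (default `"GoodBenefit"`).
#' @return Data frame `gene`, `metric`, sorted descending by metric.
#' @export
group_rank_list <- function(expression, strata, focal = "GoodBenefit") {
  labels <- strata$binary_label[match(colnames(expression),
                                      strata$sample_id)]
  if (any(is.na(labels)))
    stop("expression sample(s) missing from strata: ",
         paste(colnames(expression)[is.na(labels)], collapse = ", "))
  if (min(table(labels)) < 2L)
    stop("each stratum needs >= 2 samples")
  z <- .zscore_rows(expression)
  metric <- rowMeans(z[, labels == focal, drop = FALSE])
  out <- data.frame(gene = rownames(expression), metric = unname(metric),
                    stringsAsFactors = FALSE)
  out[order(-out$metric, out$gene), , drop = FALSE]
}

# Weighted KS running-sum enrichment score of one signature on a ranked
# list. in_ord: logical over list positions; absw: |metric|^weight.
.gsea_es <- function(in_ord, absw) {
  nh <- sum(in_ord)
  n <- length(in_ord)
  hit <- ifelse(in_ord, absw, 0)
  total <- sum(hit)
  if (total == 0) hit <- ifelse(in_ord, 1 / nh, 0) else hit <- hit / total
  miss <- ifelse(in_ord, 0, 1 / (n - nh))
  running <- cumsum(hit - miss)
  running[which.max(abs(running))]
}

#' Pre-ranked GSEA with a gene-label permutation null
#'
#' Classic weighted Kolmogorov-Smirnov enrichment: the score is the maximum
#' deviation of the running sum with hit weights `|metric|^1`. The null
#' distribution permutes gene labels (random signature positions on the
#' fixed ranked list), seeded and therefore reproducible. NES divides the
#' score by the mean magnitude of same-sign null scores; the q-value is the
#' GSEA-style FDR over the signature collection (pooled normalized null
#' scores), with Benjamini-Hochberg on the permutation p-values available
#' via `fdr = "bh"`. A signature is called enriched when q < 0.10 and
#' NES > 0, depleted when q < 0.10 and NES < 0, otherwise ns.
#'
#' @param ranked Data frame from [group_rank_list()] (`gene`, `metric`) or
#'   a named numeric vector.
#' @param signatures Named list of gene vectors or `gene_set` objects.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation null.
#' @param fdr `"gsea"` (default) or `"bh"`.
#' @return Data frame: `signature`, `size`, `es`, `nes`, `p_value`,
#'   `q_value`, `call`.
#' @export
preranked_gsea <- function(ranked, signatures, n_perm = 1000, seed = 1,
                           fdr = c("gsea", "bh")) {
  fdr <- match.arg(fdr)
  stopifnot(n_perm >= 100)
  if (is.data.frame(ranked)) {
    metric <- stats::setNames(ranked$metric, toupper(ranked$gene))
  } else metric <- stats::setNames(as.numeric(ranked),
                                   toupper(names(ranked)))
  ord <- order(-metric, names(metric))
  metric <- metric[ord]
  genes <- names(metric)
  n <- length(genes)
  absw <- abs(metric)
  sig_genes <- lapply(signatures, function(s)
    if (inherits(s, "gene_set")) s$genes else toupper(s))
  if (is.null(names(sig_genes)))
    names(sig_genes) <- vapply(signatures, function(s)
      if (inherits(s, "gene_set")) s$name else stop("unnamed signature"),
      character(1))
  keep <- vapply(sig_genes, function(g) sum(genes %in% g) >= 2L, logical(1))
  if (!all(keep))
    warning("skipped signature(s) with < 2 list genes: ",
            paste(names(sig_genes)[!keep], collapse = ", "))
  sig_genes <- sig_genes[keep]
  if (length(sig_genes) == 0L) stop("no scorable signatures")
  set.seed(seed)
  res <- lapply(names(sig_genes), function(nm) {
    in_ord <- genes %in% sig_genes[[nm]]
    nh <- sum(in_ord)
    es <- .gsea_es(in_ord, absw)
    null_es <- vapply(seq_len(n_perm), function(i) {
      perm <- logical(n)
      perm[sample.int(n, nh)] <- TRUE
      .gsea_es(perm, absw)
    }, numeric(1))
    same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(null_es))
    nes <- es / denom
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    list(signature = nm, size = nh, es = es, nes = nes, p_value = p,
         null_nes = null_es / denom)
  })
  out <- data.frame(
    signature = vapply(res, `[[`, character(1), "signature"),
    size = vapply(res, `[[`, numeric(1), "size"),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = vapply(res, `[[`, numeric(1), "nes"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  if (fdr == "bh") {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  } else {
    pool <- unlist(lapply(res, `[[`, "null_nes"))
    out$q_value <- vapply(seq_len(nrow(out)), function(i) {
      nes <- out$nes[i]
      if (is.na(nes)) return(NA_real_)
      if (nes >= 0) {
        num <- mean(pool[pool >= 0] >= nes)
        den <- mean(out$nes[out$nes >= 0] >= nes)
      } else {
        num <- mean(pool[pool < 0] <= nes)
        den <- mean(out$nes[out$nes < 0] <= nes)
      }
      if (is.nan(num)) num <- 0
      min(1, max(0, num / max(den, .Machine$double.eps)))
    }, numeric(1))
  }
  out$call <- ifelse(out$q_value < 0.10 & out$nes > 0, "enriched",
                     ifelse(out$q_value < 0.10 & out$nes < 0, "depleted",
                            "ns"))
  out
}

#' Per-gene expression contrast between strata
#'
#' Each requested gene is z-scored across all samples and compared between
#' GoodBenefit and BadBenefit by [rank_sum_test()]; q-values are
#' Benjamini-Hochberg across the requested genes. Genes absent from the
#' matrix are reported in the `present` column, never fatal.
#'
#' @param expression Genes-by-samples matrix.
#' @param strata Output of [assign_strata()].
#' @param genes Character vector of genes of interest.
#' @param mode Test mode passed to [rank_sum_test()].
#' @return Data frame: `gene`, `present`, `mean_good`, `mean_bad`,
#'   `p_value`, `q_value`.
#' @export
compare_gene_expression <- function(expression, strata, genes,
                                    mode = "wilcoxon") {
  genes <- toupper(genes)
  labels <- strata$binary_label[match(colnames(expression),
                                      strata$sample_id)]
  good <- labels == "GoodBenefit"
  if (!any(good) || all(good)) stop("both strata must be non-empty")
  z <- .zscore_rows(expression)
  rows <- lapply(genes, function(gn) {
    if (!gn %in% rownames(z))
      return(data.frame(gene = gn, present = FALSE, mean_good = NA_real_,
                        mean_bad = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    v <- z[gn, ]
    tst <- suppressWarnings(rank_sum_test(v[good], v[!good], mode = mode))
    data.frame(gene = gn, present = TRUE, mean_good = mean(v[good]),
               mean_bad = mean(v[!good]), p_value = tst$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  out$q_value[out$present] <- stats::p.adjust(out$p_value[out$present],
                                              method = "BH")
  out
}
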