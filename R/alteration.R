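#' Build the sample-by-pathway alteration matrix
#'
#' A sample is altered in a pathway if at least one of that pathway's genes
#' carries a non-synonymous mutation in the sample. Every clinical sample
#' gets a row (all-`FALSE` rows are legal: zero pathway hits never drops a
#' patient); genes absent from every pathway are ignored.
#'
#' @param cohort A [cohort()].
#' @param catalog A [pathway_catalog()].
#' @param classes Non-synonymous class set, see [nonsynonymous_classes()].
#' @return Logical matrix (samples x pathways) with `dimnames`, carrying the
#'   catalog provenance in attribute `"catalog_provenance"` and the DDR set
#'   names in attribute `"ddr_names"`.
#' @export
build_alteration_matrix <- function(cohort, catalog,
                                    classes = nonsynonymous_classes()) {
  stopifnot(inherits(cohort, "cohort"), inherits(catalog, "pathway_catalog"))
  if (length(catalog) == 0L) stop("catalog is empty")
  samples <- cohort$clinical$sample_id
  pathways <- catalog_names(catalog)
  m <- matrix(FALSE, nrow = length(samples), ncol = length(pathways),
              dimnames = list(samples, pathways))
  mut <- cohort$mutations
  if (nrow(mut)) {
    mut <- mut[is_nonsynonymous(mut$variant_class, classes), , drop = FALSE]
    for (p in pathways) {
      hit <- unique(mut$sample_id[mut$gene %in% catalog$sets[[p]]$genes])
      m[hit, p] <- TRUE
    }
  }
  attr(m, "catalog_provenance") <- catalog$provenance
  attr(m, "ddr_names") <- ddr_names(catalog)
  m
}

#' Stratify samples by NOTCH and co-DDR alteration
#'
#' co-DDR means two or more DDR pathways altered in the same sample. The
#' binary rule labels a sample GoodBenefit exactly when it is NOTCH-altered
#' AND co-DDR (the NOTCH+/co-DDR+ stratum); everything else is BadBenefit.
#' The three-group rule splits BadBenefit into SinglePath (exactly one of
#' NOTCH-altered / co-DDR holds) and WildType (neither).
#'
#' @param matrix Alteration matrix from [build_alteration_matrix()].
#' @param ddr Character vector of DDR pathway names present in the matrix;
#'   defaults to the matrix's `"ddr_names"` attribute.
#' @param notch Name of the anchor pathway column (default `"NOTCH"`).
#' @return Data frame with columns `sample_id`, `notch_altered`,
#'   `n_ddr_altered`, `co_ddr`, `binary_label`, `three_group_label`.
#' @export
assign_strata <- function(matrix, ddr = attr(matrix, "ddr_names"),
                          notch = "NOTCH") {
  if (is.null(ddr)) stop("DDR pathway names not supplied")
  if (!notch %in% colnames(matrix))
    stop("anchor pathway column '", notch, "' absent from alteration matrix")
  if (!all(ddr %in% colnames(matrix)))
    stop("DDR name(s) absent from alteration matrix: ",
         paste(setdiff(ddr, colnames(matrix)), collapse = ", "))
  notch_altered <- matrix[, notch]
  n_ddr <- if (length(ddr) == 1L) as.integer(matrix[, ddr])
           else as.integer(rowSums(matrix[, ddr, drop = FALSE]))
  co_ddr <- n_ddr >= 2L
  good <- notch_altered & co_ddr
  three <- ifelse(good, "CoPath",
                  ifelse(notch_altered | co_ddr, "SinglePath", "WildType"))
  data.frame(
    sample_id = rownames(matrix),
    notch_altered = unname(notch_altered),
    n_ddr_altered = n_ddr,
    co_ddr = unname(co_ddr),
    binary_label = factor(ifelse(good, "GoodBenefit", "BadBenefit"),
                          levels = c("GoodBenefit", "BadBenefit")),
    three_group_label = factor(three,
                               levels = c("CoPath", "SinglePath",
                                          "WildType")),
    stringsAsFactors = FALSE
  )
}

#' Pathway alteration prevalence by response group
#'
#' Within-group percentage of altered samples per pathway, with a two-sided
#' Fisher exact p on the altered-by-response 2x2 table and a
#' Benjamini-Hochberg q across pathways.
#'
#' @param matrix Alteration matrix.
#' @param clinical Clinical data frame with `sample_id` and `response`.
#' @return Data frame: `pathway`, `n_dcb`, `n_ndb`, `pct_dcb`, `pct_ndb`,
#'   `p_value`, `q_value`.
#' @export
pathway_prevalence_by_response <- function(matrix, clinical) {
  resp <- clinical$response[match(rownames(matrix), clinical$sample_id)]
  dcb <- resp == "DCB"
  ndb <- resp == "NDB"
  if (!any(dcb) || !any(ndb))
    stop("both DCB and NDB groups must be non-empty")
  out <- do.call(rbind, lapply(colnames(matrix), function(p) {
    alt <- matrix[, p]
    tab <- rbind(c(sum(alt & dcb), sum(alt & ndb)),
                 c(sum(!alt & dcb), sum(!alt & ndb)))
    data.frame(
      pathway = p,
      n_dcb = sum(alt & dcb), n_ndb = sum(alt & ndb),
      pct_dcb = 100 * sum(alt & dcb) / sum(dcb),
      pct_ndb = 100 * sum(alt & ndb) / sum(ndb),
      p_value = fisher_exact_2x2(tab)$p_value,
      stringsAsFactors = FALSE
    )
  }))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Co-occurrence enrichment of pathways with an anchor pathway
#'
#' For each pathway P other than the anchor, tests whether the joint
#' alteration (anchor AND P) is enriched in the DCB response group: the 2x2
#' table is joint-altered yes/no by DCB/NDB. The alternative construction
#' (`construction = "within_anchor"`) instead tests P altered vs not among
#' anchor-altered samples only. Odds ratios use the Haldane-Anscombe +0.5
#' correction on all four cells whenever any cell is zero, keeping the log2
#' odds ratio finite.
#'
#' @param matrix Alteration matrix.
#' @param clinical Clinical data frame with `response`.
#' @param anchor Anchor pathway name (default `"NOTCH"`).
#' @param construction `"joint_vs_response"` (default) or `"within_anchor"`.
#' @return Data frame: `pathway`, the four cell counts `a`,`b`,`c`,`d`,
#'   `odds_ratio`, `log2_odds_ratio`, `p_value`, `neg_log2_p`, `q_value`.
#' @export
notch_cooccurrence_enrichment <- function(matrix, clinical,
                                          anchor = "NOTCH",
                                          construction =
                                            c("joint_vs_response",
                                              "within_anchor")) {
  construction <- match.arg(construction)
  if (!anchor %in% colnames(matrix))
    stop("anchor pathway '", anchor, "' absent from alteration matrix")
  resp <- clinical$response[match(rownames(matrix), clinical$sample_id)]
  keep <- resp %in% c("DCB", "NDB")
  m <- matrix[keep, , drop = FALSE]
  resp <- resp[keep]
  anchor_alt <- m[, anchor]
  others <- setdiff(colnames(m), anchor)
  out <- do.call(rbind, lapply(others, function(p) {
    if (construction == "joint_vs_response") {
      joint <- anchor_alt & m[, p]
      tab <- rbind(c(sum(joint & resp == "DCB"), sum(joint & resp == "NDB")),
                   c(sum(!joint & resp == "DCB"),
                     sum(!joint & resp == "NDB")))
    } else {
      sub <- m[anchor_alt, , drop = FALSE]
      subresp <- resp[anchor_alt]
      alt <- sub[, p]
      tab <- rbind(c(sum(alt & subresp == "DCB"),
                     sum(alt & subresp == "NDB")),
                   c(sum(!alt & subresp == "DCB"),
                     sum(!alt & subresp == "NDB")))
    }
    or <- odds_ratio_2x2(tab)
    data.frame(pathway = p,
               a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
               odds_ratio = or, log2_odds_ratio = log2(or),
               p_value = fisher_exact_2x2(tab)$p_value,
               stringsAsFactors = FALSE)
  }))
  out$neg_log2_p <- -log2(out$p_value)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Sample odds ratio of a 2x2 table with zero-cell correction
#'
#' Cross-product ratio `(a*d)/(b*c)`; if any cell is zero, 0.5 is added to
#' all four cells (Haldane-Anscombe) so the ratio and its log are finite.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return Positive scalar odds ratio.
#' @export
odds_ratio_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)),
            all(table >= 0))
  t2 <- if (any(table == 0)) table + 0.5 else table
  (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
}

#' Per-gene mutation frequency across a cohort
#'
#' Number and percentage of clinical samples carrying at least one
#' non-synonymous mutation in each gene (a sample counts once per gene no
#' matter how many hits).
#'
#' @param cohort A [cohort()].
#' @param genes Optional character filter; default all mutated genes.
#' @param classes Non-synonymous class set.
#' @return Data frame: `gene`, `n_mutated`, `pct`, sorted by decreasing
#'   frequency then gene name.
#' @export
gene_mutation_frequency <- function(cohort, genes = NULL,
                                    classes = nonsynonymous_classes()) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort$clinical)
  mut <- cohort$mutations
  if (nrow(mut))
    mut <- mut[is_nonsynonymous(mut$variant_class, classes), , drop = FALSE]
  universe <- if (is.null(genes)) sort(unique(mut$gene))
              else toupper(genes)
  pairs <- unique(mut[mut$gene %in% universe, c("sample_id", "gene")])
  counts <- table(factor(pairs$gene, levels = universe))
  out <- data.frame(gene = universe, n_mutated = as.integer(counts),
                    pct = if (n > 0) 100 * as.integer(counts) / n else 0,
                    stringsAsFactors = FALSE)
  out[order(-out$n_mutated, out$gene), , drop = FALSE]
}
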