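test_that("ssGSEA score matches a hand-enumerated running sum", {
  values <- c(A = 5, B = 4, C = 3, D = 2, E = 1)
  # signature = top two genes, alpha = 0: unweighted KS running sum.
  # in-set steps 1/2 at positions 1,2; out-set steps 1/3 at 3,4,5:
  # P_in  = 0.5, 1, 1,   1,   1
  # P_out = 0,   0, 1/3, 2/3, 1
  # ES = sum of differences = 0.5 + 1 + 2/3 + 1/3 + 0 = 2.5
  expect_equal(ssgsea_score(values, c("A", "B"), alpha = 0), 2.5)
  # bottom two genes mirror to -2.5
  expect_equal(ssgsea_score(values, c("D", "E"), alpha = 0), -2.5)
  # signature covering every gene: no out-of-set mass, 0 by convention
  expect_equal(ssgsea_score(values, names(values)), 0)
  expect_warning(na <- ssgsea_score(values, "A"), "overlap")
  expect_true(is.na(na))
})

test_that("ssGSEA depends only on within-sample ranks", {
  set.seed(40)
  values <- setNames(rnorm(50), sprintf("G%02d", 1:50))
  sig <- sample(names(values), 10)
  for (a in c(0, 0.25)) {
    es <- ssgsea_score(values, sig, alpha = a)
    es_cubed <- ssgsea_score(values^3, sig, alpha = a)
    es_exp <- ssgsea_score(setNames(exp(values), names(values)), sig,
                           alpha = a)
    expect_equal(es_cubed, es)
    expect_equal(es_exp, es)
  }
})

test_that("cohort scoring is consistent and equivariant", {
  set.seed(41)
  expr <- matrix(rnorm(200), nrow = 20,
                 dimnames = list(sprintf("G%02d", 1:20),
                                 sprintf("S%02d", 1:10)))
  sigs <- list(SIG1 = sprintf("G%02d", 1:5))
  scores <- score_cohort(expr, sigs, alpha = 0.25)
  expect_equal(dim(scores), c(10L, 1L))
  expect_equal(scores["S03", "SIG1"],
               ssgsea_score(expr[, "S03"], sigs$SIG1, alpha = 0.25))

  perm <- sample(ncol(expr))
  scores_perm <- score_cohort(expr[, perm], sigs, alpha = 0.25)
  expect_equal(scores_perm[colnames(expr), ], scores[, 1])

  expect_error(score_cohort(expr, list(BAD = "G01")), "every signature")
})

test_that("planted signature shift raises scores in shifted samples", {
  set.seed(11)
  genes <- sprintf("G%03d", 1:200)
  sig <- genes[1:15]
  n <- 60
  expr <- matrix(rnorm(200 * n), nrow = 200,
                 dimnames = list(genes, sprintf("S%02d", 1:n)))
  shifted <- 1:30
  expr[sig, shifted] <- expr[sig, shifted] + 2
  scores <- score_cohort(expr, list(SIG = sig), alpha = 0.25)
  p <- wilcox.test(scores[shifted, 1], scores[-shifted, 1],
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("immune clustering recovers separated blobs and orders labels", {
  set.seed(3)
  centers <- c(0, 3, 6)
  truth <- rep(1:3, each = 10)
  scores <- matrix(rnorm(30 * 5, mean = centers[truth], sd = 0.1),
                   nrow = 30,
                   dimnames = list(sprintf("S%02d", 1:30),
                                   paste0("CT", 1:5)))
  cl <- cluster_immune(scores, k = 3)
  expect_equal(ari(cl$cluster, truth), 1.0)
  # labels ordered by descending mean score
  means <- tapply(rowMeans(scores), cl$cluster, mean)
  expect_true(means["immune-high"] > means["immune-intermediate"])
  expect_true(means["immune-intermediate"] > means["immune-low"])

  one <- cluster_immune(scores, k = 1)
  expect_equal(length(unique(one$cluster)), 1L)
  expect_error(cluster_immune(scores[1:2, ], k = 3), "exceeds")

  # ward.D merge heights are non-decreasing
  set.seed(44)
  rnd <- matrix(rnorm(40 * 4), nrow = 40)
  hc <- attr(cluster_immune(`dimnames<-`(rnd, list(paste0("R", 1:40),
                                                   paste0("C", 1:4))),
                            k = 3), "hclust")
  expect_true(all(diff(hc$height) >= -1e-10))

  # sample order does not change the labeling (up to the fixed rule)
  perm <- sample(nrow(scores))
  cl2 <- cluster_immune(scores[perm, ], k = 3)
  expect_equal(cl2$cluster[match(cl$sample_id, cl2$sample_id)],
               cl$cluster)
})

test_that("ranked list: z-normalization identity and planted top gene", {
  set.seed(45)
  expr <- matrix(rnorm(50 * 20), nrow = 50,
                 dimnames = list(sprintf("G%02d", 1:50),
                                 sprintf("S%02d", 1:20)))
  strata <- data.frame(
    sample_id = colnames(expr),
    binary_label = factor(rep(c("GoodBenefit", "BadBenefit"), each = 10),
                          levels = c("GoodBenefit", "BadBenefit")),
    stringsAsFactors = FALSE)
  expr["G01", 1:10] <- expr["G01", 1:10] + 10
  ranked <- group_rank_list(expr, strata)
  expect_equal(ranked$gene[1], "G01")
  # mean z across ALL samples is 0 for every gene
  z <- (expr - rowMeans(expr)) /
    sqrt(rowMeans((expr - rowMeans(expr))^2))
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  # metric equals mean z in the focal stratum
  expect_equal(ranked$metric[ranked$gene == "G05"],
               mean(z["G05", 1:10]))

  flat <- expr
  flat["G02", ] <- 7
  expect_warning(r2 <- group_rank_list(flat, strata), "zero-variance")
  expect_equal(r2$metric[r2$gene == "G02"], 0)
})

test_that("pre-ranked GSEA: planted enrichment, null behavior, determinism", {
  set.seed(46)
  genes <- sprintf("G%03d", 1:200)
  metric <- sort(rnorm(200, sd = 1) + seq(2, -2, length.out = 200),
                 decreasing = TRUE)
  names(metric) <- genes
  sigs <- list(TOP = genes[1:10],
               SPREAD = genes[seq(5, 200, by = 20)])
  res <- preranked_gsea(metric, sigs, n_perm = 500, seed = 5)
  top <- res[res$signature == "TOP", ]
  expect_gt(top$es, 0)
  expect_gt(top$nes, 0)
  expect_equal(top$call, "enriched")
  spread <- res[res$signature == "SPREAD", ]
  expect_equal(spread$call, "ns")

  res2 <- preranked_gsea(metric, sigs, n_perm = 500, seed = 5)
  expect_identical(res, res2)

  # enriched/depleted calls obey the q/NES rule
  expect_true(all(res$call[res$q_value < 0.10 & res$nes > 0] == "enriched"))
  expect_true(all(res$call[res$q_value >= 0.10] == "ns"))
})

test_that("pre-ranked enrichment scores agree with fgsea", {
  skip_if_not_installed("fgsea")
  set.seed(47)
  genes <- sprintf("G%03d", 1:150)
  metric <- setNames(rnorm(150), genes)
  sigs <- list(A = genes[1:12], B = genes[seq(3, 150, 11)],
               C = sample(genes, 20))
  ours <- preranked_gsea(metric, sigs, n_perm = 500, seed = 5)
  ref <- suppressWarnings(
    fgsea::fgseaSimple(sigs, sort(metric, decreasing = TRUE),
                       nperm = 500, scoreType = "std"))
  for (nm in names(sigs)) {
    expect_equal(ours$es[ours$signature == nm],
                 ref$ES[ref$pathway == nm], tolerance = 1e-6)
  }
})

test_that("per-gene contrasts report planted effects and BH dominance", {
  set.seed(2)
  expr <- matrix(rnorm(30 * 40), nrow = 30,
                 dimnames = list(sprintf("G%02d", 1:30),
                                 sprintf("S%02d", 1:40)))
  strata <- data.frame(
    sample_id = colnames(expr),
    binary_label = factor(rep(c("GoodBenefit", "BadBenefit"), each = 20),
                          levels = c("GoodBenefit", "BadBenefit")),
    stringsAsFactors = FALSE)
  expr["G01", 1:20] <- expr["G01", 1:20] + 3
  out <- compare_gene_expression(expr, strata,
                                 c("G01", "G05", "NOTPRESENT"))
  expect_lt(out$p_value[out$gene == "G01"], 0.001)
  expect_gt(out$mean_good[out$gene == "G01"],
            out$mean_bad[out$gene == "G01"])
  expect_false(out$present[out$gene == "NOTPRESENT"])
  ok <- out$present
  expect_true(all(out$q_value[ok] >= out$p_value[ok]))
})
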