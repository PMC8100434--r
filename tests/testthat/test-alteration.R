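test_that("alteration matrix equals the brute-force triple loop", {
  set.seed(20)
  for (i in 1:20) {
    co <- random_toy_cohort(n = sample(5:15, 1))
    m <- build_alteration_matrix(co, toy_catalog())
    expect_identical(unclass(m)[, ], brute_force_alteration(co, toy_catalog()))
  }
})

test_that("alteration rule: >=1 non-synonymous hit, all-false rows legal", {
  clinical <- data.frame(sample_id = c("A", "B"), response = "DCB",
                         pfs_months = 1, pfs_event = 1,
                         stringsAsFactors = FALSE)
  mutations <- data.frame(sample_id = "A", gene = "NOTCH1",
                          variant_class = "Missense_Mutation",
                          protein_change = NA_character_,
                          stringsAsFactors = FALSE)
  m <- build_alteration_matrix(cohort(clinical, mutations),
                               default_catalog())
  expect_true(m["A", "NOTCH"])
  expect_false(any(m["A", ddr_names(default_catalog())]))
  expect_false(any(m["B", ]))

  silent <- mutations
  silent$variant_class <- "Silent"
  m2 <- build_alteration_matrix(cohort(clinical, silent), default_catalog())
  expect_false(any(m2))
})

test_that("stratum labels match the exhaustive truth table", {
  for (notch in c(FALSE, TRUE)) {
    for (n_ddr in 0:3) {
      m <- matrix(FALSE, 1, 5,
                  dimnames = list("S", c("NOTCH", "D1", "D2", "D3", "D4")))
      m[1, "NOTCH"] <- notch
      if (n_ddr > 0) m[1, paste0("D", seq_len(n_ddr))] <- TRUE
      s <- assign_strata(m, ddr = paste0("D", 1:4))
      good <- notch && n_ddr >= 2
      expect_equal(s$co_ddr, n_ddr >= 2)
      expect_equal(s$n_ddr_altered, n_ddr)
      expect_equal(as.character(s$binary_label),
                   if (good) "GoodBenefit" else "BadBenefit")
      expect_equal(as.character(s$three_group_label),
                   if (good) "CoPath"
                   else if (notch || n_ddr >= 2) "SinglePath"
                   else "WildType")
    }
  }
  expect_error(assign_strata(matrix(FALSE, 1, 1,
                                    dimnames = list("S", "D1")),
                             ddr = "D1"), "NOTCH")
})

test_that("strata partition the cohort and labels agree across rules", {
  set.seed(21)
  for (i in 1:10) {
    co <- random_toy_cohort(n = 20)
    m <- build_alteration_matrix(co, toy_catalog())
    s <- assign_strata(m)
    expect_equal(nrow(s), 20L)
    expect_false(any(is.na(s$binary_label)))
    expect_false(any(is.na(s$three_group_label)))
    expect_equal(sum(s$binary_label == "GoodBenefit"),
                 sum(s$three_group_label == "CoPath"))
    expect_equal(sum(s$three_group_label == "WildType"),
                 sum(!s$notch_altered & !s$co_ddr))
  }
})

test_that("adding mutations never un-alters: monotonicity", {
  set.seed(22)
  co <- random_toy_cohort(n = 15)
  m1 <- build_alteration_matrix(co, toy_catalog())
  s1 <- assign_strata(m1)
  extra <- data.frame(
    sample_id = sample(co$clinical$sample_id, 10, TRUE),
    gene = sample(c("N1", "M1", "H2"), 10, TRUE),
    variant_class = "Missense_Mutation",
    protein_change = NA_character_, stringsAsFactors = FALSE)
  co2 <- cohort(co$clinical, rbind(co$mutations, extra))
  m2 <- build_alteration_matrix(co2, toy_catalog())
  s2 <- assign_strata(m2)
  expect_true(all(m2[m1]))
  expect_true(all(s2$n_ddr_altered >= s1$n_ddr_altered))
  was_good <- s1$binary_label == "GoodBenefit"
  expect_true(all(s2$binary_label[was_good] == "GoodBenefit"))
})

test_that("prevalence percentages equal direct count ratios", {
  set.seed(23)
  for (i in 1:10) {
    co <- random_toy_cohort(n = 16)
    if (!all(c("DCB", "NDB") %in% co$clinical$response)) next
    m <- build_alteration_matrix(co, toy_catalog())
    prev <- pathway_prevalence_by_response(m, co$clinical)
    for (j in seq_len(nrow(prev))) {
      p <- prev$pathway[j]
      dcb_ids <- co$clinical$sample_id[co$clinical$response == "DCB"]
      ndb_ids <- co$clinical$sample_id[co$clinical$response == "NDB"]
      expect_equal(prev$pct_dcb[j], 100 * sum(m[dcb_ids, p]) /
                     length(dcb_ids))
      expect_equal(prev$pct_ndb[j], 100 * sum(m[ndb_ids, p]) /
                     length(ndb_ids))
    }
  }
})

test_that("a universally altered pathway gives 100/100 and p = 1", {
  clinical <- data.frame(sample_id = c("A", "B", "C", "D"),
                         response = c("DCB", "DCB", "NDB", "NDB"),
                         pfs_months = 1, pfs_event = 1,
                         stringsAsFactors = FALSE)
  mutations <- data.frame(sample_id = c("A", "B", "C", "D"), gene = "N1",
                          variant_class = "Missense_Mutation",
                          protein_change = NA_character_,
                          stringsAsFactors = FALSE)
  m <- build_alteration_matrix(cohort(clinical, mutations), toy_catalog())
  prev <- pathway_prevalence_by_response(m, clinical)
  notch <- prev[prev$pathway == "NOTCH", ]
  expect_equal(notch$pct_dcb, 100)
  expect_equal(notch$pct_ndb, 100)
  expect_equal(notch$p_value, 1)
})

test_that("co-occurrence enrichment odds ratios and corrections", {
  expect_equal(odds_ratio_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(odds_ratio_2x2(matrix(c(8, 2, 2, 8), 2)), 16)
  corrected <- odds_ratio_2x2(matrix(c(4, 2, 0, 6), 2, byrow = FALSE))
  expect_equal(corrected, (4.5 * 6.5) / (0.5 * 2.5))
  expect_true(is.finite(log2(corrected)))

  set.seed(24)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(odds_ratio_2x2(tab),
                 (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
  }
})

test_that("enrichment table construction against a hand-built cohort", {
  # 8 samples: NOTCH+MMR jointly altered in 3 of 4 DCB and 0 of 4 NDB
  clinical <- data.frame(sample_id = sprintf("S%d", 1:8),
                         response = rep(c("DCB", "NDB"), each = 4),
                         pfs_months = 1, pfs_event = 1,
                         stringsAsFactors = FALSE)
  mk <- function(s, g) data.frame(sample_id = s, gene = g,
                                  variant_class = "Missense_Mutation",
                                  protein_change = NA_character_,
                                  stringsAsFactors = FALSE)
  mutations <- rbind(mk(c("S1", "S2", "S3"), "N1"),
                     mk(c("S1", "S2", "S3"), "M1"),
                     mk("S5", "N1"))
  m <- build_alteration_matrix(cohort(clinical, mutations), toy_catalog())
  enr <- notch_cooccurrence_enrichment(m, clinical)
  mmr <- enr[enr$pathway == "MMR", ]
  expect_equal(c(mmr$a, mmr$b, mmr$c, mmr$d), c(3, 0, 1, 4))
  expect_equal(mmr$odds_ratio, (3.5 * 4.5) / (0.5 * 1.5))
  expect_equal(mmr$p_value,
               fisher_enum_p(matrix(c(3, 1, 0, 4), 2)))
  expect_equal(mmr$neg_log2_p, -log2(mmr$p_value))
  # within-anchor construction restricted to the 4 NOTCH-altered samples
  enr2 <- notch_cooccurrence_enrichment(m, clinical,
                                        construction = "within_anchor")
  mmr2 <- enr2[enr2$pathway == "MMR", ]
  expect_equal(c(mmr2$a, mmr2$b, mmr2$c, mmr2$d), c(3, 0, 0, 1))
})

test_that("gene frequencies: zeros, percentages, pathway consistency", {
  set.seed(25)
  co <- random_toy_cohort(n = 20)
  freq <- gene_mutation_frequency(co, genes = c("N1", "NEVERMUT"))
  never <- freq[freq$gene == "NEVERMUT", ]
  expect_equal(never$n_mutated, 0L)
  expect_equal(never$pct, 0)

  clinical <- data.frame(sample_id = sprintf("P%03d", 1:100),
                         response = "DCB", pfs_months = 1, pfs_event = 1,
                         stringsAsFactors = FALSE)
  mutations <- data.frame(sample_id = sprintf("P%03d", 1:7), gene = "N1",
                          variant_class = "Missense_Mutation",
                          protein_change = NA_character_,
                          stringsAsFactors = FALSE)
  f2 <- gene_mutation_frequency(cohort(clinical, mutations))
  expect_equal(f2$pct[f2$gene == "N1"], 7)

  m <- build_alteration_matrix(co, toy_catalog())
  allfreq <- gene_mutation_frequency(co)
  for (p in catalog_names(toy_catalog())) {
    genes <- toy_catalog()$sets[[p]]$genes
    per_gene <- allfreq$n_mutated[allfreq$gene %in% genes]
    if (length(per_gene))
      expect_gte(sum(m[, p]), max(per_gene))
  }
})
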