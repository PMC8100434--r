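test_that("Kaplan-Meier estimate matches closed forms and the hand product", {
  fit <- km_fit(1:4, rep(1, 4))
  expect_equal(fit$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(fit$median, 2)

  flat <- km_fit(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(flat$survival == 1))
  expect_true(is.na(flat$median))

  # 10-subject mixed-censoring fixture vs the definitional product
  times <- c(1, 2, 2, 3, 4, 4, 5, 6, 8, 9)
  events <- c(1, 1, 0, 1, 1, 0, 0, 1, 1, 0)
  fit <- km_fit(times, events)
  oracle <- km_oracle(times, events)
  at_events <- match(oracle$times, fit$times)
  expect_equal(fit$survival[at_events], oracle$survival)
  expect_equal(fit$median, oracle$median)

  # product formula on random fixtures
  set.seed(30)
  for (i in 1:10) {
    tt <- sample(1:12, 15, replace = TRUE)
    ev <- rbinom(15, 1, 0.7)
    if (sum(ev) == 0) next
    f <- km_fit(tt, ev)
    o <- km_oracle(tt, ev)
    expect_equal(f$survival[match(o$times, f$times)], o$survival)
  }
  expect_error(km_fit(numeric(0), logical(0)), "no subjects")
})

test_that("log-rank test: symmetry, degenerate input, hand summation", {
  ta <- c(1, 3, 5, 7, 9); ea <- c(1, 1, 0, 1, 0)
  same <- logrank_test(ta, ea, ta, ea)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  expect_warning(nul <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
                 "no events")
  expect_equal(nul$p_value, 1)

  tb <- c(2, 4, 6, 8); eb <- c(1, 0, 1, 1)
  got <- logrank_test(ta, ea, tb, eb)
  oracle <- logrank_oracle(ta, ea, tb, eb)
  expect_equal(got$statistic, oracle$statistic, tolerance = 1e-8)
  expect_equal(got$p_value, oracle$p_value, tolerance = 1e-8)

  flipped <- logrank_test(tb, eb, ta, ea)
  expect_equal(flipped$statistic, got$statistic, tolerance = 1e-12)
  expect_equal(flipped$p_value, got$p_value, tolerance = 1e-12)
})

test_that("Cox fit: symmetry zero, brute-force likelihood maximizer", {
  # identical time/event multisets in both covariate groups -> coef 0
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- rep(c(0, 1), each = 4)
  fit <- cox_fit(data.frame(x = x), tt, ev)
  expect_equal(fit$terms$coef, 0, tolerance = 1e-6)
  expect_equal(fit$terms$hr, 1, tolerance = 1e-6)

  # 6 subjects, distinct event times: maximizer of the explicit partial
  # likelihood found by golden-section search
  tt6 <- c(1, 2, 3, 4, 5, 6)
  ev6 <- c(1, 1, 1, 0, 1, 1)
  x6 <- c(1, 0, 1, 1, 0, 0)
  fit6 <- cox_fit(data.frame(x = x6), tt6, ev6)
  opt <- optimize(function(b) cox_pl_1d(b, x6, tt6, ev6),
                  interval = c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(fit6$terms$coef, opt$maximum, tolerance = 1e-4)
  expect_equal(fit6$loglik, opt$objective, tolerance = 1e-6)

  # returned coefficient is a local optimum on a surrounding grid
  grid <- fit6$terms$coef + seq(-0.5, 0.5, by = 0.05)
  ll <- vapply(grid, function(b) cox_pl_1d(b, x6, tt6, ev6), numeric(1))
  expect_true(all(fit6$loglik >= ll - 1e-10))

  expect_equal(fit6$terms$ci_low,
               exp(fit6$terms$coef - 1.96 * fit6$terms$se))
  expect_equal(fit6$terms$ci_high,
               exp(fit6$terms$coef + 1.96 * fit6$terms$se))

  expect_error(cox_fit(data.frame(x = rep(1, 4)), 1:4, rep(1, 4)),
               "constant covariate")
  expect_error(cox_fit(data.frame(x = c(0, 1)), 1:2, c(0, 0)), "no events")
})

test_that("Cox separation is flagged, not silently returned", {
  # perfectly separated: all events in one group, early
  tt <- c(1, 2, 3, 10, 11, 12)
  ev <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_fit(data.frame(x = x), tt, ev)
  expect_true(fit$separation)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  set.seed(32)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_enum_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("rank-sum test: exact enumeration, approximation agreement", {
  exact <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(exact$p_value, 0.1)
  expect_equal(exact$method, "wilcoxon_exact")

  set.seed(33)
  for (i in 1:10) {
    x <- runif(sample(3:8, 1)); y <- runif(sample(3:8, 1))
    expect_equal(rank_sum_test(x, y)$p_value, wilcox_enum_p(x, y),
                 tolerance = 1e-10)
  }
  # exact and normal-approximation branches agree closely at n = 9
  for (i in 1:5) {
    x <- runif(9); y <- runif(9)
    appr <- rank_sum_test(x, y)$p_value
    ex <- wilcox_enum_p(x, y)
    expect_lt(abs(appr - ex), 0.01)
  }

  expect_warning(t0 <- rank_sum_test(c(1, 1), c(1, 1), mode = "t"),
                 "zero variance")
  expect_equal(t0$p_value, 1)
  tt <- rank_sum_test(rnorm(10), rnorm(10) + 5, mode = "t")
  expect_lt(tt$p_value, 0.001)
})

test_that("summary table reproduces within-column percentages", {
  cl <- table1_clinical()
  tab <- cohort_summary_table(cl)
  get <- function(v, l, col) tab[tab$variable == v & tab$level == l, col]
  expect_equal(get("response", "DCB", "pct_overall"), 48.1)
  expect_equal(get("histology", "Squamous", "pct_DCB"), 86.3)
  expect_equal(get("histology", "Squamous", "n_overall"), 87)
  expect_equal(get("best_response", "CR/PR", "pct_DCB"), 66.7)
  expect_equal(get("pdl1", "Strong", "pct_DCB"), 27.5)
  expect_equal(get("smoking", "Current/Former", "pct_overall"), 80.2)
  expect_equal(get("best_response", "PD/NE", "pct_NDB"), 65.5)
  # Unknown PD-L1 shown in counts but excluded from the association test
  expect_equal(get("pdl1", "Unknown", "n_overall"), 9)
  p_pdl1 <- tab$p_value[tab$variable == "pdl1"][1]
  sub <- cl[cl$pdl1 != "Unknown", ]
  expect_equal(p_pdl1,
               suppressWarnings(chisq.test(table(sub$pdl1, sub$response),
                                           correct = FALSE)$p.value))
})

test_that("pathway forest: consistency with cox_fit and skip rules", {
  set.seed(34)
  co <- random_toy_cohort(n = 30)
  m <- build_alteration_matrix(co, toy_catalog())
  # force one constant pathway
  m[, "RTK_RAS"] <- FALSE
  forest <- pathway_forest(m, co$clinical)
  expect_true(!is.na(forest$skipped[forest$term == "RTK_RAS"]))
  for (term in c("NOTCH", "MMR")) {
    x <- as.integer(m[, term])
    if (sum(x) %in% c(0, nrow(m))) next
    direct <- cox_fit(data.frame(z = x), co$clinical$pfs_months,
                      co$clinical$pfs_event)
    row <- forest[forest$term == term, ]
    expect_equal(row$hr, direct$terms$hr, tolerance = 1e-10)
    expect_equal(row$p, direct$terms$p, tolerance = 1e-10)
  }
})

test_that("rounding is half away from zero at one decimal", {
  expect_equal(round_half_up(27.45), 27.5)
  expect_equal(round_half_up(82.05), 82.1)
  expect_equal(round_half_up(-2.25), -2.3)
  expect_equal(round_half_up(2.24), 2.2)
})
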