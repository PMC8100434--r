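#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] exposing the curve as plain
#' vectors. Censored subjects leave the risk set without a step. The median
#' is the smallest time at which the survival estimate is at or below 0.5,
#' `NA` if the curve never gets there (never extrapolated).
#'
#' @param times Non-negative follow-up times.
#' @param events Logical/0-1 event indicators (TRUE = event observed).
#' @return Object of class `survival_curve`: list with `times`, `survival`,
#'   `at_risk`, `n_events`, `median`, `n`.
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0L) stop("no subjects")
  stopifnot(length(times) == length(events), all(times >= 0))
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  surv <- fit$surv
  med <- if (any(surv <= 0.5)) min(fit$time[surv <= 0.5]) else NA_real_
  structure(list(times = fit$time, survival = surv, at_risk = fit$n.risk,
                 n_events = fit$n.event, median = med, n = length(times)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n = %d, events = %d, median = %s\n", x$n,
              sum(x$n_events), ifelse(is.na(x$median), "not reached",
                                      format(x$median))))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Chi-square statistic on one degree of freedom from observed-minus-
#' expected events with hypergeometric variance across distinct event times
#' (via [survival::survdiff()]). When neither group has an event the test is
#' undefined; a warning is issued and p = 1 returned.
#'
#' @param times_a,events_a Follow-up and event indicators, group A.
#' @param times_b,events_b Same, group B.
#' @return List of class `copath_test`: `statistic`, `p_value`, `method`,
#'   `n` (per-group sizes).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be non-empty")
  ev <- c(as.integer(as.logical(events_a)), as.integer(as.logical(events_b)))
  tt <- c(times_a, times_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  if (sum(ev) == 0L) {
    warning("no events in either group; log-rank test undefined, p = 1")
    return(structure(list(statistic = 0, p_value = 1, method = "log-rank",
                          n = c(A = length(times_a), B = length(times_b))),
                     class = "copath_test"))
  }
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ grp)
  structure(list(statistic = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1,
                                         lower.tail = FALSE),
                 method = "log-rank",
                 n = c(A = length(times_a), B = length(times_b))),
            class = "copath_test")
}

#' @export
print.copath_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie correction by default
#' (via [survival::coxph()], Newton iterations, coefficient tolerance 1e-8,
#' at most 50 iterations). Standard errors come from the inverse observed
#' information; 95\% CIs are `exp(coef +/- 1.96 * se)`. Monotone likelihood
#' (separation) is detected from runaway coefficients/standard errors and
#' flagged rather than silently returned.
#'
#' @param design Data frame or matrix of numeric covariates (booleans coded
#'   0/1, categoricals pre-encoded).
#' @param times Follow-up times.
#' @param events Event indicators.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_result`: data frame `terms` (one row per
#'   covariate: `term`, `coef`, `hr`, `se`, `ci_low`, `ci_high`, `p`), plus
#'   `loglik`, `iter`, `converged`, `separation`, `n`, `n_events`.
#' @export
cox_fit <- function(design, times, events, tie_method = c("efron",
                                                          "breslow")) {
  tie_method <- match.arg(tie_method)
  design <- as.data.frame(design)
  stopifnot(nrow(design) == length(times), length(times) == length(events))
  events <- as.integer(as.logical(events))
  if (sum(events) == 0L) stop("no events; Cox model is not identifiable")
  if (nrow(design) < ncol(design) + 1L)
    stop("fewer subjects than covariates")
  const <- vapply(design, function(x) length(unique(x)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(design)[const],
                                          collapse = ", "))
  dat <- cbind(data.frame(.time = times, .event = events), design)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(design)), collapse = " + ")))
  warned <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = tie_method,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  coefs <- s$coefficients
  terms <- data.frame(
    term = names(design),
    coef = unname(coefs[, "coef"]),
    hr = unname(exp(coefs[, "coef"])),
    se = unname(coefs[, "se(coef)"]),
    ci_low = unname(exp(coefs[, "coef"] - 1.96 * coefs[, "se(coef)"])),
    ci_high = unname(exp(coefs[, "coef"] + 1.96 * coefs[, "se(coef)"])),
    p = unname(coefs[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  separation <- any(abs(terms$coef) > 10 | terms$se > 100) ||
    any(grepl("infinite|converged before", warned))
  converged <- fit$iter < 50 && !any(grepl("did not converge", warned))
  if (!converged) warning("Cox fit did not converge; result flagged")
  structure(list(terms = terms, loglik = fit$loglik[2], iter = fit$iter,
                 converged = converged, separation = separation,
                 n = fit$n, n_events = fit$nevent,
                 tie_method = tie_method),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d, loglik = %.3f%s\n", x$n,
              x$n_events, x$loglik,
              if (x$separation) " [separation flagged]" else ""))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

# Encode a clinical covariate column to numeric design columns
# (numeric passthrough; logical -> 0/1; categorical -> treatment dummies).
.encode_covariate <- function(x, name) {
  if (is.numeric(x)) return(stats::setNames(data.frame(x), name))
  if (is.logical(x)) return(stats::setNames(data.frame(as.integer(x)), name))
  f <- factor(x)
  if (nlevels(f) < 2L) stop("constant covariate(s): ", name)
  mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(mm) <- paste0(name, levels(f)[-1])
  as.data.frame(mm)
}

#' Univariate Cox forest over pathways
#'
#' One univariate Cox fit per pathway (altered vs not) plus the
#' NOTCH+/co-DDR+ (GoodBenefit) indicator; optionally one multivariable fit
#' of the GoodBenefit indicator adjusted for the given clinical covariates.
#' Pathways altered in none or all samples are skipped with the reason
#' recorded.
#'
#' @param matrix Alteration matrix.
#' @param clinical Clinical data frame.
#' @param endpoint `"PFS"` or `"OS"`.
#' @param adjust Optional character vector of clinical covariate columns for
#'   the multivariable fit (e.g. `c("tmb", "histology", "smoking", "pdl1")`;
#'   `tmb` is log1p-scaled).
#' @param strata Optional output of [assign_strata()]; computed from the
#'   matrix when absent.
#' @return Data frame: `term`, `model`, `n`, `n_altered`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `skipped` (reason or NA).
#' @export
pathway_forest <- function(matrix, clinical, endpoint = c("PFS", "OS"),
                           adjust = NULL, strata = NULL) {
  endpoint <- match.arg(endpoint)
  cl <- clinical[match(rownames(matrix), clinical$sample_id), , drop = FALSE]
  if (endpoint == "PFS") {
    times <- cl$pfs_months; events <- cl$pfs_event
  } else {
    times <- cl$os_months; events <- cl$os_event
  }
  ok <- !is.na(times) & !is.na(events)
  if (is.null(strata)) strata <- assign_strata(matrix)
  good <- strata$binary_label[match(rownames(matrix),
                                    strata$sample_id)] == "GoodBenefit"
  indicators <- cbind(as.data.frame(matrix),
                      GoodBenefit = good)
  rows <- lapply(names(indicators), function(term) {
    x <- as.integer(indicators[[term]])[ok]
    base <- data.frame(term = term, model = "univariate",
                       n = sum(ok), n_altered = sum(x),
                       hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p = NA_real_, skipped = NA_character_,
                       stringsAsFactors = FALSE)
    if (sum(x) == 0L || sum(x) == length(x)) {
      base$skipped <- sprintf("altered in %s samples",
                              if (sum(x) == 0L) "no" else "all")
      return(base)
    }
    fit <- cox_fit(stats::setNames(data.frame(x), term),
                   times[ok], events[ok])
    base$hr <- fit$terms$hr; base$ci_low <- fit$terms$ci_low
    base$ci_high <- fit$terms$ci_high; base$p <- fit$terms$p
    base
  })
  out <- do.call(rbind, rows)
  if (!is.null(adjust)) {
    design <- data.frame(GoodBenefit = as.integer(good)[ok])
    for (cov in adjust) {
      if (!cov %in% names(cl)) stop("unknown adjustment covariate: ", cov)
      v <- cl[[cov]][ok]
      if (cov %in% c("tmb", "tnb")) v <- log1p(as.numeric(v))
      design <- cbind(design, .encode_covariate(v, cov))
    }
    cc <- stats::complete.cases(design)
    fit <- cox_fit(design[cc, , drop = FALSE], times[ok][cc],
                   as.integer(events[ok])[cc])
    gb <- fit$terms[fit$terms$term == "GoodBenefit", ]
    out <- rbind(out, data.frame(
      term = "GoodBenefit", model = "multivariable", n = sum(cc),
      n_altered = sum(design$GoodBenefit[cc]),
      hr = gb$hr, ci_low = gb$ci_low, ci_high = gb$ci_high, p = gb$p,
      skipped = NA_character_, stringsAsFactors = FALSE))
  }
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Point-probability two-sided p: the sum of probabilities, under the
#' hypergeometric null with fixed margins, of every table whose probability
#' does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return `copath_test` list with `statistic` (sample odds ratio with
#'   zero-cell correction), `p_value`, `method`, `n`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integers")
  if (sum(table) == 0L) stop("all-zero table")
  p <- stats::fisher.test(table)$p.value
  structure(list(statistic = odds_ratio_2x2(table), p_value = min(p, 1),
                 method = "fisher_exact", n = sum(table)),
            class = "copath_test")
}

#' Two-sample comparison: Wilcoxon rank-sum or Welch t
#'
#' Wilcoxon mode uses exact enumeration when both groups have at most 8
#' tie-free observations, otherwise the normal approximation with midranks,
#' tie correction and continuity correction. t mode is the two-sided Welch
#' test; when both groups are constant the test is undefined and p = 1 is
#' returned with a warning.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"wilcoxon"` (default) or `"t"`.
#' @return `copath_test` list.
#' @export
rank_sum_test <- function(x, y, mode = c("wilcoxon", "t")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  if (mode == "wilcoxon") {
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                   method = if (exact) "wilcoxon_exact"
                            else "wilcoxon_normal_approx",
                   n = c(length(x), length(y))),
              class = "copath_test")
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      warning("zero variance in both groups; t test undefined, p = 1")
      return(structure(list(statistic = 0, p_value = 1, method = "welch_t",
                            n = c(length(x), length(y))),
                       class = "copath_test"))
    }
    tt <- stats::t.test(x, y)
    structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                   method = "welch_t", n = c(length(x), length(y))),
              class = "copath_test")
  }
}

#' Round half away from zero
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  y <- abs(x) * scale
  fl <- floor(y)
  # tolerance absorbs binary representation error at the .5 boundary
  up <- (y - fl) >= (0.5 - 1e-8)
  sign(x) * (fl + up) / scale
}

#' Cohort characteristics summary table
#'
#' Per categorical variable: level counts with within-column percentages
#' (denominator = column total, one decimal, half away from zero) overall
#' and per group, plus an association p-value — Fisher exact for 2x2,
#' Pearson chi-square without continuity correction for larger tables.
#' Levels named "Unknown" are shown in the counts but excluded from the
#' test. The grouping variable itself is summarized first (overall column
#' only).
#'
#' @param clinical Clinical data frame.
#' @param group_by Grouping column (default `"response"`); rows whose group
#'   value is `"unknown"`/NA are excluded.
#' @param variables Categorical columns to summarize; defaults to the
#'   standard clinical covariates present in the table.
#' @return Data frame: `variable`, `level`, `n_overall`, `pct_overall`,
#'   then `n_`/`pct_` per group, and `p_value` (on the variable's first
#'   level row).
#' @export
cohort_summary_table <- function(clinical, group_by = "response",
                                 variables = NULL) {
  g <- as.character(clinical[[group_by]])
  keep <- !is.na(g) & !(tolower(g) %in% c("unknown", ""))
  cl <- clinical[keep, , drop = FALSE]
  g <- g[keep]
  groups <- sort(unique(g))
  if (length(groups) < 2L) stop("grouping variable needs >= 2 levels")
  if (is.null(variables)) {
    variables <- intersect(c("histology", "sex", "smoking", "pdl1",
                             "best_response", "treatment"), names(cl))
    variables <- variables[vapply(variables, function(v)
      any(!is.na(cl[[v]])), logical(1))]
  }
  n_all <- nrow(cl)
  n_grp <- vapply(groups, function(gr) sum(g == gr), integer(1))
  fmt_block <- function(variable, values) {
    levels_v <- unique(values[!is.na(values)])
    rows <- lapply(levels_v, function(lev) {
      cnt_all <- sum(values == lev, na.rm = TRUE)
      row <- data.frame(variable = variable, level = lev,
                        n_overall = cnt_all,
                        pct_overall = round_half_up(100 * cnt_all / n_all),
                        stringsAsFactors = FALSE)
      for (i in seq_along(groups)) {
        cnt <- sum(values == lev & g == groups[i], na.rm = TRUE)
        row[[paste0("n_", groups[i])]] <- cnt
        row[[paste0("pct_", groups[i])]] <-
          round_half_up(100 * cnt / n_grp[i])
      }
      row
    })
    block <- do.call(rbind, rows)
    test_lev <- levels_v[tolower(levels_v) != "unknown"]
    block$p_value <- NA_real_
    if (length(test_lev) >= 2L) {
      sub <- !is.na(values) & values %in% test_lev
      tab <- table(factor(values[sub], levels = test_lev), g[sub])
      p <- if (all(dim(tab) == c(2, 2)))
        fisher_exact_2x2(as.matrix(tab))$p_value
      else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      block$p_value[1] <- p
    }
    block
  }
  head_rows <- lapply(groups, function(gr) {
    row <- data.frame(variable = group_by, level = gr,
                      n_overall = sum(g == gr),
                      pct_overall = round_half_up(100 * sum(g == gr) / n_all),
                      stringsAsFactors = FALSE)
    for (i in seq_along(groups)) {
      row[[paste0("n_", groups[i])]] <- NA_integer_
      row[[paste0("pct_", groups[i])]] <- NA_real_
    }
    row$p_value <- NA_real_
    row
  })
  blocks <- lapply(variables, function(v) fmt_block(v, as.character(cl[[v]])))
  do.call(rbind, c(head_rows, blocks))
}
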