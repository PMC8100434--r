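# Independent brute-force oracles and small fixture builders used across the
# suite. Everything here is deliberately naive and separate from the package
# implementation paths it checks.

# A tiny random cohort over a toy 4-pathway catalog (2 oncogenic, 2 DDR).
toy_catalog <- function() {
  pathway_catalog(list(
    gene_set("NOTCH", c("N1", "N2", "N3"), "oncogenic"),
    gene_set("RTK_RAS", c("R1", "R2"), "oncogenic"),
    gene_set("MMR", c("M1", "M2"), "ddr"),
    gene_set("HRR", c("H1", "H2", "H3"), "ddr")
  ), provenance = "toy")
}

random_toy_cohort <- function(n = 12, catalog = toy_catalog()) {
  ids <- sprintf("T%02d", seq_len(n))
  genes <- c(unique(unlist(lapply(catalog$sets, `[[`, "genes"))),
             "OFFPATH1", "OFFPATH2")
  classes <- c("Missense_Mutation", "Silent", "Frame_Shift_Del",
               "Nonsense_Mutation", "Intron")
  n_mut <- rpois(1, 3 * n)
  mutations <- data.frame(
    sample_id = sample(ids, n_mut, replace = TRUE),
    gene = sample(genes, n_mut, replace = TRUE),
    variant_class = sample(classes, n_mut, replace = TRUE),
    protein_change = NA_character_, stringsAsFactors = FALSE)
  clinical <- data.frame(
    sample_id = ids,
    response = sample(c("DCB", "NDB"), n, replace = TRUE),
    best_response = NA_character_,
    pfs_months = round(rexp(n, 0.2), 2),
    pfs_event = rbinom(n, 1, 0.8),
    os_months = NA_real_, os_event = NA_integer_,
    histology = NA_character_, sex = NA_character_,
    smoking = NA_character_, pdl1 = NA_character_,
    treatment = NA_character_, tmb = NA_real_, tnb = NA_real_,
    stringsAsFactors = FALSE)
  cohort(clinical, mutations, name = "toy")
}

# Triple loop over (sample, pathway, gene): the definitional alteration rule.
brute_force_alteration <- function(cohort, catalog) {
  samples <- cohort$clinical$sample_id
  m <- matrix(FALSE, length(samples), length(catalog$sets),
              dimnames = list(samples, catalog_names(catalog)))
  nonsyn <- toupper(nonsynonymous_classes())
  for (s in samples) {
    for (p in catalog_names(catalog)) {
      for (g in catalog$sets[[p]]$genes) {
        rows <- cohort$mutations$sample_id == s &
          cohort$mutations$gene == g &
          toupper(cohort$mutations$variant_class) %in% nonsyn
        if (any(rows)) m[s, p] <- TRUE
      }
    }
  }
  m
}

# Product-limit estimator written out directly from the definition.
km_oracle <- function(times, events) {
  events <- as.logical(events)
  ts <- sort(unique(times[events]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events)
    s <- s * (1 - d / n_at_risk)
    surv[i] <- s
  }
  list(times = ts, survival = surv,
       median = if (any(surv <= 0.5)) min(ts[surv <= 0.5]) else NA_real_)
}

# Hand log-rank: observed-minus-expected with hypergeometric variance.
logrank_oracle <- function(ta, ea, tb, eb) {
  tt <- c(ta, tb); ev <- as.logical(c(ea, eb))
  grp <- rep(1:2, c(length(ta), length(tb)))
  ts <- sort(unique(tt[ev]))
  oe <- 0; v <- 0
  for (t in ts) {
    n1 <- sum(tt >= t & grp == 1); n2 <- sum(tt >= t & grp == 2)
    d1 <- sum(tt == t & ev & grp == 1); d2 <- sum(tt == t & ev & grp == 2)
    n <- n1 + n2; d <- d1 + d2
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  stat <- oe^2 / v
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Cox partial log-likelihood for a single covariate, distinct event times.
cox_pl_1d <- function(beta, x, times, events) {
  events <- as.logical(events)
  ll <- 0
  for (i in which(events)) {
    risk <- times >= times[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# Exhaustive hypergeometric two-sided Fisher p (point-probability method).
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon p by full enumeration of rank assignments.
wilcox_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(us <= min(u_obs, 2 * mu - u_obs) | us >= max(u_obs, 2 * mu - u_obs))
}

# Adjusted Rand index from the pair-counting formula.
ari <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Clinical table whose marginal counts per response group reproduce the
# discovery-cohort characteristics table (106 patients, 51 DCB / 55 NDB).
table1_clinical <- function() {
  fill <- function(n, counts) rep(names(counts), counts)[seq_len(n)]
  dcb <- data.frame(
    sample_id = sprintf("D%03d", 1:51), response = "DCB",
    histology = fill(51, c(Squamous = 44, `Non-squamous` = 7)),
    sex = fill(51, c(Female = 26, Male = 25)),
    smoking = fill(51, c(`Current/Former` = 43, Never = 8)),
    pdl1 = fill(51, c(Strong = 14, Weak = 21, Negative = 12, Unknown = 4)),
    best_response = fill(51, c(`CR/PR` = 34, SD = 17)),
    treatment = fill(51, c(`PD-1` = 14, `PD-1 plus CTLA-4` = 37)),
    stringsAsFactors = FALSE)
  ndb <- data.frame(
    sample_id = sprintf("N%03d", 1:55), response = "NDB",
    histology = fill(55, c(Squamous = 43, `Non-squamous` = 12)),
    sex = fill(55, c(Female = 28, Male = 27)),
    smoking = fill(55, c(`Current/Former` = 42, Never = 13)),
    pdl1 = fill(55, c(Strong = 4, Weak = 27, Negative = 19, Unknown = 5)),
    best_response = fill(55, c(`PD/NE` = 36, SD = 19)),
    treatment = fill(55, c(`PD-1` = 17, `PD-1 plus CTLA-4` = 38)),
    stringsAsFactors = FALSE)
  out <- rbind(dcb, ndb)
  out$pfs_months <- 1; out$pfs_event <- 1L
  out
}
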