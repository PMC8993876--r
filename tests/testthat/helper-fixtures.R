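# fixtures and independent oracles built in code

make_test_patients <- function(n = 6, karyotype = "46,XX[20]") {
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    age = (30 + 10 * (seq_len(n) - 1)) %% 75 + 16,
    sex = rep(c("male", "female"), length.out = n),
    hemoglobin = rep(c(9.5, 7.2, 11.0), length.out = n),
    platelets = rep(c(120, 42, 88), length.out = n),
    anc = rep(c(1.2, 0.5, 2.0), length.out = n),
    bm_blast_pct = rep(c(1, 3, 8), length.out = n),
    morphology = rep(c("SLD", "MLD", "EB"), length.out = n),
    karyotype = rep(karyotype, n),
    os_months = 5 * seq_len(n),
    event = rep(c(1L, 0L), length.out = n),
    stringsAsFactors = FALSE)
}

make_test_cohort <- function(n = 6, mutations = NULL, karyotype = "46,XX[20]") {
  ch <- mds_cohort(make_test_patients(n, karyotype))
  if (!is.null(mutations)) ch <- attach_mutations(ch, mutations)
  ch
}

make_calls <- function(patient_id, gene) {
  n <- max(length(patient_id), length(gene))
  data.frame(patient_id = rep_len(patient_id, n), gene = rep_len(gene, n),
             variant_class = rep_len("substitution", n),
             raw_ref = rep_len(NA_character_, n),
             raw_alt = rep_len(NA_character_, n), stringsAsFactors = FALSE)
}

# independent Fisher oracle: full enumeration over the hypergeometric
# support with fixed margins, point-probability two-sided rule
fisher_enum_oracle <- function(a, b, c, d, tol = 1e-7) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(k, m)
  probs <- dhyper(xs, m, n2, k)
  sum(probs[probs <= dhyper(a, m, n2, k) * (1 + tol)])
}

# independent textbook log-rank: observed minus expected events with
# hypergeometric variance, evaluated from scratch
logrank_oracle <- function(times, events, group) {
  group <- as.integer(factor(group))
  stopifnot(length(unique(group)) == 2)
  ts <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n1 <- sum(at_risk & group == 1)
    n2 <- sum(at_risk & group == 2)
    nj <- n1 + n2
    dj <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + dj * n1 / nj
    if (nj > 1) V <- V + dj * (n1 / nj) * (n2 / nj) * (nj - dj) / (nj - 1)
  }
  stat <- (O1 - E1)^2 / V
  list(stat = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# two-arm survival dataset with a planted hazard ratio
planted_two_arm <- function(n, hr, seed, dropout = 0.2,
                            baseline = 0.02, horizon = 60) {
  a0 <- generate_survival_arm(n / 2, 1, baseline_rate = baseline,
                              censor_horizon = horizon, seed = seed,
                              dropout_fraction = dropout)
  a1 <- generate_survival_arm(n / 2, hr, baseline_rate = baseline,
                              censor_horizon = horizon, seed = seed + 10000,
                              dropout_fraction = dropout)
  list(times = c(a0$times, a1$times), events = c(a0$events, a1$events),
       x = c(rep(0, n / 2), rep(1, n / 2)))
}

# cohort wrapper so survival covariates can be fed through the package API
arm_cohort <- function(arm, gene = "TP53") {
  n <- length(arm$times)
  patients <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    age = 50, sex = "female", hemoglobin = 10, platelets = 150, anc = 1.5,
    bm_blast_pct = 1, morphology = "SLD", karyotype = "46,XX[20]",
    os_months = arm$times, event = arm$events, stringsAsFactors = FALSE)
  ch <- mds_cohort(patients)
  mut <- make_calls(patients$patient_id[arm$x == 1], gene)
  attach_mutations(ch, mut)
}
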