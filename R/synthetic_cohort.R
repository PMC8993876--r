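# Default per-gene mutation counts emulated for a 152-patient cohort.
# Independent Bernoulli per gene; prevalence = count / 152.
DEFAULT_GENE_COUNTS <- c(
  SF3B1 = 28, SRSF2 = 22, U2AF1 = 16, ASXL1 = 11, RUNX1 = 11, TET2 = 10,
  TP53 = 10, ATM = 7, NRAS = 6, JAK2 = 4, JAK3 = 2, DNMT3A = 5, KMT2D = 5,
  NOTCH1 = 5, ZRSR2 = 5, SETBP1 = 5, KRAS = 4, NPM1 = 4, IDH1 = 1,
  IDH2 = 2, BCOR = 3, EZH2 = 1, PTPN11 = 2, CBL = 2, GNAS = 1)

# Log-hazard coefficients for the survival model (univariate hazard
# ratios of the emulated study).
DEFAULT_SURVIVAL_COEF <- c(
  age60 = log(1.885), morphology = log(1.852), cyto3 = log(1.675),
  `gene:TET2` = log(1.821), `gene:ASXL1` = log(2.556),
  `gene:TP53` = log(6.290), `gene:RUNX1` = log(2.376),
  `gene:NRAS` = log(3.403), `gene:KRAS` = log(3.697),
  `gene:NOTCH1` = log(2.507))

#' Simulation configuration for synthetic MDS cohorts
#'
#' Defaults emulate a 152-patient cohort: ages with median 55 on [16, 90]
#' (discretized triangular), 83:69 male:female, WHO morphology mix
#' SLD/MLD/EB of 45:50:46, cytogenetic category probabilities
#' 0.816/0.105/0.053/0.026 (Good/Intermediate/Poor/VeryPoor), per-gene
#' Bernoulli mutation prevalences from the emulated frequency table, and
#' proportional-hazards survival with an exponential baseline scaled by
#' the per-factor hazard ratios, administratively censored at the horizon
#' with a uniform-dropout fraction. The baseline rate is calibrated so
#' that about 35\% of patients die before censoring.
#'
#' @param n_patients cohort size.
#' @param seed RNG seed for \code{\link{generate_cohort}}.
#' @param age_range,age_mode triangular age distribution parameters (years).
#' @param p_male probability of male sex.
#' @param morphology_probs named probabilities over SLD/MLD/EB.
#' @param cyto_probs named probabilities over
#'   Good/Intermediate/Poor/VeryPoor.
#' @param p_abnormal_good probability that a Good-category karyotype is an
#'   abnormal one (isolated del(5q)/del(20q)/del(12p)) rather than normal.
#' @param gene_prev named per-gene mutation probabilities.
#' @param variant_class_probs named probabilities over
#'   substitution/deletion/insertion/duplication.
#' @param survival_coef named log-hazard coefficients over the covariates
#'   \code{age60}, \code{morphology}, \code{cyto3} and \code{gene:SYMBOL}
#'   entries.
#' @param baseline_rate exponential baseline hazard, events per month.
#' @param censor_horizon administrative censoring time, months.
#' @param dropout_fraction fraction of patients censored uniformly before
#'   the horizon.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_patients = 152, seed = NULL,
                              age_range = c(16, 90), age_mode = 57.1,
                              p_male = 83 / 152,
                              morphology_probs = c(SLD = 45, MLD = 50, EB = 46) / 141,
                              cyto_probs = c(Good = 0.816, Intermediate = 0.105,
                                             Poor = 0.053, VeryPoor = 0.026),
                              p_abnormal_good = 33 / 124,
                              gene_prev = DEFAULT_GENE_COUNTS / 152,
                              variant_class_probs = c(substitution = 159, deletion = 21,
                                                      insertion = 12, duplication = 10) / 202,
                              survival_coef = DEFAULT_SURVIVAL_COEF,
                              baseline_rate = 0.0008,
                              censor_horizon = 120,
                              dropout_fraction = 0.15) {
  if (!is_count(n_patients) || n_patients < 1) stop_mds("n_patients must be >= 1")
  chk_probs <- function(p, name, sum_to_one = FALSE) {
    if (any(p < 0 | p > 1)) stop_mds(name, " probabilities must lie in [0, 1]")
    if (sum_to_one && abs(sum(p) - 1) > 1e-9) {
      stop_mds(name, " probabilities must sum to 1")
    }
  }
  chk_probs(cyto_probs, "cytogenetic", sum_to_one = TRUE)
  chk_probs(morphology_probs, "morphology", sum_to_one = TRUE)
  chk_probs(variant_class_probs, "variant class", sum_to_one = TRUE)
  chk_probs(gene_prev, "gene prevalence")
  chk_probs(c(p_male, p_abnormal_good, dropout_fraction), "fraction")
  stopifnot(baseline_rate > 0, censor_horizon > 0)
  structure(list(n_patients = n_patients, seed = seed, age_range = age_range,
                 age_mode = age_mode, p_male = p_male,
                 morphology_probs = morphology_probs, cyto_probs = cyto_probs,
                 p_abnormal_good = p_abnormal_good, gene_prev = gene_prev,
                 variant_class_probs = variant_class_probs,
                 survival_coef = survival_coef, baseline_rate = baseline_rate,
                 censor_horizon = censor_horizon,
                 dropout_fraction = dropout_fraction),
            class = "simulation_config")
}

# inverse-CDF sample from a triangular distribution, rounded to years
sample_ages <- function(n, lo, hi, mode) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  x <- ifelse(u < fc,
              lo + sqrt(u * (hi - lo) * (mode - lo)),
              hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
  pmin(hi, pmax(lo, round(x)))
}

# ISCN templates per drawn cytogenetic category; %s is the sex complement
sample_karyotype <- function(category, sex, p_abnormal_good) {
  sx <- if (sex == "male") "XY" else "XX"
  pick <- function(templates, probs) {
    sprintf(sample(templates, 1, prob = probs), sx)
  }
  switch(category,
    Good = {
      if (stats::runif(1) < p_abnormal_good) {
        pick(c("46,%s,del(5)(q13q33)[20]",
               "46,%s,del(20)(q11.2)[20]",
               "46,%s,del(12)(p11.2)[20]"), c(0.5, 0.35, 0.15))
      } else {
        sprintf("46,%s[20]", sx)
      }
    },
    Intermediate = pick(c("47,%s,+8[20]",
                          "46,%s,del(7)(q31)[20]",
                          "47,%s,+19[20]",
                          "46,%s,i(17)(q10)[20]",
                          "46,%s,add(2)(q31)[20]"),
                        c(0.45, 0.2, 0.1, 0.1, 0.15)),
    Poor = pick(c("45,%s,-7[20]",
                  "46,%s,inv(3)(q21q26)[20]",
                  "46,%s,del(5)(q13q33),-7,+8[20]"),
                c(0.5, 0.25, 0.25)),
    VeryPoor = pick(c("45,%s,del(5)(q13q33),-7,add(17)(p13),del(12)(p11.2)[20]",
                      "45,%s,del(5)(q13q33),-7,-18,add(17)(p13),+mar[20]"),
                    c(0.6, 0.4)),
    stop_mds("unknown cytogenetic category: ", category))
}

# per-subtype CBC draws; clinically plausible cytopenic marrow values
sample_cbc <- function(morphology) {
  hb <- min(14, max(3, stats::rnorm(1, 8.6, 1.9)))
  plt <- min(700, max(5, stats::rlnorm(1, log(95), 0.75)))
  anc <- min(15, max(0.05, stats::rlnorm(1, log(1.3), 0.65)))
  blast <- switch(morphology,
                  SLD = round(stats::runif(1, 0, 3), 1),
                  MLD = round(stats::runif(1, 0, 4.4), 1),
                  EB = round(stats::runif(1, 5, 19), 1))
  list(hemoglobin = round(hb, 1), platelets = round(plt, 1),
       anc = round(anc, 2), bm_blast_pct = blast)
}

#' Generate a seeded synthetic MDS cohort
#'
#' Draws a fully populated patient and mutation table from a
#' \code{\link{simulation_config}}, with ISCN karyotype strings consistent
#' with each patient's drawn cytogenetic category and overall survival
#' drawn from the proportional-hazards model. The realized linear
#' predictors, true coefficients and censoring times are returned as a
#' ground-truth sidecar for recovery testing; the analysis pipeline never
#' reads it. Identical seeds give identical cohorts.
#'
#' @param config a \code{simulation_config}.
#' @return list with elements \code{cohort} (an \code{mds_cohort}) and
#'   \code{truth}.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
    age <- sample_ages(n, config$age_range[1], config$age_range[2],
                       config$age_mode)
    morphology <- sample(names(config$morphology_probs), n, replace = TRUE,
                         prob = config$morphology_probs)
    cyto <- sample(names(config$cyto_probs), n, replace = TRUE,
                   prob = config$cyto_probs)
    karyotype <- vapply(seq_len(n), function(i)
      sample_karyotype(cyto[i], sex[i], config$p_abnormal_good), "")
    cbc <- lapply(morphology, sample_cbc)

    genes <- names(config$gene_prev)
    mut_matrix <- matrix(stats::runif(n * length(genes)) <
                           rep(config$gene_prev, each = n),
                         nrow = n, dimnames = list(ids, genes))
    mut_rows <- which(mut_matrix, arr.ind = TRUE)
    mutations <- if (nrow(mut_rows) > 0) {
      data.frame(
        patient_id = ids[mut_rows[, 1]],
        gene = genes[mut_rows[, 2]],
        variant_class = sample(names(config$variant_class_probs),
                               nrow(mut_rows), replace = TRUE,
                               prob = config$variant_class_probs),
        raw_ref = NA_character_, raw_alt = NA_character_,
        stringsAsFactors = FALSE)
    } else empty_mutation_table()
    ord <- order(mutations$patient_id, mutations$gene)
    mutations <- mutations[ord, , drop = FALSE]

    # proportional-hazards survival on the generated covariates
    pooling <- load_gene_pooling()
    pooled_mut <- function(g) {
      members <- c(g, names(pooling)[pooling == g])
      rowSums(mut_matrix[, intersect(members, genes), drop = FALSE]) > 0
    }
    covars <- list(
      age60 = as.numeric(age >= 60),
      morphology = as.numeric(factor(morphology, c("SLD", "MLD", "EB"))) - 1,
      cyto3 = pmin(as.numeric(factor(cyto, c("Good", "Intermediate", "Poor",
                                             "VeryPoor"))) - 1, 2))
    lp <- rep(0, n)
    for (nm in names(config$survival_coef)) {
      x <- if (grepl("^gene:", nm)) {
        as.numeric(pooled_mut(sub("^gene:", "", nm)))
      } else covars[[nm]]
      if (is.null(x)) stop_mds("survival coefficient for unknown covariate: ", nm)
      lp <- lp + config$survival_coef[[nm]] * x
    }
    true_time <- stats::rexp(n, rate = config$baseline_rate * exp(lp))
    censor_time <- ifelse(stats::runif(n) < config$dropout_fraction,
                          stats::runif(n, 0, config$censor_horizon),
                          config$censor_horizon)
    event <- as.integer(true_time <= censor_time)
    os_months <- round(pmax(pmin(true_time, censor_time), 0.5), 1)

    patients <- data.frame(
      patient_id = ids, age = age, sex = sex,
      hemoglobin = vapply(cbc, `[[`, 0, "hemoglobin"),
      platelets = vapply(cbc, `[[`, 0, "platelets"),
      anc = vapply(cbc, `[[`, 0, "anc"),
      bm_blast_pct = vapply(cbc, `[[`, 0, "bm_blast_pct"),
      morphology = morphology, karyotype = karyotype,
      os_months = os_months, event = event, stringsAsFactors = FALSE)

    cohort <- mds_cohort(patients, mutations,
                         provenance = paste0("synthetic(seed=",
                                             config$seed %||% "NULL", ")"))
    truth <- list(coefficients = as.list(config$survival_coef),
                  baseline_rate = config$baseline_rate,
                  linear_predictor = stats::setNames(lp, ids),
                  censor_times = stats::setNames(censor_time, ids),
                  drawn_cyto_category = stats::setNames(cyto, ids),
                  seed = config$seed)
    list(cohort = cohort, truth = truth)
  })
}

#' Fixed contingency-table fixtures
#'
#' Small deterministic tables reproducing a published 152-patient MDS
#' study's printed counts: mutation status by the IPSS-R 3.5-point
#' dichotomy and by four-group cytogenetic risk, TP53 and SF3B1 mutation
#' by risk group among the 111 mutated patients, and NPM1 mutation by sex
#' and by karyotype normality.
#'
#' @return named list of \code{contingency_table} objects.
#' @export
make_fixture_tables <- function() {
  list(
    ipssr35_mutation = contingency_table(
      matrix(c(43, 28, 68, 13), 2, byrow = TRUE,
             dimnames = list(c("le3.5", "gt3.5"), c("with", "without"))),
      row_name = "ipssr35", col_name = "mutation_status"),
    cyto4_mutation = contingency_table(
      matrix(c(94, 30, 8, 8, 7, 1, 2, 2), 4, byrow = TRUE,
             dimnames = list(c("Good", "Intermediate", "Poor", "VeryPoor"),
                             c("with", "without"))),
      row_name = "cyto4", col_name = "mutation_status"),
    tp53_risk = contingency_table(
      matrix(c(0, 43, 10, 58), 2, byrow = TRUE,
             dimnames = list(c("lower", "higher"), c("TP53_mut", "TP53_wt"))),
      row_name = "ipssr35", col_name = "gene:TP53"),
    sf3b1_risk = contingency_table(
      matrix(c(16, 27, 12, 56), 2, byrow = TRUE,
             dimnames = list(c("lower", "higher"), c("SF3B1_mut", "SF3B1_wt"))),
      row_name = "ipssr35", col_name = "gene:SF3B1"),
    npm1_sex = contingency_table(
      matrix(c(4, 0, 65, 83), 2, byrow = TRUE,
             dimnames = list(c("NPM1_mut", "NPM1_wt"), c("female", "male"))),
      row_name = "gene:NPM1", col_name = "sex"),
    npm1_karyotype = contingency_table(
      matrix(c(4, 0, 87, 61), 2, byrow = TRUE,
             dimnames = list(c("NPM1_mut", "NPM1_wt"), c("normal", "abnormal"))),
      row_name = "gene:NPM1", col_name = "normal_karyotype"))
}

#' Generate one exponential survival arm
#'
#' Supports parameter-recovery tests: exponential event times at rate
#' \code{baseline_rate * hr}, administratively censored at the horizon,
#' with an optional uniform-dropout fraction.
#'
#' @param n arm size (>= 2).
#' @param hr hazard ratio relative to the baseline rate (> 0).
#' @param baseline_rate events per month.
#' @param censor_horizon months.
#' @param seed RNG seed; \code{NULL} uses the current stream.
#' @param dropout_fraction fraction censored uniformly before the horizon.
#' @return list with \code{times} and \code{events}.
#' @export
generate_survival_arm <- function(n, hr, baseline_rate = 0.02,
                                  censor_horizon = 60, seed = NULL,
                                  dropout_fraction = 0) {
  if (!is_count(n) || n < 2) stop_mds("n must be an integer >= 2")
  if (!is.numeric(hr) || hr <= 0) stop_mds("hr must be > 0")
  with_seed(seed, {
    true_time <- stats::rexp(n, rate = baseline_rate * hr)
    censor_time <- ifelse(stats::runif(n) < dropout_fraction,
                          stats::runif(n, 0, censor_horizon), censor_horizon)
    list(times = pmin(true_time, censor_time),
         events = as.integer(true_time <= censor_time))
  })
}
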