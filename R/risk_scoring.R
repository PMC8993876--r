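#' Load a score table
#'
#' Score tables are pure data: JSON files defining per-factor point bins
#' and tier cutpoints. A malformed table (bins that overlap, leave gaps,
#' or do not start at zero) is rejected at load.
#'
#' @param path JSON file; defaults ship with the package
#'   (\code{ipssr_default.json}, \code{mipssr_default.json}).
#' @return object of class \code{score_table}.
#' @export
load_score_table <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(tab$system) || is.null(tab$version) || is.null(tab$factors)) {
    stop_mds("score table lacks system/version/factors")
  }
  for (fname in names(tab$factors)) {
    f <- tab$factors[[fname]]
    if (identical(f$kind, "bins")) validate_bins(f$bins, fname)
    if (identical(f$kind, "morphology")) validate_bins(f$blast_bins, fname,
                                                      domain_lo = 5)
  }
  structure(tab, class = "score_table")
}

# bins must tile [domain_lo, Inf) with no gaps or overlaps
validate_bins <- function(bins, fname, domain_lo = 0) {
  los <- vapply(bins, function(b) as.numeric(b$lo), 0)
  ord <- order(los)
  bins <- bins[ord]
  prev_hi <- domain_lo
  prev_hi_incl <- FALSE
  for (b in bins) {
    lo <- as.numeric(b$lo)
    hi <- if (length(b$hi) == 0) Inf else as.numeric(b$hi)
    if (lo != prev_hi || identical(isTRUE(b$lo_incl), prev_hi_incl)) {
      stop_mds("score table factor '", fname,
               "': bins overlap or leave a gap near ", lo)
    }
    if (hi < lo) stop_mds("score table factor '", fname, "': empty bin")
    p <- as.numeric(b$points)
    if (p < 0 || (p * 2) %% 1 != 0) {
      stop_mds("score table factor '", fname,
               "': points must be non-negative multiples of 0.5")
    }
    prev_hi <- hi
    prev_hi_incl <- isTRUE(b$hi_incl)
  }
  if (!is.infinite(prev_hi)) {
    stop_mds("score table factor '", fname, "': bins do not cover the domain")
  }
  invisible(TRUE)
}

default_ipssr_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_score_table(mds_config_path("ipssr_default.json"))
    cache
  }
})

default_mipssr_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_score_table(mds_config_path("mipssr_default.json"))
    cache
  }
})

bin_points <- function(bins, x) {
  for (b in bins) {
    lo <- as.numeric(b$lo)
    hi <- if (length(b$hi) == 0) Inf else as.numeric(b$hi)
    lo_ok <- if (isTRUE(b$lo_incl)) x >= lo else x > lo
    hi_ok <- if (isTRUE(b$hi_incl)) x <= hi else x < hi
    if (lo_ok && hi_ok) return(as.numeric(b$points))
  }
  stop_mds("value ", x, " falls outside all bins")
}

tier_of <- function(total, tiers) {
  cuts <- unlist(tiers$cuts)
  labels <- unlist(tiers$labels)
  idx <- sum(total > cuts) + 1
  labels[idx]
}

#' Compute the IPSS-R score for one patient
#'
#' Sums the five IPSS-R component points: cytogenetic category,
#' bone-marrow blast percentage, hemoglobin, platelets, and absolute
#' neutrophil count. Totals range 0-10 in steps of 0.5 and map to five
#' tiers (VeryLow/Low/Intermediate/High/VeryHigh at cutpoints
#' 1.5/3/4.5/6); a four-group collapse merging VeryLow into Low is also
#' reported.
#'
#' @param hemoglobin g/dL.
#' @param platelets x10^9/L.
#' @param anc x10^9/L.
#' @param bm_blast_pct percent marrow blasts.
#' @param cyto_category one of VeryGood/Good/Intermediate/Poor/VeryPoor.
#' @param table a \code{score_table}; default is the shipped IPSS-R table.
#' @return object of class \code{score_breakdown}: per-factor
#'   \code{points}, \code{total}, \code{tier}, \code{tier4},
#'   \code{system}, \code{version}.
#' @export
score_ipssr <- function(hemoglobin, platelets, anc, bm_blast_pct,
                        cyto_category, table = default_ipssr_table()) {
  comp <- list(hemoglobin = hemoglobin, platelets = platelets, anc = anc,
               bm_blast_pct = bm_blast_pct, cytogenetics = cyto_category)
  for (nm in names(comp)) {
    if (is.null(comp[[nm]]) || length(comp[[nm]]) != 1 || is.na(comp[[nm]])) {
      stop_mds("missing IPSS-R component: ", nm)
    }
  }
  f <- table$factors
  cyto_pts <- f$cytogenetics$points[[cyto_category]]
  if (is.null(cyto_pts)) stop_mds("unknown cytogenetic category: ", cyto_category)
  points <- c(
    cytogenetics = as.numeric(cyto_pts),
    bm_blast_pct = bin_points(f$bm_blast_pct$bins, bm_blast_pct),
    hemoglobin = bin_points(f$hemoglobin$bins, hemoglobin),
    platelets = bin_points(f$platelets$bins, platelets),
    anc = bin_points(f$anc$bins, anc))
  total <- sum(points)
  tier <- tier_of(total, table$tiers)
  tier4 <- tier
  for (from in names(table$tiers$collapse4 %||% list())) {
    if (tier4 == from) tier4 <- table$tiers$collapse4[[from]]
  }
  structure(list(points = points, total = total, tier = tier, tier4 = tier4,
                 system = table$system, version = table$version),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("%s total %.1f -> %s (table %s)\n", x$system, x$total, x$tier,
              x$version))
  print(x$points)
  invisible(x)
}

#' Dichotomize an IPSS-R score at 3.5 points
#'
#' Lower-risk MDS is defined as a total of at most 3.5 points; higher-risk
#' as more than 3.5.
#'
#' @param breakdown a \code{score_breakdown} with system IPSS-R, or a bare
#'   numeric total.
#' @return \code{"lower"} or \code{"higher"}.
#' @export
dichotomize_ipssr <- function(breakdown) {
  total <- if (inherits(breakdown, "score_breakdown")) {
    if (!identical(breakdown$system, "IPSS-R")) {
      stop_mds("dichotomize_ipssr expects an IPSS-R breakdown")
    }
    breakdown$total
  } else as.numeric(breakdown)
  if (total <= 3.5) "lower" else "higher"
}

#' Count distinct selected-gene mutations for one patient
#'
#' The mutation factor of the M-IPSS-R counts distinct selected genes with
#' at least one call, after gene-family pooling; repeated calls in the
#' same gene count once.
#'
#' @param genes character vector of (possibly repeated) mutated gene
#'   symbols for the patient.
#' @param selected selected-gene set; default from the shipped M-IPSS-R
#'   table.
#' @param pooling pooling map applied before matching (\code{NULL} to skip).
#' @return integer count.
#' @export
count_selected_mutations <- function(genes,
                                     selected = unlist(default_mipssr_table()$selected_genes),
                                     pooling = load_gene_pooling()) {
  if (length(selected) == 0) stop_mds("selected gene set is empty")
  genes <- unique(pool_genes(toupper(genes), pooling))
  sum(genes %in% selected)
}

#' Compute the M-IPSS-R score for one patient
#'
#' Sums four factor points: number of distinct selected-gene mutations
#' (0/1/2/3/4/>4 -> 0/1/2/3/4/5), marrow morphology (SLD 0, MLD 1; blast
#' bins 5-10% -> 2 and >10% -> 3 for patients with excess blasts),
#' cytogenetic category (Good 0, Intermediate 1, Poor 2, VeryPoor 3), and
#' age (<=30 0, 31-50 0.5, 51-60 1, >60 2). Totals range 0-13.
#'
#' @param n_selected_mutations distinct selected-gene mutation count.
#' @param morphology \code{"SLD"}, \code{"MLD"} or \code{"EB"}.
#' @param bm_blast_pct percent marrow blasts (chooses the blast bin for EB
#'   patients or any patient with blasts >= 5%).
#' @param cyto_category cytogenetic category.
#' @param age years.
#' @param table a \code{score_table}; default is the shipped
#'   reconstructed table.
#' @return object of class \code{score_breakdown}.
#' @export
score_mipssr <- function(n_selected_mutations, morphology, bm_blast_pct,
                         cyto_category, age, table = default_mipssr_table()) {
  comp <- list(n_selected_mutations = n_selected_mutations,
               morphology = morphology, cyto_category = cyto_category,
               age = age)
  for (nm in names(comp)) {
    if (is.null(comp[[nm]]) || length(comp[[nm]]) != 1 || is.na(comp[[nm]])) {
      stop_mds("missing M-IPSS-R factor: ", nm)
    }
  }
  if (!is_count(n_selected_mutations)) {
    stop_mds("n_selected_mutations must be a non-negative integer")
  }
  f <- table$factors
  mut_key <- if (n_selected_mutations > 4) "gt4" else as.character(n_selected_mutations)
  mut_pts <- as.numeric(f$gene_mutations$points[[mut_key]])

  use_blast_bins <- morphology == "EB" ||
    (!is.na(bm_blast_pct) && bm_blast_pct >= 5)
  morph_pts <- if (use_blast_bins) {
    # EB is a morphologic call: an EB patient below 5% blasts still scores
    # the lowest blast bin
    b <- if (is.na(bm_blast_pct)) 5 else max(bm_blast_pct, 5)
    bin_points(f$morphology$blast_bins, b)
  } else {
    p <- f$morphology$dysplasia_points[[morphology]]
    if (is.null(p)) stop_mds("unknown morphology: ", morphology)
    as.numeric(p)
  }
  cyto_pts <- f$cytogenetics$points[[cyto_category]]
  if (is.null(cyto_pts)) stop_mds("unknown cytogenetic category: ", cyto_category)
  points <- c(gene_mutations = mut_pts, morphology = morph_pts,
              cytogenetics = as.numeric(cyto_pts),
              age = bin_points(f$age$bins, age))
  total <- sum(points)
  structure(list(points = points, total = total,
                 tier = classify_mipssr(total, table),
                 system = table$system, version = table$version),
            class = "score_breakdown")
}

#' Assign the M-IPSS-R risk tier
#'
#' Low for totals up to 3 (totals below 1.5 are also classified Low),
#' Intermediate for 3.5-5.5, High above 5.5.
#'
#' @param total non-negative score total.
#' @param table a \code{score_table} carrying the tier cutpoints.
#' @return \code{"Low"}, \code{"Intermediate"} or \code{"High"}.
#' @export
classify_mipssr <- function(total, table = default_mipssr_table()) {
  if (!is.numeric(total) || length(total) != 1 || is.na(total) || total < 0) {
    stop_mds("total must be a non-negative number")
  }
  tier_of(total, table$tiers)
}

#' Score every patient in a cohort under both systems
#'
#' @param cohort an \code{mds_cohort}.
#' @param cyto per-patient cytogenetic classification from
#'   \code{\link{classify_cohort_cytogenetics}}; computed on the fly if
#'   \code{NULL}.
#' @param ipssr_table,mipssr_table score tables.
#' @param pooling gene-pooling map.
#' @return data frame with one row per patient: factor points, totals,
#'   tiers for IPSS-R (5-tier and 4-group) and M-IPSS-R, and the 3.5-point
#'   dichotomy.
#' @export
score_cohort <- function(cohort, cyto = NULL,
                         ipssr_table = default_ipssr_table(),
                         mipssr_table = default_mipssr_table(),
                         pooling = load_gene_pooling()) {
  if (is.null(cyto)) {
    cyto <- classify_cohort_cytogenetics(cohort,
                                         missing_karyotype = "assume_normal")
  }
  pts <- cohort$patients
  cyto_cat <- cyto$category[match(pts$patient_id, cyto$patient_id)]
  selected <- unlist(mipssr_table$selected_genes)
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    ip <- score_ipssr(p$hemoglobin, p$platelets, p$anc, p$bm_blast_pct,
                      cyto_cat[i], ipssr_table)
    nsel <- count_selected_mutations(patient_genes(cohort, p$patient_id),
                                     selected, pooling)
    mp <- score_mipssr(nsel, p$morphology, p$bm_blast_pct, cyto_cat[i],
                       p$age, mipssr_table)
    data.frame(patient_id = p$patient_id, cyto_category = cyto_cat[i],
               ipssr_total = ip$total, ipssr_tier = ip$tier,
               ipssr_group4 = ip$tier4,
               ipssr_dichotomy = dichotomize_ipssr(ip),
               n_selected_mutations = nsel,
               mipssr_total = mp$total, mipssr_tier = mp$tier,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

MIPSSR_ORDINAL <- c(Low = 1, Intermediate = 2, High = 3)
IPSSR4_ORDINAL <- c(Low = 1, Intermediate = 2, High = 3, VeryHigh = 3)

#' Compare IPSS-R and M-IPSS-R stratification
#'
#' Aligns the IPSS-R four-group scale (Low < Intermediate < High <
#' VeryHigh, with VeryHigh mapped to the top M-IPSS-R level) against the
#' M-IPSS-R three-tier scale and reports, per patient, whether the risk
#' group decreased, stayed, or increased, with counts and fractions (one
#' decimal).
#'
#' @param cohort an \code{mds_cohort}, or a data frame from
#'   \code{\link{score_cohort}}.
#' @param ... passed to \code{\link{score_cohort}} when \code{cohort} is
#'   an \code{mds_cohort}.
#' @return object of class \code{reclassification_report}: per-patient
#'   table, direction counts, fractions, and the denominator used.
#' @export
compare_stratification <- function(cohort, ...) {
  scores <- if (inherits(cohort, "mds_cohort")) score_cohort(cohort, ...) else cohort
  ip_ord <- IPSSR4_ORDINAL[scores$ipssr_group4]
  mp_ord <- MIPSSR_ORDINAL[scores$mipssr_tier]
  direction <- ifelse(mp_ord < ip_ord, "decreased",
                      ifelse(mp_ord > ip_ord, "increased", "unchanged"))
  per_patient <- data.frame(patient_id = scores$patient_id,
                            ipssr_group = scores$ipssr_group4,
                            mipssr_group = scores$mipssr_tier,
                            direction = direction, stringsAsFactors = FALSE)
  counts <- c(decreased = sum(direction == "decreased"),
              unchanged = sum(direction == "unchanged"),
              increased = sum(direction == "increased"))
  n <- nrow(per_patient)
  structure(list(per_patient = per_patient, counts = counts,
                 fractions = round1(100 * counts / n), n_compared = n),
            class = "reclassification_report")
}

#' @export
print.reclassification_report <- function(x, ...) {
  cat(sprintf("reclassification over %d patients: decreased %d (%.1f%%), unchanged %d (%.1f%%), increased %d (%.1f%%)\n",
              x$n_compared,
              x$counts["decreased"], x$fractions["decreased"],
              x$counts["unchanged"], x$fractions["unchanged"],
              x$counts["increased"], x$fractions["increased"]))
  invisible(x)
}
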