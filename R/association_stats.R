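#' Build a factor specification
#'
#' Factor specs name patient groupings with a declared level order (used
#' for deterministic table layout). Presets accepted as strings:
#' \code{"mutation_status"}, \code{"ipssr35"} (the 3.5-point dichotomy),
#' \code{"ipssr4"}, \code{"mipssr"}, \code{"age59"}, \code{"age60"},
#' \code{"cyto4"}, \code{"sex"}, \code{"normal_karyotype"}, and
#' \code{"gene:SYMBOL"} (mutated vs wild-type, after gene pooling).
#'
#' @param spec preset name, or a list with \code{name}, \code{levels}, and
#'   \code{fun(cohort, context)} returning a character vector over
#'   patients.
#' @return object of class \code{factor_spec}.
#' @export
factor_spec <- function(spec) {
  if (inherits(spec, "factor_spec")) return(spec)
  if (is.list(spec)) {
    stopifnot(!is.null(spec$name), !is.null(spec$levels), is.function(spec$fun))
    return(structure(spec, class = "factor_spec"))
  }
  stopifnot(is.character(spec), length(spec) == 1)
  if (grepl("^gene:", spec)) {
    gene <- sub("^gene:", "", spec)
    return(structure(list(
      name = spec, levels = c("mutated", "wild_type"),
      fun = function(cohort, context) {
        pooling <- context$pooling %||% load_gene_pooling()
        st <- vapply(cohort$patients$patient_id, function(id)
          gene %in% patient_genes(cohort, id, pooling), logical(1))
        ifelse(st, "mutated", "wild_type")
      }), class = "factor_spec"))
  }
  preset <- switch(spec,
    mutation_status = list(
      levels = c("with", "without"),
      fun = function(cohort, context)
        ifelse(mutation_counts(cohort) >= 1, "with", "without")),
    ipssr35 = list(
      levels = c("lower", "higher"),
      fun = function(cohort, context)
        need_scores(cohort, context)$ipssr_dichotomy),
    ipssr4 = list(
      levels = c("Low", "Intermediate", "High", "VeryHigh"),
      fun = function(cohort, context)
        need_scores(cohort, context)$ipssr_group4),
    mipssr = list(
      levels = c("Low", "Intermediate", "High"),
      fun = function(cohort, context)
        need_scores(cohort, context)$mipssr_tier),
    age59 = list(
      levels = c("le59", "gt59"),
      fun = function(cohort, context)
        ifelse(cohort$patients$age <= 59, "le59", "gt59")),
    age60 = list(
      levels = c("lt60", "ge60"),
      fun = function(cohort, context)
        ifelse(cohort$patients$age < 60, "lt60", "ge60")),
    cyto4 = list(
      levels = c("Good", "Intermediate", "Poor", "VeryPoor"),
      fun = function(cohort, context) {
        cy <- context$cyto %||% classify_cohort_cytogenetics(
          cohort, missing_karyotype = "assume_normal")
        cy$group4[match(cohort$patients$patient_id, cy$patient_id)]
      }),
    sex = list(
      levels = c("male", "female"),
      fun = function(cohort, context) cohort$patients$sex),
    normal_karyotype = list(
      levels = c("normal", "abnormal"),
      fun = function(cohort, context) {
        cy <- context$cyto %||% classify_cohort_cytogenetics(
          cohort, missing_karyotype = "assume_normal")
        n_abn <- cy$n_abnormalities[match(cohort$patients$patient_id,
                                          cy$patient_id)]
        ifelse(n_abn == 0, "normal", "abnormal")
      }),
    stop_mds("unknown factor spec: ", spec))
  structure(c(list(name = spec), preset), class = "factor_spec")
}

need_scores <- function(cohort, context) {
  context$scores %||% score_cohort(cohort)
}

eval_factor <- function(cohort, spec, context = list()) {
  spec <- factor_spec(spec)
  vals <- spec$fun(cohort, context)
  factor(vals, levels = spec$levels)
}

#' Cross-tabulate two patient groupings
#'
#' Patients for whom either factor is missing are excluded (with a logged
#' count). Label order is the spec's declared order, never lexical.
#'
#' @param cohort an \code{mds_cohort}.
#' @param row_factor,col_factor factor specs (see \code{\link{factor_spec}}).
#' @param context optional list with precomputed \code{scores},
#'   \code{cyto}, \code{pooling} to avoid recomputation.
#' @return object of class \code{contingency_table} (an integer matrix
#'   with dimnames and factor names as attributes).
#' @export
crosstab <- function(cohort, row_factor, col_factor, context = list()) {
  if (nrow(cohort$patients) == 0) stop_mds("empty cohort")
  rf <- factor_spec(row_factor); cf <- factor_spec(col_factor)
  if (length(rf$levels) < 2) stop_mds("row factor '", rf$name, "' has one level only")
  if (length(cf$levels) < 2) stop_mds("col factor '", cf$name, "' has one level only")
  rv <- eval_factor(cohort, rf, context)
  cv <- eval_factor(cohort, cf, context)
  keep <- !is.na(rv) & !is.na(cv)
  if (any(!keep)) {
    message(sum(!keep), " patient(s) excluded from crosstab (missing factor value)")
  }
  tab <- table(rv[keep], cv[keep])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  contingency_table(m, row_name = rf$name, col_name = cf$name)
}

#' Construct a contingency table object
#' @param counts r x c matrix of non-negative integer counts.
#' @param row_name,col_name factor names.
#' @return object of class \code{contingency_table}.
#' @export
contingency_table <- function(counts, row_name = "rows", col_name = "cols") {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop_mds("contingency table entries must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(counts, row_name = row_name, col_name = col_name,
            class = c("contingency_table", "matrix", "array"))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: %s x %s\n", attr(x, "row_name"),
              attr(x, "col_name")))
  print(unclass(x))
  invisible(x)
}

association_result <- function(table, test, p_value, statistic = NA_real_,
                               df = NA_integer_, flag = NA_character_) {
  structure(list(table = table, test = test,
                 p_value = min(max(p_value, .Machine$double.xmin), 1),
                 statistic = statistic, df = df, flag = flag),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: p = %.4g", x$test, x$p_value))
  if (!is.na(x$statistic)) cat(sprintf(" (stat %.4g, df %d)", x$statistic, x$df))
  if (!is.na(x$flag)) cat(" [", x$flag, "]")
  cat("\n")
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test with fixed margins; the two-sided p-value is the
#' point-probability (minimum-likelihood) sum: all tables whose
#' hypergeometric probability does not exceed the observed table's (to a
#' 1e-7 relative tolerance) contribute.
#'
#' @param table 2x2 \code{contingency_table} or matrix.
#' @return an \code{association_result}.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- contingency_table(table)
  if (!all(dim(tab) == c(2, 2))) stop_mds("fisher_exact_2x2 needs a 2x2 table")
  if (sum(tab) == 0) stop_mds("all-zero table")
  p <- stats::fisher.test(unclass(tab), alternative = "two.sided")$p.value
  association_result(tab, "fisher_exact", p)
}

#' Pearson chi-square test without continuity correction
#'
#' @param table r x c \code{contingency_table} or matrix with no zero row
#'   or column margin.
#' @return an \code{association_result} carrying the statistic and df.
#' @export
pearson_chi2 <- function(table) {
  tab <- contingency_table(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_mds("zero row/column margin")
  }
  ht <- suppressWarnings(stats::chisq.test(unclass(tab), correct = FALSE))
  association_result(tab, "pearson_chi2", ht$p.value,
                     statistic = unname(ht$statistic),
                     df = as.integer(unname(ht$parameter)))
}

#' Per-gene association screen
#'
#' For each gene, cross-tabulates mutated vs wild-type status against a
#' patient grouping and tests the 2x2 (or r x 2) table. The default policy
#' is Fisher's exact test for 2x2 tables and Pearson's chi-square for
#' larger ones. A gene absent from the cohort (or mutated in every
#' patient) yields a degenerate table: it is flagged and reported with
#' p = 1, not an error. No multiplicity adjustment is applied by default.
#'
#' @param cohort an \code{mds_cohort}.
#' @param genes character vector of (pooled) gene labels to screen.
#' @param grouping factor spec for the columns.
#' @param denominator \code{"mutated_only"} restricts to patients with at
#'   least one mutation call (the frequency-table population);
#'   \code{"all"} uses the whole cohort.
#' @param test \code{"policy"} (Fisher for 2x2, chi-square otherwise),
#'   \code{"fisher"}, or \code{"chi2"}.
#' @param adjust optional \code{"BH"} to append Benjamini-Hochberg
#'   adjusted p-values; off by default.
#' @param context optional precomputed context (see \code{\link{crosstab}}).
#' @return data frame: gene, per-cell counts, test, p_value, flag (and
#'   p_adjusted when requested), plus the tables as an attribute.
#' @export
association_screen <- function(cohort, genes, grouping,
                               denominator = c("mutated_only", "all"),
                               test = c("policy", "fisher", "chi2"),
                               adjust = NULL, context = list()) {
  denominator <- match.arg(denominator)
  test <- match.arg(test)
  sub <- cohort
  if (denominator == "mutated_only") {
    keep <- names(which(mutation_counts(cohort) >= 1))
    sub$patients <- cohort$patients[cohort$patients$patient_id %in% keep, ,
                                    drop = FALSE]
    sub$mutations <- cohort$mutations[cohort$mutations$patient_id %in% keep, ,
                                      drop = FALSE]
  }
  grp <- eval_factor(sub, grouping, context)
  keep <- !is.na(grp)
  if (any(!keep)) {
    message(sum(!keep), " patient(s) excluded from screen (missing grouping)")
  }
  ids <- sub$patients$patient_id[keep]
  grp <- grp[keep]
  pooling <- context$pooling %||% load_gene_pooling()
  genes_by_patient <- lapply(ids, function(id) patient_genes(sub, id, pooling))
  tables <- list()
  rows <- lapply(genes, function(g) {
    status <- factor(ifelse(vapply(genes_by_patient, function(gs) g %in% gs,
                                   logical(1)), "mutated", "wild_type"),
                     levels = c("mutated", "wild_type"))
    m <- matrix(as.integer(table(status, grp)), nrow = 2,
                dimnames = list(levels(status), levels(grp)))
    tab <- contingency_table(m, row_name = paste0("gene:", g),
                             col_name = factor_spec(grouping)$name)
    tables[[g]] <<- tab
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      res <- association_result(tab, "none", 1, flag = "degenerate")
    } else {
      use_fisher <- test == "fisher" ||
        (test == "policy" && all(dim(tab) == c(2, 2)))
      res <- if (use_fisher) fisher_exact_2x2(tab) else pearson_chi2(tab)
    }
    cells <- as.vector(t(unclass(tab)))
    names(cells) <- paste0(rep(rownames(tab), each = ncol(tab)), "_",
                           rep(colnames(tab), 2))
    cbind(data.frame(gene = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(cells)),
          data.frame(test = res$test, p_value = res$p_value,
                     flag = res$flag, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (identical(adjust, "BH")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  attr(out, "tables") <- tables
  out
}
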