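#' Build a pipeline run configuration
#'
#' Exactly one of \code{input} (paths to patient and mutation tables) or
#' \code{simulation} (a \code{\link{simulation_config}}) must be given.
#'
#' @param out_dir output directory for the report bundle.
#' @param input list with \code{patient} and optional \code{mutation}
#'   table paths, or \code{NULL}.
#' @param simulation a \code{simulation_config}, or \code{NULL}.
#' @param seed seed applied to the simulation and any other randomness.
#' @param strict turn validation warnings into errors.
#' @param screen_genes genes for the association screen; default is the
#'   M-IPSS-R selected genes plus the most frequent splice-factor genes.
#' @param survival_genes genes for per-gene KM comparisons.
#' @param ipssr_table_path,mipssr_table_path,cyto_rules_path optional
#'   overrides of the shipped configuration files.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(out_dir, input = NULL, simulation = NULL, seed = 1,
                       strict = FALSE,
                       screen_genes = c("SF3B1", "SRSF2", "U2AF1", "ASXL1",
                                        "RUNX1", "TET2", "TP53", "NRAS",
                                        "KRAS", "NOTCH1", "JAK2/3"),
                       survival_genes = c("TET2", "ASXL1", "TP53", "RUNX1",
                                          "NRAS", "KRAS", "NOTCH1"),
                       ipssr_table_path = NULL, mipssr_table_path = NULL,
                       cyto_rules_path = NULL) {
  if (is.null(input) == is.null(simulation)) {
    stop_mds("exactly one of input or simulation must be set")
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "simulation_config"))
    simulation$seed <- seed
  }
  structure(list(out_dir = out_dir, input = input, simulation = simulation,
                 seed = seed, strict = strict, screen_genes = screen_genes,
                 survival_genes = survival_genes,
                 ipssr_table_path = ipssr_table_path,
                 mipssr_table_path = mipssr_table_path,
                 cyto_rules_path = cyto_rules_path),
            class = "run_config")
}

#' Validate pipeline inputs
#'
#' Schema, range, and referential checks on the configured inputs. In
#' strict mode warnings are promoted to errors.
#'
#' @param config a \code{run_config}.
#' @return list with \code{errors} and \code{warnings} (character
#'   vectors); invisibly the loaded cohort as \code{cohort} when loading
#'   succeeded.
#' @export
validate_inputs <- function(config) {
  errors <- character()
  warnings <- character()
  cohort <- NULL
  res <- withCallingHandlers(
    tryCatch({
      cohort <- load_pipeline_cohort(config)
      NULL
    }, error = function(e) conditionMessage(e)),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!is.null(res)) errors <- c(errors, res)
  if (config$strict && length(warnings) > 0) {
    errors <- c(errors, paste0("strict: ", warnings))
    warnings <- character()
  }
  list(errors = errors, warnings = warnings, cohort = cohort)
}

load_pipeline_cohort <- function(config) {
  if (!is.null(config$simulation)) {
    return(generate_cohort(config$simulation))
  }
  paths <- config$input
  if (is.null(paths$patient) || !file.exists(paths$patient)) {
    stop_mds("patient table path unreadable: ", paths$patient %||% "<missing>")
  }
  cohort <- read_patient_table(paths$patient, dialect = paths$dialect %||% "tsv")
  if (!is.null(paths$mutation)) {
    calls <- read_mutation_table(paths$mutation,
                                 dialect = paths$dialect %||% "tsv")
    cohort <- attach_mutations(cohort, calls, strict = isTRUE(config$strict))
  }
  list(cohort = cohort, truth = NULL)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the cohort; validate; cytogenetic
#' classification; IPSS-R and M-IPSS-R scoring; cohort summary;
#' association tables (mutation status by risk dichotomy, cytogenetic
#' group and age group; per-gene screen); per-gene Kaplan-Meier/log-rank;
#' univariate and multivariate Cox; reclassification report. A manifest
#' records the seed, configuration versions and an MD5 hash of every
#' emitted file. Outputs are deterministic given the seed; a stage
#' failure aborts with the stage name and removes partial outputs.
#'
#' @param config a \code{run_config}.
#' @return object of class \code{report_bundle}: a list of the in-memory
#'   results plus \code{files} (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- "load"
  on_fail <- function(e) {
    unlink(written)
    stop_mds("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  }
  tryCatch({
    loaded <- load_pipeline_cohort(config)
    cohort <- loaded$cohort

    stage <- "validate"
    patients_in <- nrow(cohort$patients)
    message("stage=load patients=", patients_in,
            " calls=", nrow(cohort$mutations))

    stage <- "cytogenetics"
    rules <- if (is.null(config$cyto_rules_path)) load_cyto_rules() else
      load_cyto_rules(config$cyto_rules_path)
    cyto <- classify_cohort_cytogenetics(cohort, rules,
                                         missing_karyotype = if (config$strict)
                                           "error" else "assume_normal")
    f_cyto <- write_tsv(cyto, file.path(out, "cytogenetics.tsv"))
    written <- c(written, f_cyto)
    message("stage=cytogenetics abnormal=", sum(cyto$n_abnormalities > 0))

    stage <- "scoring"
    ipssr_table <- if (is.null(config$ipssr_table_path)) default_ipssr_table()
      else load_score_table(config$ipssr_table_path)
    mipssr_table <- if (is.null(config$mipssr_table_path)) default_mipssr_table()
      else load_score_table(config$mipssr_table_path)
    scores <- score_cohort(cohort, cyto, ipssr_table, mipssr_table)
    f_scores <- write_tsv(scores, file.path(out, "scores.tsv"))
    written <- c(written, f_scores)
    context <- list(scores = scores, cyto = cyto)
    message("stage=scoring higher_risk=",
            sum(scores$ipssr_dichotomy == "higher"))

    stage <- "summary"
    summ <- summarize_cohort(cohort)
    f_summary <- file.path(out, "cohort_summary.json")
    jsonlite::write_json(unclass(summ), f_summary, auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, f_summary)

    stage <- "associations"
    assoc_tables <- list(
      mutation_by_ipssr35 = crosstab(cohort, "ipssr35", "mutation_status", context),
      mutation_by_cyto4 = crosstab(cohort, "cyto4", "mutation_status", context),
      mutation_by_age59 = crosstab(cohort, "age59", "mutation_status", context))
    assoc_rows <- lapply(names(assoc_tables), function(nm) {
      tab <- assoc_tables[[nm]]
      res <- if (all(dim(tab) == c(2, 2))) fisher_exact_2x2(tab) else
        pearson_chi2(tab)
      data.frame(table = nm, test = res$test, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    })
    f_assoc <- write_tsv(do.call(rbind, assoc_rows),
                         file.path(out, "associations.tsv"))
    screen <- association_screen(cohort, config$screen_genes, "ipssr35",
                                 denominator = "mutated_only",
                                 context = context)
    f_screen <- write_tsv(screen, file.path(out, "gene_screen.tsv"))
    written <- c(written, f_assoc, f_screen)

    stage <- "survival"
    surv_rows <- list()
    logrank <- list()
    for (g in config$survival_genes) {
      gc_ <- tryCatch(suppressMessages(
        km_by_factor(cohort, paste0("gene:", g), context)),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(gc_)) next
      gr <- gc_$groups
      gr$gene <- g
      surv_rows[[g]] <- gr
      logrank[[g]] <- list(stat = gc_$logrank_stat, df = gc_$df,
                           p_value = gc_$p_value)
    }
    surv_df <- if (length(surv_rows) > 0) do.call(rbind, surv_rows) else
      data.frame()
    f_surv <- write_tsv(surv_df, file.path(out, "survival_by_gene.tsv"))
    f_logrank <- file.path(out, "logrank.json")
    jsonlite::write_json(logrank, f_logrank, auto_unbox = TRUE, digits = NA)
    written <- c(written, f_surv, f_logrank)
    message("stage=survival genes_tested=", length(logrank))

    stage <- "cox"
    variates <- c("age60", "morphology", "cyto3", "blast5", "ipssr35",
                  paste0("gene:", config$survival_genes))
    uni_rows <- lapply(variates, function(v) {
      tryCatch(suppressMessages(suppressWarnings(
        cox_univariate(cohort, v, context = context)))$table,
        error = function(e)
          data.frame(variate = v, hr = NA_real_, ci_lower = NA_real_,
                     ci_upper = NA_real_, p_value = NA_real_,
                     model = "univariate", n = NA_integer_,
                     events = NA_integer_, converged = FALSE,
                     stringsAsFactors = FALSE))
    })
    multi <- tryCatch(suppressMessages(suppressWarnings(
      cox_multivariate(cohort, variates, context = context)))$table,
      error = function(e) data.frame())
    cox_df <- rbind(do.call(rbind, uni_rows),
                    if (nrow(multi) > 0) multi else NULL)
    f_cox <- write_tsv(cox_df, file.path(out, "cox.tsv"))
    written <- c(written, f_cox)

    stage <- "reclassification"
    reclass <- compare_stratification(scores)
    f_reclass <- file.path(out, "reclassification.json")
    jsonlite::write_json(list(counts = as.list(reclass$counts),
                              fractions = as.list(reclass$fractions),
                              n_compared = reclass$n_compared,
                              per_patient = reclass$per_patient),
                         f_reclass, auto_unbox = TRUE, digits = NA)
    written <- c(written, f_reclass)

    stage <- "truth"
    if (!is.null(loaded$truth)) {
      f_truth <- file.path(out, "truth.json")
      jsonlite::write_json(loaded$truth, f_truth, auto_unbox = TRUE,
                           digits = NA)
      written <- c(written, f_truth)
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("mdsrisk")),
      seed = config$seed,
      score_tables = list(ipssr = ipssr_table$version,
                          mipssr = mipssr_table$version),
      cyto_rules = rules$version,
      test_policy = "fisher-2x2/chi2-rxc",
      files = lapply(stats::setNames(nm = basename(written)), function(f)
        unname(tools::md5sum(file.path(out, f)))))
    f_manifest <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA)
    written <- c(written, f_manifest)

    structure(list(cohort = cohort, cyto = cyto, scores = scores,
                   summary = summ, associations = assoc_tables,
                   gene_screen = screen, survival = surv_df,
                   logrank = logrank, cox = cox_df,
                   reclassification = reclass, manifest = manifest,
                   files = written),
              class = "report_bundle")
  }, error = on_fail)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle:", length(x$files), "files\n")
  cat(" ", paste(basename(x$files), collapse = ", "), "\n")
  invisible(x)
}
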