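PATIENT_COLUMNS <- c("patient_id", "age", "sex", "hemoglobin", "platelets",
                     "anc", "bm_blast_pct", "morphology", "karyotype",
                     "os_months", "event")
NUMERIC_PATIENT_COLUMNS <- c("age", "hemoglobin", "platelets", "anc",
                             "bm_blast_pct", "os_months")
MORPHOLOGY_LEVELS <- c("SLD", "MLD", "EB")
VARIANT_CLASSES <- c("substitution", "deletion", "insertion", "duplication")

#' Construct an MDS cohort object
#'
#' An \code{mds_cohort} bundles a patient table with its attached mutation
#' calls. Patients are one row each; mutation calls reference patients by
#' \code{patient_id} and there may be several calls per patient and gene.
#'
#' @param patients data frame with columns \code{patient_id}, \code{age},
#'   \code{sex} (\code{"male"}/\code{"female"}), \code{hemoglobin} (g/dL),
#'   \code{platelets} (x10^9/L), \code{anc} (x10^9/L), \code{bm_blast_pct},
#'   \code{morphology} (\code{"SLD"}, \code{"MLD"}, \code{"EB"}),
#'   \code{karyotype} (ISCN string or \code{NA}), \code{os_months},
#'   \code{event} (1 = death, 0 = censored).
#' @param mutations data frame of mutation calls (see
#'   \code{\link{read_mutation_table}}); may be empty.
#' @param provenance free-text source description (file path or generator
#'   seed).
#' @return An object of class \code{mds_cohort}.
#' @export
mds_cohort <- function(patients, mutations = empty_mutation_table(),
                       provenance = NA_character_) {
  patients <- validate_patient_frame(patients)
  mutations <- validate_mutation_frame(mutations)
  unknown <- setdiff(mutations$patient_id, patients$patient_id)
  if (length(unknown) > 0) {
    stop_mds("mutation calls reference unknown patient_id(s): ",
             paste(unique(unknown), collapse = ", "))
  }
  structure(list(patients = patients, mutations = mutations,
                 provenance = provenance),
            class = "mds_cohort")
}

#' @export
print.mds_cohort <- function(x, ...) {
  cat(sprintf("mds_cohort: %d patients, %d mutation calls (%d mutated patients)\n",
              nrow(x$patients), nrow(x$mutations),
              length(unique(x$mutations$patient_id))))
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

empty_mutation_table <- function() {
  data.frame(patient_id = character(), gene = character(),
              variant_class = character(), raw_ref = character(),
              raw_alt = character(), stringsAsFactors = FALSE)
}

validate_patient_frame <- function(patients) {
  missing_cols <- setdiff(PATIENT_COLUMNS, names(patients))
  if (length(missing_cols) > 0) {
    stop_mds("patient table lacks required column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  patients$patient_id <- as.character(patients$patient_id)
  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup) > 0) {
    stop_mds("duplicate patient_id(s): ", paste(unique(dup), collapse = ", "))
  }
  for (col in NUMERIC_PATIENT_COLUMNS) {
    v <- patients[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad) > 0) {
        stop_mds("column '", col, "' unparseable as numeric at row(s): ",
                 paste(bad, collapse = ", "))
      }
      patients[[col]] <- parsed
    }
  }
  patients$sex <- normalize_sex(patients$sex)
  morph <- normalize_morphology(patients$morphology)
  patients$morphology <- morph$morphology
  patients$morphology_subclass <- morph$subclass
  patients$karyotype <- as.character(patients$karyotype)
  patients$karyotype[!is.na(patients$karyotype) &
                       !nzchar(trimws(patients$karyotype))] <- NA_character_
  patients$event <- normalize_event(patients$event)

  chk_range <- function(col, lo, hi) {
    v <- patients[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad) > 0) {
      stop_mds("column '", col, "' out of range [", lo, ", ", hi,
               "] at row(s): ", paste(bad, collapse = ", "))
    }
  }
  chk_range("age", 0, 130)
  chk_range("bm_blast_pct", 0, 100)
  chk_range("hemoglobin", 0, Inf)
  chk_range("platelets", 0, Inf)
  chk_range("anc", 0, Inf)
  chk_range("os_months", 0, Inf)

  # EB is a morphologic call; blasts < 5% with EB is suspicious but allowed
  odd <- which(patients$morphology == "EB" & !is.na(patients$bm_blast_pct) &
                 patients$bm_blast_pct < 5)
  if (length(odd) > 0) {
    warn_mds("morphology EB with bone-marrow blasts < 5% for patient(s): ",
             paste(patients$patient_id[odd], collapse = ", "),
             class = "mdsrisk_consistency_warning")
  }
  rownames(patients) <- NULL
  patients
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("male", "m"), "male",
                ifelse(x %in% c("female", "f"), "female", NA_character_))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    stop_mds("unrecognized sex value(s) at row(s): ", paste(bad, collapse = ", "))
  }
  out
}

normalize_morphology <- function(x) {
  raw <- toupper(trimws(as.character(x)))
  raw <- sub("^MDS[- ]?", "", raw)
  subclass <- rep(NA_character_, length(raw))
  subclass[grepl("^EB[- ]?1$", raw)] <- "EB-1"
  subclass[grepl("^EB[- ]?2$", raw)] <- "EB-2"
  morph <- ifelse(grepl("^EB([- ]?[12])?$", raw), "EB", raw)
  bad <- which(!is.na(morph) & morph != "" & !(morph %in% MORPHOLOGY_LEVELS))
  if (length(bad) > 0) {
    stop_mds("unrecognized morphology value(s): ",
             paste(unique(raw[bad]), collapse = ", "))
  }
  morph[morph == ""] <- NA_character_
  list(morphology = morph, subclass = subclass)
}

normalize_event <- function(x) {
  if (is.numeric(x)) {
    bad <- which(!is.na(x) & !(x %in% c(0, 1)))
    if (length(bad) > 0) {
      stop_mds("event must be 0 (censored) or 1 (death); bad row(s): ",
               paste(bad, collapse = ", "))
    }
    return(as.integer(x))
  }
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("1", "death", "dead", "event"), 1L,
                ifelse(x %in% c("0", "censored", "alive"), 0L, NA_integer_))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    stop_mds("unrecognized event value(s) at row(s): ", paste(bad, collapse = ", "))
  }
  out
}

validate_mutation_frame <- function(mutations) {
  need <- c("patient_id", "gene", "variant_class")
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(mutations))
  if (length(missing_cols) > 0) {
    stop_mds("mutation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(mutations$raw_ref)) mutations$raw_ref <- NA_character_
  if (is.null(mutations$raw_alt)) mutations$raw_alt <- NA_character_
  mutations$patient_id <- as.character(mutations$patient_id)
  mutations$gene <- toupper(trimws(as.character(mutations$gene)))
  if (any(!nzchar(mutations$gene))) stop_mds("empty gene symbol in mutation table")
  bad <- which(!is.na(mutations$variant_class) &
                 !(mutations$variant_class %in% VARIANT_CLASSES))
  if (length(bad) > 0) {
    stop_mds("unrecognized variant_class at row(s): ", paste(bad, collapse = ", "))
  }
  rownames(mutations) <- NULL
  mutations[c("patient_id", "gene", "variant_class", "raw_ref", "raw_alt")]
}

#' Read a patient cohort table
#'
#' Reads a TSV (default) or CSV file with one row per patient. Required
#' columns: \code{patient_id, age, sex, hemoglobin, platelets, anc,
#' bm_blast_pct, morphology, karyotype, os_months, event}. Categorical
#' fields are normalized case-insensitively; a missing karyotype is
#' recorded as \code{NA}.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return An \code{mds_cohort} with no mutation calls attached.
#' @export
read_patient_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_mds("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  mds_cohort(raw, provenance = path)
}

#' Write a patient cohort table
#'
#' @param cohort an \code{mds_cohort}.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @export
write_patient_table <- function(cohort, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  # karyotype strings contain commas: quote character fields in csv
  utils::write.table(cohort$patients[PATIENT_COLUMNS], path, sep = sep,
                     row.names = FALSE, quote = dialect == "csv", na = "NA")
  invisible(path)
}

#' Read a mutation call table
#'
#' Columns: \code{patient_id}, \code{gene}, and either \code{variant_class}
#' or both \code{raw_ref} and \code{raw_alt} (in which case the class is
#' derived with \code{\link{classify_variant_class}}). Gene symbols are
#' upper-cased.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return data frame of mutation calls.
#' @export
read_mutation_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_mds("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  if (!all(c("patient_id", "gene") %in% names(raw))) {
    stop_mds("mutation table lacks column(s): ",
             paste(setdiff(c("patient_id", "gene"), names(raw)), collapse = ", "))
  }
  has_class <- "variant_class" %in% names(raw)
  has_alleles <- all(c("raw_ref", "raw_alt") %in% names(raw))
  if (!has_class && !has_alleles) {
    stop_mds("mutation table needs variant_class or raw_ref+raw_alt columns")
  }
  if (!has_class) raw$variant_class <- rep(NA_character_, nrow(raw))
  if (!has_alleles) {
    raw$raw_ref <- rep(NA_character_, nrow(raw))
    raw$raw_alt <- rep(NA_character_, nrow(raw))
  }
  raw$variant_class <- tolower(raw$variant_class)
  fill <- which(is.na(raw$variant_class))
  for (i in fill) {
    if (is.na(raw$raw_ref[i]) || is.na(raw$raw_alt[i])) {
      stop_mds("row ", i, ": neither variant_class nor raw_ref/raw_alt present")
    }
    raw$variant_class[i] <- classify_variant_class(raw$raw_ref[i], raw$raw_alt[i])
  }
  validate_mutation_frame(raw)
}

#' Write a mutation call table
#' @param mutations data frame of mutation calls.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @export
write_mutation_table <- function(mutations, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(mutations, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a cohort as a JSON bundle
#' @param cohort an \code{mds_cohort}.
#' @param path output path.
#' @export
write_cohort_json <- function(cohort, path) {
  jsonlite::write_json(list(patients = cohort$patients,
                            mutations = cohort$mutations,
                            provenance = cohort$provenance),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Classify a variant by its ref/alt alleles
#'
#' Equal-length alleles are substitutions; a shorter alt is a deletion; a
#' longer alt is an insertion, reported as a duplication only when flanking
#' reference context is supplied and the inserted segment repeats the
#' sequence immediately preceding it.
#'
#' @param raw_ref,raw_alt allele strings (A/C/G/T).
#' @param context optional reference sequence immediately upstream of
#'   \code{raw_ref}; required to ever call a duplication.
#' @return one of \code{"substitution"}, \code{"deletion"},
#'   \code{"insertion"}, \code{"duplication"}.
#' @export
classify_variant_class <- function(raw_ref, raw_alt, context = NULL) {
  if (is.na(raw_ref) || is.na(raw_alt) || !nzchar(raw_ref) || !nzchar(raw_alt)) {
    stop_mds("both alleles must be non-empty")
  }
  ref <- toupper(raw_ref); alt <- toupper(raw_alt)
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
    stop_mds("non-nucleotide characters in alleles: ", raw_ref, "/", raw_alt)
  }
  nr <- nchar(ref); na_ <- nchar(alt)
  if (nr == na_) return("substitution")
  if (na_ < nr) return("deletion")
  # insertion; duplication only decidable with upstream context
  pre_len <- common_prefix_len(ref, alt)
  seg <- substr(alt, pre_len + 1, pre_len + (na_ - nr))
  upstream <- paste0(toupper(context %||% ""), substr(ref, 1, pre_len))
  nu <- nchar(upstream)
  if (!is.null(context) && nu >= nchar(seg) &&
      substr(upstream, nu - nchar(seg) + 1, nu) == seg) {
    return("duplication")
  }
  "insertion"
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}

#' Attach mutation calls to a cohort
#'
#' @param cohort an \code{mds_cohort}.
#' @param calls data frame of mutation calls.
#' @param strict if \code{TRUE}, any call whose \code{patient_id} is not in
#'   the cohort is an error; otherwise such calls are dropped with a warning.
#' @return the cohort with calls attached.
#' @export
attach_mutations <- function(cohort, calls, strict = FALSE) {
  calls <- validate_mutation_frame(calls)
  unknown <- setdiff(unique(calls$patient_id), cohort$patients$patient_id)
  if (length(unknown) > 0) {
    if (strict) {
      stop_mds("mutation calls for unknown patient_id(s): ",
               paste(unknown, collapse = ", "))
    }
    warn_mds(length(unknown), " unmatched patient_id(s) dropped: ",
             paste(unknown, collapse = ", "))
    calls <- calls[calls$patient_id %in% cohort$patients$patient_id, , drop = FALSE]
  }
  cohort$mutations <- rbind(cohort$mutations, calls)
  rownames(cohort$mutations) <- NULL
  cohort
}

#' Load a gene-pooling map
#'
#' Gene families reported as one entity (JAK2/JAK3 as \code{"JAK2/3"},
#' IDH1/IDH2 as \code{"IDH1/2"}) are pooled through a configurable map.
#'
#' @param path JSON file mapping gene symbol to pooled label; default is the
#'   shipped map.
#' @return named character vector.
#' @export
load_gene_pooling <- function(path = mds_config_path("gene_pooling_default.json")) {
  m <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  stopifnot(is.character(m), !is.null(names(m)))
  m
}

#' Apply a gene-pooling map to gene symbols
#' @param genes character vector of symbols.
#' @param pooling named character vector (see \code{\link{load_gene_pooling}}),
#'   or \code{NULL} for no pooling.
#' @return character vector with pooled labels substituted.
#' @export
pool_genes <- function(genes, pooling = load_gene_pooling()) {
  if (is.null(pooling)) return(genes)
  hit <- genes %in% names(pooling)
  genes[hit] <- unname(pooling[genes[hit]])
  genes
}

#' Per-patient mutation call counts
#' @param cohort an \code{mds_cohort}.
#' @return named integer vector over all patients (zeros included).
#' @export
mutation_counts <- function(cohort) {
  counts <- table(factor(cohort$mutations$patient_id,
                         levels = cohort$patients$patient_id))
  stats::setNames(as.integer(counts), cohort$patients$patient_id)
}

#' Genes mutated in a given patient
#' @param cohort an \code{mds_cohort}.
#' @param patient_id patient identifier.
#' @param pooling optional pooling map applied to the symbols.
#' @return character vector of distinct (pooled) gene labels.
#' @export
patient_genes <- function(cohort, patient_id, pooling = NULL) {
  g <- cohort$mutations$gene[cohort$mutations$patient_id == patient_id]
  unique(pool_genes(g, pooling))
}

#' Summarize a cohort
#'
#' Counts mutated patients, tallies calls per WHO morphology subtype with
#' per-subtype means (calls per patient, 2 decimals), the median and range
#' of per-patient call counts over all patients (zeros included),
#' variant-class tallies, and age-group counts at the 59-year cut.
#'
#' @param cohort a non-empty \code{mds_cohort}.
#' @return object of class \code{cohort_summary}.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort$patients) == 0) stop_mds("empty cohort")
  counts <- mutation_counts(cohort)
  subtype <- factor(cohort$patients$morphology, levels = MORPHOLOGY_LEVELS)
  per_subtype_n <- as.integer(table(subtype))
  per_subtype_calls <- as.integer(tapply(counts, subtype, sum, default = 0))
  per_subtype_mean <- ifelse(per_subtype_n > 0,
                             round(per_subtype_calls / per_subtype_n, 2), 0)
  vc <- table(factor(cohort$mutations$variant_class, levels = VARIANT_CLASSES))
  age <- cohort$patients$age
  structure(list(
    n_patients = nrow(cohort$patients),
    n_with_mutation = sum(counts >= 1),
    per_subtype = data.frame(
      subtype = MORPHOLOGY_LEVELS, n_patients = per_subtype_n,
      n_calls = per_subtype_calls, mean_calls = per_subtype_mean,
      stringsAsFactors = FALSE),
    median_mutations = stats::median(counts),
    range_mutations = range(counts),
    variant_class_tally = stats::setNames(as.integer(vc), VARIANT_CLASSES),
    age_groups = c(le59 = sum(age <= 59, na.rm = TRUE),
                   gt59 = sum(age > 59, na.rm = TRUE))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: %d patients, %d (%.1f%%) with >=1 mutation\n",
              x$n_patients, x$n_with_mutation,
              100 * x$n_with_mutation / x$n_patients))
  cat(sprintf("median mutations per patient: %g (range %d-%d)\n",
              x$median_mutations, x$range_mutations[1], x$range_mutations[2]))
  print(x$per_subtype, row.names = FALSE)
  cat("variant classes:",
      paste(names(x$variant_class_tally), x$variant_class_tally,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
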