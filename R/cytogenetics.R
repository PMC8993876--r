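CYTO_CATEGORIES <- c("VeryGood", "Good", "Intermediate", "Poor", "VeryPoor")
CYTO_POINTS <- c(VeryGood = 0, Good = 1, Intermediate = 2, Poor = 3, VeryPoor = 4)

#' Parse an ISCN karyotype string
#'
#' Supports the ISCN subset seen in conventional MDS cytogenetics:
#' mosaic clones separated by \code{"/"}, bracketed cell counts, numerical
#' gains/losses (\code{+8}, \code{-7}, \code{-Y}), and the structural
#' tokens \code{del}, \code{add}, \code{inv}, \code{t}, \code{i},
#' \code{dup}, \code{der}, \code{mar}; \code{idem} expands the stem
#' clone's abnormalities. Abnormality identity is the normalized arm-level
#' token, so \code{del(5)(q13q33)} and \code{del(5)(q13q34)} both count
#' once as \code{del(5q)}; the same token in two subclones counts once.
#' Ring chromosomes, insertions and nested rearrangements are outside the
#' subset and raise an error naming the token.
#'
#' @param karyotype non-empty ISCN string, e.g.
#'   \code{"46,XY,del(5)(q13q33)[15]/46,XY[5]"}.
#' @return Object of class \code{karyotype_report} with elements
#'   \code{clones} (list of modal number, sex complement, abnormality
#'   tokens, cell count), \code{clonal_abnormalities} (deduplicated
#'   normalized tokens), \code{abn_details} (parsed per-token structure),
#'   \code{n_abnormalities}, and \code{is_normal}.
#' @export
parse_iscn <- function(karyotype) {
  if (length(karyotype) != 1 || is.na(karyotype) || !nzchar(trimws(karyotype))) {
    stop_mds("empty karyotype string")
  }
  clone_strs <- strsplit(trimws(karyotype), "/", fixed = TRUE)[[1]]
  clones <- list()
  stem_tokens <- NULL
  for (cs in clone_strs) {
    cs <- trimws(cs)
    cells <- NA_integer_
    m <- regmatches(cs, regexec("\\[([0-9]+)\\]$", cs))[[1]]
    if (length(m) == 2) {
      cells <- as.integer(m[2])
      cs <- sub("\\[[0-9]+\\]$", "", cs)
    }
    parts <- split_top_level(cs)
    if (length(parts) < 2) stop_mds("clone lacks modal number and sex complement: ", cs)
    modal <- suppressWarnings(as.integer(parts[1]))
    if (is.na(modal)) stop_mds("unsupported modal number token: ", parts[1])
    sex <- toupper(trimws(parts[2]))
    if (!grepl("^[XY]+$", sex)) stop_mds("unsupported sex complement token: ", parts[2])
    abn_raw <- if (length(parts) > 2) parts[-(1:2)] else character()
    tokens <- character()
    for (tok in abn_raw) {
      tok <- trimws(tok)
      if (tolower(tok) == "idem") {
        if (is.null(stem_tokens)) stop_mds("'idem' in the first clone: ", cs)
        tokens <- c(tokens, stem_tokens)
      } else {
        tokens <- c(tokens, tok)
      }
    }
    if (is.null(stem_tokens)) stem_tokens <- tokens
    clones[[length(clones) + 1]] <- list(modal = modal, sex = sex,
                                         tokens = tokens, cells = cells)
  }
  details <- do.call(rbind, c(
    list(data.frame(token = character(), type = character(),
                    chroms = character(), arms = character(),
                    stringsAsFactors = FALSE)),
    lapply(unique(unlist(lapply(clones, `[[`, "tokens"))), parse_abn_token)))
  details <- details[!duplicated(details$token), , drop = FALSE]
  rownames(details) <- NULL
  structure(list(clones = clones,
                 clonal_abnormalities = details$token,
                 abn_details = details,
                 n_abnormalities = nrow(details),
                 is_normal = nrow(details) == 0),
            class = "karyotype_report")
}

#' @export
print.karyotype_report <- function(x, ...) {
  cat(sprintf("karyotype_report: %d clone(s), %d clonal abnormalit%s\n",
              length(x$clones), x$n_abnormalities,
              if (x$n_abnormalities == 1) "y" else "ies"))
  if (x$n_abnormalities > 0) {
    cat(" ", paste(x$clonal_abnormalities, collapse = ", "), "\n")
  }
  invisible(x)
}

# split on commas not inside parentheses
split_top_level <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0
  out <- character()
  cur <- ""
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (ch == "," && depth == 0) {
      out <- c(out, cur); cur <- ""
    } else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

# one raw ISCN abnormality token -> normalized arm-level record
parse_abn_token <- function(tok) {
  tok <- gsub("−", "-", tok)  # unicode minus
  rec <- function(token, type, chroms = "", arms = "") {
    data.frame(token = token, type = type, chroms = chroms, arms = arms,
               stringsAsFactors = FALSE)
  }
  if (tok %in% c("+mar", "mar")) return(rec("mar", "mar"))
  m <- regmatches(tok, regexec("^\\+([0-9]+|X|Y)$", tok))[[1]]
  if (length(m) == 2) return(rec(paste0("+", m[2]), "gain", m[2]))
  m <- regmatches(tok, regexec("^-([0-9]+|X|Y)$", tok))[[1]]
  if (length(m) == 2) return(rec(paste0("-", m[2]), "loss", m[2]))

  # structural: op(chroms)(bands) or pre-normalized op(5q) shorthand
  m <- regmatches(tok, regexec(
    "^(del|add|inv|dup|i|t|der)\\(([0-9XY;]+)\\)(\\(([^()]*)\\))?$", tok))[[1]]
  if (length(m) == 0) {
    # accept shorthand with arm inside first parens, e.g. del(5q), i(17q), t(3q)
    m2 <- regmatches(tok, regexec(
      "^(del|add|inv|dup|i|t)\\(([0-9XY]+)([pq])\\)$", tok))[[1]]
    if (length(m2) == 4) {
      op <- m2[1]; chrom <- m2[2]; arm <- m2[3]
      if (op == "inv") return(rec(paste0("inv(", chrom, ")"), "inv", chrom, arm))
      return(rec(paste0(op, "(", chrom, arm, ")"), op, chrom, arm))
    }
    stop_mds("unsupported ISCN token: ", tok)
  }
  op <- m[2]; chroms_s <- m[3]; bands_s <- if (length(m) >= 5) m[5] else ""
  chroms <- strsplit(chroms_s, ";", fixed = TRUE)[[1]]
  bands <- if (nzchar(bands_s)) strsplit(bands_s, ";", fixed = TRUE)[[1]] else character()
  arm_of <- function(band) {
    a <- regmatches(band, regexec("^([pq])", band))[[1]]
    if (length(a) == 2) a[2] else ""
  }
  arms <- vapply(bands, arm_of, "", USE.NAMES = FALSE)
  if (op == "der") {
    return(rec(paste0("der(", chroms_s, ")"), "der", chroms_s, ""))
  }
  if (op == "inv") {
    # pericentric/paracentric alike: chromosome-level identity
    return(rec(paste0("inv(", chroms[1], ")"), "inv", chroms[1],
               paste(arms, collapse = ";")))
  }
  if (op == "t") {
    if (length(arms) != length(chroms)) arms <- rep("", length(chroms))
    lab <- paste0(chroms, arms)
    return(rec(paste0("t(", paste(lab, collapse = ";"), ")"), "t",
               paste(chroms, collapse = ";"), paste(arms, collapse = ";")))
  }
  # del/add/dup/i on a single chromosome; arm from the first band
  arm <- if (length(arms) > 0) arms[1] else ""
  if (!nzchar(arm)) stop_mds("cannot determine arm for token: ", tok)
  rec(paste0(op, "(", chroms[1], arm, ")"), op, chroms[1], arm)
}

#' Load a cytogenetic risk-rule table
#'
#' Rules are data, not code: a JSON array in precedence order, each entry
#' \code{\{id, category, points, when: \{kind, ...params\}\}}. The shipped
#' default encodes the IPSS-R comprehensive cytogenetic categories.
#'
#' @param path JSON rule file; default is the shipped IPSS-R table.
#' @return object of class \code{cyto_rules}.
#' @export
load_cyto_rules <- function(path = mds_config_path("cyto_rules_default.json")) {
  raw <- jsonlite::read_json(path)
  rules <- raw$rules
  for (r in rules) {
    if (!(r$category %in% CYTO_CATEGORIES)) {
      stop_mds("rule '", r$id, "': unknown category ", r$category)
    }
    if (r$points != CYTO_POINTS[[r$category]]) {
      stop_mds("rule '", r$id, "': points do not match category")
    }
  }
  structure(list(version = raw$version %||% "unversioned", rules = rules),
            class = "cyto_rules")
}

lesion_matches <- function(details, spec) {
  if (nrow(details) == 0) return(logical(0))
  ok <- rep(TRUE, nrow(details))
  if (!is.null(spec$type)) ok <- ok & details$type == spec$type
  if (!is.null(spec$chrom)) {
    ok <- ok & vapply(strsplit(details$chroms, ";"), function(cs)
      spec$chrom %in% cs, logical(1))
  }
  if (!is.null(spec$arm)) {
    # arm must match on the specified chromosome (translocation partners)
    ok <- ok & mapply(function(cs, as_) {
      cs <- strsplit(cs, ";")[[1]]; as_ <- strsplit(as_, ";")[[1]]
      if (length(as_) < length(cs)) as_ <- c(as_, rep("", length(cs) - length(as_)))
      any(cs == (spec$chrom %||% cs) & as_ == spec$arm)
    }, details$chroms, details$arms)
  }
  ok
}

rule_applies <- function(rule, report) {
  d <- report$abn_details
  n <- report$n_abnormalities
  w <- rule$when
  switch(w$kind,
    normal = n == 0,
    complex = {
      lo <- w$min_abnormalities %||% 0
      hi <- w$max_abnormalities %||% Inf
      n >= lo && n <= hi
    },
    contains_any = {
      max_n <- w$max_n %||% Inf
      n <= max_n && n >= 1 &&
        any(vapply(w$lesions, function(sp) any(lesion_matches(d, sp)), logical(1)))
    },
    isolated_any = {
      n == 1 &&
        any(vapply(w$lesions, function(sp) any(lesion_matches(d, sp)), logical(1)))
    },
    double_including = {
      n == 2 &&
        any(vapply(w$lesions, function(sp) any(lesion_matches(d, sp)), logical(1)))
    },
    single_or_double = n >= 1 && n <= 2,
    stop_mds("unknown rule kind: ", w$kind)
  )
}

#' Assign the IPSS-R cytogenetic risk category
#'
#' Applies the rule table in precedence order (very complex before complex
#' before specific doubles before specific singles, with any residual
#' single/double falling to Intermediate) and records which rule fired.
#'
#' @param report a \code{karyotype_report} from \code{\link{parse_iscn}}.
#' @param rules a \code{cyto_rules} table.
#' @return object of class \code{cyto_risk}: \code{category},
#'   \code{ipssr_points} (VeryGood 0 ... VeryPoor 4), \code{rule_fired}.
#' @export
classify_cytogenetic_risk <- function(report, rules = load_cyto_rules()) {
  if (!inherits(report, "karyotype_report")) {
    stop_mds("report must be a parsed karyotype_report")
  }
  for (r in rules$rules) {
    if (rule_applies(r, report)) {
      return(structure(list(category = r$category,
                            ipssr_points = CYTO_POINTS[[r$category]],
                            rule_fired = r$id),
                       class = "cyto_risk"))
    }
  }
  stop_mds("no cytogenetic rule matched (rule table not exhaustive)")
}

#' @export
print.cyto_risk <- function(x, ...) {
  cat(sprintf("cyto_risk: %s (%g points, rule %s)\n",
              x$category, x$ipssr_points, x$rule_fired))
  invisible(x)
}

#' Classify cytogenetic risk for every patient in a cohort
#'
#' @param cohort an \code{mds_cohort}.
#' @param rules a \code{cyto_rules} table.
#' @param missing_karyotype what to do with absent karyotypes:
#'   \code{"error"} (strict) or \code{"assume_normal"}, which assigns the
#'   normal-karyotype category and flags the assumption in
#'   \code{rule_fired}.
#' @param collapse_very_good merge VeryGood into Good in the
#'   \code{group4} column (the four-row grouping used for cohort tables).
#' @return data frame: patient_id, n_abnormalities, category, points,
#'   rule_fired, group4.
#' @export
classify_cohort_cytogenetics <- function(cohort, rules = load_cyto_rules(),
                                         missing_karyotype = c("error", "assume_normal"),
                                         collapse_very_good = TRUE) {
  missing_karyotype <- match.arg(missing_karyotype)
  pts <- cohort$patients
  if (nrow(pts) == 0) {
    return(data.frame(patient_id = character(), n_abnormalities = integer(),
                      category = character(), points = numeric(),
                      rule_fired = character(), group4 = character(),
                      stringsAsFactors = FALSE))
  }
  absent <- is.na(pts$karyotype)
  if (any(absent) && missing_karyotype == "error") {
    stop_mds("missing karyotype for patient(s): ",
             paste(pts$patient_id[absent], collapse = ", "))
  }
  out <- lapply(seq_len(nrow(pts)), function(i) {
    if (absent[i]) {
      list(n = 0L, category = "Good", points = 1,
           rule = "missing-karyotype:normal-assumed")
    } else {
      rep_ <- parse_iscn(pts$karyotype[i])
      risk <- classify_cytogenetic_risk(rep_, rules)
      list(n = rep_$n_abnormalities, category = risk$category,
           points = risk$ipssr_points, rule = risk$rule_fired)
    }
  })
  category <- vapply(out, `[[`, "", "category")
  group4 <- category
  if (collapse_very_good) group4[group4 == "VeryGood"] <- "Good"
  data.frame(patient_id = pts$patient_id,
             n_abnormalities = vapply(out, `[[`, 0L, "n"),
             category = category,
             points = vapply(out, `[[`, 0, "points"),
             rule_fired = vapply(out, `[[`, "", "rule"),
             group4 = group4,
             stringsAsFactors = FALSE)
}
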