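# Code-list configuration: ICD/ATC/SKS code sets, grouping edges, prices and
# the behavioural switches shared by every pipeline stage.

#' Default code-list configuration
#'
#' Builds the configuration object used throughout the pipeline: the ICD-10
#' codes defining major depressive disorder (MDD) and their severity
#' partition, the diagnosis lists that exclude a person from the cohort
#' (bipolar and other affective mood disorders, persistent mood disorder,
#' schizophrenia-spectrum disorders, dementia; in both ICD-10 and ICD-8
#' dialects), the ATC prefixes defining the four antidepressant classes
#' (SSRI, SNRI, TCA, MAOI), the SKS procedure codes identifying
#' electroconvulsive therapy (ECT), medicine cost groupings, grouping edges
#' for age and calendar-year strata, the DKK-to-EUR conversion rate, the
#' +/- 365 day phenotyping window, and analysis switches.
#'
#' @details
#' Severity classes follow the diagnosis code of the first MDD hospital
#' contact: mild (F32.0, F32.8, F32.9, F33.0, F33.4, F33.8, F33.9), moderate
#' (F32.1, F33.1), severe (F32.2, F32.3, F33.2, F33.3). Costs are carried in
#' EUR internally; DKK input columns are divided by `dkk_per_eur` (7.47) at
#' load time. The bundled `fixed_price_table` carries synthetic per-contact
#' (per bed-day for hospitalizations) EUR prices for the fixed-price costing
#' pathway; the default costing mode is `"recorded"`, which uses the
#' per-event cost fields.
#'
#' @param ... named overrides for any top-level configuration field.
#' @return an object of class `code_config` (a named list).
#' @export
#' @examples
#' cfg <- default_code_config()
#' validate_code_config(cfg)
default_code_config <- function(...) {
  cfg <- list(
    mdd_codes = c(
      "F32.0", "F32.1", "F32.2", "F32.3", "F32.8", "F32.9",
      "F33.0", "F33.1", "F33.2", "F33.3", "F33.4", "F33.8", "F33.9"
    ),
    severity_map = list(
      mild     = c("F32.0", "F32.8", "F32.9", "F33.0", "F33.4", "F33.8", "F33.9"),
      moderate = c("F32.1", "F33.1"),
      severe   = c("F32.2", "F32.3", "F33.2", "F33.3")
    ),
    exclusion_codes = list(
      icd10 = c(
        "F30", "F31",              # bipolar affective disorder
        "F38", "F39",              # other affective mood disorders
        "F34",                     # persistent mood disorder
        "F20", "F21", "F22", "F23", "F24", "F25", "F28", "F29",  # schizophrenia spectrum
        "F00", "F01", "F02", "F03", "G30", "R54.9"               # dementia
      ),
      icd8 = c(
        "296.19", "296.39", "296.89", "296.99", "298.19",
        "295.x9", "297.x9",
        "298.29", "298.39", "298.49", "298.59", "298.69", "298.79",
        "298.89", "298.99",
        "299.04", "299.05", "299.09",
        "290.x"
      )
    ),
    antidepressant_class_prefixes = list(
      SSRI = "N06AB", SNRI = "N06AX", TCA = "N06AA", MAOI = c("N06AF", "N06AG")
    ),
    ect_codes = c("BRTB1", "BRXA1"),
    medicine_cost_groups = list(
      antidepressant = "N06A",
      other_psychiatric = c("N05A", "N05B")
    ),
    # synthetic per-contact prices (EUR); hospitalization rows are per bed day
    fixed_price_table = data.frame(
      sector = c(
        "psychiatric", "psychiatric", "psychiatric", "psychiatric", "psychiatric",
        "somatic", "somatic", "somatic", "somatic",
        "primary", "primary", "primary", "primary"
      ),
      contact_type = c(
        "hospitalization", "hospitalization", "ed", "outpatient", "home_visit",
        "hospitalization", "hospitalization", "ed", "outpatient",
        "gp", "private_psychiatrist", "private_psychologist", "other_specialist"
      ),
      admission_mode = c(
        "acute", "elective", "na", "na", "na",
        "acute", "elective", "na", "na",
        "na", "na", "na", "na"
      ),
      price_eur = c(
        600, 550, 300, 250, 150,
        800, 750, 350, 300,
        25, 90, 70, 60
      ),
      stringsAsFactors = FALSE
    ),
    dkk_per_eur = 7.47,
    window_days = 365L,
    activity_window_days = 90L,
    study_years = c(1996L, 2015L),
    age_group_breaks = c(18L, 25L, 45L, 65L, 85L),
    age_group_labels = c("18-24", "25-44", "45-64", "65-84", "85+"),
    year_group_breaks = c(1996L, 2001L, 2006L, 2011L),
    year_group_labels = c("1996-2000", "2001-2005", "2006-2010", "2011-2015"),
    # behavioural switches
    re_initiation_counts = FALSE,
    ect_always_shift = FALSE,
    min_days_between_shifts = 0L,
    cost_mode = "recorded",           # "recorded" or "fixed"
    include_index_day_in_post = FALSE,
    adjust_part1 = FALSE,
    cluster_by_set = FALSE,
    allow_partial = TRUE,
    condition_pre_window = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown code_config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "code_config")
}

#' @export
print.code_config <- function(x, ...) {
  cat("<code_config>\n")
  cat("  MDD codes:", length(x$mdd_codes),
      "| severity classes:", paste(names(x$severity_map), collapse = "/"), "\n")
  cat("  antidepressant classes:",
      paste(names(x$antidepressant_class_prefixes), collapse = ", "), "\n")
  cat("  window_days:", x$window_days,
      "| study years:", paste(x$study_years, collapse = "-"),
      "| DKK/EUR:", x$dkk_per_eur, "\n")
  invisible(x)
}

#' Validate a code-list configuration
#'
#' Checks the structural invariants of a [default_code_config()]-style
#' object: severity lists pairwise disjoint, their union equal to the MDD
#' code list, antidepressant class prefixes pairwise non-nested, probabilities
#' and rates on legal scales.
#'
#' @param config a `code_config` object.
#' @return character vector of violations; `character(0)` when valid.
#' @export
validate_code_config <- function(config) {
  v <- character(0)
  sm <- config$severity_map
  all_sev <- unlist(sm, use.names = FALSE)
  dups <- unique(all_sev[duplicated(all_sev)])
  for (d in dups) {
    in_cls <- names(sm)[vapply(sm, function(s) d %in% s, logical(1))]
    v <- c(v, sprintf("code %s appears in multiple severity classes: %s",
                      d, paste(in_cls, collapse = ", ")))
  }
  missing <- setdiff(config$mdd_codes, all_sev)
  for (m in missing) {
    v <- c(v, sprintf("MDD code %s is not assigned to any severity class", m))
  }
  extra <- setdiff(all_sev, config$mdd_codes)
  for (e in extra) {
    v <- c(v, sprintf("severity code %s is not in the MDD code list", e))
  }
  pfx <- unlist(config$antidepressant_class_prefixes, use.names = FALSE)
  for (i in seq_along(pfx)) for (j in seq_along(pfx)) {
    if (i != j && startsWith(pfx[i], pfx[j])) {
      v <- c(v, sprintf("antidepressant class prefixes nested: %s within %s",
                        pfx[i], pfx[j]))
    }
  }
  if (!is.numeric(config$dkk_per_eur) || config$dkk_per_eur <= 0) {
    v <- c(v, "dkk_per_eur must be a positive number")
  }
  if (config$window_days <= 0) v <- c(v, "window_days must be positive")
  v
}

#' Read / write a configuration as YAML
#'
#' @param path file path of the YAML document.
#' @return `read_code_config()` returns a `code_config`;
#'   `write_code_config()` returns `path` invisibly.
#' @export
read_code_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$fixed_price_table)) {
    raw$fixed_price_table <- as.data.frame(raw$fixed_price_table,
                                           stringsAsFactors = FALSE)
  }
  do.call(default_code_config, raw)
}

#' @rdname read_code_config
#' @param config a `code_config` object.
#' @export
write_code_config <- function(config, path) {
  out <- unclass(config)
  out$fixed_price_table <- as.list(out$fixed_price_table)
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---- code matching helpers --------------------------------------------------

# registries mix dotted/undotted dialects; comparison is prefix-based on
# dot-stripped uppercase strings
icd_normalize <- function(code) gsub(".", "", toupper(trimws(code)), fixed = TRUE)

# TRUE where `codes` (observed) match any configured prefix in `prefixes`.
# ICD-8 entries may carry an "x" wildcard standing for one digit.
icd_matches <- function(codes, prefixes) {
  nc <- icd_normalize(codes)
  hit <- rep(FALSE, length(nc))
  for (p in prefixes) {
    np <- icd_normalize(p)
    if (grepl("x", np, ignore.case = TRUE)) {
      rx <- paste0("^", gsub("X", "[0-9]", np))
      hit <- hit | grepl(rx, nc)
    } else {
      hit <- hit | startsWith(nc, np)
    }
  }
  hit
}

# exclusion match across both dialects: ICD-10 codes start with a letter,
# ICD-8 codes with a digit
is_exclusion_code <- function(codes, config) {
  nc <- icd_normalize(codes)
  icd10 <- grepl("^[A-Z]", nc)
  out <- rep(FALSE, length(nc))
  if (any(icd10)) {
    out[icd10] <- icd_matches(codes[icd10], config$exclusion_codes$icd10)
  }
  if (any(!icd10)) {
    out[!icd10] <- icd_matches(codes[!icd10], config$exclusion_codes$icd8)
  }
  out
}

is_mdd_code <- function(codes, config) icd_matches(codes, config$mdd_codes)
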