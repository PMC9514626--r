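# Registry bundle: the five person-level tables every stage consumes, with
# schema validation, CSV readers/writers and a lossless round-trip contract.

REGISTRY_TABLES <- c("persons", "diagnoses", "prescriptions", "procedures", "contacts")

registry_schema <- list(
  persons = list(
    cols = c("person_id", "sex", "birth_date", "death_date",
             "emigration_date", "education", "cohabiting"),
    dates = c("birth_date", "death_date", "emigration_date")
  ),
  diagnoses = list(
    cols = c("person_id", "date", "icd_code", "setting"),
    dates = "date"
  ),
  prescriptions = list(
    cols = c("person_id", "redemption_date", "atc_code", "cost_eur"),
    dates = "redemption_date"
  ),
  procedures = list(
    cols = c("person_id", "date", "sks_code"),
    dates = "date"
  ),
  contacts = list(
    cols = c("person_id", "start_date", "end_date", "sector", "contact_type",
             "admission_mode", "cost_eur"),
    dates = c("start_date", "end_date")
  )
)

SEX_LEVELS <- c("F", "M")
EDUCATION_LEVELS <- c("basic", "medium", "high", "unknown")
COHABITING_LEVELS <- c("yes", "no", "unknown")
SETTING_LEVELS <- c("psych_inpatient", "psych_outpatient",
                    "somatic_inpatient", "somatic_outpatient")
SECTOR_LEVELS <- c("psychiatric", "somatic", "primary")
CONTACT_TYPE_LEVELS <- c("hospitalization", "ed", "outpatient", "home_visit",
                         "gp", "private_psychiatrist", "private_psychologist",
                         "other_specialist")
PRIMARY_TYPES <- c("gp", "private_psychiatrist", "private_psychologist",
                   "other_specialist")
ADMISSION_LEVELS <- c("acute", "elective", "na")

#' Construct a validated registry bundle
#'
#' Wraps the five registry tables (persons, hospital diagnoses, prescription
#' redemptions, procedures, healthcare contacts) together with a code
#' configuration into a single validated object. All type invariants are
#' enforced; a malformed row yields a located error, never a silent drop.
#'
#' @param persons,diagnoses,prescriptions,procedures,contacts data.frames
#'   following the documented schemas (see [load_registry()]).
#' @param config a [default_code_config()] object.
#' @return an object of class `registry_bundle`.
#' @export
registry_bundle <- function(persons, diagnoses, prescriptions, procedures,
                            contacts, config = default_code_config()) {
  tabs <- list(persons = persons, diagnoses = diagnoses,
               prescriptions = prescriptions, procedures = procedures,
               contacts = contacts)
  tabs <- lapply(names(tabs), function(nm) coerce_table(tabs[[nm]], nm))
  names(tabs) <- REGISTRY_TABLES
  b <- structure(c(tabs, list(config = config)), class = "registry_bundle")
  validate_registry(b)
  b
}

coerce_table <- function(df, name) {
  sch <- registry_schema[[name]]
  missing <- setdiff(sch$cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", name, paste(missing, collapse = ", ")))
  }
  dt <- as.data.table(df)[, sch$cols, with = FALSE]
  for (dc in sch$dates) {
    val <- dt[[dc]]
    if (!inherits(val, "Date")) {
      ch <- as.character(val)
      parsed <- as.IDate(ch, format = "%Y-%m-%d")
      bad <- which(!is.na(ch) & ch != "" & is.na(parsed))
      if (length(bad)) {
        stop(sprintf("%s row %d: unparseable date '%s' in %s",
                     name, bad[1], ch[bad[1]], dc))
      }
      parsed[!is.na(ch) & ch == ""] <- NA
      set(dt, j = dc, value = parsed)
    } else {
      set(dt, j = dc, value = as.IDate(val))
    }
  }
  dt[]
}

#' Validate a registry bundle
#'
#' Runs every schema and cross-field invariant: unique person ids; dates in
#' chronological order where required; categorical fields on their legal
#' levels; nonnegative costs; admission mode present exactly for
#' hospitalizations; primary-sector contact types consistent with sector;
#' home visits only in the psychiatric sector.
#'
#' @param bundle a `registry_bundle`.
#' @return `bundle`, invisibly; stops with a located message on violation.
#' @export
validate_registry <- function(bundle) {
  p <- bundle$persons
  dup <- p$person_id[duplicated(p$person_id)]
  if (length(dup)) {
    stop(sprintf("persons: duplicate person_id '%s'", dup[1]))
  }
  check_levels(p$sex, SEX_LEVELS, "persons", "sex")
  check_levels(p$education, EDUCATION_LEVELS, "persons", "education")
  check_levels(p$cohabiting, COHABITING_LEVELS, "persons", "cohabiting")
  bad <- which(!is.na(p$death_date) & p$death_date < p$birth_date)
  if (length(bad)) stop(sprintf("persons row %d: death_date before birth_date", bad[1]))
  bad <- which(!is.na(p$emigration_date) & p$emigration_date < p$birth_date)
  if (length(bad)) stop(sprintf("persons row %d: emigration_date before birth_date", bad[1]))

  d <- bundle$diagnoses
  check_levels(d$setting, SETTING_LEVELS, "diagnoses", "setting")
  ok_code <- grepl("^[A-Za-z][0-9]", gsub(".", "", d$icd_code, fixed = TRUE)) |
    grepl("^[0-9]", d$icd_code)
  if (any(!ok_code)) {
    stop(sprintf("diagnoses row %d: icd_code '%s' matches neither ICD-10 nor ICD-8 dialect",
                 which(!ok_code)[1], d$icd_code[which(!ok_code)[1]]))
  }

  rx <- bundle$prescriptions
  bad <- which(nchar(rx$atc_code) != 7L)
  if (length(bad)) {
    stop(sprintf("prescriptions row %d: atc_code '%s' is not a 7-character level-5 code",
                 bad[1], rx$atc_code[bad[1]]))
  }
  bad <- which(is.na(rx$cost_eur) | rx$cost_eur < 0)
  if (length(bad)) stop(sprintf("prescriptions row %d: negative or missing cost_eur", bad[1]))

  ct <- bundle$contacts
  check_levels(ct$sector, SECTOR_LEVELS, "contacts", "sector")
  check_levels(ct$contact_type, CONTACT_TYPE_LEVELS, "contacts", "contact_type")
  check_levels(ct$admission_mode, ADMISSION_LEVELS, "contacts", "admission_mode")
  bad <- which(ct$end_date < ct$start_date)
  if (length(bad)) stop(sprintf("contacts row %d: end_date < start_date", bad[1]))
  bad <- which((ct$contact_type == "hospitalization") != (ct$admission_mode != "na"))
  if (length(bad)) {
    stop(sprintf("contacts row %d: admission_mode must be acute/elective exactly for hospitalizations",
                 bad[1]))
  }
  bad <- which((ct$sector == "primary") != (ct$contact_type %in% PRIMARY_TYPES))
  if (length(bad)) {
    stop(sprintf("contacts row %d: primary sector iff contact_type is gp/private/other specialist",
                 bad[1]))
  }
  bad <- which(ct$contact_type == "home_visit" & ct$sector != "psychiatric")
  if (length(bad)) stop(sprintf("contacts row %d: home_visit only in psychiatric sector", bad[1]))
  bad <- which(is.na(ct$cost_eur) | ct$cost_eur < 0)
  if (length(bad)) stop(sprintf("contacts row %d: negative or missing cost_eur", bad[1]))

  ids <- unique(p$person_id)
  for (nm in c("diagnoses", "prescriptions", "procedures", "contacts")) {
    unknown <- setdiff(unique(bundle[[nm]]$person_id), ids)
    if (length(unknown)) {
      stop(sprintf("%s: person_id '%s' not present in persons", nm, unknown[1]))
    }
  }
  invisible(bundle)
}

check_levels <- function(x, levels, table, col) {
  bad <- which(is.na(x) | !(x %in% levels))
  if (length(bad)) {
    stop(sprintf("%s row %d: %s '%s' not in {%s}", table, bad[1], col,
                 as.character(x[bad[1]]), paste(levels, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.registry_bundle <- function(x, ...) {
  cat("<registry_bundle>\n")
  for (nm in REGISTRY_TABLES) {
    cat(sprintf("  %-13s %7d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Load a registry bundle from CSV files
#'
#' Reads the five tables, parses ISO-8601 dates, converts an optional
#' `cost_dkk` column to EUR at the configured rate, and validates every
#' schema invariant. `paths` may be a directory containing the standard
#' file names (`persons.csv`, `diagnoses.csv`, `prescriptions.csv`,
#' `procedures.csv`, `contacts.csv`) or a named list of file paths.
#'
#' @param paths directory or named list of per-table CSV paths.
#' @param config a [default_code_config()] object.
#' @return a `registry_bundle`.
#' @export
load_registry <- function(paths, config = default_code_config()) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- as.list(file.path(paths, paste0(REGISTRY_TABLES, ".csv")))
    names(paths) <- REGISTRY_TABLES
  }
  missing <- setdiff(REGISTRY_TABLES, names(paths))
  if (length(missing)) stop("missing table path(s): ", paste(missing, collapse = ", "))
  tabs <- list()
  for (nm in REGISTRY_TABLES) {
    if (!file.exists(paths[[nm]])) stop(sprintf("%s: file not found (%s)", nm, paths[[nm]]))
    dt <- fread(paths[[nm]], colClasses = list(character = "person_id"),
                na.strings = c("", "NA"))
    # optional DKK input column converted at load
    if ("cost_dkk" %in% names(dt) && !("cost_eur" %in% names(dt))) {
      dt[, cost_eur := cost_dkk / config$dkk_per_eur]
      dt[, cost_dkk := NULL]
    }
    tabs[[nm]] <- dt
  }
  registry_bundle(tabs$persons, tabs$diagnoses, tabs$prescriptions,
                  tabs$procedures, tabs$contacts, config)
}

#' Write a registry bundle to CSV files
#'
#' Serializes the five tables into `directory` with ISO-8601 (YYYY-MM-DD)
#' dates, such that `load_registry(write_registry(b, d))` reproduces `b`
#' field for field.
#'
#' @param bundle a `registry_bundle`.
#' @param directory output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_registry <- function(bundle, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (nm in REGISTRY_TABLES) {
    out <- copy(bundle[[nm]])
    for (dc in registry_schema[[nm]]$dates) {
      set(out, j = dc, value = format(out[[dc]], "%Y-%m-%d"))
    }
    fwrite(out, file.path(directory, paste0(nm, ".csv")), na = "")
  }
  invisible(directory)
}

utils::globalVariables("cost_dkk")
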