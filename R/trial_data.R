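# Data model, validation, I/O and analysis-population selection for a two-arm
# pragmatic trial with repeated measures at weeks 0/6/26 and 6-week-recall
# resource-use inventories at the two follow-ups.

ARM_LEVELS <- c("control", "intervention")
GENDER_LEVELS <- c("male", "female")
EMPLOYMENT_LEVELS <- c("employed", "unemployed", "retired", "cannot_work")
MEASURE_WEEKS <- c(0L, 6L, 26L)
FOLLOWUP_WEEKS <- c(6L, 26L)

#' Healthcare resource labels
#'
#' Canonical labels for the healthcare-service resource-use inventory. They key
#' the unit-cost table (see [default_unit_costs()]) and the per-window count
#' columns of a trial table (`hc_<resource>_w6`, `hc_<resource>_w26`).
#'
#' @return Character vector of resource labels.
#' @export
hc_resources <- function() {
  c("gp", "specialist", "chiropractor", "physiotherapy", "dietitian",
    "other_allied", "massage", "alternative", "emergency",
    "hospital_admission", "spinal_injection", "imaging", "community",
    "orthopaedic_consult", "pain_clinic")
}

#' Medication item labels
#'
#' Canonical labels for the medication inventory (count columns
#' `med_<item>_w6`, `med_<item>_w26`, in packs).
#'
#' @return Character vector of medication labels.
#' @export
med_items <- function() {
  c("analgesic", "nsaid", "opioid")
}

measure_cols <- function() {
  as.vector(outer(c("utility", "pain", "womac", "weight"),
                  paste0("_w", MEASURE_WEEKS), paste0))
}

inventory_cols <- function(window = FOLLOWUP_WEEKS) {
  unlist(lapply(window, function(w) {
    c(paste0("hc_", hc_resources(), "_w", w),
      paste0("med_", med_items(), "_w", w),
      paste0("absent_days_w", w))
  }))
}

baseline_cols <- function() {
  c("age", "gender", "education_gt_highschool", "employment",
    "indigenous_status", "country_australia", "pain_duration",
    "waitlist_days", "height", "ghs_calls")
}

#' Canonical trial-table columns
#'
#' Column set (and order) of the wide, one-row-per-participant canonical trial
#' table: identifier, arm, baseline covariates, repeated outcome measures with
#' `_w0/_w6/_w26` suffixes, and per-window resource-use inventories.
#'
#' @return Character vector of column names.
#' @export
trial_columns <- function() {
  c("id", "arm", baseline_cols(), measure_cols(), inventory_cols())
}

logical_cols <- function() {
  c("education_gt_highschool", "indigenous_status", "country_australia")
}

character_cols <- function() c("id", "arm", "gender", "employment")

#' Construct a trial dataset
#'
#' Wraps a wide participant table into a validated `trial_dataset`. Hard
#' invariant violations (duplicate ids, unknown arm labels, out-of-range
#' outcome values) are rejected; see [validate_trial()] for the full report.
#'
#' @param records Data frame with the columns of [trial_columns()]. Missing
#'   values must be `NA`, never sentinel numbers.
#' @param currency_year Calendar year costs are expressed in (default 2016).
#' @param meta Named list of provenance labels (e.g. the population rule
#'   applied by [select_population()]).
#' @return An object of class `trial_dataset` with elements `records`
#'   (tibble), `currency_year` and `meta`.
#' @export
trial_dataset <- function(records, currency_year = 2016, meta = list()) {
  records <- tibble::as_tibble(records)
  report <- validate_records(records)
  if (nrow(report$errors) > 0L) {
    heads <- utils::head(report$errors, 5L)
    stop("invalid trial records:\n",
         paste0("  [", heads$id, "] ", heads$field, ": ", heads$rule,
                collapse = "\n"),
         if (nrow(report$errors) > 5L)
           paste0("\n  ... and ", nrow(report$errors) - 5L, " more"),
         call. = FALSE)
  }
  structure(list(records = records,
                 currency_year = currency_year,
                 meta = meta),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  n_arm <- table(factor(x$records$arm, ARM_LEVELS))
  cat("<trial_dataset> ", nrow(x$records), " participants (",
      paste(names(n_arm), n_arm, sep = " = ", collapse = ", "),
      "), costs in AUD-", x$currency_year, "\n", sep = "")
  if (!is.null(x$meta$population)) {
    cat("  population: ", x$meta$population$rule, "\n", sep = "")
  }
  invisible(x)
}

# Range rules applied to the record table. Each rule: columns (regex),
# predicate on the value, and its human-readable name.
range_rules <- function() {
  list(
    list(cols = "^utility_w", rule = "utility in (0,1]",
         ok = function(v) v > 0 & v <= 1),
    list(cols = "^pain_w", rule = "pain NRS in [0,10]",
         ok = function(v) v >= 0 & v <= 10),
    list(cols = "^womac_w", rule = "WOMAC total in [0,96]",
         ok = function(v) v >= 0 & v <= 96),
    list(cols = "^weight_w", rule = "weight (kg) positive",
         ok = function(v) v > 0),
    list(cols = "^(hc|med)_.*_w(6|26)$", rule = "inventory count >= 0",
         ok = function(v) v >= 0),
    list(cols = "^absent_days_w", rule = "absence days >= 0",
         ok = function(v) v >= 0),
    list(cols = "^ghs_calls$", rule = "ghs_calls >= 0",
         ok = function(v) v >= 0),
    list(cols = "^pain_duration$", rule = "pain duration (years) >= 0",
         ok = function(v) v >= 0),
    list(cols = "^waitlist_days$", rule = "waiting-list days >= 0",
         ok = function(v) v >= 0),
    list(cols = "^height$", rule = "height (m) in (0.5, 2.5)",
         ok = function(v) v > 0.5 & v < 2.5)
  )
}

validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  errors <- list()
  warns <- list()
  add_err <- function(id, field, rule) {
    errors[[length(errors) + 1L]] <<- tibble::tibble(
      id = as.character(id), field = field, rule = rule)
  }

  missing_cols <- setdiff(trial_columns(), names(records))
  for (col in missing_cols) add_err(NA_character_, col, "required column present")

  if (!"id" %in% missing_cols) {
    dup <- unique(records$id[duplicated(records$id)])
    for (d in dup) add_err(d, "id", "participant ids unique")
  }
  if (!"arm" %in% missing_cols) {
    bad <- !records$arm %in% ARM_LEVELS & !is.na(records$arm)
    for (i in which(bad | is.na(records$arm))) {
      add_err(records$id[i], "arm",
              paste0("arm one of {", paste(ARM_LEVELS, collapse = ", "), "}"))
    }
  }
  if ("gender" %in% names(records)) {
    for (i in which(!is.na(records$gender) & !records$gender %in% GENDER_LEVELS))
      add_err(records$id[i], "gender",
              paste0("gender one of {", paste(GENDER_LEVELS, collapse = ", "), "}"))
  }
  if ("employment" %in% names(records)) {
    for (i in which(!is.na(records$employment) &
                      !records$employment %in% EMPLOYMENT_LEVELS))
      add_err(records$id[i], "employment",
              paste0("employment one of {",
                     paste(EMPLOYMENT_LEVELS, collapse = ", "), "}"))
  }

  for (rr in range_rules()) {
    cols <- grep(rr$cols, names(records), value = TRUE)
    for (col in cols) {
      v <- records[[col]]
      if (!is.numeric(v)) next
      for (i in which(!is.na(v) & !rr$ok(v))) {
        add_err(records$id[i], col, rr$rule)
      }
    }
  }
  if ("ghs_calls" %in% names(records)) {
    over <- which(!is.na(records$ghs_calls) & records$ghs_calls > 10)
    if (length(over)) {
      warns[[length(warns) + 1L]] <-
        paste0(length(over), " participant(s) with ghs_calls > 10 ",
               "(service offers 10 coaching calls)")
    }
  }

  errors <- if (length(errors)) do.call(rbind, errors) else
    tibble::tibble(id = character(), field = character(), rule = character())

  n_by_arm <- if ("arm" %in% names(records)) {
    as.list(table(factor(records$arm, ARM_LEVELS)))
  } else list()
  num_cols <- intersect(c(measure_cols(), inventory_cols()), names(records))
  missingness <- vapply(records[num_cols], function(v) mean(is.na(v)), numeric(1))

  structure(list(errors = errors,
                 warnings = unlist(warns) %||% character(),
                 counts = list(n = nrow(records),
                               n_by_arm = n_by_arm,
                               missingness = missingness)),
            class = "validation_report")
}

#' Validate a trial dataset
#'
#' Reports every invariant violation (rather than stopping at the first), plus
#' per-arm sample sizes and per-field missingness fractions. Downstream stages
#' reject datasets whose report contains errors.
#'
#' @param ds A `trial_dataset`, or a raw data frame of participant records.
#' @return A `validation_report`: list with `errors` (tibble of id/field/rule),
#'   `warnings` (character) and `counts` (n, per-arm n, missingness by field).
#' @export
validate_trial <- function(ds) {
  records <- if (inherits(ds, "trial_dataset")) ds$records else ds
  validate_records(records)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n =", x$counts$n, "\n")
  if (length(x$counts$n_by_arm)) {
    cat("  arms:", paste(names(x$counts$n_by_arm), unlist(x$counts$n_by_arm),
                         sep = " = ", collapse = ", "), "\n")
  }
  if (nrow(x$errors) == 0L) {
    cat("  errors: none\n")
  } else {
    cat("  errors:", nrow(x$errors), "\n")
    for (i in seq_len(min(nrow(x$errors), 10L))) {
      cat("    [", x$errors$id[i], "] ", x$errors$field[i], ": ",
          x$errors$rule[i], "\n", sep = "")
    }
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  mx <- x$counts$missingness
  mx <- mx[mx > 0]
  if (length(mx)) {
    cat("  missingness (nonzero fields):", length(mx), "fields, max",
        sprintf("%.2f", max(mx)), "\n")
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report` from [validate_trial()].
#' @return A JSON string.
#' @export
validation_report_json <- function(report) {
  jsonlite::toJSON(list(errors = report$errors,
                        warnings = report$warnings,
                        counts = report$counts),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

coerce_record_types <- function(records, path = "<data>") {
  for (col in intersect(character_cols(), names(records))) {
    records[[col]] <- as.character(records[[col]])
  }
  for (col in intersect(logical_cols(), names(records))) {
    v <- records[[col]]
    if (is.logical(v)) next
    v_chr <- toupper(trimws(as.character(v)))
    out <- rep(NA, length(v_chr))
    out[v_chr %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out[v_chr %in% c("FALSE", "F", "0", "NO")] <- FALSE
    bad <- !is.na(v_chr) & is.na(out) & v_chr != ""
    if (any(bad)) {
      stop("cannot parse logical column '", col, "' in ", path, ": value '",
           v[which(bad)[1]], "'", call. = FALSE)
    }
    records[[col]] <- out
  }
  num_cols <- setdiff(intersect(trial_columns(), names(records)),
                      c(character_cols(), logical_cols()))
  for (col in num_cols) {
    v <- records[[col]]
    if (is.numeric(v)) next
    parsed <- suppressWarnings(as.numeric(v))
    bad <- is.na(parsed) & !is.na(v) & trimws(as.character(v)) != ""
    if (any(bad)) {
      stop("cannot parse numeric column '", col, "' in ", path, ": value '",
           v[which(bad)[1]], "'", call. = FALSE)
    }
    records[[col]] <- parsed
  }
  records
}

pivot_long_table <- function(raw) {
  needed <- c("id", "week")
  if (!all(needed %in% names(raw))) {
    stop("long-format table requires 'id' and 'week' columns", call. = FALSE)
  }
  long_vars <- intersect(c("utility", "pain", "womac", "weight"), names(raw))
  if (!length(long_vars)) {
    stop("long-format table has no repeated-measure columns ",
         "(utility/pain/womac/weight)", call. = FALSE)
  }
  invariant <- setdiff(names(raw), c(long_vars, "week"))
  wide <- tidyr::pivot_wider(raw,
                             id_cols = tidyr::all_of(invariant),
                             names_from = "week",
                             values_from = tidyr::all_of(long_vars),
                             names_glue = "{.value}_w{week}")
  wide
}

#' Read a trial table from delimited text
#'
#' Reads a CSV trial table (wide, one row per participant; or long, one row
#' per participant-timepoint, pivoted on read), maps columns to the canonical
#' schema, coerces types, converts configured NA tokens to explicit missing
#' states, and validates. Files failing a hard invariant are rejected with the
#' offending row and rule.
#'
#' @param path Path to a CSV file (RFC-4180 quoting).
#' @param schema Optional column mapping: named character vector or list
#'   (canonical name -> file column name), or path to a YAML/JSON file holding
#'   one. `NULL` means columns already use canonical names.
#' @param na Character vector of NA tokens (default `c("", "NA")`).
#' @param currency_year Calendar year costs are expressed in.
#' @param format `"wide"` (default) or `"long"`.
#' @return A `trial_dataset`.
#' @export
read_trial_table <- function(path, schema = NULL, na = c("", "NA"),
                             currency_year = 2016,
                             format = c("wide", "long")) {
  format <- match.arg(format)
  raw <- readr::read_csv(path, na = na, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(schema)) {
    if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
      schema <- yaml::read_yaml(schema)
    }
    schema <- unlist(schema)
    found <- schema[schema %in% names(raw)]
    names(raw)[match(found, names(raw))] <- names(found)
  }
  if (format == "long") raw <- pivot_long_table(raw)
  records <- coerce_record_types(raw, path = path)
  extra <- setdiff(names(records), trial_columns())
  if (length(extra)) records <- records[setdiff(names(records), extra)]
  records <- records[intersect(trial_columns(), names(records))]
  trial_dataset(records, currency_year = currency_year,
                meta = list(source = path))
}

#' Write a trial table to CSV
#'
#' Writes the canonical wide table with missing cells as empty fields and
#' doubles at full (round-trippable) precision, so that
#' `read_trial_table(write_trial_table(ds))` reproduces `ds` exactly.
#'
#' @param ds A `trial_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(ds, path) {
  stopifnot(inherits(ds, "trial_dataset"))
  readr::write_csv(ds$records, path, na = "")
  invisible(path)
}

#' Select the analysis population
#'
#' Intention-to-treat (`"itt"`) keeps every randomised participant unchanged.
#' Per-protocol (`"per_protocol"`) keeps intervention participants who received
#' at least `min_calls` coaching calls and all control participants (the
#' adherence threshold applies to the active arm only).
#'
#' @param ds A `trial_dataset`.
#' @param rule `"itt"` or `"per_protocol"`.
#' @param min_calls Minimum coaching calls for per-protocol inclusion
#'   (default 6).
#' @return A `trial_dataset` with the population rule recorded in `meta`.
#' @export
select_population <- function(ds, rule = c("itt", "per_protocol"),
                              min_calls = 6) {
  stopifnot(inherits(ds, "trial_dataset"))
  rule <- match.arg(rule)
  records <- ds$records
  if (rule == "per_protocol") {
    if (min_calls < 0) stop("min_calls must be >= 0", call. = FALSE)
    is_int <- records$arm == "intervention"
    if (anyNA(records$ghs_calls[is_int])) {
      stop("ghs_calls missing for intervention participants; ",
           "cannot apply per-protocol rule", call. = FALSE)
    }
    keep <- !is_int | records$ghs_calls >= min_calls
    records <- records[keep, , drop = FALSE]
  }
  meta <- ds$meta
  meta$population <- list(rule = rule,
                          min_calls = if (rule == "per_protocol") min_calls else NA)
  trial_dataset(records, currency_year = ds$currency_year, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
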