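# Data model and I/O for payer claims, ctDNA test results, death records and
# tumor sidedness. Dates are integer day indices (days since an arbitrary
# epoch); ISO dates in input files are converted on load. One month is taken
# as 30.4375 days throughout, so the 6-month clean window is 183 days.

#' Therapy class vocabulary
#'
#' Enumerations used throughout the package. `FLUOROURACIL` and `BEVACIZUMAB`
#' are kept distinct from `CHEMO` and `VEGF` because changes involving either
#' agent are exempt from the line-advancement rules, even though they count as
#' chemotherapy / VEGF-targeted therapy for reporting. "Targeted therapy"
#' (`targeted_classes()`) means agents directed at tumor-cell aberrations or
#' immune checkpoints; VEGF-targeted therapy is deliberately not part of that
#' set.
#'
#' @return A character vector of class labels.
#' @export
therapy_classes <- function() {
  c("CHEMO", "VEGF", "EGFR", "BRAF", "ERBB2", "NTRK", "ICI",
    "OTHER_TARGETED", "FLUOROURACIL", "BEVACIZUMAB", "NON_CANCER")
}

#' @rdname therapy_classes
#' @export
targeted_classes <- function() {
  c("EGFR", "BRAF", "ERBB2", "NTRK", "ICI", "OTHER_TARGETED")
}

#' @rdname therapy_classes
#' @export
tumor_sides <- function() c("LEFT", "RIGHT", "MIXED", "UNSPECIFIED")

# Classes exempt from regimen-signature and line-advancement rules.
signature_exempt_classes <- function() c("FLUOROURACIL", "BEVACIZUMAB")

# Days per month used for every month<->day conversion.
DAYS_PER_MONTH <- 30.4375

# Clean-window length: 6 months at day precision.
CLEAN_WINDOW_DAYS <- 183L

#' Convert days to months
#'
#' @param days Numeric vector of day counts.
#' @return Months at 30.4375 days per month.
#' @export
days_to_months <- function(days) days / DAYS_PER_MONTH

#' Round half away from zero
#'
#' Display rounding for printed percentages (13/16 prints as 81.3, not the
#' round-half-to-even 81.2).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Convert a date column that may be ISO strings or integers to integer days.
.as_day_index <- function(x) {
  if (is.numeric(x)) return(as.integer(round(x)))
  x <- as.character(x)
  out <- suppressWarnings(as.integer(x))
  iso <- is.na(out) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(iso)) {
    out[iso] <- as.integer(as.Date(x[iso]))
  }
  out
}

#' Load the drug-code to therapy-class map
#'
#' The mapping ships as an editable two-column CSV (`code,class`) seeded with
#' generic mCRC agent names; real deployments would swap in NDC/HCPCS
#' vocabularies. Unknown codes always classify as `NON_CANCER`.
#'
#' @param path Path to a CSV with columns `code` and `class`. Defaults to the
#'   map packaged under `extdata/drug_classes.csv`.
#' @return Named character vector mapping code to therapy class.
#' @export
load_class_map <- function(path = system.file("extdata", "drug_classes.csv",
                                              package = "ctdnaRWE")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "class") %in% names(df))) {
    stop("class map must have columns 'code' and 'class'")
  }
  bad <- setdiff(unique(df$class), therapy_classes())
  if (length(bad)) {
    stop("unknown therapy class in map: ", paste(bad, collapse = ", "))
  }
  stats::setNames(df$class, df$code)
}

#' Classify a drug code into a therapy class
#'
#' Total and deterministic: codes absent from the map are `NON_CANCER`.
#'
#' @param code Character vector of drug codes.
#' @param class_map Named character vector from [load_class_map()].
#' @return Character vector of therapy classes, same length as `code`.
#' @export
classify_agent <- function(code, class_map) {
  out <- unname(class_map[code])
  out[is.na(out)] <- "NON_CANCER"
  out
}

#' Load claims from CSV
#'
#' Expected columns: `patient_id`, `date` (integer day index or ISO date),
#' `kind` (`medical`/`pharmacy`), `code`. Rows with unparseable dates or
#' unknown kinds are dropped from the returned claims but reported in the
#' attached validation report; unknown drug codes load fine (they classify as
#' `NON_CANCER` downstream) but are counted when a class map is supplied.
#'
#' @param path CSV file path.
#' @param class_map Optional class map; when given, pharmacy/drug codes not in
#'   the map are counted in the validation report.
#' @param metastatic_codes Character vector of diagnosis codes that establish
#'   metastatic disease (configurable "secondary malignancy" code set).
#' @return A `data.frame` of claims sorted by (patient_id, date) with columns
#'   `patient_id`, `date`, `kind`, `code`, `metastatic_flag`, plus a
#'   `"validation"` attribute (list with `n_bad_rows`, `bad_rows`,
#'   `n_unknown_codes`).
#' @export
load_claims <- function(path, class_map = NULL,
                        metastatic_codes = "DX_METASTATIC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       code = "character"))
  required <- c("patient_id", "date", "kind", "code")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("claims file missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$date <- .as_day_index(df$date)
  bad <- which(is.na(df$date) | !(df$kind %in% c("medical", "pharmacy")))
  validation <- list(n_bad_rows = length(bad), bad_rows = bad,
                     n_unknown_codes = 0L)
  if (length(bad)) {
    warning(length(bad), " malformed claim row(s) dropped; see validation report")
    df <- df[-bad, , drop = FALSE]
  }
  df$metastatic_flag <- df$code %in% metastatic_codes
  if (!is.null(class_map)) {
    drug_rows <- df$kind == "pharmacy"
    unknown <- drug_rows & !(df$code %in% names(class_map))
    validation$n_unknown_codes <- sum(unknown)
    if (any(unknown)) {
      warning(sum(unknown), " claim(s) with drug codes not in the class map",
              " (classified NON_CANCER)")
    }
  }
  df <- df[order(df$patient_id, df$date), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "validation") <- validation
  df
}

#' Write claims to CSV
#'
#' Round-trips with [load_claims()] on valid inputs.
#'
#' @param claims Claims `data.frame`.
#' @param path Output path.
#' @export
write_claims <- function(claims, path) {
  utils::write.csv(claims[, c("patient_id", "date", "kind", "code")],
                   path, row.names = FALSE, quote = FALSE)
}

#' Load death records
#'
#' @param path CSV with columns `patient_id`, `death_date`. At most one row
#'   per patient.
#' @return `data.frame` with integer `death_date`.
#' @export
load_deaths <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  if (!all(c("patient_id", "death_date") %in% names(df))) {
    stop("deaths file must have columns patient_id, death_date")
  }
  df$death_date <- .as_day_index(df$death_date)
  if (anyDuplicated(df$patient_id)) {
    stop("more than one death record for a patient")
  }
  df
}

#' Load tumor sidedness
#'
#' @param path CSV with columns `patient_id`, `side` (LEFT/RIGHT/MIXED/
#'   UNSPECIFIED).
#' @return `data.frame`.
#' @export
load_sides <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  if (!all(c("patient_id", "side") %in% names(df))) {
    stop("sides file must have columns patient_id, side")
  }
  bad <- setdiff(unique(df$side), tumor_sides())
  if (length(bad)) stop("unknown tumor side: ", paste(bad, collapse = ", "))
  df
}

#' Load ctDNA test results
#'
#' @param path CSV with columns `test_id`, `patient_id`, `report_date`,
#'   `detected`, `kras_mut`, `kras_variant`, `nras_mut`, `braf_v600e`,
#'   `erbb2_amp`, `msi_high`, `ntrk1_fusion`, `other` (semicolon-separated
#'   labels, reporting only).
#' @return `data.frame` with logical alteration flags and integer
#'   `report_date`.
#' @export
load_tests <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       test_id = "character"))
  flags <- c("detected", "kras_mut", "nras_mut", "braf_v600e", "erbb2_amp",
             "msi_high", "ntrk1_fusion")
  needed <- c("test_id", "patient_id", "report_date", flags)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("tests file missing column(s): ", paste(missing, collapse = ", "))
  }
  df$report_date <- .as_day_index(df$report_date)
  for (f in flags) df[[f]] <- as.logical(df[[f]])
  if (!"kras_variant" %in% names(df)) df$kras_variant <- ""
  if (!"other" %in% names(df)) df$other <- ""
  df$kras_variant[is.na(df$kras_variant)] <- ""
  df$other[is.na(df$other)] <- ""
  validate_profiles(df)
  df
}

# Profile invariant: no detection implies no alteration calls.
validate_profiles <- function(tests) {
  flags <- c("kras_mut", "nras_mut", "braf_v600e", "erbb2_amp", "msi_high",
             "ntrk1_fusion")
  any_alt <- Reduce(`|`, tests[flags])
  if (any(!tests$detected & any_alt)) {
    stop("profile invariant violated: alteration called with ctDNA undetected")
  }
  invisible(tests)
}
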