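# Eligibility filters and index-test selection, reproducing the attrition
# flow: all patients -> ctDNA test within 90 days before a second- or
# third-line start -> 6-month pre-treatment clean window with claims
# activity -> metastatic disease confirmed by claims. Attrition is always
# reported in that fixed order, each step's denominator being the survivors
# of the previous step.

#' Candidate (test, next line) pairs inside the testing window
#'
#' A test is a candidate when it falls within 90 days (inclusive on both
#' ends) before the start of that patient's second- or third-line therapy.
#'
#' @param tests Tests `data.frame` for one patient or many.
#' @param lines Line table from [derive_lines_all()] (must include
#'   `patient_id`).
#' @param window_days Inclusive maximum days between test report and line
#'   start. Default 90.
#' @return `data.frame` with `patient_id`, `test_id`, `report_date`,
#'   `line_number`, `line_start`; zero rows if no candidates.
#' @export
check_test_window <- function(tests, lines, window_days = 90) {
  ln <- lines[lines$line_number %in% c(2L, 3L), , drop = FALSE]
  out <- merge(tests[, c("patient_id", "test_id", "report_date")],
               ln[, c("patient_id", "line_number", "start_date")],
               by = "patient_id")
  gap <- out$start_date - out$report_date
  out <- out[gap >= 0 & gap <= window_days, , drop = FALSE]
  names(out)[names(out) == "start_date"] <- "line_start"
  out <- out[order(out$patient_id, out$report_date, out$test_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pre-treatment clean-window check
#'
#' TRUE when the 183 days before the first observed therapy start contain at
#' least two claims of any kind and no systemic-therapy claim, so that the
#' first observed line can be trusted to be first-line treatment. Claims that
#' also establish metastasis count toward the activity requirement.
#'
#' @param claims One patient's claims (all kinds).
#' @param first_line_start Start day of the patient's first derived line.
#' @param class_map Code-to-class map; codes mapping to anything but
#'   `NON_CANCER` count as treatment.
#' @param window_days Clean-window length in days (default 183 = 6 months).
#' @param min_claims Minimum claims of any kind required in the window.
#' @return Logical scalar.
#' @export
check_clean_window <- function(claims, first_line_start, class_map,
                               window_days = CLEAN_WINDOW_DAYS,
                               min_claims = 2L) {
  in_win <- claims$date >= (first_line_start - window_days) &
    claims$date < first_line_start
  w <- claims[in_win, , drop = FALSE]
  if (nrow(w) < min_claims) return(FALSE)
  !any(classify_agent(w$code, class_map) != "NON_CANCER")
}

#' Select the index ctDNA test
#'
#' With several candidate tests, the test conducted immediately after the
#' earliest line containing targeted therapy is used; with no prior targeted
#' therapy, the earliest test. Ties break by earlier report date, then test
#' id.
#'
#' @param candidates Candidate pairs for one patient from
#'   [check_test_window()].
#' @param lines That patient's line table.
#' @return One row of `candidates` (the index pair), or `NULL` when there are
#'   no candidates.
#' @export
select_index_test <- function(candidates, lines) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  prev_no <- candidates$line_number - 1L
  prev_targeted <- lines$contains_targeted[match(prev_no, lines$line_number)]
  prev_start <- lines$start_date[match(prev_no, lines$line_number)]
  prev_targeted[is.na(prev_targeted)] <- FALSE
  if (any(prev_targeted)) {
    cand <- candidates[prev_targeted, , drop = FALSE]
    ps <- prev_start[prev_targeted]
    cand <- cand[order(ps, cand$report_date, cand$test_id), , drop = FALSE]
  } else {
    cand <- candidates[order(candidates$report_date, candidates$test_id), ,
                       drop = FALSE]
  }
  cand[1, , drop = FALSE]
}

#' Build the study cohort with attrition accounting
#'
#' Applies the three eligibility filters in their fixed order, selects each
#' included patient's index test and index (next) line, and assigns the
#' prior-therapy arm (`prior_targeted` when the line immediately before the
#' index test contained targeted therapy).
#'
#' @param claims Claims for all patients.
#' @param tests All ctDNA tests.
#' @param deaths Death records (unused by the filters; carried through).
#' @param sides Sidedness table.
#' @param class_map Code-to-class map.
#' @param params LOT parameters from [lot_params()].
#' @param window_days Test-to-line window (days, inclusive).
#' @return List with `eligibility` (per-patient record: pass flags, index
#'   test/line, cohort label, prior-therapy arm), `attrition` (named counts
#'   in flow order), and `lines` (the derived line table).
#' @export
build_study_cohort <- function(claims, tests, deaths, sides, class_map,
                               params = lot_params(), window_days = 90) {
  lines <- derive_lines_all(claims, class_map, params)
  patients <- unique(claims$patient_id)
  if (length(patients) == 0) {
    elig <- data.frame(patient_id = character(),
                       passed_test_window = logical(),
                       passed_clean_window = logical(),
                       passed_metastatic = logical(),
                       index_test_id = character(),
                       index_line_number = integer(),
                       prior_targeted = logical(),
                       cohort_label = character(), stringsAsFactors = FALSE)
    return(list(eligibility = elig,
                attrition = c(all_patients = 0L, test_window = 0L,
                              clean_window = 0L, metastatic = 0L),
                lines = lines))
  }
  claims_by_pat <- split(claims, claims$patient_id)
  lines_by_pat <- split(lines, lines$patient_id)
  cand_all <- check_test_window(tests, lines, window_days)
  cand_by_pat <- split(cand_all, cand_all$patient_id)

  rec <- lapply(patients, function(pid) {
    pl <- lines_by_pat[[pid]]
    cand <- cand_by_pat[[pid]]
    passed_test_window <- !is.null(cand) && nrow(cand) > 0
    passed_clean_window <- FALSE
    passed_metastatic <- FALSE
    index_test_id <- NA_character_
    index_line_number <- NA_integer_
    prior_targeted <- NA
    label <- "excluded"
    if (passed_test_window) {
      passed_clean_window <- check_clean_window(
        claims_by_pat[[pid]], pl$start_date[pl$line_number == 1L], class_map)
      if (passed_clean_window) {
        passed_metastatic <- any(claims_by_pat[[pid]]$metastatic_flag)
        if (passed_metastatic) {
          idx <- select_index_test(cand, pl)
          index_test_id <- idx$test_id
          index_line_number <- idx$line_number
          prev <- pl$contains_targeted[pl$line_number == idx$line_number - 1L]
          prior_targeted <- length(prev) == 1 && isTRUE(prev)
          label <- if (index_line_number == 2L) "second_line" else "third_line"
        }
      }
    }
    data.frame(patient_id = pid,
               passed_test_window = passed_test_window,
               passed_clean_window = passed_clean_window,
               passed_metastatic = passed_metastatic,
               index_test_id = index_test_id,
               index_line_number = index_line_number,
               prior_targeted = prior_targeted,
               cohort_label = label,
               stringsAsFactors = FALSE)
  })
  elig <- do.call(rbind, rec)
  rownames(elig) <- NULL
  attrition <- c(
    all_patients = length(patients),
    test_window = sum(elig$passed_test_window),
    clean_window = sum(elig$passed_test_window & elig$passed_clean_window),
    metastatic = sum(elig$cohort_label != "excluded"))
  list(eligibility = elig, attrition = attrition, lines = lines)
}
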