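# Molecularly-informed / matched labeling of the therapy line that follows
# the index ctDNA test, and assignment to the four outcome groups.
#
# Rules: with ctDNA undetected no therapy is informed. A targeted class is
# matched only against its own biomarker (EGFR: detected RAS-wild-type
# without BRAF V600E in a non-right-sided tumor; BRAF: V600E; ERBB2:
# amplification; NTRK: NTRK1 fusion; ICI: MSI-high); OTHER_TARGETED never
# matches. Chemotherapy/VEGF-only treatment is informed when no
# biomarker-positive indication exists and either RAS is mutant or the
# tumor is right-sided (no usable EGFR option). When targeted therapy is
# given, the overall call also requires that no biomarker-positive indication
# (BRAF/ERBB2/NTRK/ICI) is left unused by the administered classes; an unused
# EGFR option penalizes only non-targeted treatment.

# Biomarker-positive indications (therapy class -> profile flag).
.marker_indications <- function(profile) {
  p <- lapply(profile[c("braf_v600e", "erbb2_amp", "ntrk1_fusion",
                        "msi_high")], isTRUE)
  out <- character()
  if (p$braf_v600e) out <- c(out, "BRAF")
  if (p$erbb2_amp) out <- c(out, "ERBB2")
  if (p$ntrk1_fusion) out <- c(out, "NTRK")
  if (p$msi_high) out <- c(out, "ICI")
  out
}

#' Classify a therapy line as molecularly informed / matched
#'
#' @param line_classes Non-empty character vector of therapy classes
#'   administered in the post-test line (e.g. `c("CHEMO", "VEGF")`).
#'   `FLUOROURACIL` and `BEVACIZUMAB` are treated as `CHEMO` and `VEGF`.
#' @param call Actionability call from [classify_actionability()].
#' @param profile Profile row (logical biomarker fields as in
#'   [classify_actionability()]).
#' @param side One of `tumor_sides()`.
#' @return List with `informed` (logical), `matched_targeted` (logical: a
#'   targeted class was administered and the overall call is informed),
#'   `per_class` (named character vector: `matched`/`unmatched`/`informed`/
#'   `not_informed` per administered class) and `reason` (why not informed;
#'   `NA` when informed).
#' @export
classify_informed <- function(line_classes, call, profile, side) {
  if (length(line_classes) == 0) stop("empty therapy class set")
  line_classes <- unique(line_classes)
  line_classes[line_classes == "FLUOROURACIL"] <- "CHEMO"
  line_classes[line_classes == "BEVACIZUMAB"] <- "VEGF"
  line_classes <- setdiff(unique(line_classes), "NON_CANCER")
  if (length(line_classes) == 0) stop("no systemic therapy class in line")

  detected <- isTRUE(profile$detected)
  markers <- .marker_indications(profile)
  egfr_ok <- "EGFR" %in% call$indicated
  targeted_given <- intersect(line_classes, targeted_classes())
  per_class <- stats::setNames(rep(NA_character_, length(line_classes)),
                               line_classes)

  if (!detected) {
    per_class[] <- "not_informed"
    return(list(informed = FALSE, matched_targeted = FALSE,
                per_class = per_class, reason = "no_ctdna"))
  }

  matched_ok <- TRUE
  reason <- NA_character_
  for (cl in targeted_given) {
    m <- switch(cl,
                EGFR = egfr_ok,
                BRAF = isTRUE(profile$braf_v600e),
                ERBB2 = isTRUE(profile$erbb2_amp),
                NTRK = isTRUE(profile$ntrk1_fusion),
                ICI = isTRUE(profile$msi_high),
                OTHER_TARGETED = FALSE)
    per_class[cl] <- if (m) "matched" else "unmatched"
    if (!m) {
      matched_ok <- FALSE
      if (is.na(reason)) {
        reason <- switch(cl,
                         EGFR = paste0(call$egfr_blocked_reason, "_egfr"),
                         ICI = "msi_absent",
                         OTHER_TARGETED = "no_match_rule",
                         "marker_absent")
      }
    }
  }

  unused_markers <- setdiff(markers, line_classes)
  if (length(targeted_given) > 0) {
    informed <- matched_ok && length(unused_markers) == 0
    if (matched_ok && !informed) reason <- "actionable_ignored"
  } else {
    # chemotherapy and/or VEGF only
    informed <- length(markers) == 0 && !egfr_ok
    if (!informed) reason <- "actionable_ignored"
  }
  nt <- setdiff(line_classes, targeted_classes())
  per_class[nt] <- if (informed) "informed" else "not_informed"

  list(informed = informed,
       matched_targeted = informed && length(targeted_given) > 0,
       per_class = per_class, reason = reason)
}

#' Assign a patient to one of the four outcome groups
#'
#' Partition used for the time-to-discontinuation comparisons: matched
#' actionable, unmatched actionable, not actionable, and ctDNA not detected.
#'
#' @param call Actionability call from [classify_actionability()].
#' @param informed Informed call from [classify_informed()].
#' @param profile Profile row.
#' @return One of `"ACTIONABLE_MATCHED"`, `"ACTIONABLE_UNMATCHED"`,
#'   `"NOT_ACTIONABLE"`, `"CTDNA_NOT_DETECTED"`.
#' @export
assign_outcome_group <- function(call, informed, profile) {
  if (!isTRUE(profile$detected)) return("CTDNA_NOT_DETECTED")
  if (call$actionable && informed$matched_targeted) return("ACTIONABLE_MATCHED")
  if (call$actionable) return("ACTIONABLE_UNMATCHED")
  "NOT_ACTIONABLE"
}

#' Label a cohort's post-test therapy lines
#'
#' Vectorized driver over a cohort: joins tests, sidedness, actionability and
#' the administered class set of each patient's post-test line, returning a
#' per-patient label table.
#'
#' @param tests Tests `data.frame` (one index test per patient).
#' @param sides Sidedness `data.frame`.
#' @param line_classes Named list mapping `patient_id` to the character
#'   vector of therapy classes of the post-test line.
#' @param policy From [actionability_policy()].
#' @return `data.frame` with `patient_id`, `actionable`, `indicated`,
#'   `informed`, `matched_targeted`, `group`, `reason`.
#' @export
label_cohort <- function(tests, sides, line_classes,
                         policy = actionability_policy()) {
  side <- sides$side[match(tests$patient_id, sides$patient_id)]
  rows <- lapply(seq_len(nrow(tests)), function(i) {
    prof <- tests[i, ]
    call <- classify_actionability(prof, side[i], policy)
    lc <- line_classes[[prof$patient_id]]
    inf <- classify_informed(lc, call, prof, side[i])
    data.frame(patient_id = prof$patient_id,
               actionable = call$actionable,
               indicated = paste(call$indicated, collapse = ","),
               informed = inf$informed,
               matched_targeted = inf$matched_targeted,
               group = assign_outcome_group(call, inf, prof),
               reason = ifelse(is.na(inf$reason), "", inf$reason),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
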