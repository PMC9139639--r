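# Actionability classification of ctDNA panel results under a fixed
# six-biomarker rule set (therapeutic levels 1/2/R1): KRAS and NRAS point
# mutations, BRAF V600E, ERBB2 amplification, NTRK1 fusion, MSI-high, with
# primary tumor sidedness modulating EGFR candidacy. Other panel findings
# (RET/ALK/ROS1/FGFR3 fusions, MET exon 14 skipping) are carried for
# reporting but never confer actionability.

#' Actionability policy
#'
#' @param ras_wt_right_actionable Whether a detected, RAS-wild-type profile
#'   with no other actionable biomarker in a right-sided tumor counts as
#'   actionable (the sample-level wording) even though it confers no therapy
#'   indication. Default `TRUE`; matched-therapy accounting excludes these
#'   patients regardless.
#' @param egfr_blocked_sides Tumor sides that block EGFR candidacy. Only the
#'   right colon by default; MIXED and UNSPECIFIED stay eligible.
#' @return Policy list for [classify_actionability()].
#' @export
actionability_policy <- function(ras_wt_right_actionable = TRUE,
                                 egfr_blocked_sides = "RIGHT") {
  list(ras_wt_right_actionable = ras_wt_right_actionable,
       egfr_blocked_sides = egfr_blocked_sides)
}

#' Classify a ctDNA profile for clinical actionability
#'
#' A detected sample without KRAS/NRAS mutations has an actionable molecular
#' profile and is an EGFR-therapy candidate unless BRAF V600E is present or
#' the tumor is right-sided. BRAF V600E, ERBB2 amplification, NTRK1 fusion
#' and MSI-high each indicate their corresponding therapy class regardless of
#' RAS status.
#'
#' @param profile One-row `data.frame` (or list) with logical fields
#'   `detected`, `kras_mut`, `nras_mut`, `braf_v600e`, `erbb2_amp`,
#'   `msi_high`, `ntrk1_fusion`.
#' @param side One of `tumor_sides()`.
#' @param policy From [actionability_policy()].
#' @return List with `actionable` (logical), `indicated` (character vector of
#'   therapy classes, subset of EGFR/BRAF/ERBB2/NTRK/ICI) and
#'   `egfr_blocked_reason` (`NA` or one of `no_ctdna`, `ras_mutant`,
#'   `braf_v600e`, `right_sided`).
#' @export
classify_actionability <- function(profile, side,
                                   policy = actionability_policy()) {
  stopifnot(side %in% tumor_sides())
  p <- lapply(profile[c("detected", "kras_mut", "nras_mut", "braf_v600e",
                        "erbb2_amp", "msi_high", "ntrk1_fusion")], isTRUE)
  if (!p$detected &&
      (p$kras_mut || p$nras_mut || p$braf_v600e || p$erbb2_amp ||
       p$msi_high || p$ntrk1_fusion)) {
    stop("profile invariant violated: alteration called with ctDNA undetected")
  }
  ras_wt <- !p$kras_mut && !p$nras_mut

  indicated <- character()
  if (p$braf_v600e) indicated <- c(indicated, "BRAF")
  if (p$erbb2_amp) indicated <- c(indicated, "ERBB2")
  if (p$ntrk1_fusion) indicated <- c(indicated, "NTRK")
  if (p$msi_high) indicated <- c(indicated, "ICI")

  blocked <- NA_character_
  if (!p$detected) {
    blocked <- "no_ctdna"
  } else if (!ras_wt) {
    blocked <- "ras_mutant"
  } else if (p$braf_v600e) {
    blocked <- "braf_v600e"
  } else if (side %in% policy$egfr_blocked_sides) {
    blocked <- "right_sided"
  } else {
    indicated <- c("EGFR", indicated)
  }

  actionable <- p$detected && (ras_wt || length(indicated) > 0)
  if (actionable && ras_wt && length(indicated) == 0 &&
      !policy$ras_wt_right_actionable) {
    actionable <- FALSE
  }
  list(actionable = actionable, indicated = indicated,
       egfr_blocked_reason = blocked)
}

#' Classify actionability for a table of tests
#'
#' @param tests Tests `data.frame` as from [load_tests()].
#' @param sides Sidedness `data.frame` (`patient_id`, `side`).
#' @param policy From [actionability_policy()].
#' @return `data.frame` with `test_id`, `patient_id`, `side`, `actionable`,
#'   `indicated` (comma-joined), `egfr_blocked_reason`.
#' @export
classify_actionability_all <- function(tests, sides,
                                       policy = actionability_policy()) {
  side <- sides$side[match(tests$patient_id, sides$patient_id)]
  if (anyNA(side)) stop("missing sidedness for some tested patients")
  calls <- lapply(seq_len(nrow(tests)), function(i) {
    classify_actionability(tests[i, ], side[i], policy)
  })
  data.frame(
    test_id = tests$test_id,
    patient_id = tests$patient_id,
    side = side,
    actionable = vapply(calls, `[[`, logical(1), "actionable"),
    indicated = vapply(calls, function(cl)
      paste(cl$indicated, collapse = ","), character(1)),
    egfr_blocked_reason = vapply(calls, `[[`, character(1),
                                 "egfr_blocked_reason"),
    stringsAsFactors = FALSE)
}

#' Alteration frequency table with arm comparisons
#'
#' Per-alteration counts and percentages over two denominators (all tested
#' samples and samples with detectable ctDNA), overall and split by a
#' two-level arm label (e.g. prior targeted vs non-targeted therapy), with
#' pairwise arm p-values from [two_prop_test()] on both denominators.
#'
#' @param tests Tests `data.frame`.
#' @param arm Character/factor vector aligned with `tests` rows giving the
#'   arm label; `NULL` for no arm split.
#' @return `data.frame`, one row per alteration.
#' @export
summarize_frequencies <- function(tests, arm = NULL) {
  flags <- c(kras_mut = "KRAS mutation", nras_mut = "NRAS mutation",
             any_ras = "Any RAS mutation", braf_v600e = "BRAF V600E",
             erbb2_amp = "ERBB2 amplification", msi_high = "MSI-high",
             ntrk1_fusion = "NTRK1 fusion")
  tests$any_ras <- tests$kras_mut | tests$nras_mut
  count_block <- function(df, prefix) {
    n_all <- nrow(df)
    n_det <- sum(df$detected)
    out <- lapply(names(flags), function(f) {
      n <- sum(df[[f]])
      c(n, 100 * n / max(n_all, 1), 100 * n / max(n_det, 1))
    })
    out <- do.call(rbind, out)
    colnames(out) <- paste0(prefix, c("_n", "_pct_all", "_pct_detected"))
    list(counts = out, n_all = n_all, n_det = n_det)
  }
  total <- count_block(tests, "total")
  res <- data.frame(alteration = unname(flags), total$counts,
                    stringsAsFactors = FALSE)
  if (!is.null(arm)) {
    lv <- unique(arm)
    if (length(lv) != 2) stop("arm must have exactly two levels")
    empty <- vapply(lv, function(l) sum(arm == l) == 0, logical(1))
    if (any(empty)) {
      warning("empty arm omitted: ", paste(lv[empty], collapse = ", "))
    } else {
      a <- count_block(tests[arm == lv[1], , drop = FALSE], "arm1")
      b <- count_block(tests[arm == lv[2], , drop = FALSE], "arm2")
      res <- cbind(res, a$counts, b$counts)
      res$p_all <- res$p_detected <- NA_real_
      for (i in seq_along(flags)) {
        res$p_all[i] <- two_prop_test(a$counts[i, 1], a$n_all,
                                      b$counts[i, 1], b$n_all,
                                      method = "auto")$p.value
        res$p_detected[i] <- two_prop_test(a$counts[i, 1], a$n_det,
                                           b$counts[i, 1], b$n_det,
                                           method = "auto")$p.value
      }
      attr(res, "arm_levels") <- lv
    }
  }
  res
}
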