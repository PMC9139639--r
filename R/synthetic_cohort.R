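# Synthetic cohort generator. Emits per-patient claim streams (pre-treatment
# activity, metastasis code, one or two derivable prior therapy lines, a
# post-test line), ctDNA test records timed before the second- or third-line
# start, death records and tumor sidedness, with the statistical structure
# the downstream analysis assumes: detection rate 93.7%, alteration
# prevalences conditional on detection split by prior-therapy arm, sidedness
# mix 44.5/18.9/25.8/10.8, 13% prior targeted therapy, and a 642:422
# second:third-line split. A configurable fraction of patients violates each
# eligibility filter so attrition accounting can be exercised.

#' Simulation configuration
#'
#' Defaults are the study conditions of the claims cohort the generator
#' emulates. Alteration prevalences are conditional on ctDNA detection and
#' split by prior-therapy arm.
#'
#' @param n_patients Number of patients.
#' @param detection_prob Probability ctDNA is detected.
#' @param prevalence_targeted,prevalence_non_targeted Named vectors
#'   (`kras`, `nras`, `braf_v600e`, `erbb2_amp`, `msi_high`, `ntrk1_fusion`)
#'   of alteration probabilities given detection, for patients with / without
#'   targeted therapy in the immediately prior line.
#' @param kras_g12c_frac Fraction of KRAS mutations that are G12C, per arm.
#' @param other_alteration_probs Named vectors of reporting-only alteration
#'   probabilities given detection, per arm.
#' @param sidedness_probs Probabilities of LEFT/RIGHT/MIXED/UNSPECIFIED.
#' @param prior_targeted_prob Probability the line before the index test
#'   contains targeted therapy.
#' @param p_second_line Probability the index test precedes second-line (vs
#'   third-line) therapy.
#' @param braf_ras_exclusivity Down-weighting of BRAF V600E given a RAS
#'   mutation (1 = fully exclusive, 0 = independent). The RAS-wild-type BRAF
#'   rate is raised to preserve the configured marginal prevalence.
#' @param frac_fail_test_window,frac_fail_clean_window,frac_fail_metastatic
#'   Fractions of patients planted to violate each eligibility filter.
#' @param p_targeted_given_actionable Probability an actionable patient
#'   receives targeted therapy in the post-test line.
#' @param p_matched_given_targeted Probability that targeted therapy given to
#'   an actionable patient is directed at an indicated class.
#' @param p_targeted_given_other Probability a non-actionable or undetected
#'   patient receives (necessarily unmatched) targeted therapy.
#' @param ttd_median_months Named vector of true discontinuation-time medians
#'   (months) for the four outcome groups (exponential model).
#' @param os_median_months,followup_median_months Medians (months) of the
#'   independent exponential death and last-claim (loss of follow-up)
#'   processes, both measured from the ctDNA report date.
#' @param admin_interval_days Days between administrations within a line.
#' @param msi_era_cutoff Optional day index; MSI-high calls are zeroed for
#'   tests reported before it (assay-era modelling). Default `NULL` (off).
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    n_patients = 1000,
    detection_prob = 0.937,
    prevalence_targeted = c(kras = 0.215, nras = 0.089, braf_v600e = 0.126,
                            erbb2_amp = 0.059, msi_high = 0.022,
                            ntrk1_fusion = 0.007),
    prevalence_non_targeted = c(kras = 0.458, nras = 0.046,
                                braf_v600e = 0.065, erbb2_amp = 0.023,
                                msi_high = 0.020, ntrk1_fusion = 0.000),
    kras_g12c_frac = c(targeted = 0.172, non_targeted = 0.091),
    other_alteration_probs = list(
      targeted = c(RET_fusion = 0.007, ALK_fusion = 0.007,
                   FGFR3_fusion = 0.007),
      non_targeted = c(RET_fusion = 0.001, ROS1_fusion = 0.001,
                       FGFR3_fusion = 0.001, MET_exon14 = 0.001)),
    sidedness_probs = c(LEFT = 0.445, RIGHT = 0.189, MIXED = 0.258,
                        UNSPECIFIED = 0.108),
    prior_targeted_prob = 0.13,
    p_second_line = 642 / 1064,
    braf_ras_exclusivity = 0.9,
    frac_fail_test_window = 0.05,
    frac_fail_clean_window = 0.05,
    frac_fail_metastatic = 0.05,
    p_targeted_given_actionable = 0.469,
    p_matched_given_targeted = 193 / 238,
    p_targeted_given_other = 0.18,
    ttd_median_months = c(ACTIONABLE_MATCHED = 5.3, ACTIONABLE_UNMATCHED = 3.9,
                          NOT_ACTIONABLE = 3.5, CTDNA_NOT_DETECTED = 3.5),
    os_median_months = 15,
    followup_median_months = 24,
    admin_interval_days = 14,
    msi_era_cutoff = NULL) {
  cfg <- as.list(environment())
  probs <- c(detection_prob, prevalence_targeted, prevalence_non_targeted,
             sidedness_probs, prior_targeted_prob, p_second_line,
             frac_fail_test_window, frac_fail_clean_window,
             frac_fail_metastatic, p_targeted_given_actionable,
             p_matched_given_targeted, p_targeted_given_other)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(sidedness_probs) - 1) > 1e-8) {
    stop("sidedness_probs must sum to 1")
  }
  if (n_patients < 0) stop("n_patients must be >= 0")
  if (frac_fail_test_window + frac_fail_clean_window +
        frac_fail_metastatic > 1) {
    stop("violation fractions exceed 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

# BRAF V600E rate conditional on RAS status that preserves the configured
# marginal prevalence under the exclusivity factor.
.braf_conditional <- function(p_braf, p_kras, p_nras, exclusivity) {
  p_ras <- 1 - (1 - p_kras) * (1 - p_nras)
  q_wt <- p_braf / ((1 - p_ras) + p_ras * (1 - exclusivity))
  q_wt <- min(q_wt, 1)
  c(wt = q_wt, mut = q_wt * (1 - exclusivity))
}

#' Draw one ctDNA profile
#'
#' Uses the current RNG state. Alterations are independent Bernoulli draws
#' given detection, except that BRAF V600E is down-weighted when a RAS
#' mutation was drawn (marginal prevalence preserved). No alterations are
#' called when ctDNA is undetected.
#'
#' @param prior_targeted Whether the patient's immediately prior line
#'   contained targeted therapy (selects the prevalence column).
#' @param config A [sim_config()].
#' @return One-row `data.frame` of profile flags (without ids/dates).
#' @export
generate_profile <- function(prior_targeted, config = sim_config()) {
  detected <- stats::runif(1) < config$detection_prob
  prev <- if (prior_targeted) config$prevalence_targeted else
    config$prevalence_non_targeted
  g12c_frac <- if (prior_targeted) config$kras_g12c_frac[["targeted"]] else
    config$kras_g12c_frac[["non_targeted"]]
  other_p <- config$other_alteration_probs[[
    if (prior_targeted) "targeted" else "non_targeted"]]
  kras <- nras <- braf <- erbb2 <- msi <- ntrk <- FALSE
  kras_variant <- ""
  other <- ""
  if (detected) {
    kras <- stats::runif(1) < prev[["kras"]]
    nras <- stats::runif(1) < prev[["nras"]]
    qb <- .braf_conditional(prev[["braf_v600e"]], prev[["kras"]],
                            prev[["nras"]], config$braf_ras_exclusivity)
    braf <- stats::runif(1) < (if (kras || nras) qb[["mut"]] else qb[["wt"]])
    erbb2 <- stats::runif(1) < prev[["erbb2_amp"]]
    msi <- stats::runif(1) < prev[["msi_high"]]
    ntrk <- stats::runif(1) < prev[["ntrk1_fusion"]]
    if (kras && stats::runif(1) < g12c_frac) kras_variant <- "G12C"
    hit <- names(other_p)[stats::runif(length(other_p)) < other_p]
    other <- paste(hit, collapse = ";")
  }
  data.frame(detected = detected, kras_mut = kras, kras_variant = kras_variant,
             nras_mut = nras, braf_v600e = braf, erbb2_amp = erbb2,
             msi_high = msi, ntrk1_fusion = ntrk, other = other,
             stringsAsFactors = FALSE)
}

# Representative agent per targeted class for simulated post-test regimens.
.class_agents <- c(EGFR = "panitumumab", BRAF = "encorafenib",
                   ERBB2 = "trastuzumab", NTRK = "larotrectinib",
                   ICI = "pembrolizumab", OTHER_TARGETED = "regorafenib")

#' Generate a synthetic cohort
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same (config, seed) pair reproduces the
#'   output exactly.
#' @return List with `claims`, `tests`, `deaths`, `sides` data frames (the
#'   I/O schemas of the loaders) and `truth`, the generator's bookkeeping:
#'   per patient, the planted eligibility violation (`none`,
#'   `test_window`, `clean_window`, `metastatic`), intended index line
#'   number, prior-therapy arm, and the planted treatment intent.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_patients
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(
      claims = empty(patient_id = character(), date = integer(),
                     kind = character(), code = character()),
      tests = empty(test_id = character(), patient_id = character(),
                    report_date = integer(), detected = logical(),
                    kras_mut = logical(), kras_variant = character(),
                    nras_mut = logical(), braf_v600e = logical(),
                    erbb2_amp = logical(), msi_high = logical(),
                    ntrk1_fusion = logical(), other = character()),
      deaths = empty(patient_id = character(), death_date = integer()),
      sides = empty(patient_id = character(), side = character()),
      truth = empty(patient_id = character(), planted_violation = character(),
                    index_line_number = integer(), prior_targeted = logical(),
                    detected = logical(), planted_therapy = character(),
                    planted_group = character()),
      config = config, seed = seed))
  }

  claims_l <- vector("list", n)
  tests_l <- vector("list", n)
  deaths_l <- vector("list", n)
  truth_l <- vector("list", n)
  side_v <- character(n)
  interval <- config$admin_interval_days
  ttd_rate <- log(2) / (config$ttd_median_months * DAYS_PER_MONTH)
  os_rate <- log(2) / (config$os_median_months * DAYS_PER_MONTH)
  fu_rate <- log(2) / (config$followup_median_months * DAYS_PER_MONTH)

  viol_levels <- c("test_window", "clean_window", "metastatic", "none")
  viol_probs <- c(config$frac_fail_test_window, config$frac_fail_clean_window,
                  config$frac_fail_metastatic,
                  1 - config$frac_fail_test_window -
                    config$frac_fail_clean_window - config$frac_fail_metastatic)
  if (viol_probs[4] < 0) stop("violation fractions exceed 1")

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    side <- sample(names(config$sidedness_probs), 1,
                   prob = config$sidedness_probs)
    side_v[i] <- side
    violation <- sample(viol_levels, 1, prob = viol_probs)
    index_line <- if (stats::runif(1) < config$p_second_line) 2L else 3L
    prior_targeted <- stats::runif(1) < config$prior_targeted_prob

    cl <- list()
    add_claims <- function(dates, kind, codes) {
      cl[[length(cl) + 1]] <<- data.frame(
        patient_id = pid, date = as.integer(rep(dates, each = length(codes))),
        kind = kind, code = rep(codes, times = length(dates)),
        stringsAsFactors = FALSE)
    }

    # pre-treatment activity (first-line start is day 0)
    if (violation == "clean_window") {
      add_claims(-60L, "medical", "DX_OFFICE_VISIT")
    } else {
      add_claims(c(-150L, -60L), "medical", "DX_OFFICE_VISIT")
    }
    if (violation != "metastatic") {
      add_claims(10L, "medical", "DX_METASTATIC")
    }

    # prior lines; index line is number index_line
    d1 <- round(stats::runif(1, 90, 150))
    admin1 <- seq(0L, d1, by = interval)
    agents1 <- c("oxaliplatin", "fluorouracil")
    if (stats::runif(1) < 0.5) agents1 <- c(agents1, "bevacizumab")
    if (prior_targeted && index_line == 2L) agents1 <- c(agents1, "cetuximab")
    add_claims(admin1, "pharmacy", agents1)
    prev_last <- max(admin1)
    prev_agents <- agents1
    if (index_line == 3L) {
      s2 <- prev_last + round(stats::runif(1, 21, 60))
      d2 <- round(stats::runif(1, 90, 150))
      admin2 <- seq(s2, s2 + d2, by = interval)
      agents2 <- c("irinotecan", "fluorouracil")
      if (prior_targeted) agents2 <- c(agents2, "cetuximab")
      add_claims(admin2, "pharmacy", agents2)
      prev_last <- max(admin2)
      prev_agents <- agents2
    }
    index_start <- prev_last + round(stats::runif(1, 21, 60))

    # index ctDNA test
    report <- if (violation == "test_window") {
      index_start + round(stats::runif(1, 10, 40))
    } else {
      index_start - round(stats::runif(1, 7, 60))
    }
    prof <- generate_profile(prior_targeted, config)
    if (!is.null(config$msi_era_cutoff) &&
        report < config$msi_era_cutoff) {
      prof$msi_high <- FALSE
    }

    # post-test therapy choice driven by the profile
    call <- classify_actionability(prof, side)
    give_targeted <- if (call$actionable) {
      stats::runif(1) < config$p_targeted_given_actionable
    } else {
      stats::runif(1) < config$p_targeted_given_other
    }
    if (give_targeted) {
      if (call$actionable &&
          stats::runif(1) < config$p_matched_given_targeted &&
          length(call$indicated) > 0) {
        klass <- call$indicated[1]
        planted <- "matched_targeted"
      } else {
        klass <- setdiff(c("ICI", "EGFR", "BRAF"), call$indicated)[1]
        planted <- "unmatched_targeted"
      }
      agents_idx <- .class_agents[[klass]]
    } else {
      backbone <- if (index_line == 2L) "irinotecan" else
        "trifluridine_tipiracil"
      agents_idx <- c(backbone, "fluorouracil")
      if (stats::runif(1) < 0.6) agents_idx <- c(agents_idx, "bevacizumab")
      planted <- "non_targeted"
    }

    # outcome processes
    group <- if (!prof$detected) "CTDNA_NOT_DETECTED" else
      if (!call$actionable) "NOT_ACTIONABLE" else
        if (planted == "matched_targeted") "ACTIONABLE_MATCHED" else
          "ACTIONABLE_UNMATCHED"
    ttd_true <- stats::rexp(1, ttd_rate[[group]])
    # death conditioned on surviving to the post-test line start (patients in
    # the cohort started that line by construction); memoryless, so this is
    # the exponential clock from the report restricted to death > line start
    death <- index_start + stats::rexp(1, os_rate)
    fu_end <- report + stats::rexp(1, fu_rate)
    horizon <- max(floor(min(death, fu_end)), index_start)
    admin_end <- min(index_start + ttd_true, horizon)
    admin_idx <- seq(index_start, max(admin_end, index_start), by = interval)
    add_claims(admin_idx, "pharmacy", agents_idx)
    # trailing claim activity until loss of follow-up or death
    if (max(admin_idx) + 45L <= horizon) {
      add_claims(seq(max(admin_idx) + 45L, horizon, by = 45L),
                 "medical", "DX_OFFICE_VISIT")
    }

    claims_l[[i]] <- do.call(rbind, cl)
    tests_l[[i]] <- cbind(
      data.frame(test_id = paste0("T", pid), patient_id = pid,
                 report_date = as.integer(report), stringsAsFactors = FALSE),
      prof)
    if (death <= fu_end) {
      deaths_l[[i]] <- data.frame(patient_id = pid,
                                  death_date = as.integer(floor(death)),
                                  stringsAsFactors = FALSE)
    }
    truth_l[[i]] <- data.frame(
      patient_id = pid, planted_violation = violation,
      index_line_number = index_line, prior_targeted = prior_targeted,
      detected = prof$detected, planted_therapy = planted,
      planted_group = group, stringsAsFactors = FALSE)
  }

  claims <- do.call(rbind, claims_l)
  claims$metastatic_flag <- claims$code == "DX_METASTATIC"
  claims <- claims[order(claims$patient_id, claims$date), , drop = FALSE]
  rownames(claims) <- NULL
  deaths_l <- deaths_l[!vapply(deaths_l, is.null, logical(1))]
  deaths <- if (length(deaths_l)) do.call(rbind, deaths_l) else
    empty(patient_id = character(), death_date = integer())
  list(claims = claims,
       tests = do.call(rbind, tests_l),
       deaths = deaths,
       sides = data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                          side = side_v, stringsAsFactors = FALSE),
       truth = do.call(rbind, truth_l),
       config = config, seed = seed)
}

#' Write a generated cohort to CSV files
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("claims.csv", "tests.csv", "deaths.csv",
                            "sides.csv", "truth.csv"))
  write_claims(cohort$claims, paths[1])
  utils::write.csv(cohort$tests, paths[2], row.names = FALSE)
  utils::write.csv(cohort$deaths, paths[3], row.names = FALSE)
  utils::write.csv(cohort$sides, paths[4], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[5], row.names = FALSE)
  invisible(paths)
}
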