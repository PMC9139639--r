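# Hand-specified fixture cohorts: deterministic test/side/therapy strata for
# the worked examples, built from a stratum table rather than random draws.

# Profile categories a fixture stratum may request.
.fixture_profiles <- function() {
  list(
    no_ctdna = list(detected = FALSE),
    ras_mut = list(detected = TRUE, kras_mut = TRUE),
    nras_mut = list(detected = TRUE, nras_mut = TRUE),
    ras_wt_clear = list(detected = TRUE),
    braf_v600e = list(detected = TRUE, braf_v600e = TRUE),
    erbb2_amp = list(detected = TRUE, erbb2_amp = TRUE),
    msi_high = list(detected = TRUE, msi_high = TRUE),
    msi_braf = list(detected = TRUE, msi_high = TRUE, braf_v600e = TRUE),
    ntrk1_fusion = list(detected = TRUE, ntrk1_fusion = TRUE))
}

#' Build a deterministic fixture cohort
#'
#' Each row of `spec` describes a stratum: `count` patients whose index test
#' shows `profile` (one of `no_ctdna`, `ras_mut`, `nras_mut`, `ras_wt_clear`,
#' `braf_v600e`, `erbb2_amp`, `msi_high`, `msi_braf`, `ntrk1_fusion`), with
#' tumor `side` and post-test `therapy` class(es) (`+`-separated, e.g.
#' `"CHEMO+VEGF"`).
#'
#' @param spec `data.frame` with columns `count`, `profile`, `side`,
#'   `therapy`.
#' @param total Optional expected cohort size; an error if the stratum counts
#'   do not sum to it.
#' @return List with `tests`, `sides` data frames and `therapy`, a named list
#'   mapping patient id to the administered therapy classes.
#' @export
build_fixture <- function(spec, total = NULL) {
  stopifnot(all(c("count", "profile", "side", "therapy") %in% names(spec)))
  if (any(spec$count < 0) || any(spec$count != round(spec$count))) {
    stop("stratum counts must be non-negative integers")
  }
  if (!is.null(total) && sum(spec$count) != total) {
    stop("stratum counts sum to ", sum(spec$count), ", expected ", total)
  }
  profs <- .fixture_profiles()
  bad <- setdiff(spec$profile, names(profs))
  if (length(bad)) stop("unknown profile category: ", paste(bad, collapse = ", "))
  bad <- setdiff(spec$side, tumor_sides())
  if (length(bad)) stop("unknown side: ", paste(bad, collapse = ", "))

  rows <- list()
  therapy <- list()
  k <- 0L
  for (s in seq_len(nrow(spec))) {
    base <- list(detected = FALSE, kras_mut = FALSE, kras_variant = "",
                 nras_mut = FALSE, braf_v600e = FALSE, erbb2_amp = FALSE,
                 msi_high = FALSE, ntrk1_fusion = FALSE, other = "")
    base[names(profs[[spec$profile[s]]])] <- profs[[spec$profile[s]]]
    for (j in seq_len(spec$count[s])) {
      k <- k + 1L
      pid <- sprintf("F%04d", k)
      rows[[k]] <- cbind(
        data.frame(test_id = paste0("T", pid), patient_id = pid,
                   report_date = 0L, side = spec$side[s],
                   stringsAsFactors = FALSE),
        as.data.frame(base, stringsAsFactors = FALSE))
      therapy[[pid]] <- strsplit(spec$therapy[s], "+", fixed = TRUE)[[1]]
    }
  }
  all_rows <- do.call(rbind, rows)
  list(tests = all_rows[, setdiff(names(all_rows), "side")],
       sides = data.frame(patient_id = all_rows$patient_id,
                          side = all_rows$side, stringsAsFactors = FALSE),
       therapy = therapy)
}

#' Worked-example fixture cohorts
#'
#' Stratum tables for the four targeted-therapy cohorts used as worked
#' examples: 233 EGFR-treated patients (14 ctDNA-undetected, 23 RAS-mutant,
#' 18 RAS-wild-type right-sided, 21 BRAF V600E, 1 MSI-high, 156 RAS-wild-type
#' left-sided with no other actionable marker), 78 immune-checkpoint-treated
#' patients (16 MSI-high, 3 undetected, 4 BRAF V600E, 2 ERBB2-amplified, 14
#' RAS-wild-type, 39 RAS-mutant), 16 BRAF-treated (13 with V600E) and 21
#' ERBB2-treated (19 with amplification).
#'
#' @return A fixture cohort as from [build_fixture()].
#' @export
fixture_egfr_233 <- function() {
  spec <- data.frame(
    count = c(14, 23, 18, 21, 1, 156),
    profile = c("no_ctdna", "ras_mut", "ras_wt_clear", "braf_v600e",
                "msi_high", "ras_wt_clear"),
    side = c("LEFT", "LEFT", "RIGHT", "LEFT", "LEFT", "LEFT"),
    therapy = "EGFR", stringsAsFactors = FALSE)
  build_fixture(spec, total = 233)
}

#' @rdname fixture_egfr_233
#' @export
fixture_ici_78 <- function() {
  spec <- data.frame(
    count = c(16, 3, 4, 2, 14, 39),
    profile = c("msi_high", "no_ctdna", "braf_v600e", "erbb2_amp",
                "ras_wt_clear", "ras_mut"),
    side = "LEFT", therapy = "ICI", stringsAsFactors = FALSE)
  build_fixture(spec, total = 78)
}

#' @rdname fixture_egfr_233
#' @export
fixture_braf_16 <- function() {
  spec <- data.frame(
    count = c(13, 3), profile = c("braf_v600e", "ras_mut"),
    side = "LEFT", therapy = "BRAF", stringsAsFactors = FALSE)
  build_fixture(spec, total = 16)
}

#' @rdname fixture_egfr_233
#' @export
fixture_erbb2_21 <- function() {
  spec <- data.frame(
    count = c(19, 2), profile = c("erbb2_amp", "ras_mut"),
    side = "LEFT", therapy = "ERBB2", stringsAsFactors = FALSE)
  build_fixture(spec, total = 21)
}

#' Fraction of a fixture cohort classified molecularly informed
#'
#' Runs the actionability and informed-therapy classifiers over a fixture
#' cohort and returns the informed percentage.
#'
#' @param fixture A fixture from [build_fixture()].
#' @param policy From [actionability_policy()].
#' @param digits Decimal places for the returned percentage (`NULL` for full
#'   precision).
#' @return List with `n`, `informed` (count) and `percent`.
#' @export
fixture_informed_fraction <- function(fixture,
                                      policy = actionability_policy(),
                                      digits = 1) {
  labels <- label_cohort(fixture$tests, fixture$sides, fixture$therapy,
                         policy)
  pct <- 100 * mean(labels$informed)
  if (!is.null(digits)) pct <- round_half_up(pct, digits)
  list(n = nrow(labels), informed = sum(labels$informed), percent = pct)
}
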