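# End-to-end study pipeline: derive lines, select the cohort, classify
# actionability and informed therapy, compute TTD/OS, run the comparison
# statistics, and assemble the report tables (attrition flow, prior-therapy
# mix, alteration frequencies, informed-therapy fractions, KM summaries).

# Therapy-mix categories used by the prior-therapy and post-test tables.
.class_categories <- function(classes) {
  targeted <- intersect(classes, targeted_classes())
  non_targ <- length(targeted) == 0
  c(chemo_only = non_targ &&
      all(classes %in% c("CHEMO", "FLUOROURACIL")),
    vegf_no_targeted = non_targ &&
      any(classes %in% c("VEGF", "BEVACIZUMAB")),
    any_non_targeted = non_targ,
    any_targeted = !non_targ,
    EGFR = "EGFR" %in% classes,
    BRAF = "BRAF" %in% classes,
    ERBB2 = "ERBB2" %in% classes,
    NTRK = "NTRK" %in% classes,
    OTHER_TARGETED = "OTHER_TARGETED" %in% classes,
    ICI = "ICI" %in% classes,
    any = TRUE)
}

.category_table <- function(class_sets, informed = NULL) {
  mat <- t(vapply(class_sets, .class_categories,
                  logical(length(.class_categories(character())))))
  out <- data.frame(category = colnames(mat), n = colSums(mat),
                    stringsAsFactors = FALSE)
  if (!is.null(informed)) {
    out$informed_n <- colSums(mat & informed)
    out$informed_pct <- ifelse(out$n > 0,
                               round_half_up(100 * out$informed_n / out$n, 1), NA)
  } else {
    out$pct <- round_half_up(100 * out$n / max(length(class_sets), 1), 1)
  }
  rownames(out) <- NULL
  out
}

#' Run the full claims-to-outcomes study pipeline
#'
#' @param claims,tests,deaths,sides Input tables in the loader schemas.
#' @param class_map Drug-code map; defaults to the packaged map.
#' @param params LOT parameters from [lot_params()].
#' @param policy Actionability policy from [actionability_policy()].
#' @param window_days Test-to-line-start eligibility window (days).
#' @return An object of class `ctdna_study`: eligibility records, attrition
#'   counts, derived lines, per-patient labels, TTD and OS records, KM fits,
#'   log-rank and Cox results across the four outcome groups, the alteration
#'   frequency table by prior-therapy arm, and the assembled report.
#' @export
ctdna_study <- function(claims, tests, deaths, sides,
                        class_map = load_class_map(),
                        params = lot_params(),
                        policy = actionability_policy(),
                        window_days = 90) {
  cohort <- build_study_cohort(claims, tests, deaths, sides, class_map,
                               params, window_days)
  elig <- cohort$eligibility
  inc <- elig[elig$cohort_label != "excluded", , drop = FALSE]
  lines <- cohort$lines

  labels <- NULL
  ttd <- os <- NULL
  km_ttd <- logrank <- cox <- freq <- NULL
  if (nrow(inc) > 0) {
    idx_tests <- tests[match(inc$index_test_id, tests$test_id), , drop = FALSE]
    last_claim <- tapply(claims$date, claims$patient_id, max)
    death_at <- deaths$death_date[match(inc$patient_id, deaths$patient_id)]

    line_classes <- lapply(seq_len(nrow(inc)), function(i) {
      r <- lines[lines$patient_id == inc$patient_id[i] &
                   lines$line_number == inc$index_line_number[i], ]
      strsplit(r$classes, ",", fixed = TRUE)[[1]]
    })
    names(line_classes) <- inc$patient_id

    labels <- label_cohort(idx_tests, sides, line_classes, policy)
    labels$cohort_label <- inc$cohort_label
    labels$prior_targeted <- inc$prior_targeted

    recs <- lapply(seq_len(nrow(inc)), function(i) {
      r <- lines[lines$patient_id == inc$patient_id[i] &
                   lines$line_number == inc$index_line_number[i], ]
      lc <- as.numeric(last_claim[[inc$patient_id[i]]])
      d <- death_at[i]
      t1 <- compute_ttd(r, lc, d)
      t2 <- compute_os(idx_tests$report_date[i], d, max(lc, idx_tests$report_date[i]))
      data.frame(patient_id = inc$patient_id[i],
                 ttd_time = t1$time, ttd_event = t1$event,
                 os_time = t2$time, os_event = t2$event,
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    ttd <- data.frame(patient_id = recs$patient_id, time = recs$ttd_time,
                      event = recs$ttd_event, group = labels$group,
                      stringsAsFactors = FALSE)
    os <- data.frame(patient_id = recs$patient_id, time = recs$os_time,
                     event = recs$os_event, group = labels$group,
                     cohort_label = inc$cohort_label,
                     stringsAsFactors = FALSE)
    km_ttd <- km_fit(ttd)
    groups_present <- unique(ttd$group)
    if (length(groups_present) >= 2) {
      logrank <- logrank_test(ttd)
      if (sum(tapply(ttd$event, ttd$group, sum) > 0) >= 2) {
        ref <- if ("ACTIONABLE_MATCHED" %in% groups_present)
          "ACTIONABLE_MATCHED" else sort(groups_present)[1]
        cox <- cox_ph(ttd, reference = ref)
      }
    }
    arm <- ifelse(labels$prior_targeted, "targeted", "non_targeted")
    if (length(unique(arm)) == 2) {
      freq <- summarize_frequencies(idx_tests, arm)
    } else {
      freq <- summarize_frequencies(idx_tests)
    }
  }

  res <- structure(list(
    eligibility = elig, attrition = cohort$attrition, lines = lines,
    labels = labels, ttd = ttd, os = os, km_ttd = km_ttd,
    logrank = logrank, cox = cox, freq = freq,
    policy = policy, params = params, window_days = window_days),
    class = "ctdna_study")
  res$report <- build_report(res)
  res
}

#' Assemble the study report
#'
#' Report tables in the flow's fixed order, each percentage carried with its
#' numerator/denominator pair (display values rounded to one decimal, full
#' precision retained alongside).
#'
#' @param study A `ctdna_study` object.
#' @param config Optional provenance block (e.g. the simulation config and
#'   seed) stored verbatim.
#' @return A list of class `ctdna_report`.
#' @export
build_report <- function(study, config = NULL) {
  att <- as.list(study$attrition)
  steps <- unlist(att)
  att$step_pct <- round_half_up(100 * steps[-1] / pmax(steps[-length(steps)], 1), 1)

  informed_table <- prior_table <- group_counts <- NULL
  informed_overall <- NULL
  if (!is.null(study$labels) && nrow(study$labels) > 0) {
    inc <- study$eligibility[study$eligibility$cohort_label != "excluded", ,
                             drop = FALSE]
    post_sets <- lapply(seq_len(nrow(inc)), function(i) {
      r <- study$lines[study$lines$patient_id == inc$patient_id[i] &
                         study$lines$line_number == inc$index_line_number[i], ]
      strsplit(r$classes, ",", fixed = TRUE)[[1]]
    })
    prior_sets <- lapply(seq_len(nrow(inc)), function(i) {
      r <- study$lines[study$lines$patient_id == inc$patient_id[i] &
                         study$lines$line_number ==
                           inc$index_line_number[i] - 1L, ]
      if (nrow(r)) strsplit(r$classes, ",", fixed = TRUE)[[1]] else character()
    })
    informed_table <- .category_table(post_sets, study$labels$informed)
    prior_table <- .category_table(prior_sets)
    group_counts <- as.list(table(study$labels$group))
    informed_overall <- list(
      n = nrow(study$labels),
      informed = sum(study$labels$informed),
      pct = round_half_up(100 * mean(study$labels$informed), 1),
      pct_full = 100 * mean(study$labels$informed))
  }
  km <- if (!is.null(study$km_ttd)) study$km_ttd$medians else NULL
  structure(list(
    attrition = att,
    group_counts = group_counts,
    informed_overall = informed_overall,
    prior_therapy = prior_table,
    informed_therapy = informed_table,
    alteration_frequencies = study$freq,
    km_medians = km,
    logrank = study$logrank,
    cox_pairwise = if (!is.null(study$cox)) study$cox$pairwise else NULL,
    provenance = list(package = "ctdnaRWE",
                      version = as.character(utils::packageVersion("ctdnaRWE")),
                      config = config)),
    class = "ctdna_report")
}

#' Write a study report to disk
#'
#' @param report A `ctdna_report`.
#' @param dir Output directory; JSON report plus CSV tables.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  for (nm in c("prior_therapy", "informed_therapy", "alteration_frequencies",
               "km_medians", "cox_pairwise")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(json)
}

#' Simulate a cohort and run the full pipeline
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the generator.
#' @param out_dir Optional directory; when given, the cohort CSVs and the
#'   report bundle are written there.
#' @param ... Passed to [ctdna_study()] (policy, params, ...).
#' @return The `ctdna_study` object, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, out_dir = NULL,
                         ...) {
  cohort <- generate_cohort(config, seed)
  study <- ctdna_study(cohort$claims, cohort$tests, cohort$deaths,
                       cohort$sides, ...)
  study$report$provenance$config <- list(seed = seed,
                                         n_patients = config$n_patients)
  if (!is.null(out_dir)) {
    write_cohort(cohort, file.path(out_dir, "cohort"))
    write_report(study$report, out_dir)
    return(invisible(study))
  }
  study
}

#' @export
print.ctdna_study <- function(x, ...) {
  cat("ctDNA-guided therapy study\n")
  cat("Attrition:", paste(names(x$attrition), x$attrition, sep = "=",
                          collapse = " -> "), "\n")
  if (!is.null(x$labels)) {
    cat("Included:", nrow(x$labels), "patients (",
        sum(x$labels$cohort_label == "second_line"), "second-line /",
        sum(x$labels$cohort_label == "third_line"), "third-line )\n")
    cat("Outcome groups:\n")
    print(table(x$labels$group))
    io <- x$report$informed_overall
    cat(sprintf("Molecularly informed therapy: %d/%d (%.1f%%)\n",
                io$informed, io$n, io$pct))
    if (!is.null(x$logrank)) {
      cat(sprintf("TTD log-rank across groups: chisq=%.3f df=%d p=%.4f\n",
                  x$logrank$chisq, x$logrank$df, x$logrank$p.value))
    }
  } else {
    cat("No patients met the eligibility filters.\n")
  }
  invisible(x)
}

#' @export
summary.ctdna_study <- function(object, ...) {
  print(object)
  if (!is.null(object$km_ttd)) {
    cat("\nMedian TTD by group (months):\n")
    print(object$km_ttd$medians, row.names = FALSE)
  }
  if (!is.null(object$cox)) {
    cat("\nPairwise hazard ratios (TTD):\n")
    print(object$cox$pairwise, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.ctdna_study <- function(x, ...) {
  if (is.null(x$km_ttd)) {
    stop("nothing to plot: no included patients")
  }
  plot(x$km_ttd, ...)
}
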