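# Line-of-therapy reconstruction from a patient's systemic-therapy claims.
#
# Rules, applied per administration date in this precedence:
#   (1) the regimen signature ignores fluorouracil and bevacizumab;
#   (2) adding/modifying a targeted agent (incl. VEGF agents other than
#       bevacizumab) strictly more than 60 days after line start opens a new
#       line;
#   (3) adding/switching a chemotherapy agent strictly more than 15 days
#       after line start opens a new line;
#   (4) otherwise a claim more than 90 days (strict) after the last
#       administration opens a new line (same regimen resuming within 90
#       days merges);
#   (5) pure discontinuation never opens a new line.
# Thresholds are strict ("more than") for 60/15 and inclusive for the 90-day
# gap, measured last-administration-to-next-administration. New-agent rules
# are evaluated before the gap rule when a single date does both.

#' Default line-of-therapy parameters
#'
#' @param gap_days Maximum gap (inclusive) between administrations of the
#'   same regimen that still merges into one line. Default 90.
#' @param targeted_change_days New targeted agents strictly later than this
#'   many days after line start open a new line. Default 60.
#' @param chemo_change_days New chemotherapy agents strictly later than this
#'   many days after line start open a new line. Default 15.
#' @param exposure_window_days Named numeric vector or single number: days of
#'   assumed drug exposure after the last administration, per therapy class,
#'   used only to estimate the end of a line (one cycle length, default 28
#'   for every class). The maximum over the classes present in the line is
#'   used.
#' @return A list of parameters for [derive_lines()].
#' @export
lot_params <- function(gap_days = 90, targeted_change_days = 60,
                       chemo_change_days = 15, exposure_window_days = 28) {
  list(gap_days = gap_days,
       targeted_change_days = targeted_change_days,
       chemo_change_days = chemo_change_days,
       exposure_window_days = exposure_window_days)
}

#' Regimen signature
#'
#' Canonical, order-independent identity of a regimen: the sorted set of
#' agent codes excluding fluorouracil- and bevacizumab-class agents, whose
#' addition or removal never defines a new regimen.
#'
#' @param codes Character vector of agent codes.
#' @param classes Therapy classes of `codes` (same length).
#' @return Sorted character vector of non-exempt codes.
#' @export
regimen_signature <- function(codes, classes) {
  sort(unique(codes[!(classes %in% signature_exempt_classes())]))
}

# Classes subject to the 60-day targeted-modification rule. VEGF agents other
# than bevacizumab are treated as targeted modifications here even though
# they are excluded from the narrow "targeted therapy" definition used for
# matched-therapy accounting.
.rule_targeted_classes <- function() {
  c(targeted_classes(), "VEGF")
}

#' Derive lines of therapy for one patient
#'
#' @param claims Claims `data.frame` for a single patient (any `NON_CANCER`
#'   claims are ignored), sorted by date.
#' @param class_map Named code-to-class map from [load_class_map()].
#' @param params Parameters from [lot_params()].
#' @return A `data.frame` with one row per line: `line_number`, `start_date`,
#'   `last_admin_date`, `est_end_date`, `agents` (comma-joined codes),
#'   `classes` (comma-joined class set), `contains_targeted`, `n_claims`.
#'   Empty input yields a zero-row frame. The claim-to-line assignment is
#'   returned in attribute `"claim_lines"` (integer line number per retained
#'   therapy claim, in date order).
#' @export
derive_lines <- function(claims, class_map, params = lot_params()) {
  empty <- data.frame(line_number = integer(), start_date = integer(),
                      last_admin_date = integer(), est_end_date = integer(),
                      agents = character(), classes = character(),
                      contains_targeted = logical(), n_claims = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(claims) == 0) return(empty)
  if (is.unsorted(claims$date)) stop("claims must be sorted by date")
  cls <- classify_agent(claims$code, class_map)
  keep <- cls != "NON_CANCER"
  claims <- claims[keep, , drop = FALSE]
  cls <- cls[keep]
  if (nrow(claims) == 0) return(empty)

  dates <- claims$date
  udates <- unique(dates)
  # per-line accumulators
  lines <- list()
  cur <- NULL        # list(start, last_admin, codes, classes, n_claims)
  claim_line <- integer(nrow(claims))
  line_no <- 0L

  open_line <- function(t) {
    line_no <<- line_no + 1L
    cur <<- list(start = t, last_admin = t, codes = character(),
                 classes = character(), n_claims = 0L)
  }

  for (t in udates) {
    idx <- which(dates == t)
    codes_t <- claims$code[idx]
    cls_t <- cls[idx]
    if (is.null(cur)) {
      open_line(t)
    } else {
      new_idx <- !(codes_t %in% cur$codes)
      new_cls <- cls_t[new_idx]
      elapsed <- t - cur$start
      gap <- t - cur$last_admin
      new_targeted <- any(new_cls %in% .rule_targeted_classes())
      new_chemo <- any(new_cls == "CHEMO")
      if (new_targeted && elapsed > params$targeted_change_days) {
        lines[[line_no]] <- cur
        open_line(t)
      } else if (new_chemo && elapsed > params$chemo_change_days) {
        lines[[line_no]] <- cur
        open_line(t)
      } else if (gap > params$gap_days) {
        lines[[line_no]] <- cur
        open_line(t)
      }
    }
    cur$codes <- union(cur$codes, codes_t)
    cur$classes <- union(cur$classes, cls_t)
    cur$last_admin <- t
    cur$n_claims <- cur$n_claims + length(idx)
    claim_line[idx] <- line_no
  }
  lines[[line_no]] <- cur

  windows <- params$exposure_window_days
  est_end <- function(l) {
    if (length(windows) == 1L && is.null(names(windows))) {
      w <- windows
    } else {
      w <- max(windows[l$classes], 0, na.rm = TRUE)
    }
    l$last_admin + max(w)
  }
  out <- data.frame(
    line_number = seq_along(lines),
    start_date = vapply(lines, function(l) as.integer(l$start), integer(1)),
    last_admin_date = vapply(lines, function(l) as.integer(l$last_admin),
                             integer(1)),
    est_end_date = vapply(lines, function(l) as.integer(est_end(l)),
                          integer(1)),
    agents = vapply(lines, function(l) paste(sort(l$codes), collapse = ","),
                    character(1)),
    classes = vapply(lines, function(l) paste(sort(l$classes), collapse = ","),
                     character(1)),
    contains_targeted = vapply(lines, function(l)
      any(l$classes %in% targeted_classes()), logical(1)),
    n_claims = vapply(lines, function(l) l$n_claims, integer(1)),
    stringsAsFactors = FALSE)
  attr(out, "claim_lines") <- claim_line
  out
}

#' Derive lines of therapy for every patient in a claims table
#'
#' @inheritParams derive_lines
#' @param claims Claims for any number of patients, sorted by
#'   (patient_id, date).
#' @return Stacked per-patient line tables with a leading `patient_id`
#'   column.
#' @export
derive_lines_all <- function(claims, class_map, params = lot_params()) {
  pieces <- lapply(split(claims, claims$patient_id), function(df) {
    df <- df[order(df$date), , drop = FALSE]
    ln <- derive_lines(df, class_map, params)
    if (nrow(ln)) ln$patient_id <- df$patient_id[1]
    ln
  })
  pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
  if (!length(pieces)) {
    out <- derive_lines(claims[0, , drop = FALSE], class_map, params)
    out$patient_id <- character()
    return(out[, c("patient_id", setdiff(names(out), "patient_id"))])
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("patient_id", setdiff(names(out), "patient_id"))]
}

#' Estimate the end date of a therapy line
#'
#' Last administration date plus the largest per-class exposure window among
#' the classes in the line (a proxy for one treatment cycle; claims carry no
#' days-supply field in this schema).
#'
#' @param last_admin_date Integer day of the last administration.
#' @param classes Character vector of therapy classes present in the line.
#' @param exposure_window_days Single number or named per-class vector.
#' @return Integer day of estimated end of therapy.
#' @export
estimate_line_end <- function(last_admin_date, classes,
                              exposure_window_days = 28) {
  if (length(exposure_window_days) == 1L && is.null(names(exposure_window_days))) {
    w <- exposure_window_days
  } else {
    w <- max(exposure_window_days[classes], 0, na.rm = TRUE)
  }
  as.integer(last_admin_date + max(w))
}
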