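# Independent reference implementations used to validate the package. Each
# is written as a literal, claim-by-claim / record-by-record transcription of
# the rules, deliberately structured differently from the package code.

oracle_class_map <- c(
  oxaliplatin = "CHEMO", irinotecan = "CHEMO",
  trifluridine_tipiracil = "CHEMO", fluorouracil = "FLUOROURACIL",
  capecitabine = "FLUOROURACIL", bevacizumab = "BEVACIZUMAB",
  ramucirumab = "VEGF", aflibercept = "VEGF",
  cetuximab = "EGFR", panitumumab = "EGFR", encorafenib = "BRAF",
  trastuzumab = "ERBB2", lapatinib = "ERBB2",
  trastuzumab_deruxtecan = "ERBB2", larotrectinib = "NTRK",
  pembrolizumab = "ICI", nivolumab = "ICI", ipilimumab = "ICI",
  regorafenib = "OTHER_TARGETED")

# Brute-force line-of-therapy derivation. Walks claim dates one at a time and
# re-derives every line attribute from the claims assigned so far.
lot_oracle <- function(claims, class_map = oracle_class_map,
                       gap = 90, targeted_after = 60, chemo_after = 15) {
  cls <- unname(class_map[claims$code])
  cls[is.na(cls)] <- "NON_CANCER"
  keep <- cls != "NON_CANCER"
  claims <- claims[keep, , drop = FALSE]
  cls <- cls[keep]
  if (nrow(claims) == 0) return(integer(0))
  rule60 <- c("EGFR", "BRAF", "ERBB2", "NTRK", "ICI", "OTHER_TARGETED",
              "VEGF")
  assign <- rep(NA_integer_, nrow(claims))
  line <- 0L
  for (d in sort(unique(claims$date))) {
    here <- which(claims$date == d)
    if (line == 0L) {
      line <- 1L
    } else {
      prev <- which(assign == line)
      line_start <- min(claims$date[prev])
      line_last <- max(claims$date[prev])
      seen <- unique(claims$code[prev])
      fresh <- setdiff(unique(claims$code[here]), seen)
      fresh_cls <- unname(class_map[fresh])
      fresh_cls[is.na(fresh_cls)] <- "NON_CANCER"
      starts_new <-
        (any(fresh_cls %in% rule60) && d - line_start > targeted_after) ||
        (any(fresh_cls == "CHEMO") && d - line_start > chemo_after) ||
        (d - line_last > gap)
      if (starts_new) line <- line + 1L
    }
    assign[here] <- line
  }
  assign
}

# Random claim stream generator for property tests.
random_claim_stream <- function(max_claims = 8,
                                agents = c("oxaliplatin", "irinotecan",
                                           "fluorouracil", "bevacizumab",
                                           "cetuximab")) {
  n <- sample.int(max_claims, 1)
  data.frame(patient_id = "X",
             date = sort(sample.int(260, n, replace = TRUE)) - 1L,
             kind = "pharmacy",
             code = sample(agents, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Straight-line transcription of the TTD event/censoring rule.
ttd_oracle <- function(start, est_end, last_claim, death) {
  stops <- c(est_end, last_claim, death)
  endpoint <- min(stops, na.rm = TRUE)
  if (!is.na(death) && death <= endpoint) {
    return(list(time = death - start, event = TRUE))
  }
  if (last_claim < est_end) {
    return(list(time = last_claim - start, event = FALSE))
  }
  list(time = est_end - start, event = (last_claim - est_end) >= 90)
}

os_oracle <- function(report, death, last_claim) {
  if (!is.na(death)) list(time = death - report, event = TRUE)
  else list(time = last_claim - report, event = FALSE)
}

# Hand-rolled product-limit estimator (no ties handling beyond exact dates).
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  at_risk <- length(time)
  s <- 1
  out_t <- numeric(0); out_s <- numeric(0)
  for (t in unique(time)) {
    d <- sum(time == t & event)
    n <- sum(time >= t)
    if (d > 0) {
      s <- s * (1 - d / n)
      out_t <- c(out_t, t); out_s <- c(out_s, s)
    }
  }
  list(time = out_t, surv = out_s)
}

# Two-group log-rank statistic computed directly from the O-E/V definition.
logrank_stat_oracle <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  O <- E <- V <- 0
  for (t in sort(unique(time[event]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) 0 else (O - E)^2 / V
}

# Exact permutation p-value of the two-group log-rank statistic: enumerates
# every reassignment of the group labels.
logrank_perm_oracle <- function(time, event, group) {
  obs <- logrank_stat_oracle(time, event, group)
  n <- length(time)
  n1 <- sum(group == sort(unique(group))[1])
  combs <- utils::combn(n, n1)
  stats <- apply(combs, 2, function(idx) {
    g <- rep("B", n); g[idx] <- "A"
    logrank_stat_oracle(time, event, g)
  })
  mean(stats >= obs - 1e-12)
}

# Exact two-sided Fisher p by hypergeometric enumeration (point-probability
# rule).
fisher_oracle <- function(x1, n1, x2, n2) {
  m <- x1 + x2
  ks <- max(0, m - n2):min(n1, m)
  probs <- stats::dhyper(ks, n1, n2, m)
  p_obs <- stats::dhyper(x1, n1, n2, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Breslow partial log-likelihood for a binary group covariate, maximised
# directly.
cox_loglik_oracle <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event]))) {
    d_idx <- which(time == t & event)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d_idx]) -
      length(d_idx) * log(sum(exp(beta * x[risk])))
  }
  ll
}

cox_mle_oracle <- function(time, event, x) {
  stats::optimize(function(b) -cox_loglik_oracle(b, time, event, x),
                  c(-10, 10))$minimum
}
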