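truth <- read.csv(test_path("fixtures", "classifier_truth_table.csv"),
                  stringsAsFactors = FALSE)

informed_for <- function(r, classes, detected = TRUE) {
  prof <- data.frame(detected = detected, kras_mut = r$kras,
                     nras_mut = r$nras, braf_v600e = r$braf,
                     erbb2_amp = r$erbb2, msi_high = r$msi,
                     ntrk1_fusion = r$ntrk)
  call <- classify_actionability(prof, r$side)
  classify_informed(classes, call, prof, r$side)
}

test_that("informed calls match the committed truth table for chemo, EGFR and ICI", {
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    expect_equal(informed_for(r, "CHEMO")$informed, r$informed_chemo,
                 info = paste("chemo row", i))
    expect_equal(informed_for(r, "EGFR")$informed, r$informed_egfr,
                 info = paste("egfr row", i))
    expect_equal(informed_for(r, "ICI")$informed, r$informed_ici,
                 info = paste("ici row", i))
  }
})

test_that("informed rules reproduce the canonical therapy scenarios", {
  row_of <- function(kras = FALSE, nras = FALSE, braf = FALSE, erbb2 = FALSE,
                     msi = FALSE, ntrk = FALSE, side = "LEFT") {
    data.frame(kras = kras, nras = nras, braf = braf, erbb2 = erbb2,
               msi = msi, ntrk = ntrk, side = side)
  }
  # chemo+VEGF with a RAS mutation and nothing else: informed
  expect_true(informed_for(row_of(kras = TRUE), c("CHEMO", "VEGF"))$informed)
  # chemo in right-sided RAS-wild-type: informed (no usable EGFR option)
  expect_true(informed_for(row_of(side = "RIGHT"), "CHEMO")$informed)
  # chemo in left-sided RAS-wild-type: not informed (EGFR option ignored)
  left <- informed_for(row_of(), "CHEMO")
  expect_false(left$informed)
  expect_equal(left$reason, "actionable_ignored")
  # EGFR therapy against a RAS mutation: unmatched
  egfr_ras <- informed_for(row_of(kras = TRUE), "EGFR")
  expect_false(egfr_ras$informed)
  expect_equal(unname(egfr_ras$per_class["EGFR"]), "unmatched")
  # ICI with MSI-high: matched even when the EGFR option goes unused
  ici <- informed_for(row_of(msi = TRUE), "ICI")
  expect_true(ici$informed)
  expect_true(ici$matched_targeted)
  # matched EGFR with an unused MSI-high indication: not informed
  egfr_msi <- informed_for(row_of(msi = TRUE), "EGFR")
  expect_false(egfr_msi$informed)
  expect_equal(egfr_msi$reason, "actionable_ignored")
  # undetected ctDNA: nothing is informed
  expect_false(informed_for(row_of(), "ICI", detected = FALSE)$informed)
  expect_equal(informed_for(row_of(), "CHEMO", detected = FALSE)$reason,
               "no_ctdna")
  # OTHER_TARGETED never matches
  expect_false(informed_for(row_of(kras = TRUE), "OTHER_TARGETED")$informed)
  # empty therapy set is a contract violation
  r <- row_of()
  expect_error(informed_for(r, character()), "empty")
})

test_that("outcome groups partition every profile/side/therapy combination", {
  sets <- list("CHEMO", "EGFR", "ICI", c("CHEMO", "VEGF"))
  groups <- c("ACTIONABLE_MATCHED", "ACTIONABLE_UNMATCHED", "NOT_ACTIONABLE",
              "CTDNA_NOT_DETECTED")
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    prof <- data.frame(detected = TRUE, kras_mut = r$kras, nras_mut = r$nras,
                       braf_v600e = r$braf, erbb2_amp = r$erbb2,
                       msi_high = r$msi, ntrk1_fusion = r$ntrk)
    call <- classify_actionability(prof, r$side)
    for (s in sets) {
      inf <- classify_informed(s, call, prof, r$side)
      g <- assign_outcome_group(call, inf, prof)
      expect_true(g %in% groups)
      expect_true(!inf$matched_targeted || inf$informed)  # matched => informed
      if (g == "ACTIONABLE_MATCHED") expect_true(call$actionable)
    }
  }
  # undetected always lands in its own group
  prof0 <- data.frame(detected = FALSE, kras_mut = FALSE, nras_mut = FALSE,
                      braf_v600e = FALSE, erbb2_amp = FALSE,
                      msi_high = FALSE, ntrk1_fusion = FALSE)
  call0 <- classify_actionability(prof0, "LEFT")
  inf0 <- classify_informed("CHEMO", call0, prof0, "LEFT")
  expect_equal(assign_outcome_group(call0, inf0, prof0), "CTDNA_NOT_DETECTED")
})

test_that("removing an unused actionable biomarker never un-informs a call", {
  markers <- c("braf", "erbb2", "msi", "ntrk")
  checks <- 0L
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    for (s in list("CHEMO", "EGFR", "ICI", "BRAF")) {
      base <- informed_for(r, s)
      for (mk in markers[unlist(r[markers])]) {
        mk_class <- c(braf = "BRAF", erbb2 = "ERBB2", msi = "ICI",
                      ntrk = "NTRK")[[mk]]
        if (mk_class %in% s) next  # only remove *unused* biomarkers
        r2 <- r
        r2[[mk]] <- FALSE
        # dropping an unused biomarker can only preserve or gain informed
        # status, never lose it
        if (informed_for(r2, s)$informed < base$informed) {
          fail(paste("row", i, "set", paste(s, collapse = "+"), "minus", mk))
        }
        checks <- checks + 1L
      }
    }
  }
  expect_gt(checks, 100)
})
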