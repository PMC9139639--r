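test_that("configs validate probabilities and sizes", {
  expect_error(sim_config(detection_prob = 1.2), "probabilities")
  expect_error(sim_config(sidedness_probs = c(LEFT = 0.5, RIGHT = 0.5,
                                              MIXED = 0.2, UNSPECIFIED = 0)),
               "sum to 1")
  expect_error(sim_config(n_patients = -1), "n_patients")
  expect_error(sim_config(frac_fail_test_window = 0.5,
                          frac_fail_clean_window = 0.4,
                          frac_fail_metastatic = 0.3),
               "exceed")
})

test_that("n = 0 yields empty outputs; identical seeds reproduce exactly", {
  z <- generate_cohort(sim_config(n_patients = 0), seed = 1)
  expect_equal(nrow(z$claims), 0)
  expect_equal(nrow(z$tests), 0)
  a <- generate_cohort(sim_config(n_patients = 60), seed = 17)
  b <- generate_cohort(sim_config(n_patients = 60), seed = 17)
  expect_identical(a$claims, b$claims)
  expect_identical(a$tests, b$tests)
  expect_identical(a$deaths, b$deaths)
  expect_identical(a$sides, b$sides)
  c2 <- generate_cohort(sim_config(n_patients = 60), seed = 18)
  expect_false(identical(a$claims, c2$claims))
})

test_that("undetected profiles carry no alterations; detected respect arm prevalences", {
  set.seed(4)
  cfg <- sim_config()
  flags <- c("kras_mut", "nras_mut", "braf_v600e", "erbb2_amp", "msi_high",
             "ntrk1_fusion")
  for (i in 1:200) {
    p <- generate_profile(prior_targeted = FALSE, cfg)
    if (!p$detected) expect_false(any(unlist(p[flags])))
  }
  # arm-specific KRAS rates at moderate n (loose 4-SE guard; the tight
  # calibration check runs on the full generator)
  set.seed(5)
  draw_kras <- function(arm, n) {
    mean(vapply(seq_len(n), function(i) {
      repeat {
        p <- generate_profile(arm, cfg)
        if (p$detected) return(p$kras_mut)
      }
    }, logical(1)))
  }
  n <- 1500
  for (arm in c(TRUE, FALSE)) {
    p0 <- if (arm) 0.215 else 0.458
    expect_lt(abs(draw_kras(arm, n) - p0), 4 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("BRAF/RAS exclusivity suppresses co-occurrence but keeps the marginal", {
  set.seed(6)
  cfg <- sim_config()
  n <- 4000
  draws <- do.call(rbind, lapply(seq_len(n), function(i) {
    repeat {
      p <- generate_profile(FALSE, cfg)
      if (p$detected) return(p[c("kras_mut", "nras_mut", "braf_v600e")])
    }
  }))
  ras <- draws$kras_mut | draws$nras_mut
  p_braf <- mean(draws$braf_v600e)
  expect_lt(abs(p_braf - 0.065), 4 * sqrt(0.065 * 0.935 / n))
  # co-occurrence is ~10x rarer than under independence
  expect_lt(mean(draws$braf_v600e[ras]), 0.05)
})

test_that("every generated claim stream is consumable by the line engine", {
  co <- generate_cohort(sim_config(n_patients = 80), seed = 23)
  cmap <- load_class_map()
  lines <- derive_lines_all(co$claims, cmap)
  expect_true(all(unique(co$claims$patient_id) %in% lines$patient_id))
  # line numbering is consecutive from 1 within each patient
  for (pid in unique(lines$patient_id)) {
    ln <- lines$line_number[lines$patient_id == pid]
    expect_equal(ln, seq_along(ln))
  }
  # eligible patients carry at least their intended index line
  elig <- co$truth[co$truth$planted_violation == "none", ]
  n_lines <- tapply(lines$line_number, lines$patient_id, max)
  expect_true(all(n_lines[elig$patient_id] >= elig$index_line_number))
})

test_that("MSI-era cutoff zeroes MSI calls on early tests", {
  cfg <- sim_config(n_patients = 150, msi_era_cutoff = 10000L,
                    prevalence_targeted = c(kras = 0.2, nras = 0.05,
                                            braf_v600e = 0.06,
                                            erbb2_amp = 0.02, msi_high = 0.5,
                                            ntrk1_fusion = 0),
                    prevalence_non_targeted = c(kras = 0.2, nras = 0.05,
                                                braf_v600e = 0.06,
                                                erbb2_amp = 0.02,
                                                msi_high = 0.5,
                                                ntrk1_fusion = 0))
  co <- generate_cohort(cfg, seed = 2)
  early <- co$tests$report_date < 10000L
  expect_false(any(co$tests$msi_high[early]))
})

test_that("fixture builder enforces its stratum contract", {
  spec <- data.frame(count = 3, profile = "no_ctdna", side = "LEFT",
                     therapy = "BRAF", stringsAsFactors = FALSE)
  fx <- build_fixture(spec)
  expect_equal(nrow(fx$tests), 3)
  expect_false(any(fx$tests$detected))
  expect_equal(unname(fx$therapy[[fx$tests$patient_id[1]]]), "BRAF")
  expect_error(build_fixture(spec, total = 5), "sum to")
  bad <- spec; bad$profile <- "weird"
  expect_error(build_fixture(bad), "unknown profile")
  multi <- data.frame(count = 2, profile = "ras_mut", side = "RIGHT",
                      therapy = "CHEMO+VEGF", stringsAsFactors = FALSE)
  expect_equal(unname(build_fixture(multi)$therapy[["F0001"]]),
               c("CHEMO", "VEGF"))
})
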