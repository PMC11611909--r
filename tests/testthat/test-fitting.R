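test_that("localization classification uses the 1.5 / 3.0 cutoffs", {
  expect_equal(classify_localization(10, 10), "cytosol")
  expect_equal(classify_localization(25.1, 1), "membrane")
  expect_equal(classify_localization(2, 1), "undefined")
  expect_equal(classify_localization(c(1.49, 1.5, 3, 0.1), rep(1, 4)),
               c("cytosol", "undefined", "membrane", "cytosol"))
  expect_true(is.na(classify_localization(5, 0)))
})

test_that("mixed-SE weights apply the half/half rule and the 0.06 floor", {
  obs <- data.frame(gene_id = "g", region = "exon_1",
                    compartment = c("cytosol", "cytosol"),
                    time = c(15, 60), share = c(0.1, 0.5),
                    se = c(0.02, 0.02))
  w <- compute_weights(obs)
  expect_equal(w$weight, rep(1 / 0.06, 2))          # floor binds
  obs$se <- c(0.10, 0.02)                           # comp mean = 0.06
  w <- compute_weights(obs)
  expect_equal(w$mixed_se[1], 0.5 * 0.10 + 0.5 * 0.06)
  expect_equal(w$weight[1], 1 / 0.08)
  # halving sub-floor SEs changes no weight
  obs2 <- obs; obs2$se <- c(0.02, 0.01)
  obs3 <- obs; obs3$se <- c(0.01, 0.005)
  expect_equal(compute_weights(obs2)$weight, compute_weights(obs3)$weight)
  # missing SEs are dropped with a message
  obs$se[2] <- NA
  expect_message(w2 <- compute_weights(obs), "dropped")
  expect_equal(nrow(w2), 1L)
})

test_that("ratio constraints reproduce the printed +-5 SE worked example", {
  ss <- data.frame(tpm_nuc = 100, se_nuc = 0, tpm_cyto = 24.0, se_cyto = 0,
                   tpm_mem = 200.6, se_mem = 0)
  fac <- list(a_nuc = 0.39, b_cyto = 0.15, c_mem = 0.45)
  cons <- build_ratio_constraints(ss, fac, fit_config())
  ratio <- attr(cons, "ratios")$mem$ratio
  expect_equal(round(ratio, 1), 25.1)
  # the printed bounds follow from the rounded ratio and SE 1.1
  expect_equal(round(25.1 - 5 * 1.1, 1), 19.6)
  expect_equal(round(25.1 + 5 * 1.1, 1), 30.6)
  # with SE = 0 the band degenerates to +-1e-6 relative
  expect_equal(cons$mem[1], ratio * (1 - 1e-6), tolerance = 1e-9)
  expect_equal(cons$mem[2], ratio * (1 + 1e-6), tolerance = 1e-9)
})

test_that("nonpositive lower ratio bounds are clipped with a warning", {
  ss <- data.frame(tpm_nuc = 10, se_nuc = 30, tpm_cyto = 10, se_cyto = 30,
                   tpm_mem = 10, se_mem = 30)
  fac <- list(a_nuc = 0.39, b_cyto = 0.15, c_mem = 0.45)
  w <- testthat::capture_warnings(
    cons <- build_ratio_constraints(ss, fac, fit_config()))
  expect_true(any(grepl("clipped", w)))
  expect_gt(cons$nuc[1], 0)
})

test_that("BIC formula penalizes parameters by log(n)", {
  expect_equal(compute_bic(10, 50, 5) - compute_bic(10, 50, 4), log(50))
  expect_equal(compute_bic(3, 20, 2), 3 + 2 * log(20))
  expect_error(compute_bic(1, 3, 5), "more data points")
})

test_that("QC rule (a): reduced chi-squared above 4 fails", {
  expect_true(quality_control(mock_fit(redchi = 4.5))[["chi2_fail"]])
  expect_false(quality_control(mock_fit(redchi = 3.9))[["chi2_fail"]])
})

test_that("QC rule (b): pool relative sd above 0.05 fails, zero spread passes", {
  f <- mock_fit()
  expect_false(quality_control(f)[["instability_fail"]])
  f$pool[, "k2"] <- f$pool[, "k2"] * seq(0.9, 1.1, length.out = 10)
  expect_true(quality_control(f)[["instability_fail"]])
})

test_that("QC rule (c): boundary check respects the localization class", {
  cfg <- fit_config()
  # cytosol-localized gene with cytosolic decay at the upper bound
  p <- kinetic_params(k1 = 0.05, k2 = 0.01, gamma3 = 2.0, v = 1,
                      check = FALSE)
  expect_true(quality_control(mock_fit(params = p))[["boundary_fail"]])
  # same rate pattern is ignored for the membrane-localized class
  p4 <- kinetic_params(k1 = 0.05, k2 = 0.01, k3 = 2.0, gamma4 = 0.05, v = 1,
                       check = FALSE)
  qc4 <- quality_control(mock_fit(params = p4, localization = "membrane"))
  expect_false(qc4[["boundary_fail"]])
  # membrane decay at the bound does fail for membrane-localized genes
  p4b <- kinetic_params(k1 = 0.05, k2 = 0.01, k3 = 0.5, gamma4 = 2.0, v = 1,
                        check = FALSE)
  expect_true(quality_control(mock_fit(params = p4b,
                                       localization = "membrane"))[["boundary_fail"]])
  # elongation rate at its bound is a separate flag
  pv <- kinetic_params(k1 = 0.05, k2 = 0.01, gamma3 = 0.05, v = 10,
                       check = FALSE)
  qc <- quality_control(mock_fit(params = pv))
  expect_false(qc[["boundary_fail"]])
  expect_true(qc[["v_boundary"]])
})

test_that("decay-model selection follows the BIC and SE rules", {
  null <- mock_fit(); null$bic <- 100; null$variant <- "three_step"
  null$failed <- FALSE
  ext <- mock_fit(with_decay = TRUE)
  ext$variant <- "three_step"
  ext$params$gamma2 <- 0.02
  ext$qc <- c(chi2_fail = FALSE, instability_fail = FALSE,
              boundary_fail = FALSE, v_boundary = FALSE)
  ext$param_se <- c(gamma2 = 0.01)
  ext$bic <- 88                       # dBIC = 12, SE < gamma2
  expect_true(compare_nuclear_decay_models(null, ext)$includes_nuclear_decay)
  ext$param_se <- c(gamma2 = 0.04)    # SE rule violated
  expect_false(compare_nuclear_decay_models(null, ext)$includes_nuclear_decay)
  ext$param_se <- c(gamma2 = 0.01)
  ext$bic <- 92                       # dBIC = 8 < 10
  expect_false(compare_nuclear_decay_models(null, ext)$includes_nuclear_decay)
  ext$bic <- 88
  ext$qc["chi2_fail"] <- TRUE         # failed QC never replaces the null
  dec <- compare_nuclear_decay_models(null, ext)
  expect_false(dec$includes_nuclear_decay)
  expect_match(dec$note, "QC")
})

test_that("noise-free synthetic genes are recovered accurately", {
  design <- simulation_design()
  fac <- default_factors()
  cfg <- fit_config(n_starts = 40)
  # one cytosolic intron-containing gene, one membrane gene
  g3 <- gene_model("gA", 20, exon_distances_kb = c(0.5, 8, 16),
                   has_introns = TRUE)
  p3 <- kinetic_params(k1 = 0.04, k2 = 0.009, gamma3 = 0.08, v = 1.5)
  g4 <- gene_model("gB", 25, exon_distances_kb = c(1, 12),
                   has_introns = TRUE, localization = "membrane")
  p4 <- kinetic_params(k1 = 0.03, k2 = 0.012, k3 = 0.6, gamma4 = 0.035,
                       v = 2, variant = "four_step")
  for (cse in list(list(g = g3, p = p3, var = "three_step"),
                   list(g = g4, p = p4, var = "four_step"))) {
    obs <- simulate_labeling_timeseries(cse$p, cse$g, design, noise = FALSE)
    ss <- simulate_steady_state_expression(cse$p, cse$g, design,
                                           noise = FALSE)
    cons <- build_ratio_constraints(ss, fac, cfg)
    fit <- multistart_fit(cse$g, obs, cons, cfg, cse$var,
                          localization = cse$g$localization)
    est <- coef(fit)
    tru <- coef(structure(list(params = cse$p), class = "slam_fit"))
    for (nm in setdiff(names(tru), "gamma2"))
      expect_lt(abs(est[[nm]] - tru[[nm]]) / tru[[nm]], 0.01)
    expect_lt(fit$chi2, 1e-4)
    # the 4-step constraint is honored by the returned fit
    if (cse$var == "four_step") {
      r <- est[["k3"]] / est[["gamma4"]]
      expect_gte(r, cons$mem[1] * (1 - 1e-6))
      expect_lte(r, cons$mem[2] * (1 + 1e-6))
    }
  }
})

test_that("fits are deterministic and independent of cohort composition", {
  coh <- fixture_cohort(4, seed = 21)
  fac <- default_factors()
  cfg <- fit_config(n_starts = 25)
  g <- coh$genes[[3]]
  ss <- coh$expression[3, ]
  f1 <- fit_kinetics(g, coh$labeling, ss, fac, cfg,
                     compare_nuclear_decay = FALSE)
  f2 <- fit_kinetics(g, coh$labeling, ss, fac, cfg,
                     compare_nuclear_decay = FALSE)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  # dropping other genes' rows changes nothing (per-gene seeds)
  sub <- coh$labeling[coh$labeling$gene_id == g$gene_id, ]
  f3 <- fit_kinetics(g, sub, ss, fac, cfg, compare_nuclear_decay = FALSE)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-12)
})

test_that("insufficient data is rejected with a clear error", {
  coh <- fixture_cohort(4, seed = 21)
  g <- coh$genes[[1]]
  one_time <- coh$labeling[coh$labeling$time == 15, ]
  expect_error(multistart_fit(g, one_time, list(nuc = c(1, 2), mem = NULL),
                              fit_config(n_starts = 5, n_best_pool = 5), "three_step"),
               "insufficient data")
})

test_that("slam_fit methods are coherent", {
  coh <- fixture_cohort(4, seed = 21)
  fac <- default_factors()
  fit <- fit_kinetics(coh$genes[[1]], coh$labeling, coh$expression[1, ],
                      fac, fit_config(n_starts = 25),
                      compare_nuclear_decay = FALSE)
  expect_s3_class(fit, "slam_fit")
  expect_output(print(fit), "Kinetic fit")
  expect_output(print(summary(fit)), "reduced chi2")
  expect_true(all(coef(fit) > 0 | names(coef(fit)) == "gamma2"))
  pred <- predict(fit, times = c(0, 30, 60))
  expect_true(all(pred$share >= 0 & pred$share <= 1))
  r <- residuals(fit)
  expect_equal(sum(r^2), fit$chi2, tolerance = 1e-8)
  sim <- simulate(fit, nsim = 1, seed = 2)
  expect_s3_class(sim[[1]], "labeling_observation")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
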