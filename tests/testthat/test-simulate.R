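test_that("gene generation is deterministic, valid and rejects bad input", {
  g1 <- generate_gene_models(20, seed = 1)
  g2 <- generate_gene_models(20, seed = 1)
  expect_identical(g1, g2)
  for (g in g1) {
    expect_true(all(g$exon_distances_kb <= g$gene_length_kb))
    expect_gte(length(g$exon_distances_kb), 1L)
  }
  expect_error(generate_gene_models(0), ">= 1")
})

test_that("membrane-localized fraction matches the configured proportion", {
  g <- generate_gene_models(1000, seed = 1)
  frac <- mean(vapply(g, function(x) x$localization == "membrane",
                      logical(1)))
  expect_gt(frac, 0.12)
  expect_lt(frac, 0.27)
})

test_that("sampled rates respect bounds and model variants", {
  genes <- generate_gene_models(400, seed = 5)
  pars <- sample_kinetic_params(genes, seed = 5)
  for (p in pars) {
    rts <- c(p$k1, p$k2, p$gamma3, p$k3, p$gamma4)
    rts <- rts[!is.na(rts)]
    expect_true(all(rts >= 0.001 & rts <= 2))
    expect_true(p$gamma2 == 0 || (p$gamma2 >= 1e-6 && p$gamma2 <= 2))
    if (!is.na(p$v)) expect_true(p$v >= 0.1 && p$v <= 10)
  }
  loc <- vapply(genes, `[[`, "", "localization")
  expect_true(all(vapply(pars[loc == "cytosol"], function(p)
    is.null(p$gamma4), logical(1))))
  expect_true(all(vapply(pars[loc != "cytosol"], function(p)
    !is.null(p$gamma4), logical(1))))
})

test_that("the nuclear-decay subpopulation is near 6%", {
  genes <- generate_gene_models(10000, seed = 2)
  pars <- sample_kinetic_params(genes, seed = 2)
  frac <- mean(vapply(pars, function(p) p$gamma2 > 0, logical(1)))
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.08)
})

test_that("noise-free labeling curves saturate and respect delay monotonicity", {
  design <- simulation_design()
  g <- gene_model("g", 40, exon_distances_kb = c(1, 15, 30),
                  has_introns = TRUE)
  p <- kinetic_params(k1 = 0.05, k2 = 0.01, gamma3 = 0.08, v = 1)
  obs <- simulate_labeling_timeseries(p, g, design, seed = 1, noise = FALSE)
  expect_equal(obs$se, rep(0, nrow(obs)))
  # saturation at a very late extra time point
  late <- simulation_design(times_min = c(15, 30, 1e4),
                            replicates_per_time = c(2, 2, 2))
  obs_late <- simulate_labeling_timeseries(p, g, late, noise = FALSE)
  expect_true(all(obs_late$share[obs_late$time == 1e4] > 0.999))
  # the exon nearer the 3' end labels at least as fast, everywhere
  for (cp in c("nuclear", "cytosol")) {
    for (tt in design$times_min) {
      sh <- sapply(paste0("exon_", 1:3), function(rg)
        obs$share[obs$region == rg & obs$compartment == cp & obs$time == tt])
      expect_true(all(diff(sh) <= 1e-12))
    }
  }
})

test_that("whole-cell labeling is the amount-weighted compartment mixture", {
  design <- simulation_design()
  g <- gene_model("g", 10, exon_distances_kb = 0.5, has_introns = TRUE,
                  localization = "membrane")
  p <- kinetic_params(k1 = 0.05, k2 = 0.01, k3 = 0.8, gamma4 = 0.04, v = 1,
                      variant = "four_step")
  obs <- simulate_labeling_timeseries(p, g, design, noise = FALSE)
  amounts <- steady_state_amounts(p)
  tt <- delayed_time(design$times_min, 0.5, 1, 5)
  sh <- share_new_analytic(exit_rates(p), tt)
  mix <- drop(sh %*% amounts) / sum(amounts)
  got <- obs$share[obs$region == "exon_1" & obs$compartment == "whole_cell"]
  expect_equal(got, mix, tolerance = 1e-12)
})

test_that("replicate noise yields clipped shares, positive SEs, determinism", {
  design <- simulation_design()
  g <- gene_model("g", 12, exon_distances_kb = c(0.3, 6),
                  has_introns = TRUE)
  p <- kinetic_params(k1 = 0.04, k2 = 0.01, gamma3 = 0.05, v = 1)
  o1 <- simulate_labeling_timeseries(p, g, design, seed = 9)
  o2 <- simulate_labeling_timeseries(p, g, design, seed = 9)
  expect_identical(o1, o2)
  expect_true(all(o1$share >= 0 & o1$share <= 1))
  expect_true(all(o1$n_rep >= 2))
  bad <- simulation_design()
  bad$replicates_per_time[1] <- 1L
  expect_error(simulate_labeling_timeseries(p, g, bad), "2 replicates")
})

test_that("steady-state TPM construction reproduces the parameter ratios", {
  design <- simulation_design()
  g <- gene_model("g", 15, exon_distances_kb = 1, has_introns = TRUE,
                  localization = "membrane")
  p <- kinetic_params(k1 = 0.03, k2 = 0.01, k3 = 0.6, gamma4 = 0.03, v = 1,
                      variant = "four_step")
  ss <- simulate_steady_state_expression(p, g, design, expression = 500,
                                         noise = FALSE)
  f <- design$abundance_factors
  # abundance-scaled membrane/cytosol ratio equals k3 / gamma4
  got <- (f[["membrane"]] * ss$tpm_mem) / (f[["cytosol"]] * ss$tpm_cyto)
  expect_equal(got, 0.6 / 0.03, tolerance = 1e-9)
  # whole-cell TPM is exactly the abundance-weighted sum
  expect_equal(ss$tpm_whole,
               f[["nuclear"]] * ss$tpm_nuc + f[["cytosol"]] * ss$tpm_cyto +
                 f[["membrane"]] * ss$tpm_mem,
               tolerance = 1e-9)
})

test_that("3-step genes sit below the membrane-enrichment cutoff", {
  design <- simulation_design()
  g <- gene_model("g", 15, exon_distances_kb = 1, has_introns = TRUE)
  p <- kinetic_params(k1 = 0.03, k2 = 0.01, gamma3 = 0.07, v = 1)
  ss <- simulate_steady_state_expression(p, g, design, noise = FALSE,
                                         seed = 21)
  expect_lt(ss$tpm_mem / ss$tpm_cyto, 1.5)
})

test_that("simulated cohorts are deterministic and classification-consistent", {
  c1 <- simulate_cohort(15, seed = 3)
  c2 <- simulate_cohort(15, seed = 3)
  expect_identical(c1$labeling, c2$labeling)
  expect_identical(c1$expression, c2$expression)
  loc_true <- c1$truth$localization
  loc_cls <- classify_localization(c1$expression$tpm_mem,
                                   c1$expression$tpm_cyto)
  # 3-step vs 4-step assignment survives measurement noise
  expect_true(mean((loc_true == "cytosol") == (loc_cls == "cytosol")) > 0.9)
})

test_that("inhibition chase decays from steady state and normalizes away library size", {
  g <- gene_model("g", 10, exon_distances_kb = 1, has_introns = TRUE)
  p <- kinetic_params(k1 = 0.05, k2 = 0.02, gamma3 = 0.1, v = 1)
  ts <- simulate_inhibition_timeseries(p, g, times = c(0, 30, 60, 120, 240))
  expect_true(all(ts$tpm[ts$time == 240] < ts$tpm[ts$time == 0]))
  ts2 <- simulate_inhibition_timeseries(p, g, times = c(0, 30, 60, 120, 240),
                                        library_factors = 2)
  expect_equal(ts2$tpm, 2 * ts$tpm, tolerance = 1e-12)
})
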