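test_that("closed-form shares match the numerical ODE oracle", {
  set.seed(42)
  maxerr <- 0
  for (i in 1:30) {
    r <- exp(runif(4, log(0.001), log(2)))
    tg <- sort(runif(15, 0, 400))
    maxerr <- max(maxerr, abs(share_new_analytic(r, tg) - ode_shares(r, tg)))
  }
  expect_lt(maxerr, 1e-8)
})

test_that("near-degenerate rate pairs are handled stably", {
  base <- 0.05
  for (gap in c(1e-5, 1e-7, 0)) {
    r <- c(base, base * (1 + gap), 0.4)
    tg <- c(5, 20, 80, 300)
    expect_lt(max(abs(share_new_analytic(r, tg) - ode_shares(r, tg))), 1e-8)
  }
})

test_that("shares start at zero, saturate, stay in [0,1] and keep cascade order", {
  set.seed(7)
  for (i in 1:25) {
    r <- exp(runif(4, log(0.001), log(2)))
    tg <- c(0, sort(runif(12, 0, 500)), 1e4)
    sh <- share_new_analytic(r, tg)
    expect_equal(unname(sh[1, ]), rep(0, 4))
    expect_true(all(sh >= 0 & sh <= 1))
    # saturation at very long times
    expect_true(all(sh[nrow(sh), ] > 0.99))
    # hypoexponential stochastic dominance: earlier stages label first
    expect_true(all(diff(t(sh)) <= 1e-12))
    # monotone increase in time
    expect_true(all(apply(sh, 2, function(x) all(diff(x) >= -1e-12))))
  }
})

test_that("a fast downstream stage becomes transparent", {
  r1 <- 0.02
  tg <- c(10, 50, 200)
  u1 <- share_new_analytic(r1, tg)[, 1]
  u2 <- share_new_analytic(c(r1, 500), tg)[, 2]
  expect_equal(u2, u1, tolerance = 1e-3)
})

test_that("single-stage share is the exponential CDF", {
  r <- log(2) / 22
  expect_equal(share_new_analytic(r, 22)[1, 1], 0.5,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("negative times and nonpositive rates are rejected", {
  expect_error(share_new_analytic(c(0.1), -1), "negative")
  expect_error(share_new_analytic(c(0.1, 0), 5), "positive")
})

test_that("delayed time clamps and shifts correctly", {
  expect_equal(delayed_time(15, 10, 1), 0)
  expect_equal(delayed_time(60, 10, 1), 45)
  expect_equal(delayed_time(60, 0, 3), 55)
  expect_equal(delayed_time(c(4, 5, 6), 0, 1, delta = 5), c(0, 0, 1))
  expect_error(delayed_time(10, 1, 0), "positive")
})

test_that("exit rates follow the model variant", {
  p3 <- kinetic_params(k1 = 0.03, k2 = 0.01, gamma2 = 0.03, gamma3 = 0.05,
                       v = 1)
  expect_equal(exit_rates(p3), c(0.03, 0.04, 0.05))
  p4 <- kinetic_params(k1 = 0.03, k2 = 0.01, k3 = 0.5, gamma4 = 0.02, v = 1)
  expect_equal(exit_rates(p4), c(0.03, 0.01, 0.5, 0.02))
  expect_equal(length(exit_rates(p4, drop_pre = TRUE)), 3L)
})

test_that("steady-state ratios match long-time ODE integration and scale-invariance", {
  p <- kinetic_params(k1 = 0.05, k2 = 0.008, gamma2 = 0.004, k3 = 0.9,
                      gamma4 = 0.03, v = 2)
  rt <- steady_state_ratios(p)
  expect_equal(rt$mem_over_cyto, 0.9 / 0.03, tolerance = 1e-12)
  # oracle: integrate the unscaled system with production p = 1 to steady state
  # inflows use the transition rates (k1, k2, k3), outflows the total
  # exit rates (k1, k2 + gamma2, k3, gamma4)
  inflow <- c(p$k1, p$k2, p$k3)
  outflow <- exit_rates(p)
  deriv <- function(t, y, parms)
    list(c(1, inflow * y[-4]) - outflow * y)
  ss <- deSolve::lsoda(rep(0, 4), c(0, 2e5), deriv, NULL,
                       rtol = 1e-12, atol = 1e-14)[2, -1]
  expect_equal(rt$nucmat_over_cyto, ss[2] / ss[3], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rt$nuc_total_over_cyto, (ss[1] + ss[2]) / ss[3],
               tolerance = 1e-6, ignore_attr = TRUE)
  # 3-step mature/cytosol ratio is gamma3 / k2
  p3 <- kinetic_params(k1 = 0.05, k2 = 0.02, gamma3 = 0.1, v = 1)
  expect_equal(steady_state_ratios(p3)$nucmat_over_cyto, 0.1 / 0.02)
})

test_that("predicted exon curves are pure time translations of each other", {
  g <- gene_model("g", 20, exon_distances_kb = c(0, 10), has_introns = TRUE)
  p <- kinetic_params(k1 = 0.04, k2 = 0.01, gamma3 = 0.06, v = 1, delta = 5)
  times <- seq(15, 300, by = 1)
  pr <- predict_gene_curves(g, p, times)
  near <- pr[pr$region == "exon_1" & pr$compartment == "cytosol", ]
  far <- pr[pr$region == "exon_2" & pr$compartment == "cytosol", ]
  # d = 10, v = 1: the far exon lags by exactly 10 min
  shift <- match(near$time + 10, far$time)
  ok <- !is.na(shift)
  expect_equal(far$share[shift[ok]], near$share[ok], tolerance = 1e-12)
})

test_that("full gene prediction matches the ODE oracle on the shifted time axis", {
  g <- gene_model("g", 30, exon_distances_kb = c(2, 18), has_introns = TRUE,
                  localization = "membrane")
  p <- kinetic_params(k1 = 0.03, k2 = 0.012, k3 = 0.7, gamma4 = 0.05,
                      v = 1.5, delta = 5, variant = "four_step")
  times <- c(15, 20, 30, 40, 60, 120, 180)
  pr <- predict_gene_curves(g, p, times)
  r <- exit_rates(p)
  for (i in 1:2) {
    tt <- pmax(0, times - g$exon_distances_kb[i] / p$v - p$delta)
    oracle <- ode_shares(r, pmax(tt, 1e-12))
    for (ci in c("nuclear" = 2, "cytosol" = 3, "membrane" = 4)) {
      got <- pr$share[pr$region == paste0("exon_", i) &
                      pr$compartment == names(which(c(nuclear = 2,
                        cytosol = 3, membrane = 4) == ci))]
      expect_equal(got, oracle[, ci], tolerance = 1e-8)
    }
  }
  # intronic region: stage 1 at pseudo-distance 0.1 * L
  tt <- pmax(0, times - 0.1 * 30 / p$v - p$delta)
  expect_equal(pr$share[pr$region == "intronic"],
               ode_shares(r[1], pmax(tt, 1e-12))[, 1], tolerance = 1e-8)
})

test_that("intron-less genes drop the pre-mRNA stage and elongation delay", {
  g <- gene_model("g", 8, exon_distances_kb = 1, has_introns = FALSE)
  p <- kinetic_params(k2 = 0.01, gamma3 = 0.05, delta = 5)
  pr <- predict_gene_curves(g, p, c(5, 30))
  expect_true(all(pr$share[pr$time == 5] == 0))  # clamp at t = delta
  expect_false("intronic" %in% pr$region)
  u <- share_new_analytic(c(0.01, 0.05), 25)
  expect_equal(pr$share[pr$time == 30 & pr$compartment == "nuclear"],
               u[1, 1], ignore_attr = TRUE)
  expect_equal(pr$share[pr$time == 30 & pr$compartment == "cytosol"],
               u[1, 2], ignore_attr = TRUE)
})

test_that("half-life is the log(2) inverse and handles bad input", {
  expect_equal(half_life(log(2) / 78), 78)
  expect_equal(half_life(2), 0.3466, tolerance = 1e-3)
  expect_true(is.na(half_life(0)))
  expect_true(is.na(half_life(-1)))
  x <- c(0.01, 0.1, 1)
  expect_true(all(diff(half_life(x)) < 0))
})
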