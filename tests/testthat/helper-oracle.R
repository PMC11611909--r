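# Independent numerical oracle: integrate the rescaled cascade
#   du_i/dt = r_i (u_{i-1} - u_i),  u_0 = 1,  u_i(0) = 0
# with a high-accuracy ODE solver. Used to certify the closed-form
# solutions; never calls the package's analytic path.
ode_shares <- function(rates, times, rtol = 1e-12, atol = 1e-14) {
  n <- length(rates)
  deriv <- function(t, y, p) list(rates * (c(1, y[-n]) - y))
  out <- deSolve::lsoda(y = rep(0, n), times = c(0, times), func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  m <- out[-1L, -1L, drop = FALSE]
  matrix(m, nrow = length(times), ncol = n)
}

default_factors <- function() list(a_nuc = 0.39 / 0.99, b_cyto = 0.15 / 0.99,
                                   c_mem = 0.45 / 0.99)

# small deterministic fixture cohorts, built once per test run
fixture_cohort <- local({
  cache <- list()
  function(n, seed, noise = TRUE, design = simulation_design()) {
    key <- paste(n, seed, noise, digest_design(design))
    if (is.null(cache[[key]]))
      cache[[key]] <<- simulate_cohort(n, seed = seed, design = design,
                                       noise = noise)
    cache[[key]]
  }
})

digest_design <- function(d) paste(round(unlist(d[c("noise_sd",
  "frac_membrane", "frac_nuclear_decay")]), 6), collapse = "_")

withr_like_tempdir <- function() {
  d <- tempfile("slamkin_")
  dir.create(d)
  d
}
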