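# minimal hand-built fit object for exercising the QC rules in isolation
mock_fit <- function(redchi = 1, pool = NULL, params = NULL,
                     localization = "cytosol", with_decay = FALSE,
                     cfg = fit_config()) {
  if (is.null(params))
    params <- kinetic_params(k1 = 0.05, k2 = 0.01, gamma3 = 0.06, v = 1,
                             check = FALSE)
  if (is.null(pool)) {
    nat <- c(k1 = params$k1, k2 = params$k2, gamma2 = params$gamma2,
             gamma3 = params$gamma3 %||% NA, k3 = params$k3 %||% NA,
             gamma4 = params$gamma4 %||% NA, v = params$v)
    pool <- matrix(rep(nat, each = 10), nrow = 10,
                   dimnames = list(NULL, names(nat)))
  }
  structure(list(failed = FALSE, reduced_chi2 = redchi, pool = pool,
                 params = params, localization = localization,
                 includes_nuclear_decay = with_decay, cfg = cfg),
            class = "slam_fit")
}
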