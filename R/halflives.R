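#' Model-derived pulse-chase curves
#'
#' Turns fitted transitional rates into the aggregated decay curves a
#' pulse-chase experiment would see: the share of old mRNA in each
#' compartment is one minus the share of new mRNA, and the whole-cell
#' curve is the compartment curves summed with weights proportional to the
#' abundance-scaled steady-state amounts.
#'
#' @param params a [kinetic_params] object.
#' @param times chase times (min).
#' @param weights optional nonnegative compartment weights (one per
#'   cascade stage); default: the parameters' own steady-state amounts.
#' @param include_pre include the pre-mRNA stage (intron-containing
#'   genes).
#' @return data frame with columns `compartment` (stage labels plus
#'   `whole_cell`), `time`, `share_old`.
#' @export
model_derived_pulse_chase <- function(params, times, weights = NULL,
                                      include_pre = TRUE) {
  stopifnot(inherits(params, "kinetic_params"))
  r <- exit_rates(params, drop_pre = !include_pre)
  sh <- share_new_analytic(r, times)
  w <- weights %||% unname(steady_state_amounts(params,
                                                include_pre = include_pre))
  if (length(w) != length(r)) stop("one weight per cascade stage required")
  w <- w / sum(w)
  labs <- c(if (include_pre) "nuclear_pre", "nuclear_mature", "cytosol",
            if (params$variant == "four_step") "membrane")
  old <- 1 - sh
  out <- data.frame(compartment = rep(labs, each = length(times)),
                    time = rep(times, length(labs)),
                    share_old = as.vector(old))
  rbind(out, data.frame(compartment = "whole_cell", time = times,
                        share_old = drop(old %*% w)))
}

#' Fit a single exponential decay
#'
#' Fits `y = exp(-lambda t)` (mode `"share_old"`) or
#' `y = 1 - exp(-lambda t)` (mode `"share_new"`) by least squares on the
#' rate in log space (single start; the objective is well-behaved in
#' log-lambda) and reports the rate and its half-life. Pathological
#' (non-decaying) input is not rejected; it returns a boundary rate with a
#' large residual, flagged via `poor_fit`.
#'
#' @param t,y time (min) and share observations (at least 3 points,
#'   `y` within `[0, 1]`).
#' @param mode `"share_old"` or `"share_new"`.
#' @param weights optional fit weights.
#' @return list of class `decay_fit` with `rate` (1/min), `half_life_min`,
#'   `fit_residual` (RMS), `poor_fit`.
#' @examples
#' t <- c(0, 30, 60, 120)
#' fit_exponential_decay(t, exp(-t * log(2) / 30))  # half-life 30 min
#' @export
fit_exponential_decay <- function(t, y, mode = c("share_old", "share_new"),
                                  weights = NULL) {
  mode <- match.arg(mode)
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 3L) stop("need at least 3 points")
  if (any(y < -1e-9) || any(y > 1 + 1e-9)) stop("'y' must lie within [0, 1]")
  w <- if (is.null(weights)) rep(1, length(t)) else weights[keep]
  model <- if (mode == "share_old") function(l, t) exp(-l * t)
           else function(l, t) 1 - exp(-l * t)
  resid <- function(loglam) w * (model(exp(loglam), t) - y)
  # moment start: time scale of the observed decay
  ybar <- if (mode == "share_old") y else 1 - y
  rough <- -stats::coef(stats::lm(log(pmax(ybar, 1e-6)) ~ t))[[2L]]
  start <- log(min(max(rough, 1e-4), 5))
  f <- minpack.lm::nls.lm(par = start, fn = resid,
                          lower = log(1e-5), upper = log(10),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
  lam <- exp(f$par)
  rms <- sqrt(mean(resid(f$par)^2))
  structure(list(rate = lam, half_life_min = log(2) / lam,
                 fit_residual = rms, poor_fit = rms > 0.1, mode = mode,
                 n_points = length(t)),
            class = "decay_fit")
}

#' @export
#' @method print decay_fit
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit (%s): rate %.4g /min, half-life %.4g min (RMS %.3g%s)\n",
              x$mode, x$rate, x$half_life_min, x$fit_residual,
              if (x$poor_fit) ", poor fit" else ""))
  invisible(x)
}

#' Transcription-inhibition-derived half-lives
#'
#' Aggregated (residence) half-lives from expression decay after a
#' transcription block: library sizes are normalized per sample using the
#' median ratio of long-lived reference genes to their cross-sample mean,
#' each gene's series is then normalized to its own t = 0 value, and a
#' simple exponential decay is fitted per gene and compartment. These
#' residence half-lives describe how long a transcript persists in a
#' compartment in total, as opposed to the transitional rates of the
#' kinetic model.
#'
#' @param expr_ts data frame with columns `gene_id`, `compartment`,
#'   `time`, `tpm`; the series must contain t = 0.
#' @param stable_gene_ids ids of reference genes with very long
#'   half-lives (> 14 h) used for library-size normalization.
#' @return data frame with one row per gene x compartment: `rate`,
#'   `half_life_min`, `fit_residual`, `poor_fit`.
#' @export
flavopiridol_halflives <- function(expr_ts, stable_gene_ids) {
  need <- c("gene_id", "compartment", "time", "tpm")
  stopifnot(all(need %in% names(expr_ts)), length(stable_gene_ids) >= 1L)
  stab <- expr_ts[expr_ts$gene_id %in% stable_gene_ids, , drop = FALSE]
  if (nrow(stab) == 0L) stop("no stable reference genes found in the data")
  # per-sample (compartment x time) scale factor from the stable genes
  ref <- stats::ave(stab$tpm, stab$gene_id, stab$compartment, FUN = mean)
  sample_key <- interaction(expr_ts$compartment, expr_ts$time, drop = TRUE)
  stab_key <- interaction(stab$compartment, stab$time, drop = TRUE)
  sf <- tapply(stab$tpm / ref, stab_key, stats::median)
  norm_tpm <- expr_ts$tpm / sf[as.character(sample_key)]
  out <- list()
  for (g in unique(expr_ts$gene_id)) {
    for (cp in unique(expr_ts$compartment[expr_ts$gene_id == g])) {
      i <- expr_ts$gene_id == g & expr_ts$compartment == cp
      tt <- expr_ts$time[i]; yy <- norm_tpm[i]
      if (!any(tt == 0) || sum(is.finite(yy)) < 3L) next
      y0 <- mean(yy[tt == 0])
      if (!is.finite(y0) || y0 <= 0) next
      f <- fit_exponential_decay(tt, pmin(yy / y0, 1), mode = "share_old")
      out[[paste(g, cp)]] <- data.frame(gene_id = g, compartment = cp,
                                        rate = f$rate,
                                        half_life_min = f$half_life_min,
                                        fit_residual = f$fit_residual,
                                        poor_fit = f$poor_fit)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort summary of fitted half-lives
#'
#' Medians and 10th/90th percentiles of the pre-mRNA processing, nuclear
#' retention, cytosolic and membrane half-lives across QC-passing fits,
#' plus counts per localization class and per chosen model.
#'
#' @param results list of `slam_fit` objects (or a `slam_cohort` from
#'   [fit_cohort]).
#' @param qc_pass_only summarize only fits passing the three QC rules.
#' @return list with `half_lives` (data frame of median/p10/p90 and n per
#'   parameter) and `counts` (per localization and model variant). Empty
#'   input yields empty tables.
#' @export
summarize_cohort <- function(results, qc_pass_only = TRUE) {
  if (inherits(results, "slam_cohort")) results <- results$fits
  keep <- vapply(results, function(f) {
    !isTRUE(f$failed) &&
      (!qc_pass_only || !any(f$qc[c("chi2_fail", "instability_fail",
                                    "boundary_fail")]))
  }, logical(1))
  results <- results[keep]
  if (!length(results))
    return(list(half_lives = data.frame(parameter = character(),
                                        median = numeric(), p10 = numeric(),
                                        p90 = numeric(), n = integer()),
                counts = data.frame()))
  get <- function(fn) vapply(results, fn, numeric(1))
  hl <- list(
    pre_mrna_processing = half_life(get(function(f) f$params$k1)),
    nuclear_retention =
      half_life(get(function(f) f$params$k2 + f$params$gamma2)),
    cytosolic = half_life(get(function(f)
      (f$params$gamma3 %||% f$params$k3))),
    membrane = half_life(get(function(f) f$params$gamma4 %||% NA_real_)))
  tab <- do.call(rbind, lapply(names(hl), function(nm) {
    x <- hl[[nm]][is.finite(hl[[nm]])]
    data.frame(parameter = nm,
               median = if (length(x)) stats::median(x) else NA_real_,
               p10 = if (length(x)) unname(stats::quantile(x, 0.1)) else NA_real_,
               p90 = if (length(x)) unname(stats::quantile(x, 0.9)) else NA_real_,
               n = length(x))
  }))
  loc <- vapply(results, function(f) f$localization, "")
  model <- vapply(results, function(f)
    paste0(f$variant, if (f$includes_nuclear_decay) "+decay"), "")
  list(half_lives = tab,
       counts = as.data.frame(table(localization = loc, model = model)))
}
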