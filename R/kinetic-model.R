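#' Kinetic parameters of the subcellular mRNA life cycle
#'
#' Container for the per-gene rate constants of the compartmental model of
#' the mRNA life cycle. New transcripts enter as nuclear pre-mRNA, are
#' processed to mature nuclear mRNA (rate `k1`), exported to the cytosol
#' (`k2`) or degraded in the nucleus (`gamma2`, zero by default), and are
#' then either degraded in the cytosol (`gamma3`, 3-step model of
#' cytosol-localized transcripts) or transported to the membrane compartment
#' without cytosolic decay (`k3`) and degraded there (`gamma4`, 4-step model
#' of membrane-localized and undefined transcripts). `v` is the transcript
#' elongation rate used to time-delay exon-level labeling curves and `delta`
#' a global labeling-onset delay. The pre-mRNA production rate drops out of
#' the rescaled share-of-new-mRNA system and is never fitted.
#'
#' @param k1 pre-mRNA processing rate (1/min); `NA` for intron-less genes.
#' @param k2 nuclear export rate (1/min).
#' @param gamma2 nuclear decay rate (1/min); 0 unless the extended model is
#'   selected, otherwise within `[1e-6, 2]`.
#' @param gamma3 cytosolic decay rate (1/min); 3-step model only.
#' @param k3 cytosolic transport rate to the membrane (1/min); 4-step only.
#' @param gamma4 membrane decay rate (1/min); 4-step only.
#' @param v transcript elongation rate (kb/min); `NA` when not fitted.
#' @param delta global labeling delay (min), 5 by default.
#' @param variant `"three_step"` or `"four_step"`; inferred from the
#'   supplied rates when omitted (`gamma3` implies 3-step, `k3`/`gamma4`
#'   4-step).
#' @param check if `TRUE`, warn when rates fall outside the canonical
#'   fitting bounds (`[0.001, 2]` 1/min for kinetic rates, `[0.1, 10]`
#'   kb/min for `v`).
#' @return an object of class `kinetic_params`.
#' @examples
#' kinetic_params(k1 = 0.03, k2 = 0.009, gamma3 = 0.07, v = 1.5)
#' @export
kinetic_params <- function(k1 = NA_real_, k2, gamma2 = 0, gamma3 = NULL,
                           k3 = NULL, gamma4 = NULL, v = NA_real_, delta = 5,
                           variant = NULL, check = TRUE) {
  if (is.null(variant)) {
    variant <- if (!is.null(k3) || !is.null(gamma4)) "four_step"
               else "three_step"
  }
  variant <- match.arg(variant, c("three_step", "four_step"))
  if (variant == "three_step") {
    if (is.null(gamma3)) stop("3-step model requires 'gamma3'")
    if (!is.null(k3) || !is.null(gamma4))
      stop("3-step model must not carry 'k3'/'gamma4'")
  } else {
    if (is.null(k3) || is.null(gamma4))
      stop("4-step model requires 'k3' and 'gamma4'")
    if (!is.null(gamma3)) stop("4-step model must not carry 'gamma3'")
  }
  p <- structure(list(k1 = k1, k2 = k2, gamma2 = gamma2,
                      gamma3 = gamma3, k3 = k3, gamma4 = gamma4,
                      v = v, delta = delta, variant = variant),
                 class = "kinetic_params")
  if (check) {
    rts <- c(k1 = p$k1, k2 = p$k2, gamma3 = p$gamma3, k3 = p$k3,
             gamma4 = p$gamma4)
    rts <- rts[!is.na(rts)]
    if (any(rts < 0.001 - 1e-12 | rts > 2 + 1e-12))
      warning("kinetic rate outside the canonical bounds [0.001, 2] 1/min")
    if (!(identical(gamma2, 0) || (gamma2 >= 1e-6 - 1e-18 && gamma2 <= 2 + 1e-12)))
      warning("gamma2 must be 0 or within [1e-6, 2] 1/min")
    if (!is.na(v) && (v < 0.1 - 1e-12 || v > 10 + 1e-12))
      warning("elongation rate outside [0.1, 10] kb/min")
  }
  p
}

#' @export
#' @method print kinetic_params
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters (%s model)\n",
              if (x$variant == "three_step") "3-step" else "4-step"))
  rates <- c(k1 = x$k1, k2 = x$k2, gamma2 = x$gamma2,
             gamma3 = x$gamma3 %||% NA_real_, k3 = x$k3 %||% NA_real_,
             gamma4 = x$gamma4 %||% NA_real_)
  rates <- rates[!is.na(rates)]
  for (nm in names(rates))
    cat(sprintf("  %-7s %.5g /min   (half-life %.3g min)\n",
                nm, rates[[nm]],
                if (rates[[nm]] > 0) log(2) / rates[[nm]] else Inf))
  if (!is.na(x$v)) cat(sprintf("  v       %.5g kb/min\n", x$v))
  cat(sprintf("  delta   %g min\n", x$delta))
  invisible(x)
}

#' Stage exit rates of the labeling cascade
#'
#' The rescaled share-of-new-mRNA system is a first-order cascade in which
#' stage i relaxes towards the previous stage at its total exit rate:
#' r1 = k1 (pre-mRNA processing), r2 = k2 + gamma2 (nuclear export plus
#' decay), r3 = gamma3 (3-step, cytosolic decay) or k3 (4-step, transport;
#' no cytosolic decay in the 4-step model), and r4 = gamma4 (membrane
#' decay). For intron-less genes the pre-mRNA stage is dropped and the
#' cascade starts at the mature nuclear stage.
#'
#' @param params a [kinetic_params] object.
#' @param drop_pre drop the pre-mRNA stage (intron-less genes).
#' @return named numeric vector of positive exit rates (length 2--4).
#' @export
exit_rates <- function(params, drop_pre = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  r <- c(r1 = params$k1, r2 = params$k2 + params$gamma2)
  r <- if (params$variant == "three_step") c(r, r3 = params$gamma3)
       else c(r, r3 = params$k3, r4 = params$gamma4)
  if (drop_pre) r <- r[-1L]
  if (anyNA(r)) stop("missing rates for the requested cascade")
  unname(r)
}

# CDF of a hypoexponential (sum of independent exponentials) with rates r,
# evaluated at times t >= 0. This is the closed-form solution of the
# rescaled cascade: the share of new mRNA in the last of the stages with
# exit rates r. Distinct rates use the partial-fraction form
#   F(t) = 1 - sum_j [prod_{m != j} r_m / (r_m - r_j)] exp(-r_j t);
# near-equal rates (relative gap < 1e-6 for some pair) are handled exactly
# through the matrix exponential of the bidiagonal subgenerator, which is
# the confluent limit of the partial fractions and numerically stable.
hypoexp_cdf <- function(r, t) {
  stopifnot(all(r > 0), all(t >= 0))
  n <- length(r)
  if (n == 1L) return(1 - exp(-r * t))
  gaps <- abs(outer(r, r, "-")) / outer(r, r, pmax)
  diag(gaps) <- Inf
  if (min(gaps) < 1e-6) {
    Q <- diag(-r, n)
    for (j in seq_len(n - 1L)) Q[j, j + 1L] <- r[j]
    surv <- vapply(t, function(tt) {
      sum(as.matrix(Matrix::expm(Q * tt))[1L, ])
    }, numeric(1))
    return(pmin(pmax(1 - surv, 0), 1))
  }
  co <- vapply(seq_len(n), function(j) prod(r[-j] / (r[-j] - r[j])), numeric(1))
  f <- 1 - drop(exp(-outer(t, r)) %*% co)
  pmin(pmax(f, 0), 1)
}

#' Analytic share-of-new-mRNA curves of the cascade
#'
#' Closed-form solution of the rescaled ODE cascade: the share of new mRNA
#' in stage i at time t equals the CDF of a hypoexponential waiting time
#' with the exit rates of stages 1..i. Shares start at 0, increase
#' monotonically to 1, and obey the cascade ordering
#' `u1(t) >= u2(t) >= ... ` for every t.
#'
#' @param rates positive exit rates of the cascade stages, in order (e.g.
#'   from [exit_rates]).
#' @param t nonnegative times (min). Delays are applied upstream; negative
#'   times are rejected.
#' @return a `length(t) x length(rates)` matrix; column i is the share of
#'   new mRNA in stage i.
#' @examples
#' share_new_analytic(c(0.03, 0.01, 0.07), t = c(0, 30, 120))
#' @export
share_new_analytic <- function(rates, t) {
  if (any(t < 0)) stop("negative times are not allowed; apply delays upstream")
  if (any(!is.finite(rates)) || any(rates <= 0)) stop("rates must be positive")
  out <- vapply(seq_along(rates),
                function(i) hypoexp_cdf(rates[seq_len(i)], t),
                numeric(length(t)))
  matrix(out, nrow = length(t), ncol = length(rates),
         dimnames = list(NULL, paste0("stage", seq_along(rates))))
}

#' Elongation-delayed time axis
#'
#' Sequences at distance d (kb) from the 3' end of a transcript are only
#' transcribed -- and hence labeled -- after d/v minutes; an additional
#' global delay delta (5 min by default) accounts for the lag until any
#' labeling is observed. The modified time is clamped at 0.
#'
#' @param t labeling times (min).
#' @param d_kb distance to the 3' end (kb), nonnegative.
#' @param v elongation rate (kb/min), positive.
#' @param delta global delay (min).
#' @return `pmax(0, t - d_kb / v - delta)`, recycled over inputs.
#' @examples
#' delayed_time(c(15, 60), d_kb = 10, v = 1)  # 0 and 45
#' @export
delayed_time <- function(t, d_kb, v, delta = 5) {
  if (any(v <= 0)) stop("'v' must be positive")
  if (any(d_kb < 0)) stop("'d_kb' must be nonnegative")
  pmax(0, t - d_kb / v - delta)
}

#' Predicted labeling curves for a gene
#'
#' Evaluates the model curves a fit is compared against: for
#' intron-containing genes the pooled intronic region follows the pre-mRNA
#' stage at the heuristic pseudo-distance 0.1 x gene length, and each exon
#' follows the nuclear mature, cytosolic and (4-step only) membrane stages
#' at its own elongation delay. For intron-less genes (or genes with usable
#' data in a single exon) the pre-mRNA stage is dropped, `k1` and `v` are
#' not used, and all regions share the delay `t - delta`.
#'
#' @param gene a [gene_model] object.
#' @param params a [kinetic_params] object; its variant must suit the data
#'   being predicted (4-step for membrane predictions).
#' @param times labeling times (min).
#' @return data frame with columns `region`, `compartment`, `time`, `share`.
#' @export
predict_gene_curves <- function(gene, params, times) {
  stopifnot(inherits(gene, "gene_model"), inherits(params, "kinetic_params"))
  four <- params$variant == "four_step"
  comps <- c("nuclear", "cytosol", if (four) "membrane")
  ex_d <- gene$exon_distances_kb
  ex_names <- paste0("exon_", seq_along(ex_d))
  out <- list()
  if (gene$has_introns) {
    if (is.na(params$k1) || is.na(params$v))
      stop("intron-containing genes need 'k1' and 'v'")
    r <- exit_rates(params)
    d_int <- 0.1 * gene$gene_length_kb
    tt <- delayed_time(times, d_int, params$v, params$delta)
    out[["intronic"]] <- data.frame(region = "intronic",
                                    compartment = "nuclear", time = times,
                                    share = hypoexp_cdf(r[1L], tt))
    for (i in seq_along(ex_d)) {
      tt <- delayed_time(times, ex_d[i], params$v, params$delta)
      sh <- share_new_analytic(r, tt)
      for (k in seq_along(comps))
        out[[paste(ex_names[i], comps[k])]] <-
          data.frame(region = ex_names[i], compartment = comps[k],
                     time = times, share = sh[, k + 1L])
    }
  } else {
    r <- exit_rates(params, drop_pre = TRUE)
    tt <- pmax(0, times - params$delta)
    sh <- share_new_analytic(r, tt)
    for (i in seq_along(ex_d))
      for (k in seq_along(comps))
        out[[paste(ex_names[i], comps[k])]] <-
          data.frame(region = ex_names[i], compartment = comps[k],
                     time = times, share = sh[, k])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Steady-state amounts and ratios
#'
#' Steady states of the unscaled cascade with production rate p = 1:
#' pre-mRNA `x1 = 1/k1`, nuclear mature `x2 = 1/(k2 + gamma2)`, cytosolic
#' `x3 = k2 / ((k2 + gamma2) r3)` with r3 the cytosolic exit rate, and
#' membrane `x4 = k2 / ((k2 + gamma2) gamma4)` (4-step). All ratios are
#' independent of the production rate.
#'
#' @param params a [kinetic_params] object.
#' @param include_pre include the pre-mRNA pool (set `FALSE` for
#'   intron-less genes, whose first pool is mature nuclear mRNA).
#' @return named vector of steady-state amounts (per unit production rate).
#' @export
steady_state_amounts <- function(params, include_pre = TRUE) {
  stopifnot(inherits(params, "kinetic_params"))
  r2 <- params$k2 + params$gamma2
  r3 <- if (params$variant == "three_step") params$gamma3 else params$k3
  x <- c(x1 = if (include_pre) 1 / params$k1 else NA_real_,
         x2 = 1 / r2,
         x3 = params$k2 / (r2 * r3))
  if (params$variant == "four_step")
    x <- c(x, x4 = params$k2 / (r2 * params$gamma4))
  x[!is.na(x)]
}

#' @rdname steady_state_amounts
#' @details `steady_state_ratios()` returns the expression ratios used to
#'   constrain the fit: mature-nuclear over cytosolic `r3 / k2`, total
#'   nuclear (pre + mature) over cytosolic, and (4-step) membrane over
#'   cytosolic `k3 / gamma4`.
#' @export
steady_state_ratios <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  r2 <- params$k2 + params$gamma2
  r3 <- if (params$variant == "three_step") params$gamma3 else params$k3
  out <- list(nucmat_over_cyto = r3 / params$k2,
              nuc_total_over_cyto =
                if (is.na(params$k1)) r3 / params$k2
                else (r3 / params$k2) * (1 + r2 / params$k1))
  if (params$variant == "four_step")
    out$mem_over_cyto <- params$k3 / params$gamma4
  out
}

#' Half-life of a first-order rate
#'
#' @param rate positive rate(s) (1/min).
#' @return `log(2) / rate` in minutes; `NA` for nonpositive or missing
#'   rates.
#' @examples
#' half_life(log(2) / 78)  # 78
#' @export
half_life <- function(rate) {
  out <- ifelse(is.na(rate) | rate <= 0, NA_real_, log(2) / rate)
  unname(out)
}
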