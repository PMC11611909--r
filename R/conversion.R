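#' Mutation frequency table
#'
#' Frequency a_kn of reads carrying k T>C (or, in the control orientation,
#' A>G) mismatches among n Ts, as produced by read-level mismatch counting.
#'
#' @param k mismatch counts (nonnegative integers, `k <= n`).
#' @param n T counts per read.
#' @param count number of reads with this (k, n).
#' @param orientation `"sense_T2C"` (labeling signal) or
#'   `"antisense_A2G_control"` (background error control).
#' @return data frame of class `mutation_table`.
#' @export
mutation_table <- function(k, n, count,
                           orientation = c("sense_T2C",
                                           "antisense_A2G_control")) {
  orientation <- match.arg(orientation)
  if (any(k > n)) stop("'k' must not exceed 'n'")
  if (any(k < 0) || any(n < 0) || any(count < 0))
    stop("'k', 'n' and 'count' must be nonnegative")
  out <- data.frame(k = as.integer(k), n = as.integer(n),
                    count = as.numeric(count))
  attr(out, "orientation") <- orientation
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' Pooled sequencing-error rate
#'
#' The background mismatch rate estimated from the control orientation
#' (A>G on the primary read, T>C on the secondary): total mismatches over
#' total interrogated positions.
#'
#' @param control_table a [mutation_table] from unlabeled-orientation
#'   counting.
#' @return the pooled rate `sum(k * count) / sum(n * count)` in `[0, 1]`.
#' @examples
#' estimate_error_rate(mutation_table(c(0, 1), c(10, 10), c(90, 10)))  # 0.01
#' @export
estimate_error_rate <- function(control_table) {
  stopifnot(inherits(control_table, "data.frame"),
            all(c("k", "n", "count") %in% names(control_table)))
  tot_n <- sum(control_table$n * control_table$count)
  if (nrow(control_table) == 0L || tot_n <= 0)
    stop("empty mutation table: no interrogated Ts")
  sum(control_table$k * control_table$count) / tot_n
}

#' Binomial-mixture EM fit of the conversion rate
#'
#' Fits the two-component binomial mixture
#' `P(k | n) = (1 - pi) Binom(k; n, p_e) + pi Binom(k; n, p_conv)` to a
#' mutation frequency table, with the sequencing-error rate `p_e` held
#' fixed (estimated separately from the control orientation). The E-step
#' computes the posterior probability that each read class is labeled; the
#' M-step updates the mixture weight `pi` and `p_conv` as posterior-
#' weighted mismatch rates. The log-likelihood is nondecreasing across
#' iterations; iteration stops when it changes by less than `tol`.
#'
#' @param table a [mutation_table].
#' @param p_e fixed sequencing-error rate.
#' @param init optional list with starting values `p_conv` and `pi`;
#'   defaults to `10 * p_e` (at least 1e-3) and 0.5.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap; hitting it flags `converged = FALSE`
#'   rather than raising.
#' @return list of class `conversion_estimate` with elements `p_conv`,
#'   `p_e`, `mixture_weight_new`, `log_lik`, `n_iterations`, `converged`.
#' @export
em_fit_conversion_rate <- function(table, p_e, init = NULL, tol = 1e-8,
                                   max_iter = 500L) {
  stopifnot(inherits(table, "data.frame"), nrow(table) > 0)
  k <- table$k; n <- table$n; cnt <- table$count
  p_conv <- init$p_conv %||% max(10 * p_e, 1e-3)
  pi_new <- init$pi %||% 0.5
  floor_p <- max(p_e, 1e-8)
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lb <- stats::dbinom(k, n, p_e, log = TRUE) + log1p(-pi_new)
    ln <- stats::dbinom(k, n, p_conv, log = TRUE) + log(pi_new)
    m <- pmax(lb, ln)
    lse <- m + log(exp(lb - m) + exp(ln - m))
    ll <- sum(cnt * lse)
    w <- exp(ln - lse)                      # posterior P(new | k, n)
    pi_upd <- sum(cnt * w) / sum(cnt)
    denom <- sum(cnt * w * n)
    p_upd <- if (denom > 0) sum(cnt * w * k) / denom else floor_p
    if (is.finite(loglik) && ll - loglik < tol &&
        ll - loglik > -1e-6 * max(1, abs(ll))) {
      converged <- TRUE
      break
    }
    loglik <- ll
    pi_new <- min(max(pi_upd, 0), 1)
    p_conv <- min(max(p_upd, floor_p), 1)
  }
  pinned <- p_conv <= floor_p * (1 + 1e-9)
  structure(list(p_conv = p_conv, p_e = p_e, mixture_weight_new = pi_new,
                 log_lik = ll, n_iterations = iter,
                 converged = converged && !pinned),
            class = "conversion_estimate")
}

#' @export
#' @method print conversion_estimate
print.conversion_estimate <- function(x, ...) {
  cat(sprintf(paste0("Binomial mixture fit: p_conv = %.5g, p_e = %.5g, ",
                     "pi(new) = %.3f (%d iter, %s)\n"),
              x$p_conv, x$p_e, x$mixture_weight_new, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' New-to-total mRNA ratio from T>C counts
#'
#' Converts a region's pooled T>C/T mismatch ratio into the share of new
#' mRNA. Mode `"paper"` divides the raw mismatch ratio by the conversion
#' rate; mode `"background_corrected"` (default) first subtracts the
#' sequencing-error background:
#' `((t2c / t) - p_e) / (p_conv - p_e)`. The result is clipped to
#' `[0, 1]`; `t = 0` yields `NA` (no information), never 0.
#'
#' @param t2c number of T>C mismatches in the region.
#' @param t number of interrogated Ts.
#' @param p_conv estimated conversion rate (> `p_e`).
#' @param p_e sequencing-error rate.
#' @param mode `"background_corrected"` or `"paper"`.
#' @return share of new mRNA in `[0, 1]` (or `NA`).
#' @examples
#' compute_new_total_ratio(24, 1000, p_conv = 0.024, p_e = 0, mode = "paper")
#' @export
compute_new_total_ratio <- function(t2c, t, p_conv, p_e = 0,
                                    mode = c("background_corrected",
                                             "paper")) {
  mode <- match.arg(mode)
  if (p_conv <= 0) stop("'p_conv' must be positive")
  if (mode == "background_corrected" && p_conv <= p_e)
    stop("'p_conv' must exceed 'p_e'")
  raw <- ifelse(t > 0, t2c / t, NA_real_)
  est <- switch(mode,
                paper = raw / p_conv,
                background_corrected = (raw - p_e) / (p_conv - p_e))
  pmin(pmax(est, 0), 1)
}
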