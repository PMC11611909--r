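#' Relative mRNA abundance of subcellular compartments
#'
#' Estimates how the total cellular mRNA pool is split between nucleus,
#' cytosol and membrane by fitting
#' `a * TPM_nuc + b * TPM_cyto + c * TPM_mem = TPM_whole` across highly
#' expressed genes under the constraint `a + b + c = 1` (enforced by
#' parameterizing `c = 1 - a - b`). Measurement error is present in all
#' four TPM vectors, so the fit is an errors-in-variables (total
#' least-squares) fit: each gene's residual is normalized by the standard
#' deviation it inherits from all four axes,
#' `sqrt(a^2 se_nuc^2 + b^2 se_cyto^2 + c^2 se_mem^2 + se_whole^2)`,
#' the maximum-likelihood weighting for a linear relation with known
#' per-axis error variances. When all SEs are zero the fit reduces to
#' ordinary least squares.
#'
#' @param tpm_nuc,tpm_cyto,tpm_mem,tpm_whole gene-level TPM mean vectors,
#'   aligned on gene.
#' @param se_nuc,se_cyto,se_mem,se_whole matching standard errors
#'   (default 0).
#' @param min_whole_tpm expression filter: only genes with
#'   `tpm_whole > min_whole_tpm` enter the fit (default 50).
#' @return object of class `abundance_factors`: list with `a_nuc`,
#'   `b_cyto`, `c_mem` (summing to exactly 1), their standard errors,
#'   `n_genes`, and `reduced_chi2`. Negative factors are flagged with a
#'   warning, never silently clipped.
#' @examples
#' x <- cbind(nuc = runif(100, 10, 300), cyto = runif(100, 10, 300),
#'            mem = runif(100, 10, 300))
#' whole <- x %*% c(0.39, 0.15, 0.45)
#' fit_relative_abundance(x[, 1], x[, 2], x[, 3], whole, min_whole_tpm = 0)
#' @export
fit_relative_abundance <- function(tpm_nuc, tpm_cyto, tpm_mem, tpm_whole,
                                   se_nuc = 0, se_cyto = 0, se_mem = 0,
                                   se_whole = 0, min_whole_tpm = 50) {
  n <- length(tpm_whole)
  se_nuc <- rep_len(se_nuc, n); se_cyto <- rep_len(se_cyto, n)
  se_mem <- rep_len(se_mem, n); se_whole <- rep_len(se_whole, n)
  keep <- is.finite(tpm_nuc) & is.finite(tpm_cyto) & is.finite(tpm_mem) &
    is.finite(tpm_whole) & tpm_whole > min_whole_tpm
  if (sum(keep) < 3L)
    stop("fewer than 3 genes pass the expression filter")
  xn <- tpm_nuc[keep]; xc <- tpm_cyto[keep]; xm <- tpm_mem[keep]
  y <- tpm_whole[keep]
  sn <- se_nuc[keep]; sc <- se_cyto[keep]; sm <- se_mem[keep]
  sw <- se_whole[keep]
  unweighted <- all(c(sn, sc, sm, sw) == 0)
  resid_fn <- function(p) {
    a <- p[1L]; b <- p[2L]; cc <- 1 - a - b
    num <- a * xn + b * xc + cc * xm - y
    if (unweighted) return(num)
    den <- sqrt(a^2 * sn^2 + b^2 * sc^2 + cc^2 * sm^2 + sw^2)
    num / pmax(den, .Machine$double.eps)
  }
  start <- c(a = 1 / 3, b = 1 / 3)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  a <- fit$par[[1L]]; b <- fit$par[[2L]]; cc <- 1 - a - b
  dof <- sum(keep) - 2L
  chi2 <- sum(resid_fn(fit$par)^2)
  redchi <- chi2 / dof
  cv <- tryCatch(solve(fit$hessian) * 2 * redchi,
                 error = function(e) matrix(NA_real_, 2, 2))
  se_a <- sqrt(cv[1L, 1L]); se_b <- sqrt(cv[2L, 2L])
  se_c <- sqrt(cv[1L, 1L] + cv[2L, 2L] + 2 * cv[1L, 2L])
  if (min(a, b, cc) < 0)
    warning("negative abundance factor: the compartment mixture is ",
            "ill-conditioned for these data")
  structure(list(a_nuc = a, b_cyto = b, c_mem = cc,
                 se_a = se_a, se_b = se_b, se_c = se_c,
                 n_genes = sum(keep), reduced_chi2 = redchi),
            class = "abundance_factors")
}

#' @export
#' @method print abundance_factors
print.abundance_factors <- function(x, ...) {
  cat(sprintf(paste0("Relative mRNA abundance (n = %d genes):\n",
                     "  nuclear  %.3f +- %.3g\n  cytosol  %.3f +- %.3g\n",
                     "  membrane %.3f +- %.3g\n  reduced chi2 = %.3g\n"),
              x$n_genes, x$a_nuc, x$se_a, x$b_cyto, x$se_b,
              x$c_mem, x$se_c, x$reduced_chi2))
  invisible(x)
}

#' Absolute steady-state expression ratio between compartments
#'
#' TPM values are within-fraction relative units; multiplying each by its
#' compartment's relative abundance factor puts them on a common absolute
#' scale, so `(factor_x * tpm_x) / (factor_y * tpm_y)` is the absolute
#' expression ratio between two compartments. The SE comes from
#' first-order (delta-method) propagation of the TPM standard errors; the
#' abundance factors are treated as fixed.
#'
#' @param tpm_x,tpm_y compartment TPM means.
#' @param factor_x,factor_y their relative abundance factors.
#' @param se_x,se_y TPM standard errors (default 0).
#' @return list with `ratio` and `se` (`NA` ratio when the denominator is
#'   zero).
#' @examples
#' absolute_ratio(200.6, 24.0, 0.45, 0.15)  # ratio 25.1
#' @export
absolute_ratio <- function(tpm_x, tpm_y, factor_x, factor_y,
                           se_x = 0, se_y = 0) {
  bad <- tpm_y <= 0 | factor_y <= 0
  ratio <- ifelse(bad, NA_real_, (factor_x * tpm_x) / (factor_y * tpm_y))
  se <- ifelse(bad | tpm_x <= 0, NA_real_,
               abs(ratio) * sqrt((se_x / tpm_x)^2 + (se_y / tpm_y)^2))
  list(ratio = ratio, se = se)
}
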