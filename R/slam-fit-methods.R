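#' @export
#' @method print slam_fit
print.slam_fit <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("Kinetic fit for %s: FAILED (no start converged)\n",
                x$gene_id))
    return(invisible(x))
  }
  cat(sprintf("Kinetic fit for %s (%s model%s, %s-localized%s)\n",
              x$gene_id,
              if (x$variant == "three_step") "3-step" else "4-step",
              if (x$includes_nuclear_decay) " + nuclear decay" else "",
              x$localization,
              if (x$reduced) ", reduced cascade" else ""))
  cat(sprintf("  chi2 = %.3g on %d points, reduced chi2 = %.3g, BIC = %.4g\n",
              x$chi2, x$n_points, x$reduced_chi2, x$bic))
  qc <- x$qc[c("chi2_fail", "instability_fail", "boundary_fail")]
  cat(sprintf("  QC: %s\n",
              if (any(qc)) paste(names(qc)[qc], collapse = ", ") else "pass"))
  print(x$params)
  invisible(x)
}

#' @export
#' @method summary slam_fit
summary.slam_fit <- function(object, ...) {
  x <- object
  if (isTRUE(x$failed)) return(print(x))
  est <- coef(x)
  se <- x$param_se[names(est)]
  tab <- data.frame(estimate = est, se = se,
                    rel_se = se / est,
                    half_life_min = half_life(est))
  tab["v", "half_life_min"] <- NA_real_
  out <- list(gene_id = x$gene_id, table = tab[!is.na(est), ],
              chi2 = x$chi2, reduced_chi2 = x$reduced_chi2, bic = x$bic,
              qc = x$qc, variant = x$variant,
              includes_nuclear_decay = x$includes_nuclear_decay,
              boundary_distance = x$boundary_distance)
  class(out) <- "summary.slam_fit"
  out
}

#' @export
#' @method print summary.slam_fit
print.summary.slam_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Kinetic fit summary for %s (%s)\n", x$gene_id, x$variant))
  print(signif(as.matrix(x$table), digits))
  cat(sprintf("chi2 %.4g | reduced chi2 %.4g | BIC %.5g | QC %s\n",
              x$chi2, x$reduced_chi2, x$bic,
              if (any(x$qc[1:3])) "FAIL" else "pass"))
  invisible(x)
}

#' @export
coef.slam_fit <- function(object, ...) {
  p <- object$params
  est <- c(k1 = p$k1, k2 = p$k2, gamma2 = p$gamma2,
           gamma3 = p$gamma3 %||% NA_real_, k3 = p$k3 %||% NA_real_,
           gamma4 = p$gamma4 %||% NA_real_, v = p$v)
  est[!is.na(est)]
}

#' Predicted labeling curves of a fitted gene model
#'
#' @param object a `slam_fit`.
#' @param times labeling times (min); defaults to a fine grid over the
#'   fitted range.
#' @param ... unused.
#' @return data frame of predicted shares per region, compartment, time.
#' @export
predict.slam_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    tmax <- max(object$data$time)
    times <- seq(0, tmax, length.out = 60L)
  }
  gene <- object$gene
  if (object$reduced && gene$has_introns) {
    gene$has_introns <- FALSE  # fitted on the reduced cascade
  }
  predict_gene_curves(gene, object$params, times)
}

#' @export
residuals.slam_fit <- function(object, weighted = TRUE, ...) {
  obs <- object$data
  pred <- predict.slam_fit(object, times = unique(obs$time))
  key <- function(d) paste(d$region, d$compartment, d$time)
  r <- obs$share - pred$share[match(key(obs), key(pred))]
  if (weighted) r * obs$weight else r
}

#' Plot a fitted labeling time course
#'
#' Shows the measured share of new mRNA (points with replicate SE bars)
#' and the fitted model curves, one panel per fitted compartment; exon
#' curves are drawn individually so the elongation delay is visible.
#'
#' @param x a `slam_fit`.
#' @param ... passed to `plot`.
#' @export
plot.slam_fit <- function(x, ...) {
  obs <- x$data
  comps <- unique(obs$compartment)
  pred <- predict.slam_fit(x)
  old <- graphics::par(mfrow = c(1, length(comps)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cp in comps) {
    o <- obs[obs$compartment == cp, ]
    p <- pred[pred$compartment == cp, ]
    graphics::plot(NA, xlim = range(0, o$time), ylim = c(0, 1),
                   xlab = "labeling time (min)", ylab = "share new mRNA",
                   main = paste(x$gene_id, cp), ...)
    for (rg in unique(p$region)) {
      pr <- p[p$region == rg, ]
      graphics::lines(pr$time, pr$share,
                      col = grDevices::adjustcolor("steelblue", 0.8))
    }
    suppressWarnings(  # zero-length bars for noise-free SEs
      graphics::arrows(o$time, pmax(0, o$share - o$se), o$time,
                       pmin(1, o$share + o$se), angle = 90, code = 3,
                       length = 0.02, col = "grey40"))
    graphics::points(o$time, o$share, pch = 19, cex = 0.6)
  }
  invisible(x)
}

#' Simulate replicate labeling data from a fitted model
#'
#' Draws new synthetic labeling observations from the fitted parameters
#' under the given design, e.g. for parametric-bootstrap checks.
#'
#' @param object a `slam_fit`.
#' @param nsim number of simulated data sets.
#' @param seed integer seed.
#' @param design a [simulation_design].
#' @param ... unused.
#' @return a list of `labeling_observation` data frames (length `nsim`).
#' @export
simulate.slam_fit <- function(object, nsim = 1, seed = 1L,
                              design = simulation_design(), ...) {
  gene <- object$gene
  if (object$reduced && gene$has_introns) gene$has_introns <- FALSE
  lapply(seq_len(nsim), function(i)
    simulate_labeling_timeseries(object$params, gene, design,
                                 seed = as.integer(seed) + i - 1L))
}
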