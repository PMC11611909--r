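#' Static gene structure
#'
#' @param gene_id gene identifier.
#' @param gene_length_kb gene length in kb (positive).
#' @param exon_distances_kb mean distance of each exon to the 3' end (kb);
#'   nonempty, all within the gene length.
#' @param has_introns whether intronic (pre-mRNA) labeling data exist; the
#'   pooled intronic region is modeled at the heuristic pseudo-distance
#'   0.1 x gene length.
#' @param localization `"cytosol"`, `"undefined"` or `"membrane"`; decides
#'   the 3-step vs 4-step model.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, gene_length_kb, exon_distances_kb,
                       has_introns = TRUE,
                       localization = c("cytosol", "undefined", "membrane")) {
  localization <- match.arg(localization)
  stop_if_not_scalar_num(gene_length_kb, "gene_length_kb")
  if (gene_length_kb <= 0) stop("'gene_length_kb' must be positive")
  if (length(exon_distances_kb) < 1L) stop("at least one exon is required")
  if (any(exon_distances_kb < 0) ||
      any(exon_distances_kb > gene_length_kb + 1e-9))
    stop("exon distances must lie within [0, gene_length_kb]")
  structure(list(gene_id = as.character(gene_id),
                 gene_length_kb = gene_length_kb,
                 exon_distances_kb = as.numeric(exon_distances_kb),
                 has_introns = isTRUE(has_introns),
                 localization = localization),
            class = "gene_model")
}

#' @export
#' @method print gene_model
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene %s: %.1f kb, %d exon(s), %s, %s-localized\n",
              x$gene_id, x$gene_length_kb, length(x$exon_distances_kb),
              if (x$has_introns) "intron-containing" else "intron-less",
              x$localization))
  invisible(x)
}

#' Design of a synthetic labeling experiment
#'
#' Defaults emulate the study design the package targets: 4sU labeling for
#' 15, 20, 30, 40, 60, 120 and 180 min with 2--4 biological replicates per
#' time point, three subcellular fractions plus a whole-cell extract,
#' relative compartment mRNA abundances (0.39, 0.15, 0.45) for nucleus,
#' cytosol and membrane, Gaussian replicate noise on the share scale around
#' the 0.06 standard-error floor, a 5 min global labeling delay, and about
#' 20% membrane-localized and 6% nuclear-decaying transcripts.
#'
#' @param times_min labeling times (min), strictly increasing.
#' @param replicates_per_time integer replicates per time, each in 2--4.
#' @param noise_sd typical replicate noise sd on the share scale.
#' @param noise_sd_spread lognormal spread of the per-region noise sd.
#' @param tpm_noise_cv multiplicative (lognormal) noise CV of replicate
#'   TPM values.
#' @param abundance_factors nonnegative nuclear/cytosolic/membrane relative
#'   abundances summing to 1.
#' @param frac_membrane,frac_undefined localization class proportions.
#' @param frac_nuclear_decay fraction of genes with nonzero nuclear decay.
#' @param frac_intronless fraction of genes without usable intron data.
#' @param expression_meanlog,expression_sdlog lognormal gene expression
#'   magnitudes (arbitrary TPM-like units), chosen to straddle the
#'   TPM >= 1.5 expressed-gene filter and the TPM > 50 abundance filter.
#' @param delta global labeling delay (min).
#' @param conversion_ramp optional linear ramp of labeling efficiency over
#'   time (fraction per min); off by default.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(times_min = c(15, 20, 30, 40, 60, 120, 180),
                              replicates_per_time = c(2, 4, 2, 2, 4, 2, 2),
                              noise_sd = 0.06,
                              noise_sd_spread = 0.25,
                              tpm_noise_cv = 0.1,
                              abundance_factors = c(nuclear = 0.39,
                                                    cytosol = 0.15,
                                                    membrane = 0.45) / 0.99,
                              frac_membrane = 0.20,
                              frac_undefined = 0.05,
                              frac_nuclear_decay = 0.06,
                              frac_intronless = 0.13,
                              expression_meanlog = log(30),
                              expression_sdlog = 1.3,
                              delta = 5,
                              conversion_ramp = 0) {
  if (any(diff(times_min) <= 0)) stop("'times_min' must be strictly increasing")
  if (any(times_min <= 0)) stop("'times_min' must be positive")
  replicates_per_time <- rep_len(as.integer(replicates_per_time),
                                 length(times_min))
  if (any(replicates_per_time < 2L) || any(replicates_per_time > 4L))
    stop("replicates per time must be within [2, 4]")
  if (length(abundance_factors) != 3L || any(abundance_factors < 0))
    stop("'abundance_factors' must be three nonnegative values")
  if (abs(sum(abundance_factors) - 1) > 1e-12)
    stop("'abundance_factors' must sum to 1 (within 1e-12)")
  structure(list(times_min = as.numeric(times_min),
                 replicates_per_time = replicates_per_time,
                 noise_sd = noise_sd, noise_sd_spread = noise_sd_spread,
                 tpm_noise_cv = tpm_noise_cv,
                 abundance_factors = abundance_factors,
                 frac_membrane = frac_membrane,
                 frac_undefined = frac_undefined,
                 frac_nuclear_decay = frac_nuclear_decay,
                 frac_intronless = frac_intronless,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 delta = delta, conversion_ramp = conversion_ramp),
            class = "simulation_design")
}

#' Generate synthetic gene structures
#'
#' Gene lengths are lognormal (spanning below 12 kb to beyond 30 kb), exon
#' counts 1--20 with one near-3' exon always present, and the localization
#' class is drawn with the design's membrane/undefined proportions.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @param design a [simulation_design].
#' @return list of [gene_model] objects.
#' @export
generate_gene_models <- function(n_genes, seed = 1L,
                                 design = simulation_design()) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("'n_genes' must be >= 1")
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    len <- pmin(pmax(stats::rlnorm(n_genes, log(18), 0.8), 0.5), 200)
    intronless <- stats::runif(n_genes) < design$frac_intronless
    n_ex <- ifelse(intronless, 1L, pmin(2L + stats::rpois(n_genes, 3), 20L))
    loc <- sample(c("membrane", "undefined", "cytosol"), n_genes,
                  replace = TRUE,
                  prob = c(design$frac_membrane, design$frac_undefined,
                           1 - design$frac_membrane - design$frac_undefined))
    lapply(seq_len(n_genes), function(i) {
      d <- sort(stats::runif(n_ex[i], 0, 0.95 * len[i]))
      d[1L] <- stats::runif(1, 0, 0.05 * len[i])  # 3'-terminal exon
      gene_model(gene_id = sprintf("G%05d", i), gene_length_kb = len[i],
                 exon_distances_kb = d, has_introns = !intronless[i],
                 localization = loc[i])
    })
  })
}

#' Sample ground-truth kinetic parameters for synthetic genes
#'
#' Rates are drawn log-uniformly within half-life ranges matching the
#' observed spans of the study system (pre-mRNA processing ~8--60 min,
#' nuclear retention ~20--250 min, cytosolic stability ~2--60 min, membrane
#' stability ~6--80 min), all within the canonical fitting bounds
#' `[0.001, 2]` 1/min; elongation rates are log-uniform in 0.5--5 kb/min.
#' Membrane-localized genes receive a 4-step parameter set with
#' `k3 / gamma4` between 10 and 60 (membrane enrichment above the 3.0
#' cutoff), undefined genes between 4.6 and 8.9 (between the cutoffs), and
#' cytosol-localized genes a 3-step set. A `frac_nuclear_decay` subset gets
#' nonzero nuclear decay with `gamma2 / k2` between 1 and 5.
#'
#' @param genes list of [gene_model] objects.
#' @param seed integer seed.
#' @param design a [simulation_design].
#' @return named list mapping gene id to [kinetic_params].
#' @export
sample_kinetic_params <- function(genes, seed = 1L,
                                  design = simulation_design()) {
  if (length(genes) < 1L) stop("'genes' must be nonempty")
  with_seed(seed, {
    out <- lapply(genes, function(g) {
      k1 <- if (g$has_introns) log(2) / log_unif(1, 8, 60) else NA_real_
      k2 <- log(2) / log_unif(1, 20, 250)
      gamma2 <- if (stats::runif(1) < design$frac_nuclear_decay)
        min(k2 * log_unif(1, 1, 5), 2) else 0
      v <- if (g$has_introns) log_unif(1, 0.5, 5) else NA_real_
      if (g$localization == "cytosol") {
        kinetic_params(k1 = k1, k2 = k2, gamma2 = gamma2,
                       gamma3 = log(2) / log_unif(1, 2, 60),
                       v = v, delta = design$delta, variant = "three_step")
      } else {
        rho <- if (g$localization == "membrane") log_unif(1, 10, 60)
               else log_unif(1, 4.6, 8.9)
        gamma4 <- log(2) / log_unif(1, 6, 80)
        k3 <- rho * gamma4
        if (k3 > 2) { k3 <- 2 * 0.999; gamma4 <- k3 / rho }
        kinetic_params(k1 = k1, k2 = k2, gamma2 = gamma2, k3 = k3,
                       gamma4 = gamma4, v = v, delta = design$delta,
                       variant = "four_step")
      }
    })
    names(out) <- vapply(genes, `[[`, "", "gene_id")
    out
  })
}

# Stage weights (absolute steady-state amounts) behind each observable
# region x compartment; used to mix compartment shares into whole-cell
# shares. For exons every stage the transcript passes through contributes
# (pre-mRNA contains exonic sequence too); the intronic region is pre-mRNA
# only.
.wholecell_share <- function(gene, params, times) {
  amounts <- steady_state_amounts(params, include_pre = gene$has_introns)
  if (gene$has_introns) {
    r <- exit_rates(params)
    delays <- function(d) delayed_time(times, d, params$v, params$delta)
  } else {
    r <- exit_rates(params, drop_pre = TRUE)
    delays <- function(d) pmax(0, times - params$delta)
  }
  function(d_kb) {
    sh <- share_new_analytic(r, delays(d_kb))
    drop(sh %*% amounts) / sum(amounts)
  }
}

#' Simulate a noisy labeling time series for one gene
#'
#' Per region (pooled intronic region and each exon), compartment and time
#' point, the true share of new mRNA is evaluated from the closed-form
#' cascade solutions at the elongation-delayed time; replicate values add
#' Gaussian noise on the share scale (sd drawn per region x compartment
#' around `design$noise_sd`) and are clipped to `[0, 1]`. Whole-cell
#' observations mix the compartment shares weighted by the gene's absolute
#' steady-state amounts. Means and standard errors are computed across
#' replicates. For cytosol-localized (3-step) genes the membrane fraction
#' reports the cytosolic share (background contamination of the membrane
#' fraction by cytosolic mRNA).
#'
#' @param params a [kinetic_params] object.
#' @param gene a [gene_model] object.
#' @param design a [simulation_design].
#' @param seed integer seed.
#' @param noise if `FALSE`, replicate values equal the true shares.
#' @return data frame of class `labeling_observation` with columns
#'   `gene_id`, `region`, `compartment`, `time`, `share`, `se`, `n_rep`.
#' @export
simulate_labeling_timeseries <- function(params, gene,
                                         design = simulation_design(),
                                         seed = 1L, noise = TRUE) {
  stopifnot(inherits(params, "kinetic_params"), inherits(gene, "gene_model"))
  if (any(design$replicates_per_time < 2L))
    stop("at least 2 replicates per time point are required")
  times <- design$times_min
  truth <- predict_gene_curves(gene, params, times)
  if (params$variant == "three_step") {
    mem <- truth[truth$compartment == "cytosol" &
                 truth$region != "intronic", , drop = FALSE]
    if (nrow(mem)) {
      mem$compartment <- "membrane"
      truth <- rbind(truth, mem)
    }
  }
  wc <- .wholecell_share(gene, params, times)
  regions <- unique(truth$region)
  wc_rows <- do.call(rbind, lapply(regions, function(rg) {
    d <- if (rg == "intronic") 0.1 * gene$gene_length_kb
         else gene$exon_distances_kb[as.integer(sub("exon_", "", rg))]
    share <- if (rg == "intronic") {
      r1 <- if (gene$has_introns) exit_rates(params)[1L] else NULL
      hypoexp_cdf(r1, delayed_time(times, d, params$v, params$delta))
    } else wc(d)
    data.frame(region = rg, compartment = "whole_cell", time = times,
               share = share)
  }))
  truth <- rbind(truth, wc_rows)
  if (design$conversion_ramp > 0) {
    eff <- pmin(1, design$conversion_ramp * truth$time)
    truth$share <- truth$share * eff
  }
  nrep <- design$replicates_per_time[match(truth$time, times)]
  with_seed(seed, {
    key <- interaction(truth$region, truth$compartment, drop = TRUE)
    sd_rc <- stats::setNames(
      design$noise_sd * exp(stats::rnorm(nlevels(key), 0,
                                         design$noise_sd_spread)),
      levels(key))
    stats_ <- t(mapply(function(mu, n, sdv) {
      vals <- if (noise) pmin(pmax(mu + stats::rnorm(n, 0, sdv), 0), 1)
              else rep(mu, n)
      c(mean(vals), stats::sd(vals) / sqrt(n))
    }, truth$share, nrep, sd_rc[as.character(key)]))
    out <- data.frame(gene_id = gene$gene_id, region = truth$region,
                      compartment = truth$compartment, time = truth$time,
                      share = stats_[, 1L], se = stats_[, 2L], n_rep = nrep)
    class(out) <- c("labeling_observation", "data.frame")
    out
  })
}

#' Simulate steady-state expression for one gene
#'
#' Per-compartment TPM values are proportional to the analytic steady
#' states (nuclear = pre + mature, cytosolic, membrane), divided by the
#' compartment's relative abundance factor so that, before noise, the
#' whole-cell TPM equals exactly the abundance-weighted sum
#' `a * nuc + b * cyto + c * mem`. Cytosol-localized genes carry a small
#' background membrane amount (below the 1.5 enrichment cutoff).
#' Multiplicative lognormal noise with CV `design$tpm_noise_cv` is applied
#' per replicate; means and standard errors are returned.
#'
#' @inheritParams simulate_labeling_timeseries
#' @param expression gene expression magnitude (TPM-like scale of the
#'   whole-cell amount); drawn upstream in [simulate_cohort].
#' @param n_rep replicates used for the mean/SE.
#' @return one-row data frame with TPM means and SEs per compartment and
#'   whole cell, plus the true amounts.
#' @export
simulate_steady_state_expression <- function(params, gene,
                                             design = simulation_design(),
                                             expression = 100, seed = 1L,
                                             noise = TRUE, n_rep = 4L) {
  stopifnot(inherits(params, "kinetic_params"), inherits(gene, "gene_model"))
  x <- steady_state_amounts(params, include_pre = gene$has_introns)
  a_nuc <- sum(x[names(x) %in% c("x1", "x2")])
  a_cyt <- x[["x3"]]
  a_mem <- if (params$variant == "four_step") x[["x4"]] else NA_real_
  with_seed(seed, {
    if (params$variant == "three_step")
      a_mem <- a_cyt * log_unif(1, 0.5, 3)  # fraction background
    tot <- a_nuc + a_cyt + a_mem
    scale <- expression / tot
    A <- c(nuclear = a_nuc, cytosol = a_cyt, membrane = a_mem) * scale
    f <- design$abundance_factors
    mu <- c(A / f, whole_cell = sum(A))
    obs <- vapply(mu, function(m) {
      vals <- if (noise)
        m * stats::rlnorm(n_rep, -design$tpm_noise_cv^2 / 2,
                          design$tpm_noise_cv)
      else rep(m, n_rep)
      c(mean(vals), stats::sd(vals) / sqrt(n_rep))
    }, numeric(2))
    data.frame(gene_id = gene$gene_id,
               tpm_nuc = obs[1, 1], se_nuc = obs[2, 1],
               tpm_cyto = obs[1, 2], se_cyto = obs[2, 2],
               tpm_mem = obs[1, 3], se_mem = obs[2, 3],
               tpm_whole = obs[1, 4], se_whole = obs[2, 4],
               amount_nuc = A[[1]], amount_cyto = A[[2]],
               amount_mem = A[[3]])
  })
}

#' Simulate a T>C mutation frequency table
#'
#' Each read covers a Poisson-distributed number of Ts (around
#' `mean_t_per_read`); with probability `share_new` the read derives from a
#' labeled (new) transcript and its per-T mismatch rate is `p_conv`,
#' otherwise the background sequencing-error rate `p_e`. Returns the
#' frequency table of k mismatches among reads with n Ts.
#'
#' @param share_new fraction of new transcripts in `[0, 1]`.
#' @param p_conv per-T conversion rate of labeled reads; must exceed `p_e`.
#' @param p_e background sequencing-error rate.
#' @param n_reads number of reads.
#' @param mean_t_per_read mean T count per read (75 bp paired-end reads
#'   carry about 40 Ts).
#' @param seed integer seed.
#' @return data frame of class `mutation_table` with columns `k`, `n`,
#'   `count`.
#' @export
simulate_conversion_counts <- function(share_new, p_conv, p_e = 0.001,
                                       n_reads = 1e5, mean_t_per_read = 40,
                                       seed = 1L) {
  stopifnot(share_new >= 0, share_new <= 1, n_reads >= 1)
  if (p_e < 0 || p_conv > 1 || p_conv <= p_e)
    stop("need 0 <= p_e < p_conv <= 1 (mixture is unidentifiable otherwise)")
  with_seed(seed, {
    n <- stats::rpois(n_reads, mean_t_per_read)
    new <- stats::runif(n_reads) < share_new
    k <- stats::rbinom(n_reads, n, ifelse(new, p_conv, p_e))
    tab <- stats::aggregate(list(count = rep(1L, n_reads)),
                            by = list(k = k, n = n), FUN = sum)
    tab <- tab[order(tab$n, tab$k), ]
    rownames(tab) <- NULL
    class(tab) <- c("mutation_table", "data.frame")
    tab
  })
}

#' Simulate transcription-inhibition (chase) expression decay
#'
#' Integrates the unscaled cascade with production switched off from its
#' steady state, mimicking expression decay after a transcription block,
#' and returns compartment expression over time on the TPM scale of
#' [simulate_steady_state_expression]. Used to exercise the
#' inhibition-derived half-life fits.
#'
#' @inheritParams simulate_steady_state_expression
#' @param times chase times (min), starting at 0.
#' @param library_factors optional per-time multiplicative library-size
#'   distortions (recycled), to exercise normalization.
#' @return data frame with columns `gene_id`, `compartment`, `time`, `tpm`.
#' @export
simulate_inhibition_timeseries <- function(params, gene, times,
                                           design = simulation_design(),
                                           expression = 100,
                                           library_factors = 1) {
  stopifnot(inherits(params, "kinetic_params"), times[1] == 0)
  pre <- gene$has_introns
  x0 <- steady_state_amounts(params, include_pre = pre)
  r <- exit_rates(params, drop_pre = !pre)
  n <- length(r)
  deriv <- function(t, y, parms) {
    inflow <- c(0, r[-n] * y[-n])
    list(inflow - r * y)
  }
  sol <- deSolve::lsoda(y = unname(x0), times = times, func = deriv,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  amt <- sol[, -1L, drop = FALSE]
  # collapse to observable compartments
  if (pre) {
    nuc <- amt[, 1L] + amt[, 2L]
    cyt <- amt[, 3L]
    mem <- if (n == 4L) amt[, 4L] else cyt * 0.1
  } else {
    nuc <- amt[, 1L]
    cyt <- amt[, 2L]
    mem <- if (n == 3L) amt[, 3L] else cyt * 0.1
  }
  f <- design$abundance_factors
  scale <- expression / sum(x0)  # arbitrary TPM-like scale
  lf <- rep_len(library_factors, length(times))
  data.frame(gene_id = gene$gene_id,
             compartment = rep(c("nuclear", "cytosol", "membrane"),
                               each = length(times)),
             time = rep(times, 3L),
             tpm = c(nuc / f[1L], cyt / f[2L], mem / f[3L]) * scale *
               rep(lf, 3L))
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper tying the generator together: gene structures,
#' ground-truth kinetic parameters, steady-state expression and labeling
#' time series for `n_genes` genes, with per-gene seeds derived from the
#' master seed and the gene id so that results do not depend on cohort
#' composition.
#'
#' @param n_genes number of genes.
#' @param seed master integer seed.
#' @param design a [simulation_design].
#' @param noise simulate replicate noise (default `TRUE`).
#' @return list with elements `genes`, `params`, `labeling`, `expression`,
#'   `truth` (data frame of true rates) and `design`.
#' @export
simulate_cohort <- function(n_genes, seed = 1L, design = simulation_design(),
                            noise = TRUE) {
  genes <- generate_gene_models(n_genes, seed = seed, design = design)
  params <- sample_kinetic_params(genes, seed = seed + 1L, design = design)
  expression <- with_seed(seed + 2L,
    stats::rlnorm(n_genes, design$expression_meanlog, design$expression_sdlog))
  labeling <- vector("list", n_genes)
  expr <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    g <- genes[[i]]
    s <- gene_seed(seed, g$gene_id)
    labeling[[i]] <- simulate_labeling_timeseries(params[[i]], g, design,
                                                  seed = s, noise = noise)
    expr[[i]] <- simulate_steady_state_expression(params[[i]], g, design,
                                                  expression = expression[i],
                                                  seed = s + 1L,
                                                  noise = noise)
  }
  truth <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    p <- params[[i]]
    data.frame(gene_id = genes[[i]]$gene_id, variant = p$variant,
               localization = genes[[i]]$localization,
               has_introns = genes[[i]]$has_introns,
               k1 = p$k1, k2 = p$k2, gamma2 = p$gamma2,
               gamma3 = p$gamma3 %||% NA_real_, k3 = p$k3 %||% NA_real_,
               gamma4 = p$gamma4 %||% NA_real_, v = p$v)
  }))
  labeling <- do.call(rbind, labeling)
  class(labeling) <- c("labeling_observation", "data.frame")
  list(genes = genes, params = params, labeling = labeling,
       expression = do.call(rbind, expr), truth = truth, design = design)
}
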