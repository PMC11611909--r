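# Tabular interchange: TSV with header, UTF-8, '.' decimal. Exon distances
# are precomputed kb values; no genomic coordinates cross this boundary.

#' Read and write pipeline tables
#'
#' The pipeline exchanges plain TSV tables: the labeling table (`gene_id`,
#' `region`, `compartment`, `time`, `share`, `se`, `n_rep`), the TPM table
#' (`gene_id`, `tpm_nuc`, `se_nuc`, `tpm_cyto`, `se_cyto`, `tpm_mem`,
#' `se_mem`, `tpm_whole`, `se_whole`), and the gene annotation table
#' (`gene_id`, `gene_length_kb`, `exon_distances_kb` as a comma-separated
#' list, `has_introns`).
#'
#' @param path file path.
#' @param x data frame to write.
#' @return the data frame (readers) or `path`, invisibly (writer).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_labeling_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "region", "compartment", "time", "share", "se")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("labeling table is missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("labeling_observation", "data.frame")
  df
}

#' @rdname pipeline_io
#' @export
read_tpm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tpm_nuc", "tpm_cyto", "tpm_mem", "tpm_whole")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TPM table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname pipeline_io
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_length_kb", "exon_distances_kb", "has_introns")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname pipeline_io
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert gene models to/from the annotation table
#'
#' @param genes list of [gene_model] objects, or (for the inverse) an
#'   annotation data frame.
#' @return a data frame / list of `gene_model`s.
#' @export
genes_to_annotation <- function(genes) {
  do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, gene_length_kb = g$gene_length_kb,
               exon_distances_kb = paste(signif(g$exon_distances_kb, 8),
                                         collapse = ","),
               has_introns = g$has_introns, localization = g$localization)))
}

#' @rdname genes_to_annotation
#' @export
annotation_to_genes <- function(genes) {
  lapply(seq_len(nrow(genes)), function(i) {
    gene_model(gene_id = genes$gene_id[i],
               gene_length_kb = genes$gene_length_kb[i],
               exon_distances_kb =
                 as.numeric(strsplit(genes$exon_distances_kb[i], ",")[[1]]),
               has_introns = genes$has_introns[i],
               localization = genes$localization[i] %||% "cytosol")
  })
}

#' Validate pipeline input tables
#'
#' Schema and sanity checks on the three input tables: required columns,
#' shares within `[0, 1]`, positive times in minutes, nonnegative
#' distances in kb, and at least 2 replicates behind every SE. Problems
#' are reported with column and row references; the report does not
#' raise.
#'
#' @param labeling,tpm,annotation input data frames (any may be `NULL`).
#' @return list with `ok` (logical) and `problems` (character vector).
#' @export
validate_inputs <- function(labeling = NULL, tpm = NULL, annotation = NULL) {
  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))
  if (!is.null(labeling)) {
    need <- c("gene_id", "region", "compartment", "time", "share", "se")
    for (cn in setdiff(need, names(labeling)))
      note("labeling table: missing column '%s'", cn)
    if (all(need %in% names(labeling))) {
      bad <- which(labeling$share < 0 | labeling$share > 1)
      if (length(bad))
        note("labeling table: share outside [0, 1] in row(s) %s",
             paste(utils::head(bad, 10), collapse = ", "))
      if (any(labeling$time <= 0))
        note("labeling table: nonpositive times (expected minutes > 0)")
      if ("n_rep" %in% names(labeling) && any(labeling$n_rep < 2))
        note("labeling table: n_rep < 2; SEs need >= 2 replicates")
    }
  }
  if (!is.null(tpm)) {
    need <- c("gene_id", "tpm_nuc", "tpm_cyto", "tpm_mem", "tpm_whole")
    for (cn in setdiff(need, names(tpm)))
      note("TPM table: missing column '%s'", cn)
    num <- intersect(need[-1], names(tpm))
    for (cn in num) if (any(tpm[[cn]] < 0, na.rm = TRUE))
      note("TPM table: negative values in column '%s'", cn)
  }
  if (!is.null(annotation)) {
    need <- c("gene_id", "gene_length_kb", "exon_distances_kb", "has_introns")
    for (cn in setdiff(need, names(annotation)))
      note("annotation table: missing column '%s'", cn)
    if (all(need %in% names(annotation))) {
      if (any(annotation$gene_length_kb <= 0))
        note("annotation table: nonpositive gene lengths (expected kb)")
      if (any(annotation$gene_length_kb > 5000))
        note("annotation table: gene lengths above 5000; are these bp, not kb?")
    }
  }
  list(ok = length(problems) == 0L, problems = problems)
}

#' Fit a cohort of genes
#'
#' Runs [fit_kinetics] independently for every gene (per-gene seeds derive
#' from the master seed and the gene id, so removing a gene changes no
#' other gene's fit) and collects the results into a tidy table.
#' Per-gene failures are caught and logged, not fatal.
#'
#' @param genes list of [gene_model] objects.
#' @param labeling labeling observations for all genes.
#' @param expression steady-state TPM table (one row per gene).
#' @param factors an `abundance_factors` object (or list with `a_nuc`,
#'   `b_cyto`, `c_mem`).
#' @param cfg a [fit_config].
#' @param compare_nuclear_decay run the null/extended BIC comparison.
#' @param verbose print one line per gene.
#' @return object of class `slam_cohort`: list with `fits` (named list of
#'   `slam_fit`) and `table` (one row per gene).
#' @export
fit_cohort <- function(genes, labeling, expression, factors,
                       cfg = fit_config(), compare_nuclear_decay = TRUE,
                       verbose = FALSE) {
  fits <- list()
  rows <- list()
  for (g in genes) {
    ss <- expression[expression$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(ss) != 1L) next
    fit <- tryCatch(
      fit_kinetics(g, labeling, ss, factors, cfg,
                   compare_nuclear_decay = compare_nuclear_decay),
      error = function(e) {
        if (verbose) message(g$gene_id, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    fits[[g$gene_id]] <- fit
    rows[[g$gene_id]] <- slam_fit_row(fit)
    if (verbose)
      message(sprintf("%s: chi2 %.3g qc %s", g$gene_id,
                      if (isTRUE(fit$failed)) NA else fit$chi2,
                      paste(as.integer(fit$qc), collapse = "")))
  }
  structure(list(fits = fits, table = do.call(rbind, rows)),
            class = "slam_cohort")
}

# one tidy row per fit
slam_fit_row <- function(fit) {
  if (isTRUE(fit$failed))
    return(data.frame(gene_id = fit$gene_id, failed = TRUE))
  p <- fit$params
  se <- fit$param_se
  dec <- attr(fit, "decay_decision")
  data.frame(gene_id = fit$gene_id, variant = fit$variant,
             localization = fit$localization, reduced = fit$reduced,
             includes_nuclear_decay = fit$includes_nuclear_decay,
             delta_bic = dec$delta_bic %||% NA_real_,
             k1 = p$k1, k2 = p$k2, gamma2 = p$gamma2,
             gamma3 = p$gamma3 %||% NA_real_, k3 = p$k3 %||% NA_real_,
             gamma4 = p$gamma4 %||% NA_real_, v = p$v,
             se_k1 = se[["k1"]] %||% NA_real_, se_k2 = se[["k2"]],
             hl_processing = half_life(p$k1),
             hl_nuclear = half_life(p$k2 + p$gamma2),
             hl_cytosolic = half_life(p$gamma3 %||% p$k3),
             hl_membrane = half_life(p$gamma4 %||% NA_real_),
             chi2 = fit$chi2, reduced_chi2 = fit$reduced_chi2,
             bic = fit$bic, n_points = fit$n_points,
             chi2_fail = fit$qc[["chi2_fail"]],
             instability_fail = fit$qc[["instability_fail"]],
             boundary_fail = fit$qc[["boundary_fail"]],
             v_boundary = fit$qc[["v_boundary"]],
             qc_pass = !any(fit$qc[c("chi2_fail", "instability_fail",
                                     "boundary_fail")]),
             failed = FALSE)
}

#' @export
#' @method print slam_cohort
print.slam_cohort <- function(x, ...) {
  n <- length(x$fits)
  cat(sprintf("Kinetic fits for %d gene(s); %d passing QC\n", n,
              sum(x$table$qc_pass, na.rm = TRUE)))
  invisible(x)
}

#' Pipeline configuration
#'
#' @param outdir output directory for the result bundle.
#' @param seed master seed.
#' @param synthetic run on a synthetic cohort (`n_genes` genes) instead of
#'   input tables.
#' @param n_genes synthetic cohort size.
#' @param design a [simulation_design] (synthetic mode).
#' @param fit a [fit_config]; its seed is overridden by `seed`.
#' @param labeling_path,tpm_path,annotation_path input tables
#'   (non-synthetic mode; files must exist).
#' @param expressed_min_tpm expressed-gene filter: mean TPM of at least
#'   this value in at least one subcellular fraction (default 1.5).
#' @param abundance_min_tpm whole-cell TPM filter of the abundance fit.
#' @param compare_nuclear_decay run the nuclear-decay model comparison.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, synthetic = TRUE,
                            n_genes = 50L, design = simulation_design(),
                            fit = fit_config(), labeling_path = NULL,
                            tpm_path = NULL, annotation_path = NULL,
                            expressed_min_tpm = 1.5,
                            abundance_min_tpm = 50,
                            compare_nuclear_decay = TRUE) {
  if (!synthetic) {
    for (p in c(labeling_path, tpm_path, annotation_path))
      if (is.null(p) || !file.exists(p))
        stop("input table not found: ", p %||% "(missing path)")
  }
  fit$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, n_genes = as.integer(n_genes),
                 design = design, fit = fit,
                 labeling_path = labeling_path, tpm_path = tpm_path,
                 annotation_path = annotation_path,
                 expressed_min_tpm = expressed_min_tpm,
                 abundance_min_tpm = abundance_min_tpm,
                 compare_nuclear_decay = compare_nuclear_decay),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the input tables; filter expressed
#' genes (mean TPM >= 1.5 in at least one subcellular fraction); fit the
#' relative compartment abundance factors; classify localization; run the
#' per-gene multistart fits with and without nuclear decay and select by
#' BIC; apply quality control; derive aggregated pulse-chase half-lives;
#' summarize the cohort. Every stage's output is written as TSV into
#' `config$outdir` together with a JSON manifest (seed, package version,
#' config hash); a rerun with the same config and seed is bit-identical.
#' Per-gene failures are logged and skipped, never fatal.
#'
#' @param config a [pipeline_config].
#' @return (invisibly) list with the in-memory results: `factors`,
#'   `cohort`, `halflives`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  if (config$synthetic) {
    coh <- simulate_cohort(config$n_genes, seed = config$seed,
                           design = config$design)
    labeling <- coh$labeling
    tpm <- coh$expression
    genes <- coh$genes
    write_table_tsv(coh$truth, out("ground_truth.tsv"))
  } else {
    labeling <- read_labeling_table(config$labeling_path)
    tpm <- read_tpm_table(config$tpm_path)
    genes <- annotation_to_genes(read_annotation_table(
      config$annotation_path))
  }
  rep_ok <- validate_inputs(labeling = labeling, tpm = tpm)
  if (!rep_ok$ok)
    warning("input validation: ", paste(rep_ok$problems, collapse = "; "))
  write_table_tsv(labeling, out("labeling.tsv"))
  write_table_tsv(tpm, out("tpm.tsv"))
  write_table_tsv(genes_to_annotation(genes), out("annotation.tsv"))
  expressed <- with(tpm, pmax(tpm_nuc, tpm_cyto, tpm_mem) >=
                      config$expressed_min_tpm)
  tpm_expr <- tpm[expressed, , drop = FALSE]
  if (nrow(tpm_expr) == 0L) {
    warning("no genes pass the expressed-gene TPM filter; writing empty ",
            "outputs")
    write_table_tsv(data.frame(), out("fits.tsv"))
    return(invisible(list(factors = NULL, cohort = NULL, halflives = NULL,
                          summary = NULL)))
  }
  factors <- tryCatch(
    fit_relative_abundance(tpm_expr$tpm_nuc, tpm_expr$tpm_cyto,
                           tpm_expr$tpm_mem, tpm_expr$tpm_whole,
                           tpm_expr$se_nuc %||% 0, tpm_expr$se_cyto %||% 0,
                           tpm_expr$se_mem %||% 0, tpm_expr$se_whole %||% 0,
                           min_whole_tpm = config$abundance_min_tpm),
    error = function(e) {
      warning("abundance fit failed (", conditionMessage(e),
              "); falling back to unfiltered fit")
      fit_relative_abundance(tpm_expr$tpm_nuc, tpm_expr$tpm_cyto,
                             tpm_expr$tpm_mem, tpm_expr$tpm_whole,
                             min_whole_tpm = 0)
    })
  write_table_tsv(data.frame(a_nuc = factors$a_nuc, b_cyto = factors$b_cyto,
                             c_mem = factors$c_mem, se_a = factors$se_a,
                             se_b = factors$se_b, se_c = factors$se_c,
                             n_genes = factors$n_genes),
                  out("abundance_factors.tsv"))
  genes <- genes[vapply(genes, function(g)
    g$gene_id %in% tpm_expr$gene_id, logical(1))]
  cohort <- fit_cohort(genes, labeling, tpm_expr, factors, config$fit,
                       compare_nuclear_decay = config$compare_nuclear_decay)
  write_table_tsv(cohort$table, out("fits.tsv"))
  # aggregated model-derived half-lives for QC-passing genes
  hl <- list()
  times <- seq(0, 600, by = 10)
  for (gid in names(cohort$fits)) {
    f <- cohort$fits[[gid]]
    if (isTRUE(f$failed) || !isTRUE(cohort$table[gid, "qc_pass"])) next
    pc <- model_derived_pulse_chase(f$params, times,
                                    include_pre = !f$reduced)
    wc <- pc[pc$compartment == "whole_cell", ]
    dfit <- fit_exponential_decay(wc$time, wc$share_old, mode = "share_old")
    hl[[gid]] <- data.frame(gene_id = gid,
                            whole_cell_half_life_min = dfit$half_life_min,
                            fit_residual = dfit$fit_residual)
  }
  halflives <- if (length(hl)) do.call(rbind, hl) else data.frame()
  write_table_tsv(halflives, out("derived_halflives.tsv"))
  summ <- summarize_cohort(cohort)
  write_table_tsv(summ$half_lives, out("summary_halflives.tsv"))
  cfg_plain <- config
  cfg_plain$design <- unclass(cfg_plain$design)
  cfg_plain$fit <- unclass(cfg_plain$fit)
  jsonlite::write_json(unclass(cfg_plain), out("config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  manifest <- list(package = "slamkin",
                   version = as.character(utils::packageVersion("slamkin")),
                   seed = config$seed,
                   n_genes = length(genes),
                   synthetic = config$synthetic,
                   config_hash = unname(tools::md5sum(out("config.json"))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(factors = factors, cohort = cohort, halflives = halflives,
                 summary = summ, manifest = manifest))
}
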