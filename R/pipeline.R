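# End-to-end orchestration: manifest + raw Ct CSV in; cleaned expression,
# group comparisons, subgroup reports, correlation screen and regression
# decomposition out. CSV everywhere, UTF-8, empty fields for missing values;
# every exclusion decision is logged with sample IDs.

#' Read and validate a sample manifest CSV
#'
#' Required columns: \code{sample_id}, \code{group}. Recognised covariates
#' (\code{age}, \code{sex}, \code{hemisphere}, \code{pmi}, \code{ph},
#' \code{smoker}, \code{suicide}) are kept; schema violations are reported
#' with row numbers.
#'
#' @param path CSV path.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group"))
    if (!col %in% names(m))
      stop(sprintf("manifest '%s' lacks required column '%s'", path, col),
           call. = FALSE)
  bad <- which(!nzchar(m$sample_id) | is.na(m$sample_id))
  if (length(bad))
    stop("manifest rows with empty sample_id: ",
         paste(bad, collapse = ", "), call. = FALSE)
  dup <- which(duplicated(m$sample_id))
  if (length(dup))
    stop("manifest rows with duplicate sample_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  m
}

#' Read and validate a long-format Ct table CSV
#'
#' Required columns: \code{sample_id}, \code{gene}, \code{replicate_index},
#' \code{ct}, \code{is_housekeeper}.
#'
#' @param path CSV path.
#' @return data.frame Ct table.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "replicate_index", "ct", "is_housekeeper")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop(sprintf("ct table '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  ct$is_housekeeper <- as.logical(ct$is_housekeeper)
  bad <- which(!is.finite(ct$ct) | ct$ct <= 0)
  if (length(bad))
    stop("ct table rows with non-positive or missing Ct: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  ct
}

#' Assemble an analysis configuration
#'
#' Either build in code or load from a YAML file with the same keys
#' ([read_analysis_config()]).
#'
#' @param manifest,ct_table paths to the input CSVs.
#' @param out_dir output directory for the report CSVs.
#' @param calibrator calibrator (unaffected-control) group label.
#' @param case case group label; default: first non-calibrator group found.
#' @param subgroup_genes genes to run the high-expressor fit on.
#' @param predicted_directions named list/vector, gene -> "greater"/"less",
#'   for one-tailed group tests; genes absent here are tested two-tailed.
#' @param regression list with \code{dependents} (character) and
#'   \code{predictor} (gene name), or NULL to skip the decomposition.
#' @param covariates manifest columns for the correlation screen.
#' @param alpha significance level used by screens.
#' @param quantile_type IQR convention for the subgroup threshold.
#' @param max_dev replicate-cleaning threshold, Ct.
#' @param seed integer seed (recorded in the log; analysis itself is
#'   deterministic given the inputs).
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(manifest, ct_table, out_dir = ".",
                            calibrator = "control", case = NULL,
                            subgroup_genes = character(0),
                            predicted_directions = list(),
                            regression = NULL,
                            covariates = c("age", "pmi", "ph"),
                            alpha = 0.05, quantile_type = 7,
                            max_dev = 0.5, seed = NULL) {
  check_that(alpha > 0 && alpha < 1, "alpha", "must lie in (0, 1)")
  structure(list(manifest = manifest, ct_table = ct_table, out_dir = out_dir,
                 calibrator = calibrator, case = case,
                 subgroup_genes = subgroup_genes,
                 predicted_directions = predicted_directions,
                 regression = regression, covariates = covariates,
                 alpha = alpha, quantile_type = quantile_type,
                 max_dev = max_dev, seed = seed),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML config file.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(analysis_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, y)
}

#' Run the full case-control qRT-PCR pipeline
#'
#' Sequence: read + validate inputs; clean replicates and quantify by
#' delta-delta Ct anchored on the calibrator group; per-gene case-control
#' comparison (Mann-Whitney U, one-tailed where a direction was predicted);
#' high-expressor subgroup fit for the configured genes; Spearman
#' correlation screen of expression against covariates; hierarchical
#' pH/ligand regression decomposition if configured. Writes
#' \code{expression.csv}, \code{tests.csv}, \code{subgroup.csv},
#' \code{correlations.csv}, \code{regression.csv} (when configured) and
#' \code{run_log.txt} into \code{out_dir}. Deterministic given inputs.
#'
#' @param config an [analysis_config()] or path to a YAML config.
#' @return Invisibly, a list with every table written plus the fitted
#'   \code{high_expressor} objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  manifest <- read_manifest(config$manifest)
  ct <- read_ct_table(config$ct_table)
  log_lines <- c(sprintf("hiexpr pipeline run, %s", format(Sys.time())),
                 sprintf("manifest: %s (%d samples)", config$manifest,
                         nrow(manifest)),
                 sprintf("ct table: %s (%d rows)", config$ct_table, nrow(ct)))

  if (!config$calibrator %in% manifest$group)
    stop(sprintf("calibrator group '%s' not found in manifest",
                 config$calibrator), call. = FALSE)
  orphan <- setdiff(unique(ct$sample_id), manifest$sample_id)
  if (length(orphan))
    stop("ct table contains sample(s) missing from manifest: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  case <- config$case %||%
    setdiff(unique(manifest$group), config$calibrator)[1L]

  quant <- quantify_expression(ct, manifest, config$calibrator,
                               max_dev = config$max_dev)
  expr <- quant$expression
  if (nrow(quant$cleaning_log))
    log_lines <- c(log_lines, sprintf(
      "dropped replicate: sample %s gene %s ct %.3f",
      quant$cleaning_log$sample_id, quant$cleaning_log$gene,
      quant$cleaning_log$dropped_ct))
  gf <- expr[expr$grubbs_outlier, ]
  if (nrow(gf))
    log_lines <- c(log_lines, sprintf(
      "Grubbs population outlier (flagged, not removed): sample %s gene %s rq %.4f",
      gf$sample_id, gf$gene, gf$rq))

  genes <- unique(expr$gene)
  tests <- lapply(genes, function(g) {
    d <- expr[expr$gene == g, ]
    xs <- d$rq[d$group == case]
    ys <- d$rq[d$group == config$calibrator]
    dir <- config$predicted_directions[[g]]
    cmp <- mann_whitney_u(xs, ys,
                          tails = if (is.null(dir)) "two" else "one",
                          predicted_direction = dir %||% "greater")
    data.frame(gene = g, groups = paste(case, "vs", config$calibrator),
               test = cmp$test, statistic = cmp$statistic, n = cmp$n,
               tails = cmp$tails, p_value = cmp$p_value,
               effect_size_r = cmp$effect_size_r, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)

  sub_fits <- list()
  sub_rows <- lapply(intersect(config$subgroup_genes, genes), function(g) {
    d <- expr[expr$gene == g, ]
    fit <- high_expressor(d$rq, d$group, control = config$calibrator,
                          case = case, qtype = config$quantile_type,
                          alpha = config$alpha)
    sub_fits[[g]] <<- fit
    data.frame(gene = g, threshold = fit$threshold,
               flagged_control = fit$table[1, 1],
               n_control = sum(fit$table[1, ]),
               flagged_case = fit$table[2, 1],
               n_case = sum(fit$table[2, ]),
               chi2 = fit$association$statistic %||% NA_real_,
               p = fit$association$p_value %||% NA_real_,
               risk_ratio = fit$risk_ratio %||% NA_real_,
               odds_ratio = fit$odds_ratio %||% NA_real_,
               core_mean = fit$core$mean, core_sd = fit$core$sd,
               core_n = fit$core$n, ks_D = fit$core$ks_D,
               ks_p = fit$core$ks_p, sd_distance = fit$sd_distance,
               n_removed = length(fit$core$removed),
               stringsAsFactors = FALSE)
  })
  subgroup <- if (length(sub_rows)) do.call(rbind, sub_rows) else NULL

  wide <- stats::reshape(expr[, c("sample_id", "gene", "rq")],
                         idvar = "sample_id", timevar = "gene",
                         direction = "wide")
  names(wide) <- sub("^rq\\.", "", names(wide))
  wide <- wide[match(manifest$sample_id, wide$sample_id), , drop = FALSE]
  covs <- manifest[, intersect(config$covariates, names(manifest)),
                   drop = FALSE]
  covs[] <- lapply(covs, function(v)
    if (is.numeric(v)) v else as.numeric(factor(v)))
  screen <- correlation_screen(wide[, genes, drop = FALSE], covs)
  corr <- data.frame(gene = rep(rownames(screen$r), ncol(screen$r)),
                     covariate = rep(colnames(screen$r),
                                     each = nrow(screen$r)),
                     rho = as.vector(screen$r), p = as.vector(screen$p),
                     stringsAsFactors = FALSE)

  regression <- NULL
  if (!is.null(config$regression)) {
    dep <- intersect(config$regression$dependents, genes)
    pred <- config$regression$predictor
    if (!pred %in% genes)
      stop(sprintf("regression predictor '%s' not quantified", pred),
           call. = FALSE)
    ph <- manifest$ph[match(wide$sample_id, manifest$sample_id)]
    regression <- decomposition_table(wide, dep, pred, ph)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(
    d, file.path(config$out_dir, f), row.names = FALSE, na = "")
  wcsv(expr, "expression.csv")
  wcsv(tests, "tests.csv")
  if (!is.null(subgroup)) wcsv(subgroup, "subgroup.csv")
  wcsv(corr, "correlations.csv")
  if (!is.null(regression)) wcsv(regression, "regression.csv")
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(expression = expr, tests = tests, subgroup = subgroup,
                 correlations = corr, regression = regression,
                 subgroup_fits = sub_fits, cleaning_log = quant$cleaning_log,
                 log = log_lines))
}

#' Write a simulated study to manifest + Ct CSVs
#'
#' The simulation entry point of the pipeline: generates a cohort,
#' expression and a raw Ct plate with [simulate_study()] and writes them in
#' exactly the CSV dialects [run_pipeline()] consumes (plus the ground
#' truth expression table for parameter-recovery checks).
#'
#' @param out_dir directory to write \code{manifest.csv}, \code{ct.csv}
#'   and \code{truth.csv} into.
#' @param cohort,genes,noise,seed passed to [simulate_study()].
#' @return Invisibly, the simulated study list.
#' @export
simulate_to_csv <- function(out_dir, cohort = cohort_spec(),
                            genes = gene_spec("TNFSF13"),
                            noise = ct_noise_spec(), seed = 1L) {
  sim <- simulate_study(cohort, genes, noise, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  ct <- sim$ct_table[, c("sample_id", "gene", "replicate_index", "ct",
                         "is_housekeeper")]
  utils::write.csv(ct, file.path(out_dir, "ct.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(sim$expression, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, na = "")
  invisible(sim)
}
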