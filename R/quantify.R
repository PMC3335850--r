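#' Clean a qPCR technical replicate set
#'
#' Drops any replicate deviating from the median of the replicate set by
#' more than \code{max_dev} Ct (default 0.5, conventional qPCR practice).
#' Pairs are never trimmed: with two replicates there is no majority to
#' decide which one is aberrant. At least one replicate is always retained.
#'
#' @param ct numeric vector of 1-3 replicate Ct values.
#' @param max_dev maximum allowed deviation from the replicate median, Ct.
#' @return A list: \code{retained} values, \code{dropped} values,
#'   \code{mean} of the retained replicates.
#' @examples
#' clean_triplicates(c(20.0, 20.1, 24.0))$mean  # aberrant 24.0 dropped
#' @export
clean_triplicates <- function(ct, max_dev = 0.5) {
  if (length(ct) == 0L) stop("no replicates supplied", call. = FALSE)
  stopifnot(is.numeric(ct), all(is.finite(ct)))
  if (length(ct) <= 2L)
    return(list(retained = ct, dropped = numeric(0), mean = mean(ct)))
  keep <- abs(ct - stats::median(ct)) <= max_dev
  if (!any(keep)) keep[which.min(abs(ct - stats::median(ct)))] <- TRUE
  list(retained = ct[keep], dropped = ct[!keep], mean = mean(ct[keep]))
}

#' Delta Ct against the housekeeper geometric mean
#'
#' \code{delta Ct = Ct_target - geomean(housekeeper Cts)}. The geometric
#' mean is taken of the housekeeper Ct values themselves (not of linearized
#' 2^-Ct quantities). At least three housekeepers are required.
#'
#' @param ct_target mean Ct of the target gene for one sample.
#' @param ct_housekeepers named numeric vector of housekeeper mean Cts.
#' @return delta Ct in cycles.
#' @examples
#' delta_ct(25, c(ACTB = 18, TBP = 20, UBC = 22.5))
#' @export
delta_ct <- function(ct_target, ct_housekeepers) {
  stopifnot(length(ct_target) == 1L, is.finite(ct_target))
  if (length(ct_housekeepers) < 3L)
    stop("delta Ct needs >= 3 housekeeper genes", call. = FALSE)
  bad <- !is.finite(ct_housekeepers)
  if (any(bad))
    stop(sprintf("missing housekeeper Ct for gene '%s'",
                 paste(names(ct_housekeepers)[bad], collapse = "', '")),
         call. = FALSE)
  ct_target - geomean(ct_housekeepers)
}

#' Relative quantities by the delta-delta Ct method
#'
#' Re-centres per-sample delta Ct values on the arithmetic mean delta Ct of
#' a calibrator group and converts to the linear scale:
#' \code{ddct = dct - mean(dct[calibrator])}, \code{rq = 2^-ddct}. The
#' calibrator group's mean delta-delta Ct is 0 by construction, so its
#' relative quantities have geometric mean 1.
#'
#' @param dct numeric vector of delta Ct values, one per sample.
#' @param group group label per sample.
#' @param calibrator label of the calibrator group (typically the
#'   unaffected controls).
#' @return data.frame with \code{delta_ct}, \code{ddct}, \code{rq} per
#'   input element (input order preserved).
#' @export
relative_quantity <- function(dct, group, calibrator) {
  stopifnot(length(dct) == length(group))
  if (!calibrator %in% group)
    stop(sprintf("calibrator group '%s' not present", calibrator),
         call. = FALSE)
  ddct <- dct - mean(dct[group == calibrator])
  data.frame(delta_ct = dct, ddct = ddct, rq = 2^(-ddct))
}

#' Iterative two-sided Grubbs outlier screen
#'
#' Repeatedly tests the single most extreme value against the Grubbs
#' critical value \code{G = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))} with
#' \code{t} the upper \code{alpha/(2n)} Student quantile on \code{n - 2}
#' degrees of freedom, removing it while significant. Zero-variance input
#' yields no outliers. Flags are returned; nothing is silently dropped.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level per step.
#' @return logical vector: TRUE where flagged as a population outlier.
#' @export
grubbs_screen <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  n_all <- length(values)
  if (n_all < 3L) stop("Grubbs test needs n >= 3", call. = FALSE)
  flagged <- logical(n_all)
  active <- seq_len(n_all)
  repeat {
    x <- values[active]
    n <- length(x)
    if (n < 3L) break
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    g <- dev[i] / s
    tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    g_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    if (g <= g_crit) break
    flagged[active[i]] <- TRUE
    active <- active[-i]
  }
  flagged
}

#' Quantify a raw Ct table
#'
#' Full quantification pass: per sample x gene the technical replicates are
#' cleaned with [clean_triplicates()]; per sample, target-gene delta Ct is
#' computed against the geometric mean of the housekeeper Cts; delta-delta
#' Ct is anchored on the calibrator group and converted to relative
#' quantities; finally an iterative Grubbs screen flags population outliers
#' per gene on the rq scale. Every dropped replicate and every Grubbs flag
#' is logged with its sample ID — nothing is removed silently.
#'
#' @param ct_table long data.frame with columns \code{sample_id},
#'   \code{gene}, \code{replicate_index}, \code{ct}, \code{is_housekeeper}.
#' @param groups named character vector or data.frame mapping
#'   \code{sample_id} to diagnostic group (a manifest works).
#' @param calibrator calibrator group label.
#' @param max_dev replicate-cleaning threshold, Ct.
#' @param grubbs_alpha alpha for the population-outlier screen.
#' @return An object of class \code{ddct_quant}: list with
#'   \code{expression} (sample_id, group, gene, delta_ct, ddct, rq,
#'   grubbs_outlier), \code{cleaning_log} (one row per dropped replicate)
#'   and \code{calibrator}.
#' @export
quantify_expression <- function(ct_table, groups, calibrator,
                                max_dev = 0.5, grubbs_alpha = 0.05) {
  need <- c("sample_id", "gene", "replicate_index", "ct", "is_housekeeper")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop("ct_table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    groups <- stats::setNames(groups$group, groups$sample_id)
  }
  hk_genes <- unique(ct_table$gene[ct_table$is_housekeeper])
  if (length(hk_genes) < 3L)
    stop("pipeline requires >= 3 housekeeper genes, found ",
         length(hk_genes), call. = FALSE)

  # replicate cleaning, one pass per sample x gene
  key <- interaction(ct_table$sample_id, ct_table$gene, drop = TRUE)
  cleaned <- lapply(split(ct_table, key), function(d) {
    cl <- clean_triplicates(d$ct, max_dev = max_dev)
    log <- if (length(cl$dropped))
      data.frame(sample_id = d$sample_id[1L], gene = d$gene[1L],
                 dropped_ct = cl$dropped, stringsAsFactors = FALSE)
    else NULL
    list(row = data.frame(sample_id = d$sample_id[1L], gene = d$gene[1L],
                          is_housekeeper = d$is_housekeeper[1L],
                          ct = cl$mean, stringsAsFactors = FALSE),
         log = log)
  })
  means <- do.call(rbind, lapply(cleaned, `[[`, "row"))
  logs <- do.call(rbind, Filter(Negate(is.null), lapply(cleaned, `[[`, "log")))
  if (is.null(logs))
    logs <- data.frame(sample_id = character(0), gene = character(0),
                       dropped_ct = numeric(0))
  rownames(means) <- rownames(logs) <- NULL

  # per-sample delta Ct for each target gene
  dct_rows <- lapply(split(means, means$sample_id), function(d) {
    hk <- d[d$is_housekeeper, ]
    if (nrow(hk) < 3L)
      stop(sprintf("sample '%s' has %d housekeeper genes; >= 3 required",
                   d$sample_id[1L], nrow(hk)), call. = FALSE)
    tg <- d[!d$is_housekeeper, ]
    hk_ct <- stats::setNames(hk$ct, hk$gene)
    data.frame(sample_id = tg$sample_id, gene = tg$gene,
               delta_ct = vapply(tg$ct, delta_ct, numeric(1),
                                 ct_housekeepers = hk_ct),
               stringsAsFactors = FALSE)
  })
  dct <- do.call(rbind, c(dct_rows, list(make.row.names = FALSE)))
  unknown <- setdiff(unique(dct$sample_id), names(groups))
  if (length(unknown))
    stop("no group label for sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dct$group <- unname(groups[dct$sample_id])

  # calibrator anchoring and Grubbs screen, per gene
  out <- lapply(split(dct, dct$gene), function(d) {
    rqd <- relative_quantity(d$delta_ct, d$group, calibrator)
    d$ddct <- rqd$ddct
    d$rq <- rqd$rq
    d$grubbs_outlier <- if (nrow(d) >= 3L) grubbs_screen(d$rq, grubbs_alpha)
                        else FALSE
    d
  })
  expr <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  expr <- expr[order(expr$gene, expr$sample_id),
               c("sample_id", "group", "gene", "delta_ct", "ddct", "rq",
                 "grubbs_outlier")]
  rownames(expr) <- NULL
  structure(list(expression = expr, cleaning_log = logs,
                 calibrator = calibrator),
            class = "ddct_quant")
}

#' @export
print.ddct_quant <- function(x, ...) {
  e <- x$expression
  cat("delta-delta Ct quantification\n")
  cat(sprintf("  %d samples, %d target gene(s), calibrator group '%s'\n",
              length(unique(e$sample_id)), length(unique(e$gene)),
              x$calibrator))
  cat(sprintf("  replicates dropped: %d; Grubbs-flagged values: %d\n",
              nrow(x$cleaning_log), sum(e$grubbs_outlier)))
  invisible(x)
}
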