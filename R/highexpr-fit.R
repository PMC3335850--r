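#' Control-anchored high-expression threshold
#'
#' \code{T = median(control) + k * IQR(control)} with k = 1.25 by default.
#' The quartile convention matters near the tail: the default is linear
#' interpolation between order statistics (\code{quantile type 7}, the
#' common default in scientific software); \code{type = 6} gives the
#' SPSS-style weighted-average quantile, which can differ slightly. The
#' threshold is computed from the unaffected-control group only and then
#' applied to all groups.
#'
#' @param control_values relative quantities of the control group, n >= 4.
#' @param k IQR multiplier.
#' @param qtype quantile type passed to [stats::quantile()].
#' @return The threshold T, in rq units.
#' @examples
#' high_expression_threshold(1:8)  # 4.5 + 1.25 * 3.5 = 8.875
#' @export
high_expression_threshold <- function(control_values, k = 1.25, qtype = 7) {
  control_values <- control_values[is.finite(control_values)]
  if (length(control_values) < 4L)
    stop("threshold needs >= 4 control values", call. = FALSE)
  q <- stats::quantile(control_values, c(0.25, 0.5, 0.75), type = qtype,
                       names = FALSE)
  q[2L] + k * (q[3L] - q[1L])
}

#' Normal core by reiterative maximum-removal
#'
#' Estimates the "normal core" of an expression distribution contaminated
#' by high expressors: test the current set for normality with the
#' Kolmogorov-Smirnov statistic using Lilliefors-corrected significance
#' (parameters estimated from the data; an uncorrected KS p would be
#' anti-conservative), and while p <= alpha remove the single largest
#' value and retest. Stops when normality is no longer rejected or when a
#' further removal would shrink the set below \code{min_n}. Ties at the
#' maximum lose one occurrence per iteration (the last index, so removal
#' is deterministic).
#'
#' @param values numeric vector, n >= 5.
#' @param alpha stopping level for the normality p-value.
#' @param min_n smallest admissible surviving core.
#' @return A list: \code{mean}, \code{sd}, \code{n} of the surviving core;
#'   final KS statistic \code{ks_D} and \code{ks_p}; \code{removed} values
#'   in removal order; \code{converged} flag; \code{values} surviving.
#' @export
iterative_normal_core <- function(values, alpha = 0.05, min_n = 5L) {
  values <- values[is.finite(values)]
  n0 <- length(values)
  if (n0 < min_n) stop(sprintf("need at least %d values", min_n),
                       call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant values: KS statistic undefined (zero SD)", call. = FALSE)
  current <- values
  removed <- numeric(0)
  converged <- FALSE
  repeat {
    if (stats::sd(current) == 0)
      stop("trimming produced constant values: KS undefined", call. = FALSE)
    ks <- nortest::lillie.test(current)
    if (ks$p.value > alpha) { converged <- TRUE; break }
    if (length(current) - 1L < min_n) break
    i <- max(which(current == max(current)))   # last occurrence among ties
    removed <- c(removed, current[i])
    current <- current[-i]
  }
  list(mean = mean(current), sd = stats::sd(current), n = length(current),
       ks_D = unname(ks$statistic), ks_p = ks$p.value,
       removed = removed, converged = converged, values = current)
}

#' Distance of a flagged subpopulation from the normal core
#'
#' \code{(mean(flagged) - core_mean) / core_sd}: how many core standard
#' deviations the flagged group's mean lies above the trimmed normal core.
#' Invariant under affine transformation of all the data.
#'
#' @param flagged_values values of the flagged (high-expressor) samples.
#' @param core a core summary with \code{mean} and \code{sd} (e.g. from
#'   [iterative_normal_core()]), or a numeric \code{c(mean, sd)}.
#' @return SD distance (positive when the flagged mean exceeds the core).
#' @examples
#' sd_distance(3.053, c(0.8919, 0.4308))  # about 5 SD
#' @export
sd_distance <- function(flagged_values, core) {
  if (is.numeric(core)) core <- list(mean = core[1L], sd = core[2L])
  if (!length(flagged_values)) stop("no flagged values", call. = FALSE)
  if (!is.finite(core$sd) || core$sd <= 0)
    stop("core SD must be > 0", call. = FALSE)
  (mean(flagged_values) - core$mean) / core$sd
}

#' Fit the high-expressor subgroup model
#'
#' The full subgroup-detection procedure for one gene's relative
#' quantities in a case-control cohort:
#' \enumerate{
#'   \item threshold \code{T = median + 1.25 IQR} of the control group
#'     ([high_expression_threshold()]), applied to all samples;
#'   \item 2x2 association of flag status with diagnosis by uncorrected
#'     chi-square ([chi_square_2x2()]), with the risk ratio (case
#'     prevalence over control prevalence) and, since "times more likely"
#'     phrasing is ambiguous, the odds ratio as well;
#'   \item the trimmed normal core of the pooled expression distribution
#'     ([iterative_normal_core()]), against which the flagged samples'
#'     mean is expressed in core SD units ([sd_distance()]).
#' }
#'
#' @param x relative quantities (or a formula \code{rq ~ group}).
#' @param group diagnostic group per sample.
#' @param control label of the unaffected-control group (threshold anchor
#'   and risk-ratio denominator). Defaults to \code{"control"} when
#'   present, else the first group level.
#' @param case label of the case group for the 2x2 association; defaults
#'   to the first non-control group.
#' @param k IQR multiplier for the threshold.
#' @param qtype quantile convention, see [high_expression_threshold()].
#' @param core_pool \code{"all"} (default) trims the pooled control + case
#'   distribution; \code{"controls"} trims controls only.
#' @param alpha stopping level for the core's normality rule.
#' @param ... passed between methods.
#' @return An object of class \code{high_expressor}: threshold, per-sample
#'   flags, contingency table, chi-square \code{comparison_result}, risk
#'   and odds ratios, core summary, SD distance, per-group prevalence.
#' @examples
#' set.seed(1)
#' rq <- c(rlnorm(70, 0, 0.4), rlnorm(70, 0.2, 0.4) + rbinom(70, 1, 0.3) * 4)
#' grp <- rep(c("control", "case"), each = 70)
#' fit <- high_expressor(rq, grp, control = "control")
#' print(fit)
#' @export
high_expressor <- function(x, ...) UseMethod("high_expressor")

#' @rdname high_expressor
#' @param data data.frame holding the formula's variables.
#' @export
high_expressor.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  high_expressor.default(mf[[1L]], group = mf[[2L]], ...)
}

#' @rdname high_expressor
#' @export
high_expressor.default <- function(x, group, control = NULL, case = NULL,
                                   k = 1.25, qtype = 7,
                                   core_pool = c("all", "controls"),
                                   alpha = 0.05, ...) {
  core_pool <- match.arg(core_pool)
  group <- as.character(group)
  stopifnot(length(x) == length(group))
  ok <- is.finite(x) & !is.na(group)
  x <- x[ok]; group <- group[ok]
  labels <- unique(group)
  if (is.null(control))
    control <- if ("control" %in% labels) "control" else labels[1L]
  if (!control %in% labels)
    stop(sprintf("control group '%s' not present", control), call. = FALSE)
  if (is.null(case)) case <- setdiff(labels, control)[1L]
  if (is.na(case) || !case %in% labels)
    stop("no case group available", call. = FALSE)

  threshold <- high_expression_threshold(x[group == control], k = k,
                                         qtype = qtype)
  flagged <- x > threshold

  in_pair <- group %in% c(control, case)
  tab <- matrix(c(sum(flagged & group == control),
                  sum(!flagged & group == control),
                  sum(flagged & group == case),
                  sum(!flagged & group == case)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c(control, case),
                                high = c("high", "normal")))
  prev_control <- tab[1, 1] / sum(tab[1, ])
  prev_case <- tab[2, 1] / sum(tab[2, ])

  association <- risk_ratio <- odds_ratio <- NULL
  if (sum(tab[, "high"]) == 0L) {
    warning("no sample exceeds the threshold; association undefined")
  } else {
    association <- tryCatch(chi_square_2x2(tab), error = function(e) {
      warning("association chi-square undefined: ", conditionMessage(e))
      NULL
    })
    if (prev_control == 0) {
      warning("zero flagged controls: risk ratio infinite")
      risk_ratio <- Inf
    } else risk_ratio <- prev_case / prev_control
    odds_ratio <- (tab[2, 1] * tab[1, 2]) / (tab[2, 2] * tab[1, 1])
  }

  pool <- if (core_pool == "all") x[in_pair] else x[group == control]
  core <- iterative_normal_core(pool, alpha = alpha)
  sd_dist <- if (any(flagged & group == control) && core$sd > 0)
    sd_distance(x[flagged & group == control], core)
  else NA_real_

  structure(list(threshold = threshold, k = k, qtype = qtype,
                 control = control, case = case, core_pool = core_pool,
                 flags = flagged, values = x, group = group,
                 table = tab, association = association,
                 prevalence = c(control = prev_control, case = prev_case),
                 risk_ratio = risk_ratio, odds_ratio = odds_ratio,
                 core = core, sd_distance = sd_dist,
                 call = match.call()),
            class = "high_expressor")
}

#' @export
print.high_expressor <- function(x, digits = 4, ...) {
  cat("High-expressor subgroup fit\n")
  cat(sprintf("  threshold: median + %.3g x IQR of '%s' = %.*g\n",
              x$k, x$control, digits, x$threshold))
  cat(sprintf("  flagged: %d/%d %s (%.1f%%) vs %d/%d %s (%.1f%%)\n",
              x$table[2, 1], sum(x$table[2, ]), x$case,
              100 * x$prevalence[["case"]],
              x$table[1, 1], sum(x$table[1, ]), x$control,
              100 * x$prevalence[["control"]]))
  if (!is.null(x$association))
    cat(sprintf("  association: chi2(1) = %.*g, p = %.*g (two-tailed)\n",
                digits, x$association$statistic, digits,
                x$association$p_value))
  if (!is.null(x$risk_ratio))
    cat(sprintf("  risk ratio %.*g, odds ratio %.*g\n",
                digits, x$risk_ratio, digits, x$odds_ratio))
  cat(sprintf("  normal core (%s): %.*g +/- %.*g (n = %d), KS D = %.*g, p = %.*g%s\n",
              x$core_pool, digits, x$core$mean, digits, x$core$sd,
              x$core$n, digits, x$core$ks_D, digits, x$core$ks_p,
              if (x$core$converged) "" else " [did not converge]"))
  if (is.finite(x$sd_distance))
    cat(sprintf("  flagged controls sit %.*g core SD above the core mean\n",
                digits, x$sd_distance))
  invisible(x)
}

#' @export
summary.high_expressor <- function(object, ...) {
  structure(list(fit = object), class = "summary.high_expressor")
}

#' @export
print.summary.high_expressor <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n2x2 table (group x flag):\n")
  print(f$table)
  if (length(f$core$removed)) {
    cat("\ncore trimming removed", length(f$core$removed),
        "value(s), largest first:\n")
    print(signif(f$core$removed, 4))
  } else cat("\ncore trimming removed no values\n")
  invisible(x)
}

#' @export
coef.high_expressor <- function(object, ...) {
  c(threshold = object$threshold,
    core_mean = object$core$mean,
    core_sd = object$core$sd,
    sd_distance = object$sd_distance,
    risk_ratio = object$risk_ratio %||% NA_real_,
    odds_ratio = object$odds_ratio %||% NA_real_)
}

#' Classify new expression values against a fitted threshold
#'
#' @param object a \code{high_expressor} fit.
#' @param newdata relative quantities to classify (default: training data).
#' @param ... unused.
#' @return A factor, levels \code{normal} / \code{high}.
#' @export
predict.high_expressor <- function(object, newdata = NULL, ...) {
  v <- newdata %||% object$values
  factor(ifelse(v > object$threshold, "high", "normal"),
         levels = c("normal", "high"))
}

#' Simulate cohorts from a fitted subgroup geometry
#'
#' Draws case-control cohorts from the two-component geometry the fit
#' estimated: a normal core at the fitted mean/SD plus a high-expressor
#' component displaced by the fitted SD distance, at the observed per-group
#' prevalences and group sizes.
#'
#' @param object a \code{high_expressor} fit.
#' @param nsim number of simulated cohorts.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of \code{nsim} data.frames with \code{value},
#'   \code{group}, \code{is_subpop}.
#' @export
simulate.high_expressor <- function(object, nsim = 1, seed = NULL, ...) {
  shift <- if (is.finite(object$sd_distance)) object$sd_distance else 5
  n_ctrl <- sum(object$table[1, ]); n_case <- sum(object$table[2, ])
  prev <- object$prevalence
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      grp <- rep(c(object$control, object$case), c(n_ctrl, n_case))
      pr <- ifelse(grp == object$control, prev[["control"]], prev[["case"]])
      sub <- stats::runif(length(grp)) < pr
      val <- stats::rnorm(length(grp), object$core$mean, object$core$sd) +
        ifelse(sub, shift * object$core$sd, 0)
      data.frame(value = val, group = grp, is_subpop = sub,
                 stringsAsFactors = FALSE)
    })
  })
}

#' @export
plot.high_expressor <- function(x, breaks = 30, ...) {
  h <- graphics::hist(x$values, breaks = breaks, plot = FALSE)
  graphics::hist(x$values, breaks = breaks, col = "grey85", border = "white",
                 freq = FALSE, main = "High-expressor subgroup fit",
                 xlab = "relative quantity (2^-ddCt)", ...)
  xs <- seq(min(x$values), max(x$values), length.out = 256)
  graphics::lines(xs, stats::dnorm(xs, x$core$mean, x$core$sd) *
                    x$core$n / length(x$values), lwd = 2)
  graphics::abline(v = x$threshold, lty = 2, lwd = 2)
  graphics::rug(x$values[x$flags], lwd = 1.5)
  graphics::legend("topright", bty = "n", lty = c(1, 2),
                   legend = c("trimmed normal core", "threshold"))
  invisible(x)
}
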