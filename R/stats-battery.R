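# Group-comparison battery: the test choices, tailing conventions and
# correlation-scale effect sizes conventional in case-control postmortem
# expression studies (pooled t, SPSS-convention Mann-Whitney U, uncorrected
# Pearson chi-square, two-way ANOVA, one-sample t, Spearman screens).

comparison_result <- function(test, statistic, df = NA_real_, n = NA_real_,
                              p_value, tails = "two", effect_size_r = NA_real_,
                              direction = NA_character_, note = NULL) {
  structure(list(test = test, statistic = statistic, df = df, n = n,
                 p_value = p_value, tails = tails,
                 effect_size_r = effect_size_r, direction = direction,
                 note = note),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  dftxt <- if (!is.na(x$df)) sprintf("(%s)", format(x$df)) else ""
  cat(sprintf("%s: statistic%s = %.4g, p = %.4g (%s-tailed)",
              x$test, dftxt, x$statistic, x$p_value, x$tails))
  if (!is.na(x$effect_size_r)) cat(sprintf(", effect size r = %.3f",
                                           x$effect_size_r))
  cat("\n")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Collect comparison results into a tidy data.frame
#'
#' @param ... \code{comparison_result} objects, optionally named.
#' @return One row per test: test, statistic, df, n, p_value, tails,
#'   effect_size_r, direction.
#' @export
tidy_comparisons <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) &&
      !inherits(xs[[1L]], "comparison_result")) xs <- xs[[1L]]
  rows <- lapply(xs, function(x)
    data.frame(test = x$test, statistic = x$statistic, df = x$df, n = x$n,
               p_value = x$p_value, tails = x$tails,
               effect_size_r = x$effect_size_r,
               direction = x$direction %||% NA_character_,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (!is.null(names(xs)) && any(nzchar(names(xs)))) out$label <- names(xs)
  rownames(out) <- NULL
  out
}

# Resolve a one- vs two-tailed p. When the observed direction matches the
# prediction the one-tailed p is half the two-tailed p; on a mismatch the
# conservative 1 - p/2 is reported.
tail_p <- function(p_two, observed_sign, tails, predicted_direction) {
  if (tails == "two") return(p_two)
  pred_sign <- switch(predicted_direction, greater = 1, less = -1,
                      stop("predicted_direction must be 'greater' or 'less'",
                           call. = FALSE))
  if (observed_sign == 0 || sign(observed_sign) == pred_sign) p_two / 2
  else 1 - p_two / 2
}

#' Pearson chi-square on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with
#' df = 1, expected counts from the row/column margins. Effect size
#' r = sqrt(chi2 / N).
#'
#' @param table 2x2 matrix of counts (rows = groups, columns = trait), or
#'   the four counts \code{c(a, b, c, d)} read row-wise.
#' @return A \code{comparison_result}.
#' @examples
#' chi_square_2x2(matrix(c(18, 46, 21, 11), nrow = 2))  # chi2 = 12.437
#' @export
chi_square_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2, byrow = TRUE)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  n <- sum(table)
  if (n == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square undefined: a table margin is zero", call. = FALSE)
  # small expected counts trigger chisq.test's asymptotic-approximation
  # advisory; the statistic itself is exact arithmetic, so it is silenced
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  chi2 <- unname(ht$statistic)
  comparison_result("chi-square (2x2, uncorrected)", chi2, df = 1, n = n,
                    p_value = unname(ht$p.value), tails = "two",
                    effect_size_r = effect_size_from_chi2(chi2, n))
}

#' Pooled-variance two-sample t test
#'
#' Equal-variance (pooled) t with df = n1 + n2 - 2, accepting either raw
#' vectors or printed summary statistics (n, mean, SD) per group — summary
#' input allows published tables to be checked directly. One-tailed p is
#' half the two-tailed p when the observed direction matches the
#' prediction, else the conservative 1 - p/2.
#'
#' @param x,y raw data vectors (omit when using summaries).
#' @param n1,mean1,sd1,n2,mean2,sd2 summary statistics per group.
#' @param tails "two" or "one".
#' @param predicted_direction "greater" or "less" (x relative to y);
#'   required for one-tailed tests.
#' @return A \code{comparison_result} with effect size
#'   \code{r = sqrt(t^2/(t^2 + df))}.
#' @examples
#' pooled_t_test(n1 = 71, mean1 = 27.04, sd1 = 12.15,
#'               n2 = 72, mean2 = 29.89, sd2 = 14.63)  # t(141) = -1.267
#' @export
pooled_t_test <- function(x = NULL, y = NULL,
                          n1 = NULL, mean1 = NULL, sd1 = NULL,
                          n2 = NULL, mean2 = NULL, sd2 = NULL,
                          tails = c("two", "one"),
                          predicted_direction = "greater") {
  tails <- match.arg(tails)
  if (!is.null(x)) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    n1 <- length(x); mean1 <- mean(x); sd1 <- stats::sd(x)
    n2 <- length(y); mean2 <- mean(y); sd2 <- stats::sd(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, is.finite(sd1), is.finite(sd2))
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2)
      return(comparison_result("pooled t", 0, df = df, n = n1 + n2,
                               p_value = 1, tails = tails, effect_size_r = 0))
    stop("zero pooled variance with unequal means: t is infinite",
         call. = FALSE)
  }
  t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_two <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p <- tail_p(p_two, sign(t_stat), tails, predicted_direction)
  comparison_result("pooled t", t_stat, df = df, n = n1 + n2, p_value = p,
                    tails = tails,
                    effect_size_r = effect_size_from_t(t_stat, df),
                    direction = if (t_stat >= 0) "greater" else "less")
}

#' Mann-Whitney U test, SPSS reporting convention
#'
#' U is computed from the rank sum of the first group
#' (\code{U1 = n1 n2 + n1(n1+1)/2 - R1}) and reported as
#' \code{min(U1, n1 n2 - U1)}, the convention of SPSS output. By default
#' the p-value uses the exact null distribution when both groups have at
#' most 20 observations and there are no ties, and otherwise the normal
#' approximation with the tie-corrected variance and a continuity
#' correction. Effect size \code{r = |Z| / sqrt(N)} with Z always the
#' uncorrected normal-approximation statistic.
#'
#' @param x,y data vectors for the two groups.
#' @param tails "two" or "one".
#' @param predicted_direction "greater" or "less" (x relative to y).
#' @param p_method "auto" (exact where admissible), "exact", or
#'   "approximate".
#' @return A \code{comparison_result}; \code{statistic} is the reported U,
#'   \code{n} the total N.
#' @export
mann_whitney_u <- function(x, y, tails = c("two", "one"),
                           predicted_direction = "greater",
                           p_method = c("auto", "exact", "approximate")) {
  tails <- match.arg(tails)
  p_method <- match.arg(p_method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  r1 <- sum(r[seq_len(n1)])
  u1 <- n1 * n2 + n1 * (n1 + 1) / 2 - r1
  u_rep <- min(u1, n1 * n2 - u1)
  ties <- table(r)
  has_ties <- any(ties > 1)
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    warning("all values tied across both groups; Z undefined, r set to 0")
    return(comparison_result("Mann-Whitney U", u_rep, n = n, p_value = 1,
                             tails = tails, effect_size_r = 0,
                             note = "degenerate: all observations tied"))
  }
  z <- (u1 - mu) / sqrt(sigma2)
  use_exact <- switch(p_method,
                      exact = TRUE,
                      approximate = FALSE,
                      auto = !has_ties && n1 <= 20 && n2 <= 20)
  if (use_exact) {
    if (has_ties)
      stop("exact p undefined in the presence of ties", call. = FALSE)
    # exact null distribution of U
    p_lo <- stats::pwilcox(u1, n1, n2)
    p_hi <- stats::pwilcox(u1 - 1, n1, n2, lower.tail = FALSE)
    p_two <- min(1, 2 * min(p_lo, p_hi))
  } else {
    # continuity-corrected; Z itself stays uncorrected for the effect size
    z_cc <- max(0, abs(u1 - mu) - 0.5) / sqrt(sigma2)
    p_two <- min(1, 2 * stats::pnorm(z_cc, lower.tail = FALSE))
  }
  # u1 below its mean means x tends to exceed y (fewer y-over-x precedences)
  obs_sign <- sign(mu - u1)
  p <- tail_p(p_two, obs_sign, tails, predicted_direction)
  comparison_result("Mann-Whitney U", u_rep, n = n, p_value = p,
                    tails = tails,
                    effect_size_r = effect_size_from_z(z, n),
                    direction = if (obs_sign >= 0) "greater" else "less")
}

#' One-sample t test
#'
#' \code{t = (mean - mu0) / (SD / sqrt(n))}, df = n - 1.
#'
#' @param values data vector, n >= 2.
#' @param mu0 null-hypothesis mean.
#' @param tails,predicted_direction as in [pooled_t_test()] ("greater"
#'   means the population mean exceeds \code{mu0}).
#' @return A \code{comparison_result}.
#' @export
one_sample_t <- function(values, mu0 = 0, tails = c("two", "one"),
                         predicted_direction = "greater") {
  tails <- match.arg(tails)
  values <- values[is.finite(values)]
  n <- length(values)
  stopifnot(n >= 2)
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation: t undefined", call. = FALSE)
  t_stat <- (mean(values) - mu0) / (s / sqrt(n))
  p_two <- 2 * stats::pt(abs(t_stat), n - 1, lower.tail = FALSE)
  p <- tail_p(p_two, sign(t_stat), tails, predicted_direction)
  comparison_result("one-sample t", t_stat, df = n - 1, n = n, p_value = p,
                    tails = tails,
                    effect_size_r = effect_size_from_t(t_stat, n - 1),
                    direction = if (t_stat >= 0) "greater" else "less")
}

#' Correlation-scale effect sizes
#'
#' Conversions of test statistics to the correlation-scale effect size r:
#' \code{r = sqrt(t^2 / (t^2 + df))}, \code{r = |Z| / sqrt(N)},
#' \code{r = sqrt(chi2 / N)}. These are the standard conversions used to
#' report diagnostic effect magnitudes alongside p-values.
#'
#' @param t,df t statistic and its degrees of freedom.
#' @param z,n Z statistic and total observation count.
#' @param chi2 chi-square statistic.
#' @return Effect size r in [0, 1).
#' @examples
#' effect_size_from_t(2.656, 139)  # 0.22
#' @export
effect_size_from_t <- function(t, df) {
  stopifnot(df > 0)
  sqrt(t^2 / (t^2 + df))
}

#' @rdname effect_size_from_t
#' @export
effect_size_from_z <- function(z, n) {
  stopifnot(n > 0)
  abs(z) / sqrt(n)
}

#' @rdname effect_size_from_t
#' @export
effect_size_from_chi2 <- function(chi2, n) {
  stopifnot(n > 0, chi2 >= 0)
  sqrt(chi2 / n)
}

#' Correlation screen of expression against covariates
#'
#' Correlates each expression column with each covariate, Spearman rank
#' correlation by default (average ranks for ties, asymptotic two-tailed
#' p), pairwise-complete handling of missing values. A constant column
#' yields NA ("undefined, reported as missing").
#'
#' @param expression data.frame or matrix, samples x genes.
#' @param covariates data.frame or matrix, samples x covariates (same row
#'   order).
#' @param method "spearman" (default) or "pearson".
#' @return A list of two genes x covariates matrices, \code{r} and \code{p}.
#' @export
correlation_screen <- function(expression, covariates,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  expression <- as.data.frame(expression)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(expression) == nrow(covariates))
  r <- p <- matrix(NA_real_, ncol(expression), ncol(covariates),
                   dimnames = list(names(expression), names(covariates)))
  for (i in seq_len(ncol(expression))) {
    for (j in seq_len(ncol(covariates))) {
      xi <- expression[[i]]; yj <- as.numeric(covariates[[j]])
      ok <- is.finite(xi) & is.finite(yj)
      if (sum(ok) < 3L) next
      if (stats::sd(xi[ok]) == 0 || stats::sd(yj[ok]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(xi[ok], yj[ok], method = method, exact = FALSE))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, method = method)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits \code{values ~ a * b} and reports F, df and p per factor and for
#' the interaction, using Type II sums of squares so unbalanced designs are
#' handled sensibly, plus Tukey honest-significant-difference contrasts on
#' each factor's means.
#'
#' @param values numeric response.
#' @param a,b factors (coerced); each needs >= 2 levels.
#' @return A list: \code{table} (term, F, df1, df2, p), \code{posthoc}
#'   (TukeyHSD), \code{fit} (the underlying lm).
#' @export
two_way_anova <- function(values, a, b) {
  a <- factor(a); b <- factor(b)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("each factor needs at least 2 levels", call. = FALSE)
  d <- data.frame(y = values, a = a, b = b)
  fit <- stats::lm(y ~ a * b, data = d)
  at <- car::Anova(fit, type = 2)
  df_res <- at[["Df"]][rownames(at) == "Residuals"]
  keep <- rownames(at) != "Residuals"
  tab <- data.frame(term = rownames(at)[keep],
                    F = at[["F value"]][keep],
                    df1 = at[["Df"]][keep],
                    df2 = df_res,
                    p = at[["Pr(>F)"]][keep],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  ph <- tryCatch(stats::TukeyHSD(stats::aov(y ~ a * b, data = d),
                                 which = c("a", "b")),
                 error = function(e) NULL)
  list(table = tab, posthoc = ph, fit = fit)
}
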