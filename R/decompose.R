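#' Hierarchical variance decomposition: ligand versus tissue pH
#'
#' Quantifies how much variance in a dependent transcript (e.g. an
#' interneuron or spine marker) is explained by a predictor transcript
#' alone, by tissue pH alone, and by the predictor over and above pH.
#' Three ordinary-least-squares fits are made on listwise-complete cases:
#' \code{y ~ predictor}, \code{y ~ ph} and \code{y ~ ph + predictor}. The
#' increment \code{delta_r2 = R2(ph + predictor) - R2(ph)} is tested with
#' the usual F-change statistic for a one-predictor step. Standardized
#' coefficients (beta, on z-scored variables) are reported from both the
#' single-predictor models and the two-predictor model, labelled, since
#' published tables do not always say which model their beta comes from.
#'
#' @param dependent numeric response (transcript relative quantities).
#' @param predictor numeric predictor transcript.
#' @param ph tissue pH per sample.
#' @param labels optional character vector of length 3 naming dependent,
#'   predictor and pH for printing.
#' @return An object of class \code{regression_decomposition}: list with
#'   \code{r2_predictor_alone}, \code{r2_ph_alone}, \code{r2_full},
#'   \code{delta_r2}, \code{f_change} (F, df1, df2, p),
#'   \code{beta_single} and \code{beta_joint} (standardized coefficients
#'   with t-test p-values), \code{n}, \code{stars}.
#' @examples
#' set.seed(2)
#' ph <- rnorm(70, 6.6, 0.28)
#' lig <- -0.5 * scale(ph)[, 1] + rnorm(70, 0, 0.8)
#' sst <- 0.6 * scale(ph)[, 1] - 0.3 * lig + rnorm(70, 0, 0.7)
#' fit_decomposition(sst, lig, ph, labels = c("SST", "ligand", "pH"))
#' @export
fit_decomposition <- function(dependent, predictor, ph, labels = NULL) {
  labels <- labels %||% c("dependent", "predictor", "pH")
  ok <- is.finite(dependent) & is.finite(predictor) & is.finite(ph)
  y <- dependent[ok]; x <- predictor[ok]; z <- ph[ok]
  n <- length(y)
  if (n < 4L) stop("need >= 4 complete cases", call. = FALSE)
  if (stats::sd(y) == 0) stop("zero-variance dependent", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(z) == 0 ||
      abs(stats::cor(x, z)) > 1 - 1e-12)
    stop("predictors constant or perfectly collinear", call. = FALSE)

  ys <- as.numeric(scale(y)); xs <- as.numeric(scale(x))
  zs <- as.numeric(scale(z))
  fit_x <- stats::lm(ys ~ xs)
  fit_z <- stats::lm(ys ~ zs)
  fit_zx <- stats::lm(ys ~ zs + xs)
  r2 <- function(f) summary(f)$r.squared
  r2_x <- r2(fit_x); r2_z <- r2(fit_z); r2_full <- r2(fit_zx)
  delta <- r2_full - r2_z

  df2 <- n - 3
  f_change <- (delta / 1) / ((1 - r2_full) / df2)
  p_change <- stats::pf(f_change, 1, df2, lower.tail = FALSE)

  beta_of <- function(f, term) {
    s <- summary(f)$coefficients
    c(beta = unname(s[term, "Estimate"]), p = unname(s[term, "Pr(>|t|)"]))
  }
  beta_single <- rbind(predictor = beta_of(fit_x, "xs"),
                       ph = beta_of(fit_z, "zs"))
  beta_joint <- rbind(predictor = beta_of(fit_zx, "xs"),
                      ph = beta_of(fit_zx, "zs"))

  stars <- function(p) if (!is.finite(p)) "" else
    if (p < 0.001) "***" else if (p < 0.01) "**" else
      if (p < 0.05) "*" else ""
  structure(list(labels = labels,
                 r2_predictor_alone = r2_x, r2_ph_alone = r2_z,
                 r2_full = r2_full, delta_r2 = delta,
                 f_change = c(F = f_change, df1 = 1, df2 = df2, p = p_change),
                 beta_single = beta_single, beta_joint = beta_joint,
                 n = n,
                 stars = c(delta_r2 = stars(p_change),
                           beta_predictor = stars(beta_joint["predictor", "p"]),
                           beta_ph = stars(beta_joint["ph", "p"]))),
            class = "regression_decomposition")
}

#' @export
print.regression_decomposition <- function(x, digits = 3, ...) {
  l <- x$labels
  cat(sprintf("Hierarchical decomposition of %s (n = %d)\n", l[1L], x$n))
  cat(sprintf("  R2 %s alone:  %.*f%s\n", l[2L], digits,
              x$r2_predictor_alone, ""))
  cat(sprintf("  R2 %s alone:  %.*f\n", l[3L], digits, x$r2_ph_alone))
  cat(sprintf("  delta R2 (%s over %s): %.*f%s  [F(1,%d) = %.*g, p = %.*g]\n",
              l[2L], l[3L], digits, x$delta_r2, x$stars[["delta_r2"]],
              x$f_change[["df2"]], digits, x$f_change[["F"]], digits,
              x$f_change[["p"]]))
  cat(sprintf("  beta (single-predictor models): %s %.*f, %s %.*f\n",
              l[2L], digits, x$beta_single["predictor", "beta"],
              l[3L], digits, x$beta_single["ph", "beta"]))
  cat(sprintf("  beta (joint model): %s %.*f%s, %s %.*f%s\n",
              l[2L], digits, x$beta_joint["predictor", "beta"],
              x$stars[["beta_predictor"]],
              l[3L], digits, x$beta_joint["ph", "beta"],
              x$stars[["beta_ph"]]))
  invisible(x)
}

#' Decomposition table across several dependent transcripts
#'
#' Runs [fit_decomposition()] for each dependent gene against one predictor
#' gene and tissue pH, returning the familiar published-table shape: one
#' row per dependent with R2 per block, the delta R2 increment, and
#' standardized betas.
#'
#' @param expression wide data.frame of relative quantities, one column per
#'   gene, one row per sample.
#' @param dependents character vector of dependent gene columns.
#' @param predictor name of the predictor gene column.
#' @param ph tissue pH vector (same row order).
#' @return data.frame: dependent, n, r2_predictor, r2_ph, delta_r2,
#'   delta_r2_p, beta_predictor_single, beta_predictor_joint, beta_ph_single,
#'   beta_ph_joint, stars.
#' @export
decomposition_table <- function(expression, dependents, predictor, ph) {
  stopifnot(predictor %in% names(expression),
            all(dependents %in% names(expression)))
  rows <- lapply(dependents, function(dep) {
    f <- fit_decomposition(expression[[dep]], expression[[predictor]], ph,
                           labels = c(dep, predictor, "pH"))
    data.frame(dependent = dep, n = f$n,
               r2_predictor = f$r2_predictor_alone,
               r2_ph = f$r2_ph_alone, delta_r2 = f$delta_r2,
               delta_r2_p = f$f_change[["p"]],
               beta_predictor_single = f$beta_single["predictor", "beta"],
               beta_predictor_joint = f$beta_joint["predictor", "beta"],
               beta_ph_single = f$beta_single["ph", "beta"],
               beta_ph_joint = f$beta_joint["ph", "beta"],
               stars_delta = f$stars[["delta_r2"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
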