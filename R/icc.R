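# Inter-rater consistency of the volume measurements: intraclass
# correlation for average measures from the two-way ANOVA mean squares of a
# targets-by-raters table.

#' Intraclass correlation for average measures
#'
#' Computes the ICC of the rater-averaged measurement from the two-way mean
#' squares of a complete targets-by-raters table: `MSR` between targets,
#' `MSC` between raters, `MSE` residual. The default two-way random-effects
#' absolute-agreement model is
#' `(MSR - MSE) / (MSR + (MSC - MSE)/n)`; the mixed consistency model is
#' `(MSR - MSE) / MSR` and ignores systematic rater offsets. Significance
#' is the F test of `MSR/MSE`.
#'
#' @param ratings numeric matrix or data frame, rows = targets (cases or
#'   structures), columns = raters; at least 2 of each, no missing cells.
#' @param model `"two_way_random_absolute"` (default) or
#'   `"two_way_mixed_consistency"`.
#' @return list of class `canal_icc`: `icc`, `model`, `f`, `df1`, `df2`,
#'   `p`, `label` (see [consistency_label()]), `ms` (the mean squares).
#' @export
icc_average <- function(ratings,
                        model = c("two_way_random_absolute",
                                  "two_way_mixed_consistency")) {
  model <- match.arg(model)
  x <- as.matrix(ratings)
  if (!is.numeric(x) || anyNA(x)) stop("ratings must be a complete numeric table")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 targets and 2 raters")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, grand^2))
    stop("zero between-target variance: ICC undefined")
  icc <- switch(model,
                two_way_random_absolute = (msr - mse) / (msr + (msc - mse) / n),
                two_way_mixed_consistency = (msr - mse) / msr)
  f <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE) else 0
  structure(list(icc = icc, model = model, f = f, df1 = df1, df2 = df2,
                 p = p, label = consistency_label(icc),
                 ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k),
            class = "canal_icc")
}

#' @export
print.canal_icc <- function(x, ...) {
  cat(sprintf("<canal_icc> ICC(avg, %s) = %.4f (%s), F(%d, %d) = %.3g, p = %.3g\n",
              x$model, x$icc, x$label, x$df1, x$df2, x$f, x$p))
  invisible(x)
}

#' Qualitative consistency band of a coefficient
#'
#' Bands: below 0.4 poor, 0.4 to below 0.80 general, 0.80 and above good.
#'
#' @param coefficient a value in [-1, 1].
#' @return `"poor"`, `"general"` or `"good"`.
#' @export
consistency_label <- function(coefficient) {
  if (!is.finite(coefficient) || coefficient < -1 || coefficient > 1)
    stop("coefficient must lie in [-1, 1]")
  if (coefficient >= 0.80) "good" else if (coefficient >= 0.4) "general" else "poor"
}
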