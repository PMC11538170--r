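#' Ordinary least-squares linearity assessment
#'
#' Regresses `y` on `x` and reports slope, intercept, Pearson r and the
#' two-sided p-value for r via the t transform with n - 2 degrees of
#' freedom, the layout of the method-comparison tables.
#'
#' @param x,y paired numeric vectors, n >= 3, x nonconstant.
#' @return List with `slope`, `intercept`, `r`, `p`, `n`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("linear_fit needs at least 3 pairs")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Shrout-Fleiss ICC(1,1) for k = 2 ratings per target (a reference
#' method and a candidate method measuring the same subjects):
#' `(BMS - WMS) / (BMS + (k - 1) WMS)` with between- and within-target
#' mean squares from the one-way ANOVA decomposition.  The 95% confidence
#' interval uses exact two-sided F bounds and the p-value is from
#' `F = BMS / WMS` on (n - 1, n (k - 1)) degrees of freedom.  Unlike
#' Pearson r, ICC(1,1) penalizes systematic offsets: `icc(x, x + c) < 1`
#' even though `r = 1`.
#'
#' @param x,y paired measurements of the same n >= 3 targets.
#' @param conf_level confidence level of the interval (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `p`, `F`, `n`, `k`.
#' @export
icc_1_1 <- function(x, y, conf_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("icc_1_1 needs at least 3 paired targets")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  tm <- rowMeans(dat)
  if (sum((dat - grand)^2) == 0) stop("zero total variance; ICC undefined")
  bms <- k * sum((tm - grand)^2) / (n - 1)
  wms <- sum((dat - tm)^2) / (n * (k - 1))
  icc <- (bms - wms) / (bms + (k - 1) * wms)
  Fobs <- bms / max(wms, .Machine$double.xmin)
  alpha <- 1 - conf_level
  df1 <- n - 1; df2 <- n * (k - 1)
  FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
  FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
  list(icc = icc,
       ci_low = (FL - 1) / (FL + k - 1),
       ci_high = (FU - 1) / (FU + k - 1),
       p = stats::pf(Fobs, df1, df2, lower.tail = FALSE),
       F = Fobs, n = n, k = k)
}

#' Full two-method agreement panel
#'
#' Combines [linear_fit()] (linearity) and [icc_1_1()] (absolute
#' agreement) for one candidate-vs-reference comparison.
#'
#' @inheritParams icc_1_1
#' @return An object of class `method_comparison`.
#' @export
method_comparison <- function(x, y, conf_level = 0.95) {
  lf <- linear_fit(x, y)
  ic <- icc_1_1(x, y, conf_level)
  structure(c(lf, ic[c("icc", "ci_low", "ci_high", "p", "F")] |>
                stats::setNames(c("icc", "icc_ci_low", "icc_ci_high",
                                  "icc_p", "icc_F"))),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("n = %d pairs\n", x$n))
  cat(sprintf("  linearity: slope %.3f, intercept %.3f, r = %.3f (p = %.3g)\n",
              x$slope, x$intercept, x$r, x$p))
  cat(sprintf("  agreement: ICC(1,1) = %.3f [%.3f, %.3f] (p = %.3g)\n",
              x$icc, x$icc_ci_low, x$icc_ci_high, x$icc_p))
  invisible(x)
}

#' Cohort-level method evaluation report
#'
#' Compares one or more candidate measurement sets against a reference
#' over a cohort, per region and per quantity (High / Low / AI), in the
#' shape of the published method-comparison tables: slope, intercept, r,
#' p, ICC(1,1) with its CI and F-test p-value.
#'
#' @param reference data frame with columns `subject`, `region`, `high`,
#'   `low`, `ai` holding the reference (truth or MRI-based) values.
#' @param candidates named list of data frames with the same columns, one
#'   per candidate method.
#' @return Data frame with one row per method x region x quantity.
#' @export
evaluate_methods <- function(reference, candidates) {
  stopifnot(is.data.frame(reference), is.list(candidates),
            !is.null(names(candidates)))
  need <- c("subject", "region", "high", "low", "ai")
  if (!all(need %in% names(reference)))
    stop("reference needs columns: ", paste(need, collapse = ", "))
  rows <- list()
  for (meth in names(candidates)) {
    cand <- candidates[[meth]]
    if (!all(need %in% names(cand)))
      stop("candidate '", meth, "' needs columns: ",
           paste(need, collapse = ", "))
    merged <- merge(reference, cand, by = c("subject", "region"),
                    suffixes = c("_ref", "_cand"))
    for (rg in unique(merged$region)) {
      sub <- merged[merged$region == rg, ]
      for (qty in c("high", "low", "ai")) {
        xv <- sub[[paste0(qty, "_ref")]]
        yv <- sub[[paste0(qty, "_cand")]]
        mc <- method_comparison(xv, yv)
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, region = rg, quantity = qty, n = mc$n,
          slope = mc$slope, intercept = mc$intercept, r = mc$r, p = mc$p,
          icc = mc$icc, icc_ci_low = mc$icc_ci_low,
          icc_ci_high = mc$icc_ci_high, icc_p = mc$icc_p,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
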