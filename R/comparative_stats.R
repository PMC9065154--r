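# Shape-function inference: standardized major axis regression, Welch's
# two-sample test, and grouped five-number summaries.

sma_fit_xy <- function(x, y) {
  n <- length(x)
  if (n < 3) abort("SMA regression needs at least 3 points")
  if (sd(x) == 0 || sd(y) == 0) abort("SMA regression needs positive variance in x and y")
  r <- cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p_corr <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
  list(slope = slope, intercept = intercept, r = r, p_corr = p_corr, n = n)
}

#' Standardized major axis (SMA) regression
#'
#' Fits the standardized (reduced) major axis line, the symmetric
#' line-fitting convention for structural relations between two traits:
#' `slope = sign(r) * sd(y) / sd(x)`, with the line through the centroid.
#' Significance is the Pearson correlation test (t statistic on n - 2 df).
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the predictor-convention and
#'   response-convention variables (the fit itself is symmetric: swapping
#'   them inverts the slope).
#' @return An object of class `sma_fit` with `slope`, `intercept`, `r`,
#'   `p_corr`, `n`, `residuals` (vertical-convention, see
#'   [sma_residual()]), and the fitted data.
#' @export
sma_fit <- function(data, x, y) {
  xq <- enquo(x); yq <- enquo(y)
  xv <- rlang::eval_tidy(xq, data)
  yv <- rlang::eval_tidy(yq, data)
  ok <- is.finite(xv) & is.finite(yv)
  fit <- sma_fit_xy(xv[ok], yv[ok])
  fit$x_name <- as_name(xq)
  fit$y_name <- as_name(yq)
  fit$data <- tibble(x = xv[ok], y = yv[ok])
  if ("specimen" %in% names(data)) fit$data$specimen <- data$specimen[ok]
  fit$residuals <- fit$data$y - (fit$intercept + fit$slope * fit$data$x)
  class(fit) <- "sma_fit"
  fit
}

#' Residuals from an SMA line
#'
#' By default the signed vertical (y-direction) deviation
#' `y - (intercept + slope * x)`; set `perpendicular = TRUE` for the
#' signed perpendicular distance to the line.
#'
#' @param fit An `sma_fit` object.
#' @param x,y Coordinates of the point(s); defaults to the fitted data.
#' @param perpendicular Use the perpendicular-distance convention.
#' @return Numeric vector of signed residuals.
#' @export
sma_residual <- function(fit, x = NULL, y = NULL, perpendicular = FALSE) {
  stopifnot(inherits(fit, "sma_fit"))
  if (is.null(x)) { x <- fit$data$x; y <- fit$data$y }
  v <- y - (fit$intercept + fit$slope * x)
  if (perpendicular) v / sqrt(1 + fit$slope^2) else v
}

#' @export
print.sma_fit <- function(x, ...) {
  cat("Standardized major axis regression:",
      x$y_name, "~", x$x_name, "\n")
  cat(sprintf("  slope %.5g  intercept %.5g  r %.4f  p(corr) %.4g  n %d\n",
              x$slope, x$intercept, x$r, x$p_corr, x$n))
  invisible(x)
}

#' @describeIn sma_fit Coefficients in broom convention (`term`,
#'   `estimate`).
#' @param ... Unused.
#' @export
tidy.sma_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @describeIn sma_fit One-row fit summary (`slope`, `intercept`, `r`,
#'   `r_squared`, `p_corr`, `n`).
#' @export
glance.sma_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r = x$r,
         r_squared = x$r^2, p_corr = x$p_corr, n = x$n)
}

#' Welch's two-sample t test
#'
#' Unequal-variance comparison of a value between two groups, with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value
#' (delegated to [stats::t.test()]). The t statistic is
#' `(mean(first) - mean(second))` over the pooled standard error, where
#' "first" is the first group level in order of appearance (or factor
#' level order).
#'
#' @param data A data frame.
#' @param value Unquoted numeric column to compare.
#' @param group Unquoted grouping column with exactly two levels.
#' @return One-row tibble: `group_a`, `group_b`, `mean_a`, `mean_b`,
#'   `t`, `df`, `p`.
#' @export
welch_test <- function(data, value, group) {
  vq <- enquo(value); gq <- enquo(group)
  v <- rlang::eval_tidy(vq, data)
  g <- rlang::eval_tidy(gq, data)
  lev <- if (is.factor(g)) levels(droplevels(g)) else unique(as.character(g))
  if (length(lev) != 2) abort("welch_test needs exactly two groups")
  a <- v[g == lev[1]]; b <- v[g == lev[2]]
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(group_a = lev[1], group_b = lev[2],
                    mean_a = mean(a), mean_b = mean(b),
                    t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    abort("zero variance in both groups")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(group_a = lev[1], group_b = lev[2],
         mean_a = mean(a), mean_b = mean(b),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Five-number summaries by group
#'
#' Minimum, lower quartile, median, upper quartile, and maximum per group
#' (boxplot statistics). Quartiles use linear interpolation between order
#' statistics ([stats::quantile()] type 7), the mainstream default;
#' hinge-based boxplot conventions differ slightly.
#'
#' @param data A data frame.
#' @param value Unquoted numeric column to summarize.
#' @param group Unquoted grouping column.
#' @return Tibble with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
group_summary <- function(data, value, group) {
  vq <- enquo(value); gq <- enquo(group)
  v <- rlang::eval_tidy(vq, data)
  g <- as.character(rlang::eval_tidy(gq, data))
  if (any(is.na(v))) abort("missing values in the summarized column")
  tibble(value = v, group = g) |>
    summarise(
      n = dplyr::n(),
      min = min(.data$value),
      q1 = unname(quantile(.data$value, 0.25, type = 7)),
      median = unname(quantile(.data$value, 0.5, type = 7)),
      q3 = unname(quantile(.data$value, 0.75, type = 7)),
      max = max(.data$value),
      .by = "group"
    )
}
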