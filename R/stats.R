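#' Group summary with a 1.96-standard-error half-width
#'
#' Mean, median and the half-width of a mean +/- 1.96 SE interval (the
#' error-bar convention used throughout the group comparisons), with SE
#' computed from the unbiased (n-1) sample SD. The median for even n is the
#' midpoint of the two central order statistics.
#'
#' @param values Numeric vector (n >= 1; the half-width needs n >= 2 and is
#'   `NA` for a single value).
#' @param label Group label.
#' @return data.frame row: `group_label`, `n`, `mean`, `median`,
#'   `halfwidth_196se`.
#' @examples
#' summarize_group(halophilic_archaea$gc_percent, "halophilic_archaea")
#' @export
summarize_group <- function(values, label = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("'values' must be a non-empty numeric vector without NAs")
  }
  n <- length(values)
  hw <- if (n >= 2L) 1.96 * stats::sd(values) / sqrt(n) else NA_real_
  data.frame(
    group_label = label, n = n, mean = mean(values),
    median = stats::median(values), halfwidth_196se = hw,
    stringsAsFactors = FALSE
  )
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. If both groups have zero variance and
#' equal means the test is degenerate and returns statistic 0, p = 1 by
#' convention.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List: `statistic`, `df`, `p_value`, `estimate` (mean(a) -
#'   mean(b)).
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, df = length(a) + length(b) - 2,
                  p_value = 1, estimate = 0))
    }
    stop("both groups have zero variance with different means: ",
         "the Welch statistic is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    estimate = mean(a) - mean(b)
  )
}

#' One-way ANOVA with Tukey HSD pairwise contrasts
#'
#' Fixed-effects one-way analysis of variance across k groups followed by
#' all-pairs Tukey honest-significant-difference comparisons (studentized
#' range on the pooled error term), the post-hoc procedure used for the
#' intergroup bipyrimidine and photoreactivity comparisons. All k(k-1)/2
#' unordered pairs are reported; the pairwise `statistic` is the
#' t-style ratio estimate / SE(difference) on the pooled error.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values` (>= 2 distinct
#'   groups, each with >= 2 observations).
#' @return List: `f_statistic`, `df_between`, `df_within`, `p_value`, and
#'   `pairwise` -- a data.frame with `group_a`, `group_b`, `estimate`
#'   (mean(a) - mean(b)), `statistic`, `p_adjusted`.
#' @export
anova_tukey <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (length(values) != length(groups)) {
    stop("'values' and 'groups' must have the same length")
  }
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$groups
  pair_names <- rownames(tk)
  ab <- do.call(rbind, strsplit(pair_names, "-", fixed = TRUE))
  mse <- tab["Residuals", "Mean Sq"]
  na <- as.numeric(sizes[ab[, 1L]])
  nb <- as.numeric(sizes[ab[, 2L]])
  se <- sqrt(mse * (1 / na + 1 / nb))
  list(
    f_statistic = tab[1L, "F value"],
    df_between = tab[1L, "Df"],
    df_within = tab["Residuals", "Df"],
    p_value = tab[1L, "Pr(>F)"],
    pairwise = data.frame(
      group_a = ab[, 1L], group_b = ab[, 2L],
      estimate = unname(tk[, "diff"]),
      statistic = unname(tk[, "diff"] / se),
      p_adjusted = unname(tk[, "p adj"]),
      stringsAsFactors = FALSE
    )
  )
}

#' Regression of photoreactivity on G+C content
#'
#' Ordinary least squares of P_g on G+C percent together with the Pearson
#' product-moment correlation and its two-sided test -- the analysis behind
#' the headline negative P_g vs G+C relationship. For simple linear
#' regression R-squared equals the squared Pearson correlation, which the
#' object's invariant check enforces.
#'
#' @param gc_percent Numeric G+C contents (percent).
#' @param pg Numeric P_g scores, same length (n >= 3; neither variable may
#'   be constant).
#' @param data Optional data.frame with columns `gc_percent` and `pg`
#'   (e.g. a score table from [score_files()]), used if `gc_percent`/`pg`
#'   are missing.
#' @return A `pg_regression` object with fields `slope`, `intercept`,
#'   `r_squared`, `pearson_r`, `p_value`, `n_points` and the underlying
#'   `lm` fit; supports `print()`, `summary()`, `coef()`, `predict()`,
#'   `residuals()` and `plot()`.
#' @examples
#' fit <- regress_pg_gc(c(30, 45, 60, 70), c(0.29, 0.26, 0.22, 0.20))
#' coef(fit)
#' @export
regress_pg_gc <- function(gc_percent, pg, data = NULL) {
  if (!is.null(data) && missing(gc_percent)) {
    gc_percent <- data$gc_percent
    pg <- data$pg
  }
  gc_percent <- as.numeric(gc_percent)
  pg <- as.numeric(pg)
  if (length(gc_percent) != length(pg)) {
    stop("'gc_percent' and 'pg' must have the same length")
  }
  if (length(pg) < 3L) stop("need at least 3 points")
  if (stats::var(gc_percent) == 0) stop("'gc_percent' is constant: slope undefined")
  if (stats::var(pg) == 0) {
    stop("'pg' is constant: Pearson correlation undefined")
  }
  d <- data.frame(gc_percent = gc_percent, pg = pg)
  fit <- stats::lm(pg ~ gc_percent, data = d)
  ct <- stats::cor.test(d$gc_percent, d$pg, method = "pearson")
  # exactly collinear input is legitimate here; summary.lm's "essentially
  # perfect fit" warning concerns coefficient tests we do not report
  r2 <- suppressWarnings(summary(fit)$r.squared)
  r <- unname(ct$estimate)
  stopifnot(abs(r2 - r^2) < 1e-10)
  structure(
    list(
      slope = unname(stats::coef(fit)[["gc_percent"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      pearson_r = r,
      p_value = ct$p.value,
      n_points = nrow(d),
      model = fit
    ),
    class = "pg_regression"
  )
}

#' @export
print.pg_regression <- function(x, digits = 4, ...) {
  cat("Linear regression of P_g on G+C content (%)\n")
  cat(sprintf("  P_g = %.*g %+.*g * GC  (n = %d)\n",
              digits, x$intercept, digits, x$slope, x$n_points))
  cat(sprintf("  R^2 = %.*g, Pearson r = %.*g, p = %.3g\n",
              digits, x$r_squared, digits, x$pearson_r, x$p_value))
  invisible(x)
}

#' @export
summary.pg_regression <- function(object, ...) {
  summary(object$model, ...)
}

#' @export
coef.pg_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.pg_regression <- function(object, gc_percent = NULL, ...) {
  if (is.null(gc_percent)) return(stats::predict(object$model, ...))
  stats::predict(object$model, newdata = data.frame(gc_percent = gc_percent))
}

#' @export
residuals.pg_regression <- function(object, ...) {
  stats::residuals(object$model, ...)
}

#' @export
plot.pg_regression <- function(x, ...) {
  d <- x$model$model
  plot(d$gc_percent, d$pg, xlab = "G+C content (%)",
       ylab = expression(P[g]), ...)
  graphics::abline(x$model, col = "red3")
  invisible(x)
}
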