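#' Fit the developmental connectivity sigmoid
#'
#' Four-parameter logistic fit of connection probability against age:
#' `p(age) = lo + (hi - lo) / (1 + exp(-slope * (age - mid)))`, with the
#' asymptotes bounded to `[0, 1]` (probabilities). Initialization is a
#' deterministic multi-start over midpoint (age quantiles) and slope
#' (both signs, several magnitudes); the refined fit with the smallest
#' residual sum of squares wins. All-equal probabilities yield a flagged
#' degenerate fit with zero slope.
#'
#' @param age_days ages, days (>= 4 points spanning the transition).
#' @param probability connection probabilities in `[0, 1]`.
#' @return object of class `sigmoid_fit`: `coef` (lo, hi, mid, slope),
#'   `fitted`, `rss`, `degenerate`.
#' @export
fit_connectivity_sigmoid <- function(age_days, probability) {
  if (length(age_days) != length(probability)) {
    stop_invalid("age and probability must have equal length")
  }
  if (length(age_days) < 4L) stop_invalid("need >= 4 points")
  if (any(probability < 0 | probability > 1)) {
    stop_invalid("probabilities must lie in [0, 1]")
  }
  if (diff(range(probability)) == 0) {
    cf <- c(lo = probability[1], hi = probability[1], mid = mean(age_days),
            slope = 0)
    return(structure(list(coef = cf, fitted = probability, rss = 0,
                          degenerate = TRUE), class = "sigmoid_fit"))
  }
  df <- data.frame(a = age_days, y = probability)
  span <- diff(range(age_days))
  mids <- stats::quantile(age_days, c(0.25, 0.5, 0.75), names = FALSE)
  slopes <- c(-4, -1, 1, 4) / span * 4
  best <- NULL
  for (mid0 in mids) for (sl0 in slopes) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ lo + (hi - lo) / (1 + exp(-slope * (a - mid))),
        data = df,
        start = list(lo = max(min(df$y), 0), hi = min(max(df$y), 1),
                     mid = mid0, slope = sl0),
        lower = c(0, 0, min(age_days) - span, -Inf),
        upper = c(1, 1, max(age_days) + span, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop(errorCondition("sigmoid fit failed from every start",
                        class = c("axq_fit_failure", "error")))
  }
  cf <- stats::coef(best$fit)
  # the 4PL is invariant under (lo, hi, slope) -> (hi, lo, -slope);
  # report the canonical orientation with lo <= hi
  if (cf[["lo"]] > cf[["hi"]]) {
    cf[c("lo", "hi")] <- cf[c("hi", "lo")]
    cf[["slope"]] <- -cf[["slope"]]
  }
  structure(list(coef = c(lo = unname(cf["lo"]), hi = unname(cf["hi"]),
                          mid = unname(cf["mid"]), slope = unname(cf["slope"])),
                 fitted = stats::fitted(best$fit), rss = best$rss,
                 degenerate = FALSE), class = "sigmoid_fit")
}

#' D'Agostino-Pearson K-squared omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into K2 = Z1^2 + Z2^2, referred to a chi-squared
#' distribution with 2 df. Requires n >= 8 for the kurtosis
#' approximation.
#'
#' @param x numeric sample (n >= 8).
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`.
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop_invalid("D'Agostino K2 requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness -> Z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis -> Z (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Group-level summaries and hypothesis tests
#'
#' Reporting plumbing over standard routines: per metric, each group is
#' checked for normality (D'Agostino K-squared; Shapiro-Wilk when a
#' group is too small for it); if all groups look normal, a parametric
#' comparison is run (t test for 2 groups, one-way ANOVA plus Tukey HSD
#' for more), otherwise a rank-based one (Mann-Whitney / Kruskal-Wallis
#' plus pairwise Wilcoxon with Holm correction). Significance is read at
#' `alpha` (0.05). Descriptives are mean +/- SEM per group.
#'
#' @param table long-format data.frame with columns `condition`,
#'   `metric`, `value` (extra columns ignored).
#' @param alpha significance level.
#' @return list per metric: `descriptives` (data.frame), `normal`
#'   (per-group logical), `family`, `test`, `p.value`, `posthoc`
#'   (when > 2 groups), `significant`.
#' @export
summarize_groups <- function(table, alpha = 0.05) {
  stopifnot(all(c("condition", "metric", "value") %in% names(table)))
  out <- list()
  for (met in unique(table$metric)) {
    sub <- table[table$metric == met & is.finite(table$value), ]
    if (nrow(sub) == 0L) next
    groups <- split(sub$value, factor(sub$condition))
    desc <- data.frame(
      condition = names(groups),
      n = vapply(groups, length, integer(1)),
      mean = vapply(groups, mean, numeric(1)),
      sem = vapply(groups, function(v)
        stats::sd(v) / sqrt(length(v)), numeric(1)),
      row.names = NULL)
    res <- list(descriptives = desc)
    if (length(groups) >= 2L && all(vapply(groups, length, integer(1)) >= 3L)) {
      normal <- vapply(groups, function(v) {
        p <- if (length(v) >= 8L) dagostino_test(v)$p.value
             else stats::shapiro.test(v)$p.value
        p > alpha
      }, logical(1))
      res$normal <- normal
      fam <- if (all(normal)) "parametric" else "rank"
      res$family <- fam
      g <- factor(rep(names(groups), lengths(groups)))
      v <- unlist(groups, use.names = FALSE)
      if (length(groups) == 2L) {
        ht <- if (fam == "parametric") stats::t.test(v ~ g)
              else stats::wilcox.test(v ~ g, exact = FALSE)
        res$test <- ht$method; res$p.value <- ht$p.value
      } else {
        if (fam == "parametric") {
          fit <- stats::aov(v ~ g)
          res$test <- "One-way ANOVA"
          res$p.value <- summary(fit)[[1]][["Pr(>F)"]][1]
          res$posthoc <- as.data.frame(stats::TukeyHSD(fit)$g)
        } else {
          kt <- stats::kruskal.test(v, g)
          res$test <- kt$method; res$p.value <- kt$p.value
          pw <- stats::pairwise.wilcox.test(v, g, p.adjust.method = "holm",
                                            exact = FALSE)
          res$posthoc <- pw$p.value
        }
      }
      res$significant <- res$p.value < alpha
    }
    out[[met]] <- res
  }
  out
}
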