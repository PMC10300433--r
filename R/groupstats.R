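#' Levene/Brown-Forsythe test of variance equality
#'
#' ANOVA on absolute deviations from the group center (median by default,
#' the robust Brown-Forsythe variant; `center = "mean"` gives classical
#' Levene).
#'
#' @param x,y numeric samples.
#' @param center `"median"` or `"mean"`.
#' @return list with statistic (F), df, p.value.
#' @export
levene_test <- function(x, y, center = c("median", "mean")) {
  center <- match.arg(center)
  cf <- if (center == "median") median else mean
  zx <- abs(x - cf(x))
  zy <- abs(y - cf(y))
  z <- c(zx, zy)
  g <- factor(c(rep("x", length(x)), rep("y", length(y))))
  n <- length(z); k <- 2L
  zb <- tapply(z, g, mean)
  zg <- mean(z)
  ssb <- sum(tabulate(g) * (zb - zg)^2)
  ssw <- sum((z - zb[g])^2)
  if (ssw == 0) return(list(statistic = NA_real_, df = c(k - 1, n - k),
                            p.value = 1))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, df = c(k - 1, n - k),
       p.value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Normality-gated two-group comparison
#'
#' The standard decision tree: Shapiro-Wilk on each group (on the paired
#' differences when `paired`); if any normality p < `alpha_gate` the
#' comparison is nonparametric (Wilcoxon signed-rank when paired, rank-sum
#' otherwise); otherwise, unpaired data are gated by a Levene test into
#' Student's t (equal variances) or Welch's t, and paired-normal data take the
#' paired t test. A Bonferroni correction (capped at 1) is applied when the
#' comparison belongs to a family of `n_comparisons` tests.
#'
#' @param x,y numeric samples (each n >= 3; equal lengths when paired).
#' @param paired logical.
#' @param alpha_gate gate level for the Shapiro-Wilk and Levene pre-tests.
#' @param n_comparisons Bonferroni family size m; p_adjusted = min(1, m * p).
#' @param var_center centering for the Levene gate ("median" or "mean").
#' @return list of class `comparison_result`: chosen_test, statistic, p_value,
#'   p_adjusted, normality_p, variance_p, decisions (character log).
#' @export
compare_groups <- function(x, y, paired = FALSE, alpha_gate = 0.05,
                           n_comparisons = 1, var_center = "median") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) stop("each sample needs n >= 3")
  if (paired && length(x) != length(y))
    stop("paired comparison requires equal lengths")
  log <- character(0)
  push <- function(msg) log <<- c(log, msg)

  sw_safe <- function(v, label) {
    if (length(unique(v)) < 3 || sd(v) == 0) {
      push(sprintf("%s degenerate (constant): normality rejected by fiat",
                   label))
      return(0)
    }
    v2 <- if (length(v) > 5000) sample(v, 5000) else v
    p <- shapiro.test(v2)$p.value
    push(sprintf("Shapiro-Wilk %s: p = %.4g", label, p))
    p
  }

  if (paired) {
    dif <- x - y
    norm_p <- sw_safe(dif, "differences")
    normal <- norm_p >= alpha_gate
    var_p <- NA_real_
    if (normal) {
      push("differences normal -> paired t test")
      ht <- t.test(x, y, paired = TRUE)
      chosen <- "paired_t"
    } else {
      push("differences non-normal -> Wilcoxon signed-rank test")
      ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
      chosen <- "wilcoxon_signed_rank"
    }
    norm_ps <- c(differences = norm_p)
  } else {
    px <- sw_safe(x, "group x")
    py <- sw_safe(y, "group y")
    norm_ps <- c(x = px, y = py)
    normal <- min(px, py) >= alpha_gate
    if (!normal) {
      push("non-normal group(s) -> Wilcoxon rank-sum test")
      ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
      chosen <- "wilcoxon_rank_sum"
      var_p <- NA_real_
    } else {
      lev <- levene_test(x, y, center = var_center)
      var_p <- lev$p.value
      push(sprintf("Levene (%s-centered): p = %.4g", var_center, var_p))
      if (var_p >= alpha_gate) {
        push("equal variances -> Student's t test")
        ht <- t.test(x, y, var.equal = TRUE)
        chosen <- "student_t"
      } else {
        push("unequal variances -> Welch's t test")
        ht <- t.test(x, y, var.equal = FALSE)
        chosen <- "welch_t"
      }
    }
  }
  p_adj <- min(1, n_comparisons * ht$p.value)
  if (n_comparisons > 1)
    push(sprintf("Bonferroni m = %d: p_adjusted = %.4g", n_comparisons, p_adj))
  structure(list(chosen_test = chosen,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value, p_adjusted = p_adj,
                 normality_p = norm_ps, variance_p = var_p,
                 alpha_gate = alpha_gate, n_comparisons = n_comparisons,
                 decisions = log),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("comparison_result:", x$chosen_test,
      sprintf("(p = %.4g, adjusted = %.4g)\n", x$p_value, x$p_adjusted))
  cat(paste0("  - ", x$decisions, collapse = "\n"), "\n")
  invisible(x)
}

#' Pearson correlation with a linear fit
#'
#' @param x,y numeric vectors (n >= 3; both non-constant).
#' @return list: R, p_value, slope, intercept, n.
#' @export
pearson_fit <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("x and y must be non-constant")
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  list(R = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}
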