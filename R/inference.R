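#' Mean and standard error summary
#'
#' @param values numeric vector.
#' @return list with `mean`, `sem` (sd with n-1 denominator over sqrt(n);
#'   `NA` with `undefined = TRUE` for a single value), and `n`.
#' @export
summarize_mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("no values to summarize")
  if (n == 1)
    return(list(mean = values, sem = structure(NA_real_, undefined = TRUE), n = 1L))
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Normality-gated statistical test selection
#'
#' Reproduces a common test-selection decision tree for small-sample group
#' comparisons: each group is first checked for normality with the
#' Shapiro-Wilk test at level `alpha`. If all groups pass, parametric tests
#' are used (unpaired: an F test on the variances chooses between Student's
#' and Welch's t test; paired: paired t; one-sample: one-sample t against
#' `null_value`). If any group fails, the nonparametric counterpart is used
#' (Mann-Whitney U, Wilcoxon matched-pairs signed-rank, or one-sample
#' Wilcoxon). All tests are two-tailed. The full decision trail (normality
#' p-values, variance-test p-value) is recorded in the result.
#'
#' @param x numeric vector (group A, or the single sample).
#' @param y numeric vector (group B) or `NULL` for one-sample designs.
#' @param design `"unpaired"`, `"paired"`, or `"one_sample"`.
#' @param null_value null hypothesis value for one-sample designs (e.g. 1
#'   for count ratios, 50 for percent-chance).
#' @param alpha level for the normality and variance gates.
#' @return list of class `striomap_test` with `test_name`, `statistic`,
#'   `p_value`, `df` (NA when undefined), `summaries` (mean ± SEM per
#'   group), and `trail` (gate p-values and decisions).
#' @export
select_and_run <- function(x, y = NULL,
                           design = c("unpaired", "paired", "one_sample"),
                           null_value = 0, alpha = 0.05) {
  design <- match.arg(design)
  if (design != "one_sample" && is.null(y))
    stop("two groups required for design '", design, "'")
  if (design == "one_sample" && !is.null(y))
    stop("one_sample design takes a single group")
  x <- x[!is.na(x)]
  if (!is.null(y)) y <- y[!is.na(y)]
  if (length(x) < 3 || (!is.null(y) && length(y) < 3))
    stop("group sizes must be >= 3 for normality testing")

  shapiro_safe <- function(v) {
    if (stats::sd(v) == 0) return(0)  # constant data: treat as non-normal
    stats::shapiro.test(v)$p.value
  }
  trail <- list(alpha = alpha)

  if (design == "one_sample") {
    trail$shapiro_p <- shapiro_safe(x)
    normal <- trail$shapiro_p >= alpha
    if (normal) {
      if (stats::sd(x) == 0)
        stop("degenerate input: zero-variance sample under a t test")
      ht <- stats::t.test(x, mu = null_value)
      name <- "One-sample t (two-tailed)"
    } else {
      ht <- stats::wilcox.test(x, mu = null_value, exact = FALSE)
      name <- "One-sample Wilcoxon signed-rank"
    }
    summaries <- list(group = summarize_mean_sem(x))
  } else if (design == "paired") {
    if (length(x) != length(y)) stop("paired design requires equal lengths")
    trail$shapiro_p <- c(A = shapiro_safe(x), B = shapiro_safe(y))
    normal <- all(trail$shapiro_p >= alpha)
    if (normal) {
      if (stats::sd(x - y) == 0)
        stop("degenerate input: zero-variance differences under a paired t test")
      ht <- stats::t.test(x, y, paired = TRUE)
      name <- "Paired t (two-tailed)"
    } else {
      ht <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
      name <- "Wilcoxon matched-pairs signed-rank"
    }
    summaries <- list(A = summarize_mean_sem(x), B = summarize_mean_sem(y))
  } else {
    trail$shapiro_p <- c(A = shapiro_safe(x), B = shapiro_safe(y))
    normal <- all(trail$shapiro_p >= alpha)
    if (normal) {
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("degenerate input: zero-variance group under a t test")
      ft <- stats::var.test(x, y)
      trail$var_test_p <- ft$p.value
      if (ft$p.value >= alpha) {
        ht <- stats::t.test(x, y, var.equal = TRUE)
        name <- "Student t (two-tailed)"
      } else {
        ht <- stats::t.test(x, y, var.equal = FALSE)
        name <- "Welch t (two-tailed)"
      }
    } else {
      ht <- stats::wilcox.test(x, y, exact = FALSE)
      name <- "Mann-Whitney U"
    }
    summaries <- list(A = summarize_mean_sem(x), B = summarize_mean_sem(y))
  }
  trail$normal <- normal
  structure(list(
    test_name = name,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    df = if (!is.null(ht$parameter)) unname(ht$parameter) else NA_real_,
    summaries = summaries,
    trail = trail
  ), class = "striomap_test")
}

#' @export
print.striomap_test <- function(x, ...) {
  cat(x$test_name, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4),
      if (!is.na(x$df)) paste0(", df = ", signif(x$df, 4)) else "", "\n",
      sep = "")
  invisible(x)
}

#' Compare between-group variability (Levene's test)
#'
#' Levene's test is robust to small and unequal sample sizes and is the
#' appropriate gate when comparing variability between cell types.
#'
#' @param x,y numeric vectors.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
compare_variability <- function(x, y) {
  dat <- data.frame(value = c(x, y),
                    group = factor(rep(c("A", "B"), c(length(x), length(y)))))
  lt <- car::leveneTest(value ~ group, data = dat)
  list(statistic = lt[1, "F value"], p_value = lt[1, "Pr(>F)"],
       df = c(lt[1, "Df"], lt[2, "Df"]))
}

#' Two-way repeated-measures ANOVA (pass-through)
#'
#' Thin wrapper over [stats::aov()] for a two-factor design with one
#' within-subject factor (e.g. input channel within cell), as used for
#' comparing input counts across channels and cells.
#'
#' @param value numeric response.
#' @param within factor varying within subject (e.g. channel).
#' @param subject subject/cell identifier.
#' @return the fitted `aov` summary.
#' @export
repeated_measures_anova <- function(value, within, subject) {
  dat <- data.frame(value = value, within = factor(within),
                    subject = factor(subject))
  fit <- stats::aov(value ~ within + Error(subject/within), data = dat)
  summary(fit)
}
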