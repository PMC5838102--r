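#' Ordinary least-squares fit of myelin thickness on axon diameter
#'
#' The classical diameter-thickness coupling, fitted across all sampled
#' sections of a group: `thickness = slope * diameter + intercept`, with
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param diameter axon diameters, um (or a 2-column data.frame/matrix of
#'   diameter and thickness).
#' @param thickness myelin thicknesses, um.
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_diameter_thickness <- function(diameter, thickness = NULL) {
  if (is.null(thickness)) {
    thickness <- diameter[[2]]; diameter <- diameter[[1]]
  }
  ok <- is.finite(diameter) & is.finite(thickness)
  diameter <- diameter[ok]; thickness <- thickness[ok]
  if (length(diameter) < 3) stop("regression needs at least 3 points")
  if (stats::var(diameter) == 0) stop("degenerate regression: diameter has zero variance")
  fit <- stats::lm(thickness ~ diameter)
  ss_tot <- sum((thickness - mean(thickness))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot   # constant response: R^2 = 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = max(0, min(1, r2)),
                 n = length(diameter)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("thickness = %.3f * diameter + %.3f (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

test_result <- function(test, statistic, p, n, extra = list()) {
  structure(c(list(test = test, statistic = statistic, p = p, n = n), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Classic Levene test for equality of variances
#'
#' One-way ANOVA on the absolute deviations from the group means (the
#' original mean-centred Levene statistic, not the Brown-Forsythe median
#' variant), via [stats::aov()]. Identical samples give F = 0, p = 1.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return A `test_result` with the F statistic and p value.
#' @export
levene_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  dev <- c(abs(a - mean(a)), abs(b - mean(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  tab <- stats::anova(stats::aov(dev ~ g))
  f <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
  if (!is.finite(f)) { f <- 0; p <- 1 }   # zero-variance deviations
  test_result("levene", f, p, c(length(a), length(b)))
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance t when `equal_var`, else Welch; two-sided.
#' The degenerate case of two zero-variance samples with equal means is
#' reported as t = 0, p = 1.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param equal_var assume equal variances (normally decided upstream by
#'   [levene_test()] at alpha = 0.05).
#' @return A `test_result` with `statistic` (t), `p`, `df`.
#' @export
unpaired_t_test <- function(a, b, equal_var = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(test_result("t", 0, 1, c(length(a), length(b)),
                         list(df = length(a) + length(b) - 2, equal_var = equal_var)))
    stop("both samples have zero variance but different means")
  }
  ht <- stats::t.test(a, b, var.equal = equal_var)
  test_result("t", unname(ht$statistic), ht$p.value, c(length(a), length(b)),
              list(df = unname(ht$parameter), equal_var = equal_var))
}

#' Levene-gated comparison of two groups
#'
#' Applies [levene_test()] at `alpha` to choose between Student's and
#' Welch's t-test, then runs [unpaired_t_test()]. Reports both the Levene F
#' and the t statistic.
#'
#' @param a,b numeric samples.
#' @param alpha gate level for the variance-equality decision (default 0.05).
#' @return One-row data.frame: `n_a`, `n_b`, `levene_F`, `levene_p`,
#'   `equal_var`, `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_two_groups <- function(a, b, alpha = 0.05) {
  lv <- levene_test(a, b)
  eq <- lv$p >= alpha
  tt <- unpaired_t_test(a, b, equal_var = eq)
  data.frame(n_a = length(a), n_b = length(b),
             levene_F = lv$statistic, levene_p = lv$p, equal_var = eq,
             t = tt$statistic, df = tt$df, p = tt$p,
             mean_a = mean(a), mean_b = mean(b))
}

#' One-way repeated-measures ANOVA with Tukey post-hoc
#'
#' Subject-blocked decomposition (`value ~ condition + subject` via
#' [stats::aov()]), whose condition F equals the one-way repeated-measures
#' F; pairwise condition contrasts by Tukey HSD on the error mean square.
#' The matrix must be complete (every subject measured in every condition).
#' All-identical conditions give F = 0, p = 1 and no significant pair.
#'
#' @param values numeric matrix, subjects x conditions.
#' @param conditions condition labels (default the column names).
#' @return List: `anova` (a `test_result` with F, p, dfs) and `tukey`
#'   (data.frame of pairwise differences and adjusted p values).
#' @export
rm_anova_tukey <- function(values, conditions = colnames(values)) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("incomplete matrix: every axon must be measured in every condition")
  if (ncol(values) < 2) stop("need at least 2 conditions")
  if (nrow(values) < 3) stop("need at least 3 subjects")
  if (is.null(conditions)) conditions <- paste0("c", seq_len(ncol(values)))
  long <- data.frame(value = as.vector(values),
                     condition = factor(rep(conditions, each = nrow(values)),
                                        levels = conditions),
                     subject = factor(rep(seq_len(nrow(values)), ncol(values))))
  fit <- stats::aov(value ~ condition + subject, data = long)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  f <- tab["condition", "F value"]; p <- tab["condition", "Pr(>F)"]
  # identical conditions leave only rounding dust in SS_condition
  tol <- 1e-10 * max(1, sum(values^2))
  if (!is.finite(f) || tab["condition", "Sum Sq"] < tol) { f <- 0; p <- 1 }
  df1 <- tab["condition", "Df"]; df2 <- tab["Residuals", "Df"]
  tk <- tryCatch({
    th <- stats::TukeyHSD(fit, which = "condition")$condition
    data.frame(pair = rownames(th), diff = th[, "diff"],
               lwr = th[, "lwr"], upr = th[, "upr"], p_adj = th[, "p adj"],
               row.names = NULL)
  }, error = function(e) {
    pairs <- utils::combn(conditions, 2, paste, collapse = "-")
    data.frame(pair = pairs, diff = 0, lwr = 0, upr = 0, p_adj = 1)
  })
  if (f == 0) tk$p_adj <- 1
  list(anova = test_result("rm_anova", f, p, nrow(values),
                           list(df1 = df1, df2 = df2)),
       tukey = tk)
}
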