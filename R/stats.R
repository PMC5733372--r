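# Group comparison of fitted cost-functional parameters.

#' Welch's unequal-variance t-test
#'
#' Two-sample t-test without the equal-variance or equal-n assumptions
#' (Welch-Satterthwaite degrees of freedom), two-sided. A thin wrapper around
#' [stats::t.test()] that validates the inputs and returns the quantities the
#' group reports need.
#'
#' @param a,b numeric samples, each with at least two values and nonzero
#'   variance.
#' @return an object of class `"group_comparison"`: list with `t`, `p`, `df`,
#'   `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @examples
#' welch_ttest(c(1, 2, 3), c(1, 2, 3, 4, 5))
#' @export
welch_ttest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both groups have zero variance; the Welch statistic is undefined",
         call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter),
                 mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.3g, p = %.4g\n",
              x$t, x$df, x$p))
  cat(sprintf("group means: %.6g (n=%d, sd %.4g) vs %.6g (n=%d, sd %.4g)\n",
              x$mean_a, x$n_a, x$sd_a, x$mean_b, x$n_b, x$sd_b))
  invisible(x)
}

#' Compare fitted weights between groups
#'
#' Runs a Welch t-test per parameter (theta_p and omega_p) between two groups
#' of fits and reports the direction of each difference.
#'
#' @param fits list of `"armioc"` fits, or a data frame with columns
#'   `theta_p` and `omega_p`.
#' @param groups factor or character vector of group labels, exactly two
#'   levels, at least two fits per group.
#' @param log10_scale compare log10-transformed weights (the weights are
#'   log-normal-like; default `FALSE`, matching raw-scale reporting).
#' @return an object of class `"cohort_comparison"`: list with per-parameter
#'   `"group_comparison"` objects (`theta_p`, `omega_p`), the group labels,
#'   and a `direction` summary.
#' @export
compare_cohort <- function(fits, groups, log10_scale = FALSE) {
  if (is.data.frame(fits)) {
    df <- fits[, c("theta_p", "omega_p")]
  } else {
    if (!all(vapply(fits, inherits, logical(1), "armioc")))
      stop("'fits' must be armioc fits or a data frame", call. = FALSE)
    df <- as.data.frame(do.call(rbind, lapply(fits, coef)))
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(df))
    stop("one group label per fit is required", call. = FALSE)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least two fits for a Welch comparison", call. = FALSE)
  if (log10_scale) df <- log10(df)
  cmp <- lapply(c(theta_p = "theta_p", omega_p = "omega_p"), function(p)
    welch_ttest(df[[p]][groups == lev[1]], df[[p]][groups == lev[2]]))
  direction <- vapply(cmp, function(x)
    if (x$mean_a > x$mean_b) paste(lev[1], ">", lev[2])
    else paste(lev[1], "<", lev[2]), character(1))
  structure(list(theta_p = cmp$theta_p, omega_p = cmp$omega_p,
                 groups = lev, direction = direction,
                 log10_scale = log10_scale),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison (%s vs %s)%s\n", x$groups[1], x$groups[2],
              if (x$log10_scale) " on log10 scale" else ""))
  for (p in c("theta_p", "omega_p")) {
    cat(sprintf("  %s: t = %.4g, p = %.4g (%s)\n",
                p, x[[p]]$t, x[[p]]$p, x$direction[[p]]))
  }
  invisible(x)
}
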