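# Group descriptives, one-way ANOVA with Dunnett many-to-one post hoc
# comparisons, and ratio-vs-control reporting.

#' Mean, SEM and n per group
#'
#' @param values numeric vector of measurements.
#' @param group group label per measurement.
#' @return `data.frame(group, mean, sem, n)`; `sem` is `NA` when `n == 1`.
#' @export
describe_groups <- function(values, group) {
  stopifnot(length(values) == length(group), length(values) > 0)
  if (any(!is.finite(values))) stop("values must be finite")
  out <- do.call(rbind, lapply(split(values, group), function(x) {
    data.frame(mean = mean(x),
               sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
               n = length(x))
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}

# One-way ANOVA decomposition; returns F, p, and the pieces Dunnett needs.
anova_oneway <- function(values, group) {
  g <- split(values, group)
  k <- length(g)
  if (k < 2) stop("need at least 2 groups")
  n <- lengths(g)
  N <- sum(n)
  df_err <- N - k
  if (df_err < 1) stop("no error degrees of freedom (all groups of size 1)")
  means <- vapply(g, mean, numeric(1))
  grand <- mean(values)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  ms_err <- ssw / df_err
  f <- if (ssw == 0 && ssb == 0) 0 else (ssb / (k - 1)) / ms_err
  list(F = f, p = pf(f, k - 1, df_err, lower.tail = FALSE),
       df1 = k - 1, df2 = df_err, ms_err = ms_err,
       means = means, n = n, groups = names(g))
}

# Monte-Carlo distribution of max |t_i| over K many-to-one comparisons with
# group sizes n (control first), pooled-variance denominator, df error d.f.
simulate_max_abs_t <- function(n_control, n_treat, df_err, ndraws) {
  k <- length(n_treat)
  z0 <- rnorm(ndraws, 0, 1 / sqrt(n_control))
  s <- sqrt(rchisq(ndraws, df_err) / df_err)
  maxt <- rep(0, ndraws)
  for (i in seq_len(k)) {
    zi <- rnorm(ndraws, 0, 1 / sqrt(n_treat[i]))
    ti <- abs(zi - z0) / (s * sqrt(1 / n_treat[i] + 1 / n_control))
    maxt <- pmax(maxt, ti)
  }
  maxt
}

#' One-way ANOVA with Dunnett many-to-one post hoc comparisons
#'
#' Classical equal-variance Dunnett test: each non-control group is compared
#' with the control using the pooled error term, and the two-sided adjusted
#' p-value is the probability that the maximum of the K absolute t statistics
#' (correlated through the shared control mean) exceeds the observed |t|.
#' That null distribution is evaluated by seeded Monte-Carlo simulation
#' (`ndraws` draws); with a single comparison it degenerates to the ordinary
#' pooled-variance t-test, which is then computed exactly.
#'
#' @param values numeric measurements.
#' @param group group label per measurement.
#' @param control control group label.
#' @param alpha significance level for the flags.
#' @param ndraws Monte-Carlo draws for the max-|t| null.
#' @param seed optional seed for the Monte-Carlo draws (local to this call).
#' @return object of class `dunnett_result`: `F`, `p_omnibus`, `df`,
#'   `comparisons` (`data.frame(group, diff, t, p_unadjusted, p_adjusted,
#'   significant)`), `control`, `alpha`.
#' @export
anova_dunnett <- function(values, group, control, alpha = 0.05,
                          ndraws = 1e5, seed = NULL) {
  stopifnot(length(values) == length(group))
  group <- as.character(group)
  if (!control %in% group) stop("control group '", control, "' not present")
  av <- anova_oneway(values, group)
  if (av$ms_err <= 0) stop("pooled within-group variance is zero")
  treat <- setdiff(av$groups, control)
  n0 <- av$n[[control]]
  m0 <- av$means[[control]]
  diffs <- av$means[treat] - m0
  se <- sqrt(av$ms_err * (1 / av$n[treat] + 1 / n0))
  tstat <- diffs / se
  p_un <- 2 * pt(-abs(tstat), av$df2)
  if (length(treat) == 1L) {
    p_adj <- p_un
  } else {
    draw <- function() simulate_max_abs_t(n0, av$n[treat], av$df2, ndraws)
    maxt <- if (is.null(seed)) draw() else with_seed(seed, draw())
    p_adj <- vapply(abs(tstat), function(t0) mean(maxt >= t0), numeric(1))
    p_adj <- pmax(p_adj, p_un)   # adjustment can only increase p
  }
  comparisons <- data.frame(group = treat, diff = as.numeric(diffs),
                            t = as.numeric(tstat),
                            p_unadjusted = as.numeric(p_un),
                            p_adjusted = as.numeric(p_adj),
                            significant = as.numeric(p_adj) < alpha,
                            row.names = NULL)
  structure(list(F = av$F, p_omnibus = av$p, df = c(av$df1, av$df2),
                 comparisons = comparisons, control = control,
                 alpha = alpha),
            class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_omnibus))
  cat(sprintf("Dunnett comparisons vs '%s' (alpha = %g):\n",
              x$control, x$alpha))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Treated mean as a percentage of the control mean
#'
#' @param control control-group mean (> 0).
#' @param treated treated-group mean.
#' @return `100 * treated / control`.
#' @export
#' @examples
#' ratio_vs_control(498.6, 101.34)   # 20.33% of control
ratio_vs_control <- function(control, treated) {
  if (any(control <= 0)) stop("control mean must be positive")
  100 * treated / control
}

#' Empirical type-I error of the omnibus ANOVA
#'
#' Simulates `n_reps` null datasets (every group drawn from the same
#' Gaussian) and reports the fraction whose omnibus p-value falls below
#' `alpha`.
#'
#' @param n_groups number of groups.
#' @param n_per_group observations per group.
#' @param n_reps replicate datasets (>= 100).
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return empirical rejection rate.
#' @export
type_i_error_check <- function(n_groups = 3, n_per_group = 9,
                               n_reps = 2000, alpha = 0.05, seed = 1L) {
  if (n_reps < 100) stop("n_reps must be at least 100")
  grp <- rep(seq_len(n_groups), each = n_per_group)
  with_seed(seed, {
    rej <- vapply(seq_len(n_reps), function(r) {
      anova_oneway(rnorm(n_groups * n_per_group), grp)$p < alpha
    }, logical(1))
  })
  mean(rej)
}
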