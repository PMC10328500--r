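#' Per-group mean with t-based 95% confidence interval
#'
#' @param values named list of numeric vectors (one per group), each n >= 2.
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `group`, `n`, `mean`, `ci95_low`,
#'   `ci95_high`.
#' @examples
#' summarize_groups(list(a = c(1, 2, 3), b = c(4, 5, 6, 7)))
#' @export
summarize_groups <- function(values, conf = 0.95) {
  if (!is.list(values) || is.null(names(values)) || any(!nzchar(names(values))))
    stop_bad_arg("`values` must be a named list of numeric vectors")
  rows <- lapply(names(values), function(g) {
    x <- values[[g]]
    if (length(x) < 2L) stop_bad_arg("group '%s' has n < 2", g)
    m <- mean(x)
    half <- stats::qt(1 - (1 - conf) / 2, length(x) - 1L) *
      stats::sd(x) / sqrt(length(x))
    data.frame(group = g, n = length(x), mean = m,
               ci95_low = m - half, ci95_high = m + half)
  })
  do.call(rbind, rows)
}

#' Group comparisons: Student's t, ANOVA + Dunnett, ANOVA + Tukey
#'
#' Mirrors conventional reporting for this kind of data: Student's t-test
#' (pooled variance; set `welch = TRUE` for the Welch correction) for two
#' groups, one-way ANOVA with Dunnett-adjusted p-values for comparisons
#' against a named control, or with Tukey HSD adjustment for all pairwise
#' comparisons. Dunnett probabilities are computed exactly by numerical
#' integration over the control-group deviate and the pooled standard
#' deviation (see [dunnett_p_adjust()]); a seeded Monte-Carlo max-|t|
#' fallback is available via `dunnett_method = "monte_carlo"`. Adjusted
#' p-values are never smaller than raw ones.
#'
#' @param values named list of numeric vectors.
#' @param design `"two_sample"`, `"vs_control"` or `"all_pairs"`.
#' @param control control group name (required for `"vs_control"`).
#' @param welch Welch correction for `"two_sample"`.
#' @param dunnett_method `"integration"` (default) or `"monte_carlo"`.
#' @param mc_draws,mc_seed Monte-Carlo settings for the fallback.
#' @return An object of class `comparison_table`: data.frame with columns
#'   `group_a`, `group_b`, `statistic`, `p_raw`, `p_adjusted`, `method`,
#'   plus attributes `anova_f` and `anova_p` for the ANOVA designs.
#' @export
compare_groups <- function(values,
                           design = c("two_sample", "vs_control", "all_pairs"),
                           control = NULL, welch = FALSE,
                           dunnett_method = c("integration", "monte_carlo"),
                           mc_draws = 1e5, mc_seed = 1L) {
  design <- match.arg(design)
  dunnett_method <- match.arg(dunnett_method)
  if (!is.list(values) || is.null(names(values)))
    stop_bad_arg("`values` must be a named list")
  groups <- names(values)
  ns <- lengths(values)
  if (any(ns < 2L)) stop_bad_arg("every group needs n >= 2")

  if (design == "two_sample") {
    if (length(values) != 2L)
      stop_bad_arg("two_sample design needs exactly 2 groups")
    tt <- stats::t.test(values[[1L]], values[[2L]], var.equal = !welch)
    tab <- data.frame(group_a = groups[1L], group_b = groups[2L],
                      statistic = unname(tt$statistic),
                      p_raw = tt$p.value, p_adjusted = tt$p.value,
                      method = "ttest")
    return(structure(tab, class = c("comparison_table", "data.frame")))
  }

  k_tot <- length(values)
  if (k_tot < 3L) stop_bad_arg("ANOVA designs need >= 3 groups")
  all_y <- unlist(values, use.names = FALSE)
  fac <- factor(rep(groups, ns), levels = groups)
  fit <- stats::aov(all_y ~ fac)
  an <- summary(fit)[[1L]]
  s2 <- an["Residuals", "Mean Sq"]
  df <- an["Residuals", "Df"]
  means <- vapply(values, mean, 0)

  if (design == "vs_control") {
    if (is.null(control) || !control %in% groups)
      stop_bad_arg("vs_control design needs `control` naming a group")
    others <- setdiff(groups, control)
    tstat <- (means[others] - means[control]) /
      sqrt(s2 * (1 / ns[others] + 1 / ns[control]))
    p_raw <- 2 * stats::pt(-abs(tstat), df)
    p_adj <- dunnett_p_adjust(abs(tstat), n_control = ns[[control]],
                              n_groups = ns[others], df = df,
                              method = dunnett_method,
                              mc_draws = mc_draws, mc_seed = mc_seed)
    tab <- data.frame(group_a = others, group_b = control,
                      statistic = unname(tstat),
                      p_raw = unname(p_raw),
                      p_adjusted = pmax(unname(p_adj), unname(p_raw)),
                      method = "anova_dunnett", row.names = NULL)
  } else {
    pairs <- utils::combn(groups, 2L)
    tstat <- p_raw <- p_adj <- numeric(ncol(pairs))
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      se <- sqrt(s2 * (1 / ns[[a]] + 1 / ns[[b]]))
      tstat[i] <- (means[[a]] - means[[b]]) / se
      p_raw[i] <- 2 * stats::pt(-abs(tstat[i]), df)
      q <- abs(means[[a]] - means[[b]]) /
        sqrt(s2 / 2 * (1 / ns[[a]] + 1 / ns[[b]]))   # Tukey-Kramer
      p_adj[i] <- stats::ptukey(q, nmeans = k_tot, df = df,
                                lower.tail = FALSE)
    }
    tab <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                      statistic = tstat, p_raw = p_raw,
                      p_adjusted = pmax(p_adj, p_raw),
                      method = "anova_tukey", row.names = NULL)
  }
  structure(tab, anova_f = an["fac", "F value"],
            anova_p = an["fac", "Pr(>F)"],
            class = c("comparison_table", "data.frame"))
}

#' Dunnett two-sided adjusted p-values
#'
#' For k treatment groups compared against one control with pooled SD on
#' `df` degrees of freedom, the Dunnett-adjusted p for an observed |t| is
#' P(max_j |T_j| >= |t|) under the global null, where the T_j share the
#' control mean and the pooled SD. `"integration"` evaluates this
#' probability exactly by conditioning on the control-group standard-normal
#' deviate z and on u = s/sigma (chi distribution), reducing the inner
#' probability to a product of normal CDFs, and integrating numerically
#' over both; `"monte_carlo"` samples the null max-|t| distribution with a
#' fixed seed.
#'
#' @param tabs vector of observed |t| statistics, one per treatment group.
#' @param n_control control group size.
#' @param n_groups treatment group sizes (same order as `tabs`).
#' @param df residual degrees of freedom.
#' @param method `"integration"` or `"monte_carlo"`.
#' @param mc_draws,mc_seed Monte-Carlo settings.
#' @return Vector of adjusted p-values.
#' @export
dunnett_p_adjust <- function(tabs, n_control, n_groups, df,
                             method = c("integration", "monte_carlo"),
                             mc_draws = 1e5, mc_seed = 1L) {
  method <- match.arg(method)
  k <- length(n_groups)
  w <- sqrt(1 / n_groups + 1 / n_control)
  if (method == "monte_carlo") {
    maxt <- with_seed(mc_seed, {
      z0 <- stats::rnorm(mc_draws) / sqrt(n_control)
      u <- sqrt(stats::rchisq(mc_draws, df) / df)
      m <- matrix(0, mc_draws, k)
      for (j in seq_len(k))
        m[, j] <- abs(stats::rnorm(mc_draws) / sqrt(n_groups[j]) - z0) /
          (u * w[j])
      apply(m, 1L, max)
    })
    return(vapply(tabs, function(t0) mean(maxt >= t0), 0))
  }
  p_all_below <- function(t0) {
    inner_at <- function(u) {
      force(u)
      function(z) {
        out <- rep(1, length(z))
        for (j in seq_len(k)) {
          hi <- sqrt(n_groups[j]) * (t0 * u * w[j] + z / sqrt(n_control))
          lo <- sqrt(n_groups[j]) * (-t0 * u * w[j] + z / sqrt(n_control))
          out <- out * (stats::pnorm(hi) - stats::pnorm(lo))
        }
        out * stats::dnorm(z)
      }
    }
    outer_f <- function(u) {
      vapply(u, function(ui)
        stats::integrate(inner_at(ui), -Inf, Inf,
                         rel.tol = 1e-9)$value, 0) * chi_dens(u, df)
    }
    stats::integrate(outer_f, 0, Inf, rel.tol = 1e-8)$value
  }
  vapply(tabs, function(t0) min(1, max(0, 1 - p_all_below(t0))), 0)
}

# density of u = sqrt(chisq_df / df)
chi_dens <- function(u, df) {
  exp((df / 2) * log(df / 2) - lgamma(df / 2) + log(2) +
        (df - 1) * log(u) - df * u^2 / 2)
}
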