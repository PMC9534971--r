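#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' The group-comparison procedure used for all region statistics: a one-way
#' ANOVA across condition groups followed by Tukey's honestly-significant-
#' difference test for pairwise contrasts with family-wise adjusted
#' p-values. Significance stars follow the caption convention of the assay
#' (`****` p < 0.001, `***` p < 0.01, `**` p < 0.1, `*` p < 0.5 by
#' default); the cutpoints are configurable. If all groups have zero
#' within-group variance the fit is flagged degenerate and exact-zero
#' p-values are reported as `< 1e-6` when printed.
#'
#' @param data a data frame of per-sample measurements.
#' @param value unquoted column with the measurement.
#' @param group unquoted column with the group label.
#' @param conf_level confidence level of the Tukey intervals.
#' @param star_cutpoints named numeric vector mapping star strings to upper
#'   p-value bounds, in increasing order.
#' @return An object of class `region_anova` with [tidy()] and [glance()]
#'   methods.
#' @examples
#' df <- data.frame(
#'   g = rep(c("static", "shear"), each = 5),
#'   v = c(rnorm(5, 10), rnorm(5, 12))
#' )
#' fit <- compare_groups(df, v, g)
#' tidy(fit)
#' glance(fit)
#' @export
compare_groups <- function(data, value, group, conf_level = 0.95,
                           star_cutpoints = c(
                             "****" = 0.001, "***" = 0.01,
                             "**" = 0.1, "*" = 0.5
                           )) {
  value_v <- rlang::eval_tidy(rlang::enquo(value), data)
  group_v <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(group_v) < 2) {
    stop_wm("Need at least 2 groups.", "config_error")
  }
  if (any(table(group_v) < 2)) {
    stop_wm("Need at least 2 observations per group.", "config_error")
  }
  df <- data.frame(.value = value_v, .group = group_v)
  fit <- aov(.value ~ .group, data = df)
  within_var <- vapply(split(value_v, group_v), stats::var, numeric(1))
  degenerate <- all(within_var < .Machine$double.eps)
  tk <- TukeyHSD(fit, conf.level = conf_level)
  structure(
    list(
      fit = fit, tukey = tk, degenerate = degenerate,
      star_cutpoints = sort(star_cutpoints),
      conf_level = conf_level,
      n_groups = nlevels(group_v), n_obs = length(value_v)
    ),
    class = "region_anova"
  )
}

p_stars <- function(p, cutpoints) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    hit <- which(pi < cutpoints)
    if (!length(hit)) "ns" else names(cutpoints)[hit[1]]
  }, character(1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise Tukey comparisons of a `region_anova`
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return A tibble with one row per pairwise contrast: `contrast`,
#'   `estimate`, `conf.low`, `conf.high`, `adj.p.value`, `stars`.
#' @method tidy region_anova
#' @export
tidy.region_anova <- function(x, ...) {
  m <- x$tukey$.group
  tibble(
    contrast = rownames(m),
    estimate = m[, "diff"],
    conf.low = m[, "lwr"],
    conf.high = m[, "upr"],
    adj.p.value = m[, "p adj"],
    stars = p_stars(m[, "p adj"], x$star_cutpoints)
  )
}

#' One-row summary of a `region_anova`
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return A tibble with `statistic` (the ANOVA F), `df`, `df.residual`,
#'   `p.value`, `n_groups`, `n_obs`, `degenerate`.
#' @method glance region_anova
#' @export
glance.region_anova <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  tibble(
    statistic = s[["F value"]][1],
    df = s[["Df"]][1],
    df.residual = s[["Df"]][2],
    p.value = s[["Pr(>F)"]][1],
    n_groups = x$n_groups,
    n_obs = x$n_obs,
    degenerate = x$degenerate
  )
}

#' @export
print.region_anova <- function(x, ...) {
  g <- glance(x)
  p_show <- if (!is.na(g$p.value) && g$p.value < 1e-6) "< 1e-6" else
    format(g$p.value, digits = 3)
  cat(sprintf(
    "<region_anova> one-way ANOVA: F(%d, %d) = %.3g, p %s%s\n",
    g$df, g$df.residual, g$statistic,
    if (grepl("^<", p_show)) p_show else paste0("= ", p_show),
    if (x$degenerate) " [degenerate: zero within-group variance]" else ""
  ))
  print(tidy(x))
  invisible(x)
}
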