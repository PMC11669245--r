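#' Significance stars
#'
#' The reporting convention: `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001,
#' `****` p <= 0.0001; `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p <= 0.0001 ~ "****",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Shapiro-Wilk normality check
#'
#' Thin, validated wrapper used as the parametric/non-parametric gate.
#' Requires 3 <= n <= 5000 finite values; ties are allowed with a warning.
#'
#' @param x Numeric sample.
#' @return Tibble: `statistic` (W), `p_value`, `n`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) abort("sample contains non-finite values")
  if (length(x) < 3 || length(x) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (anyDuplicated(x)) warn("ties present in Shapiro-Wilk sample")
  sw <- shapiro.test(x)
  tibble(statistic = unname(sw$statistic), p_value = sw$p.value,
         n = length(x))
}

#' Two-sided Mann-Whitney U test
#'
#' The non-parametric branch of the group comparisons. The p-value is exact
#' (full enumeration of the U distribution) when both samples are tie-free
#' and `n * m <= 2000`; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b Numeric samples.
#' @return List: `statistic` (U of the first sample), `p_value`, `exact`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 2000
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Normality-gated two-sample comparison
#'
#' The group-comparison rule for single-factor datasets: test each sample
#' for normality (Shapiro-Wilk at `normality_alpha`); when both pass, run a
#' two-sided Student's t-test (classical equal-variance form, or Welch with
#' `var_equal = FALSE`); otherwise a two-sided Mann-Whitney U test, exact
#' (full enumeration) when the samples are tie-free and `n * m <= 2000`,
#' with the normal approximation and tie correction otherwise. The branch
#' actually taken is always recorded.
#'
#' @param a,b Numeric samples (each n >= 3 so the gate is defined).
#' @param normality_alpha Gate level (default 0.05).
#' @param var_equal Use the classical equal-variance t (default `TRUE`).
#' @return An `mg_test` object; see [tidy.mg_test()].
#' @examples
#' two_sample_test(rnorm(20), rnorm(20, 1))
#' @export
two_sample_test <- function(a, b, normality_alpha = 0.05, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) {
    abort("both samples need n >= 3 for the normality gate")
  }
  if (length(unique(c(a, b))) == 1L) {
    abort("all values identical across both samples: test is degenerate")
  }
  sw_a <- suppressWarnings(shapiro_wilk(a))
  sw_b <- suppressWarnings(shapiro_wilk(b))
  normal <- sw_a$p_value > normality_alpha && sw_b$p_value > normality_alpha
  if (normal) {
    ht <- t.test(a, b, var.equal = var_equal)
    method <- if (var_equal) "student_t" else "welch_t"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    exact <- NA
  } else {
    mw <- mann_whitney_u(a, b)
    method <- "mann_whitney_u"
    statistic <- mw$statistic
    p <- mw$p_value
    exact <- mw$exact
  }
  structure(
    list(method = method, statistic = statistic, p_value = p,
         alternative = "two.sided",
         n = c(a = length(a), b = length(b)),
         normality_p = c(a = sw_a$p_value, b = sw_b$p_value),
         normality_alpha = normality_alpha,
         exact = exact, stars = p_stars(p),
         samples = list(a = a, b = b)),
    class = "mg_test"
  )
}

#' @export
print.mg_test <- function(x, ...) {
  cat(sprintf("<mg_test> %s: statistic = %.4g, p = %.4g %s (n = %d, %d)\n",
              x$method, x$statistic, x$p_value, x$stars, x$n[1], x$n[2]))
  cat(sprintf("  normality gate: p_a = %.3g, p_b = %.3g (alpha = %g)\n",
              x$normality_p[1], x$normality_p[2], x$normality_alpha))
  invisible(x)
}

#' Tidiers for gated two-sample tests
#'
#' @param x An `mg_test`.
#' @param ... Unused.
#' @return `tidy()`: one-row tibble with the method, statistic, p-value,
#'   stars and per-sample normality p-values. `glance()`: the same row
#'   (these objects carry a single test).
#' @export
tidy.mg_test <- function(x, ...) {
  tibble(
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    stars = x$stars, n_a = unname(x$n[1]), n_b = unname(x$n[2]),
    normality_p_a = unname(x$normality_p[1]),
    normality_p_b = unname(x$normality_p[2]),
    exact = x$exact
  )
}

#' @rdname tidy.mg_test
#' @export
glance.mg_test <- function(x, ...) tidy(x)

#' Two-way ANOVA with Bonferroni pairwise contrasts
#'
#' The two-factor rule (group x CD68 status): Type-II sums of squares on the
#' (generally unbalanced) 2 x 2 design, then the four pairwise contrasts of
#' interest — across groups within each CD68 stratum and across CD68 status
#' within each group — with Bonferroni-multiplied p-values capped at 1.
#'
#' @param data Data frame with the response and two factors.
#' @param value,group,factor2 Column names (strings) of the response, the
#'   group factor and the second factor.
#' @return An `mg_anova` object: `anova` (tibble of F-tests for both main
#'   effects and the interaction) and `contrasts` (tibble with raw and
#'   Bonferroni-adjusted p-values).
#' @export
two_way_anova_bonferroni <- function(data, value = "volume_um3",
                                     group = "group",
                                     factor2 = "cd68_status") {
  df <- data.frame(
    .y = data[[value]],
    .g = factor(data[[group]]),
    .f = factor(data[[factor2]])
  )
  counts <- table(df$.g, df$.f)
  if (any(counts < 2)) {
    bad <- which(counts < 2, arr.ind = TRUE)
    abort(sprintf("cell '%s x %s' has fewer than 2 observations",
                  rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  fit <- lm(.y ~ .g * .f, data = df)
  an <- car::Anova(fit, type = 2)
  an_tbl <- tibble(
    term = c(group, factor2, paste0(group, ":", factor2), "Residuals"),
    sumsq = an$`Sum Sq`, df = an$Df, statistic = an$`F value`,
    p_value = an$`Pr(>F)`
  )

  emm <- emmeans::emmeans(fit, ~ .g * .f)
  lv_g <- levels(df$.g); lv_f <- levels(df$.f)
  grid <- expand.grid(g = lv_g, f = lv_f)  # row order of emm
  cell <- function(g, f) as.numeric(grid$g == g & grid$f == f)
  contr <- list()
  for (f in lv_f) {
    contr[[sprintf("%s vs %s | %s", lv_g[1], lv_g[2], f)]] <-
      cell(lv_g[1], f) - cell(lv_g[2], f)
  }
  for (g in lv_g) {
    contr[[sprintf("%s vs %s | %s", lv_f[1], lv_f[2], g)]] <-
      cell(g, lv_f[1]) - cell(g, lv_f[2])
  }
  ct_raw <- summary(emmeans::contrast(emm, contr, adjust = "none"))
  k <- nrow(ct_raw)
  ct_tbl <- tibble(
    contrast = as.character(ct_raw$contrast),
    estimate = ct_raw$estimate, se = ct_raw$SE, df = ct_raw$df,
    statistic = ct_raw$t.ratio, p_raw = ct_raw$p.value,
    p_bonferroni = pmin(1, ct_raw$p.value * k)
  )
  ct_tbl$stars <- p_stars(ct_tbl$p_bonferroni)

  structure(
    list(anova = an_tbl, contrasts = ct_tbl, fit = fit,
         value = value, group = group, factor2 = factor2, data = df),
    class = "mg_anova"
  )
}

#' @export
print.mg_anova <- function(x, ...) {
  cat("<mg_anova> Type-II two-way ANOVA\n")
  print(as.data.frame(x$anova), row.names = FALSE)
  cat("Bonferroni pairwise contrasts:\n")
  print(as.data.frame(
    x$contrasts[, c("contrast", "estimate", "p_bonferroni", "stars")]),
    row.names = FALSE)
  invisible(x)
}

#' Tidiers for the two-way ANOVA
#'
#' @param x An `mg_anova`.
#' @param ... Unused.
#' @return `tidy()`: the ANOVA table stacked with the Bonferroni contrasts;
#'   `glance()`: one row with the three omnibus p-values.
#' @export
tidy.mg_anova <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$anova, kind = "anova"),
    x$contrasts |>
      dplyr::transmute(term = .data$contrast, statistic = .data$statistic,
                       p_value = .data$p_bonferroni, kind = "contrast")
  )
}

#' @rdname tidy.mg_anova
#' @export
glance.mg_anova <- function(x, ...) {
  an <- x$anova
  tibble(
    p_group = an$p_value[1], p_factor2 = an$p_value[2],
    p_interaction = an$p_value[3],
    n = nrow(x$data)
  )
}

#' Group summaries in mean +/- SEM form
#'
#' @param data Data frame.
#' @param value,group Column names (strings).
#' @return Tibble per group: `n`, `mean`, `sd`, `sem` (`sd/sqrt(n)`, sample
#'   sd with the n-1 denominator) and a formatted `label`.
#' @examples
#' summarize_groups(data.frame(v = c(2, 4, 6), g = "a"), "v", "g")
#' @export
summarize_groups <- function(data, value, group) {
  if (nrow(data) == 0) abort("no observations to summarize")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sd = ifelse(dplyr::n() > 1, sd(.data[[value]]), 0),
      sem = ifelse(dplyr::n() > 1, sd(.data[[value]]) / sqrt(dplyr::n()), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = sprintf("%.4g ± %.4g", mean, sem))
}
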