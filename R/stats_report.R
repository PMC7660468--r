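# Group statistics: median [Q1, Q3] summaries, Kruskal-Wallis across
# cardiac phases with Bonferroni-corrected Dunn pairwise tests, and
# intraclass correlation (ICC) reproducibility analysis.

#' Median [Q1, Q3] summaries per group
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param df data frame.
#' @param value column with the metric (tidy-eval).
#' @param group grouping column (tidy-eval).
#' @return Tibble: group, `median`, `q1`, `q3`, `n`.
#' @export
summarize_groups <- function(df, value, group) {
  df |>
    dplyr::group_by({{ group }}) |>
    dplyr::summarise(
      median = stats::median({{ value }}, na.rm = TRUE),
      q1 = stats::quantile({{ value }}, 0.25, na.rm = TRUE, names = FALSE),
      q3 = stats::quantile({{ value }}, 0.75, na.rm = TRUE, names = FALSE),
      n = sum(is.finite({{ value }})),
      .groups = "drop"
    )
}

# Dunn's pairwise z-tests on the pooled ranks, with tie correction --
# the omnibus-consistent post hoc for Kruskal-Wallis.
dunn_pairwise <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  rk <- rank(values)
  N <- length(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  mean_rk <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  pairs <- utils::combn(lv, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (mean_rk[[a]] - mean_rk[[b]]) / se
    tibble::tibble(group1 = a, group2 = b, z = z,
                   p_raw = 2 * stats::pnorm(-abs(z)))
  })
}

#' Compare a metric across cardiac phases
#'
#' Tie-corrected Kruskal-Wallis omnibus test; when the omnibus rejects at
#' `alpha`, Dunn pairwise z-tests on the pooled ranks are run with a
#' Bonferroni adjustment over all pairs (`p_adj = min(1, p * n_pairs)`).
#'
#' @param df data frame with one row per subject-phase observation.
#' @param value metric column (tidy-eval).
#' @param phase phase column (tidy-eval).
#' @param alpha omnibus significance level gating the post hocs.
#' @return A `cdti_phase_comparison`: per-phase summaries, omnibus H and p,
#'   and the pairwise table. Identical groups give H = 0, p = 1.
#' @export
compare_phases <- function(df, value, phase, alpha = 0.05) {
  values <- dplyr::pull(df, {{ value }})
  phases <- dplyr::pull(df, {{ phase }})
  ok <- is.finite(values) & !is.na(phases)
  values <- values[ok]; phases <- factor(phases[ok])
  if (nlevels(phases) < 2 || any(table(phases) < 2)) {
    stop("need >= 2 phases with >= 2 observations each", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    omnibus <- list(statistic = c(H = 0), p.value = 1,
                    parameter = c(df = nlevels(phases) - 1))
  } else {
    kw <- stats::kruskal.test(values, phases)
    omnibus <- list(statistic = kw$statistic, p.value = kw$p.value,
                    parameter = kw$parameter)
  }
  pairwise <- dunn_pairwise(values, phases)
  n_pairs <- nrow(pairwise)
  pairwise$p_adj <- pmin(1, pairwise$p_raw * n_pairs)
  pairwise$significant <- omnibus$p.value < alpha & pairwise$p_adj < alpha
  structure(list(
    summaries = summarize_groups(
      tibble::tibble(value = values, phase = phases), value, phase),
    statistic = unname(omnibus$statistic),
    df = unname(omnibus$parameter),
    p_value = omnibus$p.value,
    pairwise = pairwise,
    alpha = alpha,
    posthoc_run = omnibus$p.value < alpha
  ), class = "cdti_phase_comparison")
}

#' @export
print.cdti_phase_comparison <- function(x, ...) {
  cat("Kruskal-Wallis: H =", signif(x$statistic, 4), "df =", x$df,
      "p =", signif(x$p_value, 3), "\n")
  print(x$summaries)
  if (x$posthoc_run) {
    cat("Dunn pairwise (Bonferroni-adjusted):\n")
    print(x$pairwise)
  } else {
    cat("omnibus not significant at", x$alpha, "- post hocs not interpreted\n")
  }
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.cdti_phase_comparison <- function(x, ...) {
  dplyr::select(x$pairwise, "group1", "group2", "z",
                p.value = "p_raw", adj.p.value = "p_adj", "significant")
}

#' @export
#' @importFrom generics glance
glance.cdti_phase_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 posthoc_run = x$posthoc_run)
}

#' Intraclass correlation for observer reproducibility
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (ICC(2,1)) on a subjects x observations rating matrix, with the
#' F-distribution confidence bounds. With two observers each rating twice
#' (columns observer1/rep1, observer1/rep2, observer2/rep1, observer2/rep2),
#' `design` selects the observation subset: all four (`"overall"`), the
#' first rating of each observer (`"inter"`), or both ratings of one
#' observer (`"intra"` with `observer`).
#'
#' @param ratings numeric matrix, subjects in rows, observations in columns.
#' @param design `"overall"`, `"inter"`, or `"intra"`.
#' @param observer observer index (1 or 2) for `design = "intra"`; columns
#'   are assumed ordered (obs1 rep1, obs1 rep2, obs2 rep1, obs2 rep2).
#' @param conf_level confidence level for the interval.
#' @return A `cdti_icc`: estimate, CI bounds, variance components, design.
#' @export
icc <- function(ratings, design = c("overall", "inter", "intra"),
                observer = 1, conf_level = 0.95) {
  design <- match.arg(design)
  ratings <- as.matrix(ratings)
  if (design == "inter") {
    if (ncol(ratings) < 4) stop("inter-observer design needs 4 columns", call. = FALSE)
    ratings <- ratings[, c(1, 3)]
  } else if (design == "intra") {
    if (ncol(ratings) < 4) stop("intra-observer design needs 4 columns", call. = FALSE)
    ratings <- ratings[, if (observer == 1) c(1, 2) else c(3, 4)]
  }
  complete <- stats::complete.cases(ratings)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) dropped for missing observations")
    ratings <- ratings[complete, , drop = FALSE]
  }
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3) stop("ICC needs at least 3 complete subjects", call. = FALSE)

  row_means <- rowMeans(ratings); col_means <- colMeans(ratings)
  grand <- mean(ratings)
  MSR <- k * sum((row_means - grand)^2) / (n - 1)
  MSC <- n * sum((col_means - grand)^2) / (k - 1)
  MSE <- sum((ratings - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2) / ((n - 1) * (k - 1))
  if (MSR < .Machine$double.eps) {
    warning("zero between-subject variance: ICC undefined")
    est <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    # F-based bounds (McGraw & Wong A,1 absolute agreement)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    alpha <- 1 - conf_level
    Fl <- stats::qf(1 - alpha / 2, n - 1, v)
    Fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - Fl * MSE) /
      (Fl * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (Fu * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * Fu * MSR)
  }
  structure(list(estimate = est, conf_low = lo, conf_high = hi,
                 conf_level = conf_level, design = design,
                 observer = if (design == "intra") observer else NA,
                 n_subjects = n, n_observations = k,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE)),
            class = "cdti_icc")
}

#' @export
print.cdti_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) [%s]: %.3f (%d%% CI %.3f-%.3f), n = %d x %d\n",
              x$design, x$estimate, round(100 * x$conf_level),
              x$conf_low, x$conf_high, x$n_subjects, x$n_observations))
  invisible(x)
}

#' @export
tidy.cdti_icc <- function(x, ...) {
  tibble::tibble(design = x$design, estimate = x$estimate,
                 conf.low = x$conf_low, conf.high = x$conf_high,
                 n_subjects = x$n_subjects, n_observations = x$n_observations)
}
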