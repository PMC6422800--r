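#' One-way ANCOVA for a group comparison with covariates
#'
#' Fits the linear model `measure ~ group + covariates` and tests the group
#' term with a partial (type-III-equivalent, since group is the only factor)
#' F-test: `F = (SS_group / 1) / (SS_residual / df_residual)` with
#' `p = P(F(1, n - k - 1) > F)`. The effect size is partial eta squared,
#' `SS_group / (SS_group + SS_residual)`. Sex is coded 0/1 (F/M); the band
#' power covariate is log-transformed by default for variance stabilization.
#' Covariates with zero variance in the data are dropped with a message
#' rather than producing a rank-deficient design.
#'
#' @param data Data frame with a `group` column (two levels, reference
#'   ordering `IA` vs `HC` respected if present) and the measure/covariate
#'   columns.
#' @param measure Name of the outcome column (string).
#' @param covariates Character vector of covariate column names (default
#'   `age`, `sex`, `band_power`).
#' @param log_power Log-transform the `band_power` covariate (default TRUE).
#' @return An object of class `mstnet_ancova`: the fitted `lm` plus the test
#'   summary. Use [generics::tidy()] for the one-row result table.
#' @export
ancova <- function(data, measure, covariates = c("age", "sex", "band_power"),
                   log_power = TRUE) {
  data <- as.data.frame(data)
  if (!measure %in% names(data)) {
    stop("no column `", measure, "` in `data`", call. = FALSE)
  }
  groups <- unique(data$group)
  if (length(groups) < 2) stop("need two groups", call. = FALSE)
  if (length(groups) > 2) stop("more than two groups", call. = FALSE)
  if (min(table(data$group)) < 2) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  df <- data.frame(y = data[[measure]])
  lv <- if (all(c("IA", "HC") %in% groups)) c("HC", "IA") else sort(groups)
  df$group <- factor(data$group, levels = lv)
  used <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(data)) {
      stop("missing covariate column `", cv, "`", call. = FALSE)
    }
    v <- data[[cv]]
    if (cv == "sex") v <- as.numeric(v %in% c("M", "m", 1, TRUE))
    if (cv == "band_power" && log_power) v <- log(v)
    v <- as.numeric(v)
    if (!all(is.finite(v)) ) {
      stop("covariate `", cv, "` contains non-finite values", call. = FALSE)
    }
    if (var(v) == 0) {
      message("covariate `", cv, "` has zero variance; dropped")
      next
    }
    df[[cv]] <- v
    used <- c(used, cv)
  }
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  full <- lm(y ~ ., data = df)
  red <- lm(y ~ . - group, data = df)
  ss_res <- sum(residuals(full)^2)
  ss_group <- sum(residuals(red)^2) - ss_res
  df_res <- full$df.residual
  f <- (ss_group / 1) / (ss_res / df_res)
  p <- pf(f, 1, df_res, lower.tail = FALSE)
  eta2 <- ss_group / (ss_group + ss_res)
  means <- tapply(df$y, df$group, mean)
  structure(
    list(fit = full, measure = measure, covariates = used,
         F = f, df1 = 1, df2 = df_res, p = p, eta2 = eta2,
         group_means = means, n = nrow(df)),
    class = "mstnet_ancova"
  )
}

#' @export
print.mstnet_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA on %s: F(%d, %d) = %.3f, p = %.4g, partial eta2 = %.4f\n",
              x$measure, x$df1, x$df2, x$F, x$p, x$eta2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ancova
#' @param x An `mstnet_ancova` object.
#' @param alpha Significance level used to call a direction.
#' @param ... Unused.
#' @export
tidy.mstnet_ancova <- function(x, alpha = 0.05, ...) {
  lv <- names(x$group_means)
  dir <- if (is.na(x$p) || x$p >= alpha) {
    "n.s."
  } else if (x$group_means[[length(lv)]] > x$group_means[[1]]) {
    paste0(lv[length(lv)], ">", lv[1])
  } else {
    paste0(lv[length(lv)], "<", lv[1])
  }
  tibble::tibble(
    measure = x$measure, statistic = x$F, df1 = x$df1, df2 = x$df2,
    p = x$p, effect = x$eta2, direction = dir
  )
}

#' @rdname ancova
#' @export
glance.mstnet_ancova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = x$n, r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, covariates = paste(x$covariates, collapse = "+")
  )
}

#' Bonferroni correction
#'
#' Adjusted p-values `min(1, p * m)` for `m` comparisons (default 9, the
#' number of global measures tested per band, giving the per-band threshold
#' 0.05/9, conventionally printed as "p < 0.006").
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Number of comparisons (default `9`; use `length(p)` semantics
#'   explicitly if desired).
#' @param alpha Family-wise level used to report the threshold.
#' @return Adjusted p-values, with the per-band significance threshold
#'   `alpha / m` attached as attribute `"threshold"`.
#' @export
#' @examples
#' bonferroni(c(0.004, 0.5), m = 9)
bonferroni <- function(p, m = 9, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  structure(pmin(1, p * m), threshold = alpha / m)
}

#' Regional two-sample t-tests on nodal measures
#'
#' Per-channel two-sample t-tests (pooled variance by default, Welch behind
#' the flag) comparing a nodal statistic between groups. P-values are
#' uncorrected, matching common practice for regional exploration; an
#' optional FDR column is available.
#'
#' @param nodal_tbl Tibble with `subject_id`, `group`, `node` and the nodal
#'   statistic columns (see [analyze_cohort()]).
#' @param statistic `"degree"` or `"bc"`.
#' @param var_equal Pooled-variance t-test (default TRUE); `FALSE` for Welch.
#' @param fdr Add a Benjamini-Hochberg adjusted column.
#' @return A tibble with one row per node: `node`, `statistic`, `t`, `p`,
#'   group means and `direction` (NA rows where both groups have zero
#'   variance).
#' @export
regional_ttest <- function(nodal_tbl, statistic = c("degree", "bc"),
                           var_equal = TRUE, fdr = FALSE) {
  statistic <- match.arg(statistic)
  groups <- unique(nodal_tbl$group)
  if (length(groups) != 2) stop("need exactly two groups", call. = FALSE)
  if (any(table(nodal_tbl$group, nodal_tbl$node) < 2)) {
    stop("need >= 2 subjects per group at every node", call. = FALSE)
  }
  lv <- if (all(c("IA", "HC") %in% groups)) c("HC", "IA") else sort(groups)
  nodes <- unique(nodal_tbl$node)
  rows <- lapply(nodes, function(nd) {
    sub <- nodal_tbl[nodal_tbl$node == nd, ]
    a <- sub[[statistic]][sub$group == lv[2]]
    b <- sub[[statistic]][sub$group == lv[1]]
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble::tibble(node = nd, t = NA_real_, p = NA_real_,
                            mean_a = mean(a), mean_b = mean(b)))
    }
    tt <- t.test(a, b, var.equal = var_equal)
    tibble::tibble(node = nd, t = unname(tt$statistic), p = tt$p.value,
                   mean_a = mean(a), mean_b = mean(b))
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lv[2])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lv[1])
  out$statistic <- statistic
  out$direction <- dplyr::case_when(
    is.na(out$p) | out$p >= 0.05 ~ "n.s.",
    out[[paste0("mean_", lv[2])]] > out[[paste0("mean_", lv[1])]] ~
      paste0(lv[2], ">", lv[1]),
    TRUE ~ paste0(lv[2], "<", lv[1])
  )
  if (fdr) out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Pearson correlation between a measure and symptom severity
#'
#' Pearson's r with a two-sided p-value from the t transform with n - 2
#' degrees of freedom, relating a (global or regional) network measure to the
#' IAT severity score.
#'
#' @param data Data frame holding the columns.
#' @param measure Outcome column name (string).
#' @param score Severity column name (default `"iat"`).
#' @return A one-row tibble: `measure`, `n`, `r`, `p`.
#' @export
severity_correlation <- function(data, measure, score = "iat") {
  x <- as.numeric(data[[measure]])
  y <- as.numeric(data[[score]])
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(measure = measure, n = length(x),
                 r = unname(ct$estimate), p = ct$p.value)
}

#' Demographic group comparisons
#'
#' Standard cohort-description tests: two-sample t-tests for age and IAT and
#' a Pearson chi-square (no continuity correction by default, matching the
#' plain Sum((O-E)^2/E) statistic) for the sex contingency table. Expected
#' cell counts below 5 trigger a validity warning rather than an error.
#'
#' @param meta Tibble with `group`, `age`, `sex`, `iat`.
#' @param correct Apply Yates continuity correction to the chi-square.
#' @param var_equal Pooled-variance t-tests (default TRUE).
#' @return A tibble with one row per characteristic: `characteristic`,
#'   `test`, `statistic`, `p`, per-group summaries.
#' @export
demographics <- function(meta, correct = FALSE, var_equal = TRUE) {
  groups <- sort(unique(meta$group), decreasing = TRUE) # IA before HC
  if (length(groups) != 2) stop("need both groups", call. = FALSE)
  g1 <- meta[meta$group == groups[1], ]
  g2 <- meta[meta$group == groups[2], ]
  trow <- function(name, x, y) {
    tt <- t.test(x, y, var.equal = var_equal)
    tibble::tibble(
      characteristic = name, test = "two-sample t",
      statistic = unname(tt$statistic), p = tt$p.value,
      summary_1 = sprintf("%.1f ± %.2f", mean(x), sd(x)),
      summary_2 = sprintf("%.1f ± %.2f", mean(y), sd(y))
    )
  }
  tab <- table(factor(meta$group, levels = groups),
               factor(meta$sex, levels = c("M", "F")))
  if (any(tab == 0) || length(unique(meta$sex)) < 2) {
    warning("degenerate sex distribution: chi-square validity doubtful",
            call. = FALSE)
  }
  cs <- tryCatch(
    suppressWarnings(chisq.test(tab, correct = correct)),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_,
                             expected = matrix(NA_real_, 2, 2))
  )
  if (any(cs$expected < 5, na.rm = TRUE)) {
    warning("chi-square expected cell count < 5; interpret with caution",
            call. = FALSE)
  }
  out <- dplyr::bind_rows(
    trow("age", g1$age, g2$age),
    tibble::tibble(
      characteristic = "sex", test = "Pearson chi-square",
      statistic = unname(cs$statistic), p = cs$p.value,
      summary_1 = sprintf("%d/%d", tab[1, "M"], tab[1, "F"]),
      summary_2 = sprintf("%d/%d", tab[2, "M"], tab[2, "F"])
    ),
    trow("iat", g1$iat, g2$iat)
  )
  names(out)[names(out) == "summary_1"] <- groups[1]
  names(out)[names(out) == "summary_2"] <- groups[2]
  out
}

#' @importFrom stats residuals
NULL
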