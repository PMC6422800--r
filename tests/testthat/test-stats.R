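test_that("ancova matches the normal-equations oracle on a hand-built table", {
  dat <- tibble::tibble(
    group = rep(c("IA", "HC"), each = 4),
    age = c(21, 22, 20, 23, 19, 21, 22, 20),
    sex = c("M", "F", "F", "M", "F", "F", "M", "F"),
    band_power = c(3.2, 2.8, 3.5, 3.0, 2.6, 3.1, 2.9, 3.3),
    y = c(0.52, 0.49, 0.57, 0.50, 0.41, 0.44, 0.47, 0.39)
  )
  fit <- ancova(dat, "y")
  ref <- oracle_ancova(
    dat$y, as.numeric(dat$group == "IA"),
    cbind(dat$age, as.numeric(dat$sex == "M"), log(dat$band_power))
  )
  expect_equal(fit$F, ref$F, tolerance = 1e-10)
  expect_equal(fit$p, ref$p, tolerance = 1e-10)
  expect_equal(fit$eta2, ref$eta2, tolerance = 1e-10)
  td <- tidy(fit, alpha = 1) # force a direction call regardless of p
  expect_equal(td$statistic, ref$F, tolerance = 1e-10)
  expect_equal(td$direction, "IA>HC")
  expect_equal(fit$df2, 8 - 4 - 1)
  gl <- glance(fit)
  expect_equal(gl$n, 8)
})

test_that("a noiseless additive group effect drives p to 0 and eta2 to 1", {
  dat <- tibble::tibble(
    group = rep(c("IA", "HC"), each = 5),
    age = rep(20, 10), sex = rep("F", 10), band_power = rep(1, 10),
    y = rep(c(2, 1), each = 5)
  )
  fit <- suppressMessages(ancova(dat, "y"))
  expect_equal(fit$eta2, 1)
  expect_lt(fit$p, 1e-12)
})

test_that("ancova with degenerate covariates reduces to one-way ANOVA", {
  set.seed(30)
  dat <- tibble::tibble(
    group = rep(c("IA", "HC"), each = 10),
    age = rep(21, 20), sex = rep("F", 20), band_power = rep(2, 20),
    y = rnorm(20) + rep(c(0.5, 0), each = 10)
  )
  fit <- suppressMessages(ancova(dat, "y"))
  ref <- anova(lm(y ~ group, data = dat))
  expect_equal(fit$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(fit$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("ancova validates its design", {
  dat <- tibble::tibble(group = rep("IA", 4), age = 1:4, sex = "F",
                        band_power = 1, y = rnorm(4))
  expect_error(ancova(dat, "y"), "two groups")
  expect_error(ancova(dat, "nope"), "no column")
  dat2 <- tibble::tibble(group = c("IA", "IA", "HC"), age = 1:3, sex = "F",
                         band_power = 1, y = rnorm(3))
  expect_error(ancova(dat2, "y"), ">= 2 subjects")
})

test_that("bonferroni matches the printed per-band threshold and caps", {
  adj <- bonferroni(c(0.004, 0.5, 0.0001), m = 9)
  expect_equal(as.numeric(adj), c(0.036, 1, 0.0009))
  expect_equal(attr(adj, "threshold"), 0.05 / 9)
  expect_equal(round(attr(adj, "threshold"), 3), 0.006)
  expect_true(all(as.numeric(adj) >= c(0.004, 0.5, 0.0001)))
  # monotone in m
  p <- c(0.01, 0.2)
  a3 <- as.numeric(bonferroni(p, 3))
  a6 <- as.numeric(bonferroni(p, 6))
  expect_true(all(a6 >= a3))
  expect_error(bonferroni(c(0.1, 1.2)), "0, 1")
})

test_that("regional t-tests recover an injected nodal difference", {
  set.seed(31)
  nodes <- montage_1020_64()[1:10]
  n <- 15
  tbl <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", 1:(2 * n)),
    node = nodes
  )
  tbl$group <- rep(rep(c("IA", "HC"), each = n), each = 1)[
    match(tbl$subject_id, sprintf("S%02d", 1:(2 * n)))]
  tbl$degree <- rnorm(nrow(tbl), 0.3, 0.05)
  boost <- tbl$node == "C3" & tbl$group == "IA"
  tbl$degree[boost] <- tbl$degree[boost] + 0.15
  tbl$bc <- rnorm(nrow(tbl), 0.2, 0.05)
  res <- regional_ttest(tbl, "degree")
  flagged <- res$node[!is.na(res$p) & res$p < 0.05]
  expect_true("C3" %in% flagged)
  expect_equal(res$direction[res$node == "C3"], "IA>HC")
  # identical groups: no more than chance-level flagging
  tbl0 <- tbl
  tbl0$degree <- rnorm(nrow(tbl0), 0.3, 0.05)
  res0 <- regional_ttest(tbl0, "degree")
  expect_lte(sum(res0$p < 0.05), 3)
  # degenerate cases
  tiny <- tbl[tbl$subject_id %in% c("S01", "S16"), ]
  expect_error(regional_ttest(tiny, "degree"), ">= 2")
  res_fdr <- regional_ttest(tbl, "degree", fdr = TRUE)
  expect_true(all(res_fdr$p_fdr >= res_fdr$p, na.rm = TRUE))
})

test_that("zero-variance nodes are reported missing, not zero", {
  tbl <- tidyr::expand_grid(subject_id = sprintf("S%d", 1:8), node = "X")
  tbl$group <- rep(c("IA", "HC"), each = 4)
  tbl$degree <- 0.5
  tbl$bc <- 0
  res <- regional_ttest(tbl, "degree")
  expect_true(is.na(res$t))
  expect_true(is.na(res$p))
})

test_that("severity correlation hits the exact linear anchors", {
  iat <- c(25, 33, 41, 50, 55, 60, 64, 70, 74, 78)
  d1 <- tibble::tibble(iat = iat, m = 2 * iat + 1)
  expect_equal(severity_correlation(d1, "m")$r, 1)
  d2 <- tibble::tibble(iat = iat, m = -iat)
  expect_equal(severity_correlation(d2, "m")$r, -1)
  set.seed(32)
  d3 <- tibble::tibble(iat = iat, m = rnorm(10))
  res <- severity_correlation(d3, "m")
  # direct covariance-formula oracle
  r_ref <- sum((d3$m - mean(d3$m)) * (iat - mean(iat))) /
    sqrt(sum((d3$m - mean(d3$m))^2) * sum((iat - mean(iat))^2))
  expect_equal(res$r, r_ref, tolerance = 1e-12)
  t_ref <- r_ref * sqrt(8 / (1 - r_ref^2))
  expect_equal(res$p, 2 * pt(-abs(t_ref), 8), tolerance = 1e-12)
  expect_error(severity_correlation(tibble::tibble(iat = c(1, 2), m = c(1, 2)),
                                    "m"), "n >= 3")
  expect_error(severity_correlation(tibble::tibble(iat = iat, m = 1), "m"),
               "zero variance")
})

test_that("demographics reproduces the hand-computed chi-square", {
  meta <- tibble::tibble(
    group = rep(c("IA", "HC"), each = 30),
    sex = c(rep("M", 7), rep("F", 23), rep("M", 6), rep("F", 24)),
    age = c(rnorm(30, 21, 2), rnorm(30, 20.5, 1.6)),
    iat = c(round(rnorm(30, 59, 8)), round(rnorm(30, 34, 8)))
  )
  out <- demographics(meta)
  # Pearson chi-square by Sum((O-E)^2/E) on the 2x2 table [[7,23],[6,24]]
  O <- matrix(c(7, 23, 6, 24), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  expect_equal(out$statistic[out$characteristic == "sex"], chi2,
               tolerance = 1e-12)
  expect_equal(out$test[out$characteristic == "age"], "two-sample t")
  expect_true(all(c("age", "sex", "iat") %in% out$characteristic))
  # identical groups: t statistic 0, p = 1
  meta_eq <- meta
  meta_eq$age <- rep(c(20, 21, 22), 20)
  meta_eq$iat <- rep(c(30, 40, 50), 20)
  out_eq <- demographics(meta_eq)
  expect_equal(out_eq$p[out_eq$characteristic == "age"], 1)
  # degenerate all-one-sex cohort warns (also trips the expected-count check)
  meta_deg <- meta
  meta_deg$sex <- "F"
  suppressWarnings(expect_warning(demographics(meta_deg), "degenerate"))
})
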