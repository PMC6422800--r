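#' Run the per-subject network analysis over a cohort
#'
#' For every subject and requested band: zero-phase band-pass filter the
#' continuous recording, segment into epochs, apply the shared
#' amplitude-rejection mask (computed once per subject on the unfiltered
#' epochs so every band sees the same artifact-free data), estimate one PLI
#' matrix per kept epoch, extract its maximum-weight spanning tree, compute
#' nodal and global tree measures, and average across epochs. Band power (the
#' ANCOVA covariate) is the kept-epoch mean periodogram power integrated over
#' the band.
#'
#' @param cohort An `eeg_cohort` (see [gen_cohort()]) or a list with elements
#'   `recordings` (named list of [eeg_recording()]) and `meta` (tibble with
#'   `subject_id`, `group`, `age`, `sex`, `iat`).
#' @param bands Tibble of band definitions (default all of [eeg_bands()]).
#' @param epoch_len_s Epoch length in seconds.
#' @param amp_threshold Rejection threshold in microvolts.
#' @param min_epochs Sufficiency rule: subjects with fewer kept epochs are
#'   flagged (warning + `sufficient = FALSE` in the QC table), not dropped.
#' @param edge_trim Per-epoch phase-series trim fraction (see [pli_matrix()]).
#' @param pooled Pool epochs into a single PLI estimate per subject instead
#'   of per-epoch estimates averaged afterwards.
#' @param broadband Optional `c(low, high)` broadband pre-filter applied
#'   before anything else (e.g. `c(0.5, 50)`); `NULL` to skip (synthetic data
#'   are already band-limited).
#' @return A list of class `mst_analysis`:
#' * `metrics`: one row per subject x band (metadata, `band_power`, `pli`,
#'   and the averaged global tree measures) - the unit of statistical
#'   analysis;
#' * `nodal`: one row per subject x band x channel with epoch-averaged nodal
#'   `degree`, `bc`, `ecc`;
#' * `qc`: per-subject epoch counts;
#' * `mean_matrix`: per band x group element-wise mean of the subjects'
#'   epoch-averaged PLI matrices.
#' @export
analyze_cohort <- function(cohort, bands = eeg_bands(), epoch_len_s = 2,
                           amp_threshold = 150, min_epochs = 80,
                           edge_trim = 0.05, pooled = FALSE,
                           broadband = NULL) {
  recordings <- cohort$recordings
  meta <- tibble::as_tibble(cohort$meta)
  stopifnot(all(meta$subject_id %in% names(recordings)))
  bands <- tibble::as_tibble(bands)

  metric_rows <- list()
  nodal_rows <- list()
  qc_rows <- list()
  mat_acc <- list() # band:group -> accumulated matrix

  for (s in seq_len(nrow(meta))) {
    id <- meta$subject_id[s]
    rec <- recordings[[id]]
    if (!is.null(broadband)) rec <- prefilter(rec, broadband[1], broadband[2])
    ep_raw <- segment_epochs(rec, epoch_len_s)
    ep_raw <- suppressWarnings(
      reject_epochs(ep_raw, amp_threshold, min_epochs)
    )
    qc <- attr(ep_raw, "qc")
    qc_rows[[id]] <- dplyr::bind_cols(tibble::tibble(subject_id = id), qc)
    if (qc$epochs_kept == 0) {
      warning("subject ", id, ": no epochs survive rejection; skipped",
              call. = FALSE)
      next
    }
    for (b in seq_len(nrow(bands))) {
      brow <- bands[b, ]
      bp <- band_power(ep_raw, c(brow$low, brow$high))
      filt <- bandpass(rec, c(brow$low, brow$high))
      ep <- segment_epochs(filt, epoch_len_s)
      ep$kept <- ep_raw$kept
      mats <- pli_matrix(ep, band = c(brow$low, brow$high),
                         edge_trim = edge_trim, pooled = pooled)
      if (pooled) mats <- list(mats)
      n_ch <- dim(ep$data)[2]
      n_mats <- length(mats)
      glob <- matrix(NA_real_, n_mats, 8)
      deg_acc <- bc_acc <- ecc_acc <- numeric(n_ch)
      mat_sum <- matrix(0, n_ch, n_ch)
      for (k in seq_len(n_mats)) {
        w <- unclass(mats[[k]])
        smry <- cpp_mst_summary(w)
        glob[k, ] <- smry$global
        deg_acc <- deg_acc + smry$degree
        bc_acc <- bc_acc + smry$bc
        ecc_acc <- ecc_acc + smry$ecc
        mat_sum <- mat_sum + w
      }
      colnames(glob) <- c("max_degree", "max_bc", "ecc", "diameter",
                          "leaf", "th", "kappa", "r")
      avg_mat <- new_pli_matrix(mat_sum / n_mats, rec$channel_labels,
                                brow$band, "averaged", n_mats)
      key <- paste(brow$band, meta$group[s], sep = ":")
      if (is.null(mat_acc[[key]])) {
        mat_acc[[key]] <- list(sum = unclass(avg_mat), n = 1L,
                               band = brow$band, group = meta$group[s],
                               labels = rownames(avg_mat))
      } else {
        mat_acc[[key]]$sum <- mat_acc[[key]]$sum + unclass(avg_mat)
        mat_acc[[key]]$n <- mat_acc[[key]]$n + 1L
      }
      avg <- epoch_average_metrics(tibble::as_tibble(glob))
      metric_rows[[length(metric_rows) + 1L]] <- dplyr::bind_cols(
        meta[s, ], tibble::tibble(band = brow$band, band_power = bp,
                                  pli = global_pli(avg_mat)), avg
      )
      nodal_rows[[length(nodal_rows) + 1L]] <- tibble::tibble(
        subject_id = meta$subject_id[s], group = meta$group[s],
        band = brow$band, node = rec$channel_labels,
        degree = deg_acc / n_mats, bc = bc_acc / n_mats,
        ecc = ecc_acc / n_mats
      )
    }
  }
  qc <- dplyr::bind_rows(qc_rows)
  insufficient <- qc$subject_id[!qc$sufficient]
  if (length(insufficient) > 0) {
    warning("subjects below the minimum epoch count (", min_epochs, "): ",
            paste(insufficient, collapse = ", "), call. = FALSE)
  }
  mean_matrix <- lapply(mat_acc, function(a) {
    new_pli_matrix(a$sum / a$n, a$labels, a$band, "group-mean", a$n)
  })
  structure(
    list(metrics = dplyr::bind_rows(metric_rows),
         nodal = dplyr::bind_rows(nodal_rows),
         qc = qc, mean_matrix = mean_matrix),
    class = "mst_analysis"
  )
}

#' @export
print.mst_analysis <- function(x, ...) {
  cat(sprintf("<mst_analysis> %d subjects x %d band(s); %d metric rows\n",
              nrow(x$qc), length(unique(x$metrics$band)), nrow(x$metrics)))
  invisible(x)
}

# The nine global measures of the group-comparison table, in report order.
global_measures <- function() {
  c("pli", "max_degree", "ecc", "max_bc", "kappa", "r", "diameter", "leaf",
    "th")
}

#' Covariate-adjusted group comparison table
#'
#' Runs the ANCOVA of [ancova()] for every global measure within every band
#' and assembles the standard report shape: group means and SDs, F, p,
#' Bonferroni-adjusted p (m comparisons per band, default 9), partial eta
#' squared and the direction of any significant difference. Subjects with an
#' undefined degree correlation are dropped listwise for the `r` row only,
#' with the count retained in `n_used`.
#'
#' @param metrics The `metrics` tibble of [analyze_cohort()].
#' @param measures Measure columns to test (default the nine global ones).
#' @param covariates Covariates passed to [ancova()].
#' @param m Bonferroni comparison count per band (default the number of
#'   measures).
#' @param alpha Significance level for the direction call.
#' @param log_power Passed to [ancova()].
#' @return A tibble, one row per band x measure.
#' @export
group_comparison_table <- function(metrics, measures = global_measures(),
                                   covariates = c("age", "sex", "band_power"),
                                   m = length(measures), alpha = 0.05,
                                   log_power = TRUE) {
  rows <- list()
  for (bd in unique(metrics$band)) {
    sub <- metrics[metrics$band == bd, ]
    for (ms in measures) {
      use <- sub[is.finite(sub[[ms]]), ]
      fit <- ancova(use, ms, covariates = covariates, log_power = log_power)
      td <- tidy(fit, alpha = alpha)
      gm <- use |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(mean = mean(.data[[ms]]), sd = sd(.data[[ms]]),
                         .groups = "drop")
      wide <- stats::setNames(
        c(gm$mean, gm$sd),
        c(paste0("mean_", gm$group), paste0("sd_", gm$group))
      )
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(band = bd, measure = ms, n_used = fit$n),
        tibble::as_tibble(as.list(wide)),
        td[, c("statistic", "p", "effect", "direction")]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out |>
    dplyr::group_by(.data$band) |>
    dplyr::mutate(p_adjusted = as.numeric(bonferroni(.data$p, m = m))) |>
    dplyr::ungroup()
  attr(out, "bonferroni_threshold") <- alpha / m
  out
}

#' Severity correlation table
#'
#' Pearson correlations between each global measure and the IAT severity
#' score, per band (the standard severity-association report shape).
#'
#' @inheritParams group_comparison_table
#' @param score Severity column (default `"iat"`).
#' @return A tibble, one row per band x measure: `band`, `measure`, `n`,
#'   `r`, `p`.
#' @export
severity_table <- function(metrics, measures = global_measures(),
                           score = "iat") {
  rows <- list()
  for (bd in unique(metrics$band)) {
    sub <- metrics[metrics$band == bd, ]
    for (ms in measures) {
      use <- sub[is.finite(sub[[ms]]), ]
      res <- tryCatch(
        severity_correlation(use, ms, score = score),
        error = function(e) tibble::tibble(measure = ms, n = nrow(use),
                                           r = NA_real_, p = NA_real_)
      )
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(band = bd), res
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Hub report
#'
#' The group-level hub (channel with the highest group-mean nodal degree or
#' betweenness) per band, group and statistic.
#'
#' @param nodal The `nodal` tibble of [analyze_cohort()].
#' @return A tibble: `band`, `group`, `statistic`, `hub`.
#' @export
hub_table <- function(nodal) {
  grid <- expand.grid(band = unique(nodal$band),
                      group = unique(nodal$group),
                      statistic = c("degree", "bc"),
                      stringsAsFactors = FALSE)
  grid$hub <- vapply(seq_len(nrow(grid)), function(i) {
    sub <- nodal[nodal$band == grid$band[i] & nodal$group == grid$group[i], ]
    find_hub(sub, grid$statistic[i])
  }, character(1))
  tibble::as_tibble(grid)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' All arguments have working defaults; pass either a `cohort_spec` (to
#' simulate) or an `input_dir` containing recordings written by
#' [write_cohort()].
#'
#' @param cohort A [cohort_spec()], or `NULL` when reading from `input_dir`.
#' @param input_dir Directory with `*.tsv` recordings (+ JSON sidecars) and
#'   `metadata.csv`.
#' @param bands Character vector of band names from [eeg_bands()] (or from
#'   `band_definitions` when supplied).
#' @param band_definitions Optional data frame (`band`, `low`, `high`)
#'   overriding the default band table.
#' @param epoch_len_s,amp_threshold,min_epochs,edge_trim,pooled,broadband
#'   Passed to [analyze_cohort()].
#' @param bonferroni_m Comparisons per band for the adjusted p column.
#' @param var_equal Pooled-variance t-tests in the demographic/regional
#'   tables (`FALSE` = Welch).
#' @param log_power Log-transform the band-power covariate.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed controlling all randomness.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL,
                            bands = eeg_bands()$band,
                            band_definitions = NULL, epoch_len_s = 2,
                            amp_threshold = 150, min_epochs = 80,
                            edge_trim = 0.05, pooled = FALSE,
                            broadband = NULL, bonferroni_m = 9,
                            var_equal = TRUE, log_power = TRUE,
                            out_dir = "mstnet-report", seed = 1) {
  if (!is.null(band_definitions)) {
    band_definitions <- tibble::as_tibble(band_definitions)
  }
  cfg <- list(cohort = cohort, input_dir = input_dir, bands = bands,
              band_definitions = band_definitions,
              epoch_len_s = epoch_len_s, amp_threshold = amp_threshold,
              min_epochs = min_epochs, edge_trim = edge_trim, pooled = pooled,
              broadband = broadband, bonferroni_m = bonferroni_m,
              var_equal = var_equal, log_power = log_power,
              out_dir = out_dir, seed = seed)
  problems <- validate_config(cfg)
  if (length(problems) > 0) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg A configuration list.
#' @return `validate_config()` returns a character vector of problems (empty
#'   when valid).
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  if (is.null(cfg$cohort) && is.null(cfg$input_dir)) {
    problems <- c(problems, "one of `cohort` or `input_dir` is required")
  }
  if (!is.null(cfg$cohort) && !inherits(cfg$cohort, "cohort_spec")) {
    problems <- c(problems, "`cohort` must be a cohort_spec()")
  }
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir)) {
    problems <- c(problems, paste0("input_dir does not exist: ", cfg$input_dir))
  }
  band_tbl <- if (is.null(cfg$band_definitions)) eeg_bands() else
    tibble::as_tibble(cfg$band_definitions)
  if (!all(c("band", "low", "high") %in% names(band_tbl))) {
    problems <- c(problems,
                  "band_definitions needs columns band, low, high")
    band_tbl <- eeg_bands()
  }
  bad <- setdiff(cfg$bands, band_tbl$band)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("unknown band(s): ",
                                   paste(bad, collapse = ", ")))
  }
  if (!is.null(cfg$cohort) && inherits(cfg$cohort, "cohort_spec") &&
        length(bad) == 0) {
    use <- band_tbl[band_tbl$band %in% cfg$bands, ]
    if (cfg$cohort$fs <= 2 * max(use$high)) {
      problems <- c(problems, sprintf(
        "band '%s' violates Nyquist at fs = %g Hz",
        use$band[which.max(use$high)], cfg$cohort$fs))
    }
  }
  if (cfg$epoch_len_s <= 0) problems <- c(problems, "epoch_len_s must be > 0")
  if (cfg$amp_threshold <= 0) {
    problems <- c(problems, "amp_threshold must be > 0")
  }
  if (cfg$edge_trim < 0 || cfg$edge_trim >= 0.5) {
    problems <- c(problems, "edge_trim must lie in [0, 0.5)")
  }
  if (cfg$bonferroni_m < 1) problems <- c(problems, "bonferroni_m must be >= 1")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    problems <- c(problems, "seed must be a single integer")
  }
  problems
}

#' Read a pipeline configuration from YAML
#'
#' Scalar options map 1:1 to [pipeline_config()] arguments; a `cohort:` block
#' maps to [cohort_spec()] arguments (with `bands:` as a list of band names).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$bands)) y$bands <- unlist(y$bands)
  if (!is.null(y$broadband)) y$broadband <- unlist(y$broadband)
  if (!is.null(y$band_definitions)) {
    y$band_definitions <- dplyr::bind_rows(
      lapply(y$band_definitions, tibble::as_tibble)
    )
  }
  if (!is.null(y$cohort)) {
    ca <- y$cohort
    if (!is.null(ca$channel_labels)) ca$channel_labels <- unlist(ca$channel_labels)
    if (!is.null(ca$bands)) ca$bands <- eeg_bands(unlist(ca$bands))
    if (!is.null(ca$group_effects)) {
      ca$group_effects <- lapply(ca$group_effects, function(ge) {
        if (!is.null(ge$edge_boost)) {
          ge$edge_boost <- tibble::as_tibble(ge$edge_boost)
        }
        ge
      })
    }
    y$cohort <- do.call(cohort_spec, ca)
  }
  do.call(pipeline_config, y)
}

#' Run the full pipeline and write a report bundle
#'
#' Orchestrates simulate/load -> preprocess -> connectivity -> spanning tree
#' -> statistics, deterministically under the configured seed, and writes the
#' report bundle to `out_dir`: per-subject QC (`qc.csv`), the subject x band
#' metric table (`metrics.csv`), nodal measures (`nodal.csv`), the
#' group-comparison table (`group_stats.csv`), severity correlations
#' (`severity.csv`), hubs (`hubs.csv`), regional nodal t-tests
#' (`regional.csv`), demographics (`demographics.csv`),
#' per band x group mean connectivity matrices
#' (`connectivity_<band>_<group>.csv`), and a `config.json` echo carrying the
#' seed and a configuration hash that is also stamped on every table.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return The list of result tibbles, invisibly (also of class
#'   `mst_report`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # hash the scientific configuration only (output location excluded)
  cfg_echo <- unclass(config)[setdiff(names(config), "out_dir")]
  cfg_echo$cohort <- if (is.null(config$cohort)) NULL else
    unclass(config$cohort)
  cfg_hash <- rlang::hash(cfg_echo)

  if (!is.null(config$cohort)) {
    spec <- config$cohort
    spec$seed <- config$seed
    cohort <- gen_cohort(spec)
  } else {
    files <- list.files(config$input_dir, pattern = "\\.tsv$",
                        full.names = TRUE)
    recs <- lapply(files, read_recording)
    names(recs) <- sub("\\.tsv$", "", basename(files))
    meta <- tibble::as_tibble(
      utils::read.csv(file.path(config$input_dir, "metadata.csv"))
    )
    cohort <- list(recordings = recs, meta = meta)
  }

  band_tbl <- if (is.null(config$band_definitions)) eeg_bands() else
    tibble::as_tibble(config$band_definitions)
  bands <- band_tbl[match(config$bands, band_tbl$band), ]
  analysis <- analyze_cohort(
    cohort, bands = bands, epoch_len_s = config$epoch_len_s,
    amp_threshold = config$amp_threshold, min_epochs = config$min_epochs,
    edge_trim = config$edge_trim, pooled = config$pooled,
    broadband = config$broadband
  )
  stats_tbl <- group_comparison_table(
    analysis$metrics, m = config$bonferroni_m, log_power = config$log_power
  )
  sev_tbl <- severity_table(analysis$metrics)
  hubs <- hub_table(analysis$nodal)
  regional <- dplyr::bind_rows(lapply(unique(analysis$nodal$band), function(bd) {
    sub <- analysis$nodal[analysis$nodal$band == bd, ]
    dplyr::bind_rows(
      dplyr::mutate(regional_ttest(sub, "degree",
                                   var_equal = config$var_equal), band = bd),
      dplyr::mutate(regional_ttest(sub, "bc",
                                   var_equal = config$var_equal), band = bd)
    )
  }))
  demo <- demographics(cohort$meta, var_equal = config$var_equal)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(tbl) {
    tbl$config_hash <- cfg_hash
    tbl$seed <- config$seed
    tbl
  }
  utils::write.csv(stamp(analysis$qc), file.path(out, "qc.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(analysis$metrics), file.path(out, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(analysis$nodal), file.path(out, "nodal.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(stats_tbl), file.path(out, "group_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(sev_tbl), file.path(out, "severity.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(hubs), file.path(out, "hubs.csv"), row.names = FALSE)
  utils::write.csv(stamp(regional), file.path(out, "regional.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(demo), file.path(out, "demographics.csv"),
                   row.names = FALSE)
  for (key in names(analysis$mean_matrix)) {
    m <- analysis$mean_matrix[[key]]
    fn <- sprintf("connectivity_%s.csv", gsub(":", "_", key))
    utils::write.csv(as.data.frame(unclass(m)), file.path(out, fn))
  }
  jsonlite::write_json(
    list(seed = config$seed, config_hash = cfg_hash,
         bands = config$bands, epoch_len_s = config$epoch_len_s,
         amp_threshold = config$amp_threshold,
         min_epochs = config$min_epochs, edge_trim = config$edge_trim,
         pooled = config$pooled, bonferroni_m = config$bonferroni_m,
         package_version = as.character(utils::packageVersion("mstnet")),
         r_version = as.character(getRversion())),
    file.path(out, "config.json"), auto_unbox = TRUE, digits = NA
  )
  res <- structure(
    list(qc = analysis$qc, metrics = analysis$metrics,
         nodal = analysis$nodal, group_stats = stats_tbl,
         severity = sev_tbl, hubs = hubs, regional = regional,
         demographics = demo,
         mean_matrix = analysis$mean_matrix,
         config_hash = cfg_hash, out_dir = out),
    class = "mst_report"
  )
  invisible(res)
}

#' @export
print.mst_report <- function(x, ...) {
  cat(sprintf("<mst_report> written to %s (hash %s)\n", x$out_dir,
              substr(x$config_hash, 1, 8)))
  invisible(x)
}
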