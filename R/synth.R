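#' Coupling specification for synthetic narrowband signals
#'
#' Describes a set of channels carrying band-limited oscillations with
#' controllable pairwise phase-lag coupling. Each edge `(i, j, lag, strength)`
#' makes channel `j` mix in a copy of channel `i`'s oscillator delayed by
#' `lag` radians with mixing weight `strength`; the remaining weight stays on
#' channel `j`'s own (independent) oscillator. A nonzero lag produces an
#' asymmetric phase-difference distribution and hence nonzero expected PLI;
#' a zero lag is permitted (it is the canonical volume-conduction case that
#' PLI is designed to suppress).
#'
#' @param n_channels Number of channels (>= 1).
#' @param band Numeric `c(low, high)` in Hz; the oscillators live at the band
#'   centre with instantaneous-frequency jitter confined to the band.
#' @param edges Tibble/data frame with columns `i`, `j` (1-based channel
#'   indices), `lag` (radians in (-pi, pi]), `strength` (in \[0, 1\]). May be
#'   empty for uncoupled channels.
#' @param noise_sd Standard deviation (microvolts) of additive noise.
#' @param noise_exponent Spectral exponent of the noise (power ~ 1/f^x);
#'   1 = pink (EEG-like, the default), 0 = white (spectrally flat, giving
#'   effectively independent phase samples within an epoch).
#' @param amp Oscillator amplitude in microvolts.
#' @param seed Optional integer seed for reproducible generation.
#' @return A validated list of class `coupling_spec`.
#' @export
coupling_spec <- function(n_channels, band, edges = NULL, noise_sd = 0,
                          noise_exponent = 1, amp = 40, seed = NULL) {
  if (!is.numeric(n_channels) || n_channels < 1) {
    stop("`n_channels` must be a positive integer", call. = FALSE)
  }
  band <- resolve_band(band)
  if (is.null(edges)) {
    edges <- tibble::tibble(i = integer(), j = integer(),
                            lag = numeric(), strength = numeric())
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("i", "j", "lag", "strength") %in% names(edges)))
    if (any(edges$i == edges$j)) {
      stop("coupling edges must join distinct channels", call. = FALSE)
    }
    if (any(edges$i < 1 | edges$j < 1 | edges$i > n_channels |
              edges$j > n_channels)) {
      stop("edge endpoints out of channel range", call. = FALSE)
    }
    key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
    if (anyDuplicated(key)) {
      stop("duplicate unordered channel pairs in `edges`", call. = FALSE)
    }
    if (any(edges$strength < 0 | edges$strength > 1)) {
      stop("edge strengths must lie in [0, 1]", call. = FALSE)
    }
    if (any(abs(edges$lag) > pi)) {
      stop("lags must lie in (-pi, pi]", call. = FALSE)
    }
  }
  structure(
    list(n_channels = as.integer(n_channels), band = band, edges = edges,
         noise_sd = noise_sd, noise_exponent = noise_exponent, amp = amp,
         seed = seed),
    class = "coupling_spec"
  )
}

# 1/f^exponent noise, unit variance per channel, via spectral shaping of
# white noise (Hermitian-symmetric scaling keeps the inverse transform real).
# exponent = 1 is pink (the EEG-like default), 0 is white. Returns an
# n_channels x n matrix (all channels shaped in one batched FFT).
pink_noise_mat <- function(n_channels, n, exponent = 1) {
  x <- matrix(rnorm(n_channels * n), n, n_channels)
  if (exponent == 0) return(t(x))
  X <- mvfft(x)
  k <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))
  fac <- c(0, 1 / k[-1]^(exponent / 2))
  y <- Re(mvfft(X * fac, inverse = TRUE)) / n
  t(y) / apply(y, 2, sd)
}

pink_noise <- function(n, exponent = 1) {
  as.numeric(pink_noise_mat(1, n, exponent))
}

# Instantaneous-frequency track confined to `band`: band centre plus smoothed
# white-noise jitter (sd = bandwidth/6), clipped to the band edges.
jittered_frequency <- function(n, band, fs) {
  fc <- (band$low + band$high) / 2
  bw <- band$high - band$low
  L <- max(3L, round(fs / 4))
  raw <- rnorm(n + L)
  cs <- cumsum(raw)
  z <- (cs[(L + 1):(L + n)] - cs[1:n]) / L # moving average of width L
  z <- z / sd(z) * bw / 6
  pmin(pmax(fc + z, band$low), band$high)
}

#' Generate coupled narrowband signals
#'
#' Simulates a multichannel recording in which each channel carries a
#' narrowband oscillator (sinusoid at the band centre with jittered
#' instantaneous frequency) plus 1/f noise, and each coupling edge imposes a
#' phase-lagged shared source: the receiving channel's signal is the
#' power-preserving mixture `sqrt(1 - s) * own + sqrt(s) * lagged copy of
#' the source` (`strength` is the variance share taken by the source), so
#' the phase-difference distribution of a coupled pair concentrates at the
#' specified lag with concentration increasing in `strength`, while
#' per-channel variance stays independent of the coupling structure.
#'
#' @param spec A [coupling_spec()].
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz; must exceed twice the band's upper edge.
#' @return An [eeg_recording()] (channels x samples, microvolts).
#' @export
#' @examples
#' sp <- coupling_spec(2, c(8, 13),
#'                     edges = data.frame(i = 1, j = 2, lag = pi / 2,
#'                                        strength = 1),
#'                     seed = 1)
#' rec <- gen_coupled_signals(sp, duration_s = 4, fs = 128)
gen_coupled_signals <- function(spec, duration_s, fs) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (fs <= 2 * spec$band$high) {
    stop(sprintf("fs = %g violates the Nyquist requirement for band [%g, %g] Hz",
                 fs, spec$band$low, spec$band$high), call. = FALSE)
  }
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  n <- spec$n_channels
  N <- round(duration_s * fs)
  if (N < 1) stop("recording would contain no samples", call. = FALSE)
  with_seed(spec$seed, {
    phases <- matrix(0, n, N)
    for (c_ in seq_len(n)) {
      f <- jittered_frequency(N, spec$band, fs)
      phases[c_, ] <- 2 * pi * cumsum(f) / fs + runif(1, 0, 2 * pi)
    }
    # power-preserving mixing: strength is the share of the receiving
    # channel's oscillator variance contributed by the source, so amplitudes
    # are sqrt(s) for the copies and sqrt(1 - sum s) for the own oscillator;
    # per-channel variance does not depend on the coupling structure and
    # band power stays a clean nuisance covariate
    ss <- rep(0, n)
    if (nrow(spec$edges) > 0) {
      for (e in seq_len(nrow(spec$edges))) {
        j <- spec$edges$j[e]
        ss[j] <- ss[j] + spec$edges$strength[e]
      }
    }
    if (any(ss > 1 + 1e-12)) {
      stop("total incoming coupling strength exceeds 1 for some channel",
           call. = FALSE)
    }
    own_weight <- sqrt(pmax(1 - ss, 0))
    x <- own_weight * spec$amp * cos(phases)
    if (nrow(spec$edges) > 0) {
      for (e in seq_len(nrow(spec$edges))) {
        i <- spec$edges$i[e]; j <- spec$edges$j[e]
        x[j, ] <- x[j, ] + spec$amp * sqrt(spec$edges$strength[e]) *
          cos(phases[i, ] - spec$edges$lag[e])
      }
    }
    if (spec$noise_sd > 0) {
      x <- x + spec$noise_sd * pink_noise_mat(n, N, spec$noise_exponent)
    }
    rec <- eeg_recording(x, fs = fs)
    attr(rec, "provenance") <- list(
      generator = "gen_coupled_signals",
      band = c(spec$band$low, spec$band$high),
      n_edges = nrow(spec$edges),
      noise_sd = spec$noise_sd,
      seed = spec$seed
    )
    rec
  })
}

#' Build a tree graph from an edge list
#'
#' @param u,v Integer vectors of 1-based node indices (edge endpoints).
#' @param n_nodes Number of nodes; defaults to `max(u, v)`.
#' @param labels Node labels; defaults to `n01..nNN`.
#' @param weight Edge weights (recycled).
#' @return An object of class `mst_tree` with fields `labels`, `edges`
#'   (tibble `from`, `to`, `u`, `v`, `weight`) and `n`.
#' @export
tree_graph <- function(u, v, n_nodes = max(c(u, v)), labels = NULL,
                       weight = 1) {
  u <- as.integer(u); v <- as.integer(v)
  stopifnot(length(u) == length(v))
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(n_nodes))
  stopifnot(length(labels) == n_nodes)
  edges <- tibble::tibble(
    from = labels[u], to = labels[v], u = u, v = v,
    weight = rep_len(weight, length(u))
  )
  structure(list(labels = labels, edges = edges, n = as.integer(n_nodes)),
            class = "mst_tree")
}

#' @export
print.mst_tree <- function(x, ...) {
  cat(sprintf("<mst_tree> %d nodes, %d edges, total weight %.4g\n",
              x$n, nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Decode a Pruefer sequence into a labelled tree
#'
#' A sequence of length `n - 2` over `1..n` decodes to a unique labelled tree
#' on `n` nodes; sampling the sequence uniformly samples labelled trees
#' uniformly.
#'
#' @param prufer Integer vector (possibly empty, for n = 2) with entries in
#'   `1..(length(prufer) + 2)`.
#' @param labels Optional node labels.
#' @return An `mst_tree`.
#' @export
prufer_to_tree <- function(prufer, labels = NULL) {
  n <- length(prufer) + 2L
  prufer <- as.integer(prufer)
  if (n < 2 || (length(prufer) > 0 && (min(prufer) < 1 || max(prufer) > n))) {
    stop("invalid Pruefer sequence", call. = FALSE)
  }
  degree <- rep(1L, n) + tabulate(prufer, n)
  u <- integer(n - 1L); v <- integer(n - 1L)
  ptr <- 1L
  leaf <- 0L
  # classic linear-time decoding with a moving pointer over candidate leaves
  avail <- degree
  for (k in seq_along(prufer)) {
    if (leaf == 0L) {
      while (avail[ptr] != 1L) ptr <- ptr + 1L
      leaf <- ptr
    }
    s <- prufer[k]
    u[k] <- leaf; v[k] <- s
    avail[leaf] <- 0L
    avail[s] <- avail[s] - 1L
    if (avail[s] == 1L && s < ptr) leaf <- s else {
      leaf <- 0L
      if (avail[ptr] != 1L) ptr <- ptr + 1L
    }
  }
  last <- which(avail == 1L)
  u[n - 1L] <- last[1]; v[n - 1L] <- last[2]
  tree_graph(u, v, n_nodes = n, labels = labels)
}

#' Generate reference tree topologies
#'
#' `star` places node 1 as the hub; `path` chains nodes in label order;
#' `random_tree` samples uniformly over labelled trees via a random Pruefer
#' sequence.
#'
#' @param topology One of `"star"`, `"path"`, `"random_tree"`.
#' @param n_nodes Number of nodes (>= 2).
#' @param seed Optional seed (used by `random_tree`).
#' @param labels Optional node labels.
#' @return An `mst_tree`.
#' @export
#' @examples
#' gen_tree("star", 4)
gen_tree <- function(topology = c("star", "path", "random_tree"), n_nodes,
                     seed = NULL, labels = NULL) {
  topology <- match.arg(topology)
  if (!is.numeric(n_nodes) || n_nodes < 2) {
    stop("`n_nodes` must be at least 2", call. = FALSE)
  }
  n <- as.integer(n_nodes)
  switch(topology,
    star = tree_graph(rep(1L, n - 1L), 2:n, n_nodes = n, labels = labels),
    path = tree_graph(seq_len(n - 1L), 2:n, n_nodes = n, labels = labels),
    random_tree = with_seed(seed, {
      if (n == 2L) {
        tree_graph(1L, 2L, n_nodes = 2L, labels = labels)
      } else {
        prufer_to_tree(sample.int(n, n - 2L, replace = TRUE), labels = labels)
      }
    })
  )
}

#' Cohort specification for the synthetic study generator
#'
#' Describes a two-group cohort ("IA" vs "HC") of resting-state recordings
#' whose coupling structure per band is a mixture of a star graph (one hub
#' coupled to every other channel) and a path graph (channels chained in
#' montage order). A subject's mixing proportion ("star bias") defaults to
#' 0.5 and can be shifted for the IA group (`star_bias` group effect) or tied
#' to the subject's IAT score (`iat_coupling`), which is how group-dependent
#' and severity-dependent topology are injected. Metadata emulate the study
#' population: IAT 59.0 +/- 7.88 (IA, resampled into 50-79) vs
#' 34.4 +/- 8.53 (HC, resampled into 20-49), ages around 21.0 +/- 2.13 and
#' 20.5 +/- 1.59 years, and roughly 7/30 vs 6/30 male.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param channel_labels Channel names; default the 64-channel montage.
#' @param fs Sampling rate (Hz).
#' @param duration_s Recording length per subject (seconds); the study
#'   protocol is ~six minutes.
#' @param bands Tibble of band definitions to synthesise (subset of
#'   [eeg_bands()]); each band gets its own coupled oscillator component.
#' @param coupling Base coupling strength split between the star and path
#'   structures.
#' @param bias_sd Between-subject SD of the star bias.
#' @param hub Hub channel label for the star component.
#' @param amp Oscillator amplitude (microvolts) at 10 Hz; bands are tilted
#'   by `1/sqrt(f_centre/10)` to mimic the falling EEG spectrum.
#' @param noise_sd 1/f noise SD (microvolts).
#' @param artifact_prob Probability that any 2-s epoch receives an injected
#'   amplitude spike (for rejection testing).
#' @param artifact_amp Spike amplitude in microvolts (must exceed the +/-150
#'   rejection threshold to be useful).
#' @param group_effects Named list per band, e.g.
#'   `list(alpha2 = list(star_bias = 0.25))` or
#'   `list(delta = list(edge_boost = data.frame(i = 53, j = 59,
#'   dstrength = 0.8)))`; effects apply to the IA group.
#' @param iat_coupling Slope tying star bias to IAT: bias increases by
#'   `iat_coupling * (iat - 50) / 40` (centred at the scale's
#'   normal/excessive boundary of 50; applied in every synthesised band).
#' @param iat_params,age_params Per-group `c(mean, sd)` lists.
#' @param sex_ratio Per-group probability of male.
#' @param seed Optional integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 30,
                        channel_labels = montage_1020_64(),
                        fs = 500, duration_s = 360,
                        bands = eeg_bands(),
                        coupling = 0.5, bias_sd = 0.08,
                        hub = channel_labels[1],
                        amp = 40, noise_sd = 12,
                        artifact_prob = 0, artifact_amp = 250,
                        group_effects = list(),
                        iat_coupling = 0,
                        iat_params = list(IA = c(59.0, 7.88),
                                          HC = c(34.4, 8.53)),
                        age_params = list(IA = c(21.0, 2.13),
                                          HC = c(20.5, 1.59)),
                        sex_ratio = c(IA = 7 / 30, HC = 6 / 30),
                        seed = NULL) {
  if (n_per_group < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (length(channel_labels) < 2 || anyDuplicated(channel_labels)) {
    stop("need >= 2 unique channel labels", call. = FALSE)
  }
  if (!hub %in% channel_labels) stop("`hub` must be a channel label", call. = FALSE)
  if (coupling < 0 || coupling > 1) {
    stop("`coupling` must lie in [0, 1]", call. = FALSE)
  }
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("band", "low", "high") %in% names(bands)))
  if (fs <= 2 * max(bands$high)) {
    stop("fs violates Nyquist for the highest requested band", call. = FALSE)
  }
  for (nm in names(group_effects)) {
    if (!nm %in% bands$band) {
      stop("group effect refers to band not being synthesised: ", nm,
           call. = FALSE)
    }
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         channel_labels = channel_labels, fs = fs, duration_s = duration_s,
         bands = bands, coupling = coupling, bias_sd = bias_sd, hub = hub,
         amp = amp, noise_sd = noise_sd,
         artifact_prob = artifact_prob, artifact_amp = artifact_amp,
         group_effects = group_effects, iat_coupling = iat_coupling,
         iat_params = iat_params, age_params = age_params,
         sex_ratio = sex_ratio, seed = seed),
    class = "cohort_spec"
  )
}

# Truncated-normal integer IAT scores by resampling into the recruitment band.
sample_iat <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- round(rnorm(n, mean, sd))
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  as.integer(out[seq_len(n)])
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject metadata (group, age, sex, IAT) and synthesises one
#' multichannel recording per subject according to a [cohort_spec()]. The
#' returned object carries a `truth` attribute (per subject x band star bias
#' and injected artifact epochs) for parameter-recovery testing.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `eeg_cohort` with elements `recordings` (named
#'   list of [eeg_recording()]) and `meta` (tibble: `subject_id`, `group`,
#'   `age`, `sex`, `iat`).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_per_group
    groups <- rep(c("IA", "HC"), each = n)
    meta <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(2 * n)),
      group = groups,
      age = as.integer(pmax(17, round(c(
        rnorm(n, spec$age_params$IA[1], spec$age_params$IA[2]),
        rnorm(n, spec$age_params$HC[1], spec$age_params$HC[2])
      )))),
      sex = ifelse(c(rbinom(n, 1, spec$sex_ratio[["IA"]]),
                     rbinom(n, 1, spec$sex_ratio[["HC"]])) == 1, "M", "F"),
      iat = c(
        sample_iat(n, spec$iat_params$IA[1], spec$iat_params$IA[2], 50, 79),
        sample_iat(n, spec$iat_params$HC[1], spec$iat_params$HC[2], 20, 49)
      )
    )
    n_ch <- length(spec$channel_labels)
    hub_idx <- match(spec$hub, spec$channel_labels)
    others <- setdiff(seq_len(n_ch), hub_idx)
    epoch_samples <- round(2 * spec$fs)
    n_epochs <- floor(spec$duration_s * spec$fs / epoch_samples)
    N <- round(spec$duration_s * spec$fs)

    recordings <- vector("list", 2 * n)
    names(recordings) <- meta$subject_id
    truth <- vector("list", 2 * n)

    for (s in seq_len(2 * n)) {
      x <- matrix(0, n_ch, N)
      bias_rows <- list()
      subj_noise <- rnorm(1, 0, spec$bias_sd)
      for (b in seq_len(nrow(spec$bands))) {
        brow <- spec$bands[b, ]
        eff <- spec$group_effects[[brow$band]]
        bias <- 0.5 + subj_noise +
          spec$iat_coupling * (meta$iat[s] - 50) / 40
        if (!is.null(eff$star_bias) && meta$group[s] == "IA") {
          bias <- bias + eff$star_bias
        }
        bias <- min(max(bias, 0.02), 0.98)
        star_s <- spec$coupling * bias
        path_s <- spec$coupling * (1 - bias)
        # star: hub is the source for every other channel; path: montage-order
        # chain, skipping any edge that would make the hub borrow a phase (the
        # hub keeps its own oscillator, so incoming strength per channel is
        # star_s + path_s = coupling <= 1 by construction)
        path_from <- seq_len(n_ch - 1)
        path_to <- 2:n_ch
        keep <- path_to != hub_idx
        path_from <- path_from[keep]; path_to <- path_to[keep]
        n_e <- length(others) + length(path_to)
        edges <- tibble::tibble(
          i = c(rep(hub_idx, length(others)), path_from),
          j = c(others, path_to),
          lag = runif(n_e, pi / 4, 3 * pi / 4) *
            sample(c(-1, 1), n_e, replace = TRUE),
          strength = c(rep(star_s, length(others)), rep(path_s, length(path_to)))
        )
        # the star edge hub->(hub+1) and path edge hub->(hub+1) share a pair;
        # merge duplicates by summing strengths (cap at 1)
        key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
        if (anyDuplicated(key)) {
          first <- !duplicated(key)
          for (d in which(duplicated(key))) {
            k0 <- which(key == key[d])[1]
            edges$strength[k0] <- min(1, edges$strength[k0] + edges$strength[d])
          }
          edges <- edges[first, ]
        }
        if (!is.null(eff$edge_boost) && meta$group[s] == "IA") {
          eb <- tibble::as_tibble(eff$edge_boost)
          key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
          for (r in seq_len(nrow(eb))) {
            k <- paste(min(eb$i[r], eb$j[r]), max(eb$i[r], eb$j[r]))
            hit <- which(key == k)
            if (length(hit) > 0) {
              edges$strength[hit] <- pmin(1, edges$strength[hit] + eb$dstrength[r])
            } else {
              edges <- dplyr::bind_rows(edges, tibble::tibble(
                i = eb$i[r], j = eb$j[r],
                lag = runif(1, pi / 4, 3 * pi / 4) * sample(c(-1, 1), 1),
                strength = eb$dstrength[r]
              ))
            }
          }
        }
        amp_b <- spec$amp / sqrt(((brow$low + brow$high) / 2) / 10)
        cs <- coupling_spec(n_ch, c(brow$low, brow$high), edges = edges,
                            noise_sd = 0, amp = amp_b)
        comp <- gen_coupled_signals(cs, spec$duration_s, spec$fs)
        x <- x + comp$data
        bias_rows[[b]] <- tibble::tibble(
          subject_id = meta$subject_id[s], band = brow$band, star_bias = bias
        )
      }
      if (spec$noise_sd > 0) {
        x <- x + spec$noise_sd * pink_noise_mat(n_ch, N)
      }
      spike_epochs <- integer(0)
      if (spec$artifact_prob > 0 && n_epochs > 0) {
        hit <- which(runif(n_epochs) < spec$artifact_prob)
        for (ep in hit) {
          ch <- sample.int(n_ch, 1)
          at <- (ep - 1) * epoch_samples + sample.int(epoch_samples, 1)
          x[ch, at] <- x[ch, at] + sample(c(-1, 1), 1) * spec$artifact_amp
        }
        spike_epochs <- hit
      }
      rec <- eeg_recording(x, fs = spec$fs,
                           channel_labels = spec$channel_labels)
      attr(rec, "provenance") <- list(
        generator = "gen_cohort", subject_id = meta$subject_id[s],
        artifact_epochs = spike_epochs, seed = spec$seed
      )
      recordings[[s]] <- rec
      truth[[s]] <- dplyr::bind_rows(bias_rows)
    }
    out <- structure(list(recordings = recordings, meta = meta),
                     class = "eeg_cohort")
    attr(out, "truth") <- dplyr::bind_rows(truth)
    out
  })
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects (%s)\n", nrow(x$meta),
              paste(table(x$meta$group), names(table(x$meta$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Recordings as delimited text (one file + JSON sidecar per subject, via
#' [write_recording()]) and the metadata table as CSV.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$recordings)) {
    write_recording(cohort$recordings[[id]], file.path(dir, paste0(id, ".tsv")))
  }
  utils::write.csv(cohort$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}
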