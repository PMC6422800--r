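test_that("coupling_spec validates its invariants", {
  expect_error(coupling_spec(0, c(8, 13)), "positive")
  edges_dup <- data.frame(i = c(1, 2), j = c(2, 1), lag = 1, strength = 0.5)
  expect_error(coupling_spec(3, c(8, 13), edges_dup), "duplicate")
  expect_error(
    coupling_spec(3, c(8, 13), data.frame(i = 1, j = 1, lag = 1, strength = 1)),
    "distinct"
  )
  expect_error(
    coupling_spec(3, c(8, 13), data.frame(i = 1, j = 2, lag = 1, strength = 2)),
    "strengths"
  )
  expect_error(coupling_spec(2, c(13, 8)), "low < high")
})

test_that("gen_coupled_signals enforces Nyquist and reproducibility", {
  sp <- coupling_spec(2, c(8, 13), seed = 11)
  expect_error(gen_coupled_signals(sp, 2, 20), "Nyquist")
  a <- gen_coupled_signals(sp, 2, 128)
  b <- gen_coupled_signals(sp, 2, 128)
  expect_identical(a$data, b$data) # bit-identical under a fixed seed
  expect_equal(dim(a$data), c(2L, 256L))
})

test_that("a constant pi/2 lag yields PLI 1 and zero lag yields PLI 0", {
  sp <- coupling_spec(2, c(4, 8),
                      edges = data.frame(i = 1, j = 2, lag = pi / 2,
                                         strength = 1),
                      noise_sd = 0, seed = 3)
  rec <- gen_coupled_signals(sp, 4, 250)
  m <- average_pli(pli_matrix(segment_epochs(bandpass(rec, "theta"))))
  expect_equal(m[1, 2], 1)

  sp0 <- coupling_spec(2, c(4, 8),
                       edges = data.frame(i = 1, j = 2, lag = 0,
                                          strength = 1),
                       noise_sd = 0, seed = 3)
  rec0 <- gen_coupled_signals(sp0, 4, 250)
  m0 <- average_pli(pli_matrix(segment_epochs(bandpass(rec0, "theta"))))
  expect_equal(m0[1, 2], 0)
})

test_that("uncoupled broadband noise has near-zero mean PLI", {
  # 8 channels of spectrally flat noise, broadband-filtered: phase samples are
  # effectively independent across the epoch, so the signum mean stays within
  # its binomial bound
  sp <- coupling_spec(8, c(0.5, 50), noise_sd = 10, noise_exponent = 0,
                      amp = 0, seed = 21)
  rec <- gen_coupled_signals(sp, 360, 125)
  ep <- segment_epochs(prefilter(rec))
  expect_equal(dim(ep$data)[1], 180)
  avg <- average_pli(pli_matrix(ep))
  expect_lt(mean(avg[upper.tri(avg)]), 0.1)
  # pink (1/f) noise concentrates power at slow frequencies, leaving fewer
  # independent phase samples per epoch; PLI stays low but not as low
  sp1 <- coupling_spec(8, c(0.5, 50), noise_sd = 10, noise_exponent = 1,
                       amp = 0, seed = 21)
  rec1 <- gen_coupled_signals(sp1, 360, 125)
  avg1 <- average_pli(pli_matrix(segment_epochs(prefilter(rec1))))
  expect_lt(mean(avg1[upper.tri(avg1)]), 0.2)
})

test_that("expected PLI does not decrease with coupling strength", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mean_pli <- vapply(grid, function(s) {
    sp <- coupling_spec(2, c(8, 13),
                        edges = data.frame(i = 1, j = 2, lag = pi / 2,
                                           strength = s),
                        noise_sd = 5, seed = 101)
    rec <- gen_coupled_signals(sp, 60, 125)
    m <- average_pli(pli_matrix(segment_epochs(bandpass(rec, "alpha2"))))
    m[1, 2]
  }, numeric(1))
  # allow small Monte-Carlo wiggles but require a monotone trend
  expect_true(all(diff(mean_pli) > -0.05))
  expect_gt(mean_pli[5], mean_pli[1] + 0.3)
})

test_that("gen_tree produces the promised topologies", {
  st <- gen_tree("star", 4)
  expect_equal(st$edges$u, c(1L, 1L, 1L))
  expect_equal(st$edges$v, c(2L, 3L, 4L))
  pa <- gen_tree("path", 3)
  expect_equal(pa$edges$u, c(1L, 2L))
  expect_equal(pa$edges$v, c(2L, 3L))
  rt <- gen_tree("random_tree", 64, seed = 5)
  expect_equal(nrow(rt$edges), 63)
  expect_true(oracle_is_tree(rt$edges$u, rt$edges$v, 64))
  expect_error(gen_tree("star", 1), "at least 2")
  # fixed seed reproducibility
  rt2 <- gen_tree("random_tree", 64, seed = 5)
  expect_identical(rt$edges, rt2$edges)
})

test_that("fast Pruefer decoding matches the classic algorithm", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    seq <- sample.int(n, n - 2, replace = TRUE)
    fast <- prufer_to_tree(seq)
    ref <- oracle_prufer_decode(seq, n)
    canon <- function(u, v) {
      k <- paste(pmin(u, v), pmax(u, v))
      sort(k)
    }
    expect_identical(canon(fast$edges$u, fast$edges$v),
                     canon(ref[, 1], ref[, 2]))
  }
})

test_that("cohort metadata emulates the study population", {
  sp <- cohort_spec(n_per_group = 15, channel_labels = montage_1020_64()[1:4],
                    fs = 125, duration_s = 8, bands = eeg_bands("alpha2"),
                    seed = 9)
  coh <- gen_cohort(sp)
  meta <- coh$meta
  expect_equal(nrow(meta), 30)
  expect_equal(sort(unique(meta$group)), c("HC", "IA"))
  expect_true(all(meta$iat[meta$group == "IA"] >= 50 &
                    meta$iat[meta$group == "IA"] <= 79))
  expect_true(all(meta$iat[meta$group == "HC"] >= 20 &
                    meta$iat[meta$group == "HC"] <= 49))
  expect_true(all(meta$sex %in% c("M", "F")))
  expect_true(all(meta$iat == round(meta$iat)))
  expect_length(coh$recordings, 30)
  # determinism
  coh2 <- gen_cohort(sp)
  expect_identical(coh$meta, coh2$meta)
  expect_identical(coh$recordings[[1]]$data, coh2$recordings[[1]]$data)
})

test_that("an edge boost raises that pair's group-mean PLI", {
  labs <- montage_1020_64()[1:6]
  sp <- cohort_spec(
    n_per_group = 10, channel_labels = labs, fs = 125, duration_s = 30,
    bands = eeg_bands("alpha2"), coupling = 0.3,
    group_effects = list(alpha2 = list(
      edge_boost = data.frame(i = 1, j = 5, dstrength = 0.6)
    )),
    seed = 31
  )
  coh <- gen_cohort(sp)
  pli_15 <- vapply(coh$recordings, function(rec) {
    m <- average_pli(pli_matrix(segment_epochs(bandpass(rec, "alpha2"))))
    m[1, 5]
  }, numeric(1))
  ia <- pli_15[coh$meta$group == "IA"]
  hc <- pli_15[coh$meta$group == "HC"]
  expect_gt(mean(ia), mean(hc))
  expect_gt(mean(ia) - mean(hc), 0.15)
})

test_that("star bias raises the biased group's MaxDeg", {
  labs <- montage_1020_64()[1:8]
  sp <- cohort_spec(
    n_per_group = 8, channel_labels = labs, fs = 125, duration_s = 40,
    bands = eeg_bands("alpha2"),
    group_effects = list(alpha2 = list(star_bias = 0.35)),
    seed = 32
  )
  coh <- gen_cohort(sp)
  an <- suppressWarnings(
    analyze_cohort(coh, bands = eeg_bands("alpha2"), min_epochs = 10)
  )
  md <- an$metrics
  expect_gt(mean(md$max_degree[md$group == "IA"]),
            mean(md$max_degree[md$group == "HC"]))
})

test_that("recordings round-trip through the text format", {
  sp <- coupling_spec(3, c(8, 13), noise_sd = 2, seed = 12)
  rec <- gen_coupled_signals(sp, 2, 128)
  path <- file.path(withr::local_tempdir(), "rec.tsv")
  write_recording(rec, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_recording(path)
  expect_equal(back$fs, 128)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
})
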