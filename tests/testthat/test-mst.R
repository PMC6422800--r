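test_that("kruskal picks the strongest loop-free links", {
  w <- matrix(c(0, .9, .8,
                .9, 0, .1,
                .8, .1, 0), 3, byrow = TRUE)
  tr <- max_spanning_tree(w)
  key <- paste(pmin(tr$edges$u, tr$edges$v), pmax(tr$edges$u, tr$edges$v))
  expect_setequal(key, c("1 2", "1 3"))
  expect_equal(sum(tr$edges$weight), 1.7)
  expect_error(max_spanning_tree(matrix(0, 1, 1)), "2 nodes")
  expect_error(max_spanning_tree(matrix(runif(9), 3)), "symmetric")
})

test_that("a 64-node random matrix yields a spanning tree", {
  set.seed(2)
  w <- matrix(runif(64^2), 64)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  tr <- max_spanning_tree(w)
  expect_equal(nrow(tr$edges), 63)
  expect_true(oracle_is_tree(tr$edges$u, tr$edges$v, 64))
})

test_that("kruskal weight equals the exhaustive spanning-tree maximum", {
  set.seed(3)
  for (n in 3:6) {
    for (rep in 1:3) {
      w <- matrix(runif(n^2), n)
      w <- (w + t(w)) / 2
      diag(w) <- 0
      tr <- max_spanning_tree(w)
      expect_equal(sum(tr$edges$weight), oracle_max_tree_weight(w),
                   tolerance = 1e-12)
    }
  }
  # one larger case
  n <- 7
  w <- matrix(runif(n^2), n); w <- (w + t(w)) / 2; diag(w) <- 0
  expect_equal(sum(max_spanning_tree(w)$edges$weight),
               oracle_max_tree_weight(w), tolerance = 1e-12)
})

test_that("equal weights are broken deterministically by index order", {
  w <- matrix(0.5, 4, 4)
  diag(w) <- 0
  tr <- max_spanning_tree(w)
  # lexicographically smallest pairs win: (1,2), (1,3), (1,4)
  expect_equal(tr$edges$u, c(1, 1, 1))
  expect_equal(tr$edges$v, c(2, 3, 4))
})

test_that("star and path geometry give the textbook nodal values", {
  st <- gen_tree("star", 64)
  nm <- nodal_metrics(st)
  expect_equal(nm$degree[1], 1) # hub degree normalized
  expect_equal(nm$bc[1], 1)    # every leaf pair passes the hub
  expect_equal(nm$ecc_raw[1], 1L)
  expect_true(all(nm$ecc_raw[-1] == 2L))
  expect_true(all(nm$bc[-1] == 0)) # leaves have zero betweenness
  pa <- gen_tree("path", 4)
  nmp <- nodal_metrics(pa)
  expect_equal(nmp$bc[2], 2 / 3) # 2 of the 3 pairs pass a middle node
  expect_equal(sum(nm$degree_raw), 2 * 63) # handshake identity
})

test_that("global star and path measures hit their closed forms", {
  gs <- global_metrics(gen_tree("star", 64))
  expect_equal(gs$th, 0.5)
  expect_equal(gs$leaf, 63 / 64)
  expect_equal(gs$kappa, 32)
  expect_equal(gs$diameter, 2 / 63)
  expect_equal(gs$r, -1)
  gp <- global_metrics(gen_tree("path", 64))
  expect_equal(gp$leaf, 2 / 64)
  expect_equal(gp$diameter, 1)
  expect_equal(gp$max_bc, (31 * 32) / 1953)
  expect_equal(gp$th, 2 / (2 * 63 * (31 * 32) / 1953))
  # two-node tree: r undefined, reported missing
  g2 <- global_metrics(gen_tree("path", 2))
  expect_true(is.na(g2$r))
})

test_that("all metrics match the naive oracle on exhaustive small trees", {
  for (n in 2:5) {
    seqs <- all_prufer(n)
    for (i in seq_len(nrow(seqs))) {
      el <- oracle_prufer_decode(seqs[i, ], n)
      tree <- tree_graph(el[, 1], el[, 2], n_nodes = n)
      expect_tree_matches_oracle(tree)
    }
  }
})

test_that("tree invariants hold over random Pruefer samples", {
  set.seed(6)
  for (rep in 1:40) {
    n <- sample(3:40, 1)
    tr <- gen_tree("random_tree", n, seed = rep)
    nm <- nodal_metrics(tr)
    gm <- global_metrics(tr)
    expect_equal(sum(nm$degree_raw), 2 * (n - 1))
    expect_gte(sum(nm$degree_raw == 1), 2) # every tree has >= 2 leaves
    expect_lte(gm$ecc, gm$diameter)
    radius <- min(nm$ecc_raw)
    expect_lte(max(nm$ecc_raw), 2 * radius) # radius-diameter inequality
    expect_gte(gm$th, 0); expect_lte(gm$th, 1)
    expect_gte(gm$leaf, 2 / n)
    expect_gte(gm$kappa, 1)
    if (!is.na(gm$r)) {
      expect_gte(gm$r, -1); expect_lte(gm$r, 1)
    }
  }
})

test_that("tree weight and centralities agree with the igraph library", {
  set.seed(9)
  for (n in c(6, 16, 64)) {
    w <- matrix(runif(n^2), n); w <- (w + t(w)) / 2; diag(w) <- 0
    tr <- max_spanning_tree(w)
    g <- igraph::graph_from_adjacency_matrix(1 - w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ref <- igraph::mst(g) # minimum tree of 1 - w == maximum tree of w
    ref_w <- sum(1 - igraph::E(ref)$weight)
    expect_equal(sum(tr$edges$weight), ref_w, tolerance = 1e-12)
    # centralities on the extracted tree
    tg <- igraph::graph_from_edgelist(cbind(tr$edges$u, tr$edges$v),
                                      directed = FALSE)
    nm <- nodal_metrics(tr)
    expect_equal(nm$degree_raw, igraph::degree(tg))
    expect_equal(nm$bc * ((n - 1) * (n - 2) / 2),
                 igraph::betweenness(tg), tolerance = 1e-9)
    expect_equal(nm$ecc_raw, as.integer(igraph::eccentricity(tg)))
  }
})

test_that("the pipeline's one-shot summary equals the public route", {
  set.seed(7)
  for (n in c(2, 5, 8, 16, 64)) {
    w <- matrix(runif(n^2), n); w <- (w + t(w)) / 2; diag(w) <- 0
    s <- mstnet:::cpp_mst_summary(w)
    tr <- max_spanning_tree(w)
    gm <- global_metrics(tr)
    expect_equal(unname(s$global),
                 as.numeric(gm[, c("max_degree", "max_bc", "ecc", "diameter",
                                   "leaf", "th", "kappa", "r")]),
                 tolerance = 1e-12)
    nm <- nodal_metrics(tr)
    expect_equal(s$degree, nm$degree, tolerance = 1e-12)
    expect_equal(s$bc, nm$bc, tolerance = 1e-12)
    expect_equal(s$ecc, nm$ecc, tolerance = 1e-12)
  }
})

test_that("epoch averaging of global measures is element-wise with r bookkeeping", {
  e1 <- global_metrics(gen_tree("random_tree", 10, seed = 1))
  e2 <- global_metrics(gen_tree("random_tree", 10, seed = 2))
  avg <- epoch_average_metrics(dplyr::bind_rows(e1, e2))
  expect_equal(avg$diameter, (e1$diameter + e2$diameter) / 2)
  expect_equal(avg$n_epochs, 2)
  # single epoch is the identity
  one <- epoch_average_metrics(e1)
  expect_equal(one$kappa, e1$kappa)
  # r averaged only over epochs where it is defined
  star <- global_metrics(gen_tree("star", 10)) # r = -1, defined
  two_node_r_na <- e1; two_node_r_na$r <- NA_real_
  mix <- epoch_average_metrics(dplyr::bind_rows(star, two_node_r_na))
  expect_equal(mix$r, star$r)
  expect_equal(mix$r_defined, 1)
  expect_error(epoch_average_metrics(e1[0, ]), "no epochs")
})

test_that("find_hub returns the argmax of the group mean with stable ties", {
  tbl <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 3),
    node = rep(c("O1", "C4", "FP1"), 2),
    degree = c(0.9, 0.2, 0.1, 0.5, 0.8, 0.1),
    bc = c(0.1, 0.9, 0.1, 0.2, 0.8, 0.3)
  )
  expect_equal(find_hub(tbl, "degree"), "O1") # mean .7 vs .5 vs .1
  expect_equal(find_hub(tbl, "bc"), "C4")
  ties <- tibble::tibble(subject_id = "a", node = c("X", "Y"),
                         degree = c(0.5, 0.5), bc = c(0, 0))
  expect_equal(find_hub(ties, "degree"), "X") # first in montage order
  expect_error(find_hub(tbl[0, ], "degree"), "empty")
})

test_that("a cohort built with a known star hub is recovered", {
  labs <- montage_1020_64()[1:8]
  sp <- cohort_spec(n_per_group = 4, channel_labels = labs, fs = 125,
                    duration_s = 30, bands = eeg_bands("alpha2"),
                    coupling = 0.5, bias_sd = 0.02, hub = "C3",
                    group_effects = list(alpha2 = list(star_bias = 0.3)),
                    seed = 55)
  coh <- gen_cohort(sp)
  an <- suppressWarnings(
    analyze_cohort(coh, bands = eeg_bands("alpha2"), min_epochs = 5)
  )
  ia_nodal <- an$nodal[an$nodal$group == "IA", ]
  expect_equal(find_hub(ia_nodal, "degree"), "C3")
  expect_equal(find_hub(ia_nodal, "bc"), "C3")
})
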