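# Naive, independent reference implementations used as oracles.
# Deliberately simple (path enumeration, exhaustive search, normal
# equations); they share no code with the package internals.

# union-find tree check
oracle_is_tree <- function(u, v, n) {
  if (length(u) != n - 1) return(FALSE)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(u)) {
    a <- find(u[e]); b <- find(v[e])
    if (a == b) return(FALSE)
    parent[a] <- b
  }
  TRUE
}

# nodal measures by BFS + explicit path walking
oracle_tree_metrics <- function(u, v, n) {
  adj <- vector("list", n)
  for (e in seq_along(u)) {
    adj[[u[e]]] <- c(adj[[u[e]]], v[e])
    adj[[v[e]]] <- c(adj[[v[e]]], u[e])
  }
  deg <- lengths(adj)
  dist <- matrix(NA_integer_, n, n)
  parent <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n); p <- rep(NA_integer_, n)
    d[s] <- 0L
    q <- s
    while (length(q) > 0) {
      x <- q[1]; q <- q[-1]
      for (y in adj[[x]]) {
        if (is.na(d[y])) {
          d[y] <- d[x] + 1L; p[y] <- x; q <- c(q, y)
        }
      }
    }
    dist[s, ] <- d
    parent[s, ] <- p
  }
  bc <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t2 in (s + 1):n) {
        x <- parent[s, t2]
        while (x != s) {
          bc[x] <- bc[x] + 1
          x <- parent[s, x]
        }
      }
    }
  }
  list(degree_raw = deg, bc_pairs = bc, ecc_raw = apply(dist, 1, max),
       dist = dist)
}

# global measures from the naive nodal route, formulas written out once more
oracle_global <- function(u, v, n) {
  m <- oracle_tree_metrics(u, v, n)
  deg <- m$degree_raw
  npairs <- (n - 1) * (n - 2) / 2
  bc <- if (npairs > 0) m$bc_pairs / npairs else rep(0, n)
  leaf_count <- sum(deg == 1)
  max_bc <- max(bc)
  x <- c(deg[u], deg[v])
  y <- c(deg[v], deg[u])
  r <- if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  c(max_degree = max(deg) / (n - 1),
    max_bc = max_bc,
    ecc = mean(m$ecc_raw / (n - 1)),
    diameter = max(m$ecc_raw) / (n - 1),
    leaf = leaf_count / n,
    th = if (max_bc > 0) leaf_count / (2 * (n - 1) * max_bc) else NA_real_,
    kappa = sum(deg^2) / sum(deg),
    r = r)
}

# classic O(n^2) Pruefer decoding: repeatedly join the smallest leaf
oracle_prufer_decode <- function(seq, n) {
  deg <- rep(1L, n)
  for (s in seq) deg[s] <- deg[s] + 1L
  u <- integer(0); v <- integer(0)
  for (s in seq) {
    leaf <- min(which(deg == 1L))
    u <- c(u, leaf); v <- c(v, s)
    deg[leaf] <- 0L
    deg[s] <- deg[s] - 1L
  }
  rest <- which(deg == 1L)
  cbind(u = c(u, rest[1]), v = c(v, rest[2]))
}

# all Pruefer sequences over n nodes (exhaustive labelled-tree enumeration)
all_prufer <- function(n) {
  if (n == 2) return(matrix(integer(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
}

# maximum spanning-tree weight of a complete weighted graph by brute force
oracle_max_tree_weight <- function(W) {
  n <- nrow(W)
  if (n == 2) return(W[1, 2])
  seqs <- all_prufer(n)
  best <- -Inf
  for (i in seq_len(nrow(seqs))) {
    el <- oracle_prufer_decode(seqs[i, ], n)
    w <- sum(W[el])
    if (w > best) best <- w
  }
  best
}

# PLI by the printed formula, written directly
oracle_pli <- function(phi_i, phi_j) {
  abs(mean(sign(sin(phi_i - phi_j))))
}

# ANCOVA group F / p / partial eta^2 via explicit normal equations
oracle_ancova <- function(y, g01, covars) {
  X <- cbind(1, g01, covars)
  b <- solve(crossprod(X), crossprod(X, y))
  ss_full <- sum((y - X %*% b)^2)
  X0 <- cbind(1, covars)
  b0 <- solve(crossprod(X0), crossprod(X0, y))
  ss_red <- sum((y - X0 %*% b0)^2)
  df2 <- length(y) - ncol(X)
  f <- (ss_red - ss_full) / (ss_full / df2)
  list(F = f, p = stats::pf(f, 1, df2, lower.tail = FALSE),
       eta2 = (ss_red - ss_full) / ss_red)
}

# compare a package tree against both naive metric routes
expect_tree_matches_oracle <- function(tree, tol = 1e-12) {
  u <- tree$edges$u; v <- tree$edges$v; n <- tree$n
  ref_nodal <- oracle_tree_metrics(u, v, n)
  nm <- nodal_metrics(tree)
  expect_equal(nm$degree_raw, as.integer(ref_nodal$degree_raw))
  expect_equal(nm$bc * ((n - 1) * (n - 2) / 2), ref_nodal$bc_pairs,
               tolerance = tol)
  expect_equal(nm$ecc_raw, as.integer(ref_nodal$ecc_raw))
  ref_glob <- oracle_global(u, v, n)
  gm <- global_metrics(tree)
  got <- as.numeric(gm[, names(ref_glob)])
  expect_equal(got, unname(ref_glob), tolerance = tol)
}
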