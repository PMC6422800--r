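#' Maximum-weight spanning tree of a connectivity matrix
#'
#' Builds the spanning tree that keeps the strongest connections: all pairwise
#' weights are sorted in descending order and added in turn, discarding any
#' link that would close a loop (Kruskal's algorithm), until all nodes are
#' connected by n - 1 edges. This is the "minimum spanning tree" of the
#' brain-network literature, which is the maximum-weight tree of the PLI
#' matrix (equivalently the minimum tree of 1 - PLI). Equal weights are
#' broken deterministically by the lexicographically smallest channel-index
#' pair.
#'
#' @param matrix A `pli_matrix` or plain symmetric numeric matrix with at
#'   least two rows.
#' @return An `mst_tree` (see [tree_graph()]).
#' @export
#' @examples
#' w <- matrix(c(0, .9, .8, .9, 0, .1, .8, .1, 0), 3)
#' max_spanning_tree(w)$edges
max_spanning_tree <- function(matrix) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("`matrix` must be square", call. = FALSE)
  }
  if (nrow(m) < 2) stop("need at least 2 nodes", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) {
    stop("`matrix` must be symmetric", call. = FALSE)
  }
  labels <- rownames(m)
  el <- cpp_kruskal_max(m)
  tree_graph(el[, 1], el[, 2], n_nodes = nrow(m), labels = labels,
             weight = el[, 3])
}

#' Nodal tree measures
#'
#' Per-node measures of an n-node tree:
#' * `degree_raw`: number of incident edges; `degree` normalizes by the
#'   maximum possible `n - 1`.
#' * `bc`: betweenness centrality, the fraction of the (n-1)(n-2)/2 unordered
#'   pairs of other nodes whose unique tree path passes through the node
#'   (leaves always score 0).
#' * `ecc_raw`: eccentricity, the longest shortest path from the node in
#'   hops; `ecc` normalizes by `n - 1`.
#'
#' @param tree An `mst_tree`.
#' @return A tibble with one row per node: `node`, `degree_raw`, `degree`,
#'   `bc`, `ecc_raw`, `ecc`.
#' @export
nodal_metrics <- function(tree) {
  stopifnot(inherits(tree, "mst_tree"))
  n <- tree$n
  res <- cpp_tree_metrics(tree$edges$u, tree$edges$v, n)
  npairs <- (n - 1) * (n - 2) / 2
  tibble::tibble(
    node = tree$labels,
    degree_raw = res$degree_raw,
    degree = res$degree_raw / (n - 1),
    bc = if (npairs > 0) res$bc_pairs / npairs else rep(0, n),
    ecc_raw = res$ecc_raw,
    ecc = res$ecc_raw / (n - 1)
  )
}

#' Global tree measures
#'
#' One-row summary of tree topology:
#' * `max_degree`, `max_bc`: maxima of the normalized nodal degree and
#'   betweenness (hub strength).
#' * `ecc`: mean normalized nodal eccentricity; `diameter`: largest hop
#'   distance divided by `n - 1` (lower = more integrated).
#' * `leaf`: fraction of degree-1 nodes.
#' * `th`: tree hierarchy `leaf_count / (2 (n - 1) max_bc)`; ~0 for a path,
#'   0.5 for a star, balancing integration against hub overload.
#' * `kappa`: degree divergence `sum(k^2) / sum(k)`; large when strong hubs
#'   exist.
#' * `r`: degree correlation, the Pearson correlation of endpoint degrees
#'   over the symmetrized edge list (each edge counted in both orientations);
#'   `NA` when an endpoint degree has zero variance (e.g. a perfect star),
#'   never coerced to 0.
#'
#' @param tree An `mst_tree`.
#' @return A one-row tibble: `n`, `max_degree`, `max_bc`, `ecc`, `diameter`,
#'   `leaf`, `th`, `kappa`, `r`.
#' @export
#' @examples
#' global_metrics(gen_tree("star", 64))
global_metrics <- function(tree) {
  nm <- nodal_metrics(tree)
  n <- tree$n
  k <- nm$degree_raw
  leaf_count <- sum(k == 1)
  max_bc <- max(nm$bc)
  th <- if (max_bc > 0) leaf_count / (2 * (n - 1) * max_bc) else NA_real_
  deg_u <- k[tree$edges$u]
  deg_v <- k[tree$edges$v]
  x <- c(deg_u, deg_v)
  y <- c(deg_v, deg_u)
  r <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  tibble::tibble(
    n = n,
    max_degree = max(nm$degree),
    max_bc = max_bc,
    ecc = mean(nm$ecc),
    diameter = max(nm$ecc_raw) / (n - 1),
    leaf = leaf_count / n,
    th = th,
    kappa = sum(k^2) / sum(k),
    r = r
  )
}

#' Average global tree measures across epochs
#'
#' Element-wise mean over epochs of the global measures; the degree
#' correlation `r` is undefined for star-shaped epochs and is averaged over
#' the epochs where it is defined, with the count reported in `r_defined`.
#'
#' @param metrics A tibble of per-epoch [global_metrics()] rows (or a list of
#'   such one-row tibbles).
#' @return A one-row tibble with the averaged measures plus `n_epochs` and
#'   `r_defined`.
#' @export
epoch_average_metrics <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics)) {
    metrics <- dplyr::bind_rows(metrics)
  }
  if (nrow(metrics) == 0) stop("no epochs to average", call. = FALSE)
  cols <- c("max_degree", "max_bc", "ecc", "diameter", "leaf", "th", "kappa")
  out <- tibble::as_tibble(as.list(colMeans(metrics[cols])))
  r_def <- sum(!is.na(metrics$r))
  out$r <- if (r_def > 0) mean(metrics$r, na.rm = TRUE) else NA_real_
  out$n_epochs <- nrow(metrics)
  out$r_defined <- r_def
  out
}

#' Write a tree to disk
#'
#' Edge list as CSV (`from`, `to`, `weight`) and, optionally, the adjacency
#' structure in NCOL format (one `from to weight` triple per line), a plain
#' graph text format readable by igraph and other tools.
#'
#' @param tree An `mst_tree`.
#' @param path Output CSV path.
#' @param ncol_path Optional path for the NCOL export.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, ncol_path = NULL) {
  stopifnot(inherits(tree, "mst_tree"))
  utils::write.csv(tree$edges[, c("from", "to", "weight")], path,
                   row.names = FALSE)
  if (!is.null(ncol_path)) {
    writeLines(sprintf("%s %s %.17g", tree$edges$from, tree$edges$to,
                       tree$edges$weight), ncol_path)
  }
  invisible(path)
}

#' Locate the group-level hub
#'
#' The hub is the channel maximizing the group mean of a nodal statistic
#' (degree or betweenness). Ties are broken deterministically by montage
#' order (the order channels first appear in the table).
#'
#' @param nodal_tbl Tibble with columns `subject_id`, `node` and the nodal
#'   statistics (as produced by [analyze_cohort()]'s `nodal` table, possibly
#'   filtered to one group and band).
#' @param statistic `"degree"` or `"bc"`.
#' @return The hub channel label (length-1 character).
#' @export
find_hub <- function(nodal_tbl, statistic = c("degree", "bc")) {
  statistic <- match.arg(statistic)
  if (nrow(nodal_tbl) == 0) stop("empty nodal table", call. = FALSE)
  order_levels <- unique(nodal_tbl$node)
  means <- nodal_tbl |>
    dplyr::group_by(node = factor(.data$node, levels = order_levels)) |>
    dplyr::summarise(m = mean(.data[[statistic]]), .groups = "drop")
  as.character(means$node[which.max(means$m)])
}
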