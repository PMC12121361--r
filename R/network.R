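#' Build a weighted PPI network from a STRING-style edge list
#'
#' Keeps interactions with combined score strictly greater than
#' `score_threshold`, z-score-normalizes the kept scores (mean and sample sd
#' over kept edges) and pushes them through the logistic function, giving
#' edge weights in `(0, 1)`. Edges touching proteins outside `protein_ids`
#' are dropped (with a message), duplicate pairs are collapsed keeping the
#' maximum score, and self-loops are removed. When the kept scores are
#' degenerate (a single edge, or zero sd) every weight is 0.5 by convention.
#'
#' @param edges data frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (scores in `[0, 1]`; see [read_edges()] for the
#'   0-1000 STRING dialect).
#' @param protein_ids character vector fixing the node set (typically the
#'   selected target proteins); the returned matrix covers all of them,
#'   including isolated nodes.
#' @param score_threshold strict lower bound on the combined score;
#'   default `0.4`.
#' @return `d x d` symmetric weight matrix with zero diagonal and
#'   `protein_ids` as dimnames.
#' @export
build_network <- function(edges, protein_ids, score_threshold = 0.4) {
  edges <- as.data.frame(edges)
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(edges)))
    names(edges)[1:3] <- need
  if (any(edges$combined_score < 0 | edges$combined_score > 1))
    stop("combined scores must lie in [0, 1]; use read_edges() for 0-1000 files")
  d <- length(protein_ids)
  if (anyDuplicated(protein_ids)) stop("protein_ids must be unique")

  a <- as.character(edges$protein_a)
  b <- as.character(edges$protein_b)
  keep_nodes <- a %in% protein_ids & b %in% protein_ids
  if (any(!keep_nodes))
    message(sum(!keep_nodes), " edge(s) dropped: endpoint not in protein_ids")
  edges <- edges[keep_nodes & a != b, , drop = FALSE]
  a <- as.character(edges$protein_a); b <- as.character(edges$protein_b)

  W <- matrix(0, d, d, dimnames = list(protein_ids, protein_ids))
  if (nrow(edges) == 0) {
    warning("no edges retained; returning an empty network")
    return(W)
  }
  # collapse duplicates (unordered pair) keeping the maximum score
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  score <- tapply(edges$combined_score, key, max)
  pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  kept <- score > score_threshold
  if (!any(kept)) {
    warning("no edges exceed the score threshold; returning an empty network")
    return(W)
  }
  s <- as.numeric(score[kept])
  pairs <- pairs[kept, , drop = FALSE]
  sd_s <- stats::sd(s)
  w <- if (length(s) == 1 || sd_s == 0) rep(0.5, length(s))
       else stats::plogis((s - mean(s)) / sd_s)
  ia <- match(pairs[, 1], protein_ids)
  ib <- match(pairs[, 2], protein_ids)
  W[cbind(ia, ib)] <- w
  W[cbind(ib, ia)] <- w
  W
}

#' Structural statistics of a PPI network
#'
#' Density and mean degree are reported over the connected nodes (degree at
#' least one), matching the convention for sparse interaction networks; the
#' all-node density is reported alongside.
#'
#' @param network `d x d` symmetric weight matrix.
#' @return list: `n_nodes_total`, `n_nodes_connected`, `n_edges`,
#'   `density_connected_pct`, `density_total_pct`, `mean_degree_connected`,
#'   `max_degree`, `mean_edge_weight`. Degenerate (edgeless) networks report
#'   zero edges and `NA` densities.
#' @examples
#' # 93 connected nodes and 234 edges give density 5.47% and mean degree 5.03
#' @export
network_stats <- function(network) {
  W <- as_weight_matrix(network)
  validate_network(W)
  deg <- rowSums(W > 0)
  n_edges <- sum(W > 0) / 2
  n_conn <- sum(deg >= 1)
  list(
    n_nodes_total = nrow(W),
    n_nodes_connected = n_conn,
    n_edges = n_edges,
    density_connected_pct = if (n_conn >= 2)
      100 * n_edges / choose(n_conn, 2) else NA_real_,
    density_total_pct = if (nrow(W) >= 2)
      100 * n_edges / choose(nrow(W), 2) else NA_real_,
    mean_degree_connected = if (n_conn >= 1) 2 * n_edges / n_conn else 0,
    max_degree = max(deg),
    mean_edge_weight = if (n_edges > 0) mean(W[upper.tri(W) & W > 0]) else
      NA_real_
  )
}

#' Randomly subsample network edges
#'
#' Draws `round(fraction * E)` edges uniformly without replacement and
#' returns the network restricted to them; the node set is unchanged.
#'
#' @param network `d x d` symmetric weight matrix.
#' @param fraction fraction of edges to keep, in `(0, 1]`.
#' @param seed optional integer seed for reproducibility.
#' @return weight matrix of the same shape.
#' @export
subsample_edges <- function(network, fraction, seed = NULL) {
  W <- as_weight_matrix(network)
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(upper.tri(W) & W > 0)
  m <- round(fraction * length(idx))
  keep <- if (m >= length(idx)) idx else sample(idx, m)
  out <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  out[keep] <- W[keep]
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Set selected interaction weights to one
#'
#' Highlights a user-supplied edge subset (e.g. interactions verified as
#' functional, physical or regulatory) by setting their weights to exactly 1
#' in both triangles; all other weights are untouched. Pairs not present in
#' the network are collected in the `"rejects"` attribute rather than being
#' fatal. The operation is idempotent.
#'
#' @param network `d x d` symmetric weight matrix with dimnames.
#' @param edge_subset data frame (or 2-column matrix) of protein pairs.
#' @return the modified weight matrix; rejected pairs, if any, in
#'   `attr(, "rejects")`.
#' @export
highlight_edges <- function(network, edge_subset) {
  W <- as_weight_matrix(network)
  edge_subset <- as.data.frame(edge_subset)
  if (nrow(edge_subset) == 0) return(W)
  a <- as.character(edge_subset[[1]])
  b <- as.character(edge_subset[[2]])
  ia <- match(a, rownames(W)); ib <- match(b, rownames(W))
  present <- !is.na(ia) & !is.na(ib)
  present[present] <- W[cbind(ia[present], ib[present])] > 0
  if (any(!present)) {
    rej <- data.frame(protein_a = a[!present], protein_b = b[!present])
    message(nrow(rej), " highlighted pair(s) not found in the network")
  } else rej <- NULL
  W[cbind(ia[present], ib[present])] <- 1
  W[cbind(ib[present], ia[present])] <- 1
  if (!is.null(rej)) attr(W, "rejects") <- rej
  W
}
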