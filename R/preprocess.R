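#' Drop proteins with too many missing values
#'
#' Excludes proteins whose fraction of missing samples is strictly greater
#' than `max_missing` (a protein at exactly the threshold is retained).
#' Row order is preserved.
#'
#' @param x `d x n` numeric matrix with `NA` for missing entries, proteins in
#'   rows.
#' @param max_missing maximum tolerated missing fraction per protein;
#'   default `0.05`.
#' @return the filtered matrix.
#' @export
filter_missing_proteins <- function(x, max_missing = 0.05) {
  x <- as.matrix(x)
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- rowMeans(is.na(x))
  keep <- frac <= max_missing
  if (!any(keep))
    stop("no protein passes the missingness filter (", max_missing, ")")
  x[keep, , drop = FALSE]
}

#' k-nearest-neighbour imputation of missing expression values
#'
#' A missing entry (protein i, sample j) is replaced by the mean of protein
#' i's values in the `k` samples nearest to sample j. Nearness is the
#' root-mean-square Euclidean distance over the proteins observed in both
#' samples; only samples with protein i observed are candidate neighbours.
#' Ties are broken toward the lower sample index, so the result is
#' deterministic.
#'
#' @param x `d x n` matrix with `NA` for missing entries, proteins in rows.
#' @param k number of neighbours; every protein must be observed in at least
#'   `k` samples.
#' @return the completed matrix (observed entries untouched).
#' @export
impute_knn <- function(x, k = 10) {
  x <- as.matrix(x)
  n <- ncol(x)
  stopifnot(k >= 1)
  if (!anyNA(x)) return(x)
  obs_per_protein <- rowSums(!is.na(x))
  if (any(obs_per_protein < k))
    stop("protein ", rownames(x)[which(obs_per_protein < k)[1]] %||%
           which(obs_per_protein < k)[1],
         " has fewer than k = ", k, " observed samples")

  obs <- !is.na(x)
  # pairwise RMS distance over jointly observed proteins
  dist_mat <- matrix(Inf, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      shared <- obs[, a] & obs[, b]
      if (!any(shared)) next
      dist_mat[a, b] <- dist_mat[b, a] <-
        sqrt(mean((x[shared, a] - x[shared, b])^2))
    }
  }
  if (any(apply(dist_mat, 1, function(r) all(!is.finite(r)))))
    stop("a sample shares no observed proteins with any other sample")

  out <- x
  for (j in seq_len(n)) {
    miss_i <- which(!obs[, j])
    if (length(miss_i) == 0) next
    ord <- order(dist_mat[j, ], seq_len(n))   # ties -> lower index
    for (i in miss_i) {
      cand <- ord[obs[i, ord] & is.finite(dist_mat[j, ord])]
      if (length(cand) < k)
        stop("fewer than k observed neighbours for protein row ", i,
             ", sample ", j)
      out[i, j] <- mean(x[i, cand[seq_len(k)]])
    }
  }
  out
}

#' Z-score then logistic-scale an expression matrix
#'
#' Each protein row is standardized across samples (`(x - mean) / sd`, sample
#' standard deviation) and pushed through the logistic function, yielding
#' bounded values in `(0, 1)`. A constant row (zero sd) maps to 0.5
#' everywhere.
#'
#' @param x complete `d x n` numeric matrix, proteins in rows.
#' @param center,scale optional length-`d` vectors of precomputed row means
#'   and sds (e.g. from a training fold) to apply instead of the matrix's
#'   own statistics.
#' @return matrix of the same shape with entries in `(0, 1)`; the row means
#'   and sds used are attached as attributes `"center"` and `"scale"`.
#' @export
scale_expression <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("x contains missing values; impute first")
  m <- if (is.null(center)) rowMeans(x) else center
  s <- if (is.null(scale)) apply(x, 1, stats::sd) else scale
  s_safe <- ifelse(s > 0, s, 1)
  z <- (x - m) / s_safe
  z[s == 0, ] <- 0                       # constant rows -> logit 0 -> 0.5
  out <- stats::plogis(z)
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
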