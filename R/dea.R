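#' Per-protein differential expression between diagnosis groups
#'
#' Welch two-sample t-test (unequal variances, Welch-Satterthwaite degrees of
#' freedom) for every protein row, comparing biomarker-positive against
#' -negative samples; two-sided p-values. When both groups are degenerate
#' (zero variance) with identical means the protein gets `t = 0, p = 1` and
#' is flagged.
#'
#' @param x `d x n` numeric matrix, proteins in rows (typically the scaled
#'   matrix the model consumes).
#' @param y length-`n` 0/1 diagnosis vector; both groups need at least two
#'   samples.
#' @return data frame with one row per protein: `protein_id`, `statistic`,
#'   `df`, `p_value`, `direction` (`"up"` iff case mean > control mean),
#'   `neg_log10_p`, `degenerate`.
#' @export
dea_test <- function(x, y) {
  x <- as.matrix(x)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(y) != ncol(x)) stop("y must have one entry per sample")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2) stop("both groups need at least 2 samples")
  x1 <- x[, y == 1, drop = FALSE]
  x0 <- x[, y == 0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- apply(x1, 1, stats::var); v0 <- apply(x0, 1, stats::var)
  se2 <- v1 / n1 + v0 / n0
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, 0, (m1 - m0) / sqrt(ifelse(se2 == 0, 1, se2)))
  df <- ifelse(degenerate, NA_real_,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)))
  p <- ifelse(degenerate & m1 == m0, 1,
              2 * stats::pt(-abs(tstat), df))
  # degenerate variance but different means: perfectly separated
  p[degenerate & m1 != m0] <- 0
  tstat[degenerate & m1 != m0] <- Inf * sign(m1 - m0)[degenerate & m1 != m0]
  data.frame(
    protein_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    statistic = tstat, df = df, p_value = p,
    direction = ifelse(m1 > m0, "up", "down"),
    neg_log10_p = -log10(pmax(p, .Machine$double.xmin)),
    degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select target proteins shared across all biomarkers
#'
#' A protein is a target when its differential-expression p-value is below
#' `alpha` for every biomarker; the input protein order is preserved. Also
#' reports the per-biomarker DEP counts and the size of the DEP union.
#'
#' @param dea_by_biomarker named list of [dea_test()] results covering the
#'   same proteins in the same order.
#' @param alpha significance threshold on the raw (unadjusted) p-values;
#'   default `0.05`.
#' @return list of class `"target_selection"`: `targets` (character vector),
#'   `n_dep` (named per-biomarker counts), `n_union`, `alpha`.
#' @export
select_targets <- function(dea_by_biomarker, alpha = 0.05) {
  stopifnot(length(dea_by_biomarker) >= 1)
  ids <- dea_by_biomarker[[1]]$protein_id
  for (dd in dea_by_biomarker)
    if (!identical(dd$protein_id, ids))
      stop("all DEA results must cover the same proteins in the same order")
  sig <- vapply(dea_by_biomarker, function(dd) dd$p_value < alpha,
                logical(length(ids)))
  sig <- matrix(sig, nrow = length(ids))
  in_all <- rowSums(sig) == ncol(sig)
  targets <- ids[in_all]
  if (length(targets) == 0)
    warning("no protein is differentially expressed across every biomarker")
  structure(list(
    targets = targets,
    n_dep = stats::setNames(colSums(sig), names(dea_by_biomarker)),
    n_union = sum(rowSums(sig) > 0),
    alpha = alpha
  ), class = "target_selection")
}

#' @export
print.target_selection <- function(x, ...) {
  cat("Target selection at alpha =", x$alpha, "\n")
  cat("Per-biomarker DEP counts:\n")
  print(x$n_dep)
  cat("DEP union:", x$n_union, "| shared targets:", length(x$targets), "\n")
  invisible(x)
}

#' Write a differential-expression report
#'
#' One row per protein with each biomarker's statistic, p-value and
#' direction, plus a flag marking the selected targets.
#'
#' @param dea_by_biomarker named list of [dea_test()] results.
#' @param selection a [select_targets()] result.
#' @param path output TSV path.
#' @export
write_dep_report <- function(dea_by_biomarker, selection, path) {
  ids <- dea_by_biomarker[[1]]$protein_id
  out <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (b in names(dea_by_biomarker)) {
    dd <- dea_by_biomarker[[b]]
    out[[paste0(b, "_statistic")]] <- dd$statistic
    out[[paste0(b, "_p_value")]] <- dd$p_value
    out[[paste0(b, "_direction")]] <- dd$direction
  }
  out$target <- ids %in% selection$targets
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
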