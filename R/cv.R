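#' Repeated stratified k-fold cross-validation
#'
#' Refits the graph propagational network on each training fold and scores
#' the held-out fold with AUROC, AUPRC, accuracy, F1 and their average.
#' Folds are stratified on the joint label pattern across biomarkers so
#' every fold carries both classes of every biomarker whenever the class
#' counts allow it. When `scale_within_fold` is `TRUE` (default) the
#' z-score-plus-logistic scaling is recomputed from the training fold only
#' and applied to the held-out fold, so no preprocessing statistic leaks.
#'
#' @param x `d x n` expression matrix, proteins in rows. With
#'   `scale_within_fold = TRUE` pass the unscaled (complete) matrix.
#' @param labels `n x B` 0/1 matrix with biomarker column names.
#' @param network `d x d` symmetric weight matrix.
#' @param k folds; default `5`.
#' @param reps independent repetitions; default `100` (scale down for quick
#'   runs).
#' @param seed integer seed making the whole procedure reproducible.
#' @param control [gpnet_control()] used for every refit.
#' @param scale_within_fold recompute row scaling per training fold;
#'   default `TRUE`.
#' @param covariates optional `n x c` covariate matrix.
#' @return data frame of class `"cv_result"` with columns `biomarker`,
#'   `rep`, `fold`, `metric`, `value`; summarize with [cv_summary()].
#' @export
repeated_cv <- function(x, labels, network, k = 5, reps = 100, seed = NULL,
                        control = gpnet_control(), scale_within_fold = TRUE,
                        covariates = NULL) {
  x <- as.matrix(x)
  labels <- as.matrix(labels)
  n <- ncol(x)
  if (n < k) stop("need at least k samples")
  if (!is.null(seed)) set.seed(seed)
  biomarkers <- colnames(labels) %||% paste0("task", seq_len(ncol(labels)))
  colnames(labels) <- biomarkers

  rows <- vector("list", reps * k)
  ri <- 0L
  for (rep_i in seq_len(reps)) {
    fold_id <- stratified_folds(labels, k)
    for (fold_i in seq_len(k)) {
      test <- fold_id == fold_i
      if (any(colSums(labels[test, , drop = FALSE]) == 0) ||
          any(colSums(1 - labels[test, , drop = FALSE]) == 0))
        stop("stratification impossible: a held-out fold is single-class")
      x_tr <- x[, !test, drop = FALSE]
      x_te <- x[, test, drop = FALSE]
      if (scale_within_fold) {
        x_tr <- scale_expression(x_tr)
        x_te <- scale_expression(x[, test, drop = FALSE],
                                 center = attr(x_tr, "center"),
                                 scale = attr(x_tr, "scale"))
      }
      cv_tr <- if (is.null(covariates)) NULL else
        covariates[!test, , drop = FALSE]
      cv_te <- if (is.null(covariates)) NULL else
        covariates[test, , drop = FALSE]
      fit <- gpnet(x_tr, network, labels[!test, , drop = FALSE],
                   covariates = cv_tr, control = control)
      pred <- predict(fit, newdata = x_te, covariates = cv_te)
      for (b in biomarkers) {
        m <- metric_set(pred[, b], labels[test, b])
        ri <- ri + 1L
        rows[[ri]] <- data.frame(biomarker = b, rep = rep_i, fold = fold_i,
                                 metric = names(m), value = unname(m),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  class(out) <- c("cv_result", class(out))
  out
}

# fold assignment stratified on the joint label pattern; samples are dealt
# round-robin across folds (continuing the deal across patterns), so overall
# fold sizes differ by at most one
stratified_folds <- function(labels, k) {
  pattern <- apply(labels, 1, paste, collapse = "")
  fold_id <- integer(nrow(labels))
  deal <- sample.int(k)            # random fold order for the deal
  pos <- 0L
  for (pat in unique(pattern)) {
    idx <- which(pattern == pat)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- deal[(pos + seq_along(idx) - 1L) %% k + 1L]
    pos <- pos + length(idx)
  }
  fold_id
}

#' Aggregate a cross-validation result
#'
#' @param cv a [repeated_cv()] result.
#' @return data frame with the mean and sd of every metric per biomarker,
#'   plus a pooled `"all"` row per metric averaging over biomarkers.
#' @export
cv_summary <- function(cv) {
  agg <- stats::aggregate(value ~ biomarker + metric, data = cv,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(biomarker = agg$biomarker, metric = agg$metric,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    stringsAsFactors = FALSE)
  pooled <- stats::aggregate(mean ~ metric, data = out, FUN = mean)
  out <- rbind(out, data.frame(biomarker = "all", metric = pooled$metric,
                               mean = pooled$mean, sd = NA_real_))
  out[order(out$biomarker, out$metric), ]
}

#' Edge-density ablation of the PPI network
#'
#' For each edge fraction, draws random subnetworks, reruns cross-validation
#' on each, and reports the mean held-out AUROC (averaged over biomarkers).
#' The edgeless, independent-effect-only baseline (`fraction = 0`) is
#' included when requested; `fraction = 1` uses the original network once.
#'
#' @param x,labels,network as in [repeated_cv()].
#' @param fractions edge fractions to test; default
#'   `c(0.2, 0.4, 0.6, 0.8, 1.0)`.
#' @param n_networks random subnetworks per fraction; default `100` (scale
#'   down for quick runs).
#' @param seed integer seed.
#' @param k,reps,control,scale_within_fold passed to [repeated_cv()].
#' @param include_baseline add the edgeless baseline row; default `TRUE`.
#' @return data frame: `fraction`, `n_networks`, `mean_auroc`, `sd_auroc`.
#' @export
density_ablation <- function(x, labels, network,
                             fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                             n_networks = 100, seed = NULL, k = 5, reps = 1,
                             control = gpnet_control(),
                             scale_within_fold = TRUE,
                             include_baseline = TRUE) {
  W <- as_weight_matrix(network)
  if (!is.null(seed)) set.seed(seed)
  mean_cv_auroc <- function(net) {
    cv <- repeated_cv(x, labels, net, k = k, reps = reps,
                      control = control,
                      scale_within_fold = scale_within_fold)
    mean(cv$value[cv$metric == "auroc"])
  }
  rows <- list()
  if (include_baseline) {
    W0 <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
    rows[[length(rows) + 1]] <- data.frame(
      fraction = 0, n_networks = 1, mean_auroc = mean_cv_auroc(W0),
      sd_auroc = NA_real_)
  }
  for (f in fractions) {
    if (f >= 1) {
      aucs <- mean_cv_auroc(W)
      nn <- 1L
    } else {
      nn <- n_networks
      aucs <- vapply(seq_len(nn), function(i) {
        mean_cv_auroc(subsample_edges(W, f))
      }, numeric(1))
    }
    rows[[length(rows) + 1]] <- data.frame(
      fraction = f, n_networks = nn, mean_auroc = mean(aucs),
      sd_auroc = if (nn > 1) stats::sd(aucs) else NA_real_)
  }
  do.call(rbind, rows)
}
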