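#' Leave-one-protein-out importance (delta AUROC)
#'
#' Measures each protein's contribution to prediction performance as the
#' drop in mean AUROC (averaged over biomarkers) when the protein is
#' excluded from the synergetic effect. By default exclusion zeroes the
#' protein's row of `Z` at prediction time — no refit, no re-propagation;
#' with `repropagate = TRUE` the node is instead removed from the network
#' and the expression matrix before propagating again.
#'
#' @param object a fitted `"gpnet"`.
#' @param x expression matrix used for scoring; defaults to reproducing the
#'   training synergy stored in the fit.
#' @param labels `n x B` 0/1 matrix; defaults to the training labels.
#' @param network weight matrix; defaults to the training network.
#' @param repropagate remove the node and re-propagate instead of zeroing
#'   its synergy row; default `FALSE`.
#' @return data frame: `protein_id`, `delta_auroc` (baseline minus ablated),
#'   with the baseline mean AUROC as attribute `"baseline"`.
#' @export
loo_importance <- function(object, x = NULL, labels = NULL, network = NULL,
                           repropagate = FALSE) {
  stopifnot(inherits(object, "gpnet"))
  labels <- if (is.null(labels)) object$labels else as.matrix(labels)
  W <- if (is.null(network)) object$network else as_weight_matrix(network)
  z <- if (is.null(x)) object$synergy else propagate(x, W, object$phi)
  x_for_prop <- x   # only needed when repropagating

  mean_auc <- function(zmat) {
    aucs <- vapply(seq_along(object$biomarkers), function(b) {
      p <- estimate_risk(zmat, object$theta[, b], clip = object$control$clip)
      auroc(p, labels[, b])
    }, numeric(1))
    mean(aucs)
  }
  baseline <- mean_auc(z)
  d <- nrow(z)
  delta <- numeric(d)
  for (i in seq_len(d)) {
    if (repropagate) {
      Wi <- W; Wi[i, ] <- 0; Wi[, i] <- 0
      xi <- if (is.null(x_for_prop)) NULL else x_for_prop
      if (is.null(xi))
        stop("repropagate = TRUE requires the expression matrix x")
      xi[i, ] <- 0
      zi <- propagate(xi, Wi, object$phi)
      zi[i, ] <- 0
    } else {
      zi <- z
      zi[i, ] <- 0
    }
    delta[i] <- baseline - mean_auc(zi)
  }
  out <- data.frame(protein_id = object$protein_ids %||%
                      as.character(seq_len(d)),
                    delta_auroc = delta, stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  out
}

#' Major proteins: top decile of effect size and importance
#'
#' For one biomarker, the major proteins are the intersection of the top
#' `ceiling(top_frac * d)` proteins ranked by the signed estimation
#' parameter and the same-sized top set ranked by importance. Ties are
#' broken by protein-id order, so the selection is deterministic.
#'
#' @param theta named length-`d` estimation vector for the biomarker (or a
#'   column of `coef()`).
#' @param importance length-`d` importance scores aligned with `theta`
#'   (e.g. `delta_auroc` from [loo_importance()]).
#' @param top_frac fraction defining the top set; default `0.10`.
#' @param protein_ids identifiers; taken from `names(theta)` when absent.
#' @return character vector of major proteins (possibly empty).
#' @export
major_proteins <- function(theta, importance, top_frac = 0.10,
                           protein_ids = NULL) {
  d <- length(theta)
  if (length(importance) != d)
    stop("theta and importance must cover the same proteins")
  ids <- protein_ids %||% names(theta) %||% as.character(seq_len(d))
  m <- ceiling(top_frac * d)
  top_theta <- ids[order(-theta, ids)][seq_len(m)]
  top_imp <- ids[order(-importance, ids)][seq_len(m)]
  ids[ids %in% intersect(top_theta, top_imp)]
}

#' Risk scores from a protein subset
#'
#' Recomputes the per-biomarker risks with the estimation parameters of all
#' proteins outside the subset set to zero; the synergy matrix is unchanged.
#' With the full protein set this reproduces [predict.gpnet()] exactly, and
#' the logits of disjoint subsets add up to the full-model logit.
#'
#' @param object a fitted `"gpnet"`.
#' @param proteins character vector of protein ids (subset of the targets).
#' @param newdata optional expression matrix; defaults to the training data.
#' @param network optional weight matrix for `newdata`.
#' @return `n x B` risk matrix.
#' @export
subset_risk <- function(object, proteins, newdata = NULL, network = NULL) {
  stopifnot(inherits(object, "gpnet"))
  ids <- object$protein_ids %||% as.character(seq_along(object$phi))
  unknown <- setdiff(proteins, ids)
  if (length(unknown) > 0)
    stop("unknown protein(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  z <- if (is.null(newdata)) object$synergy else
    propagate(newdata, if (is.null(network)) object$network else network,
              object$phi)
  keep <- ids %in% proteins
  out <- matrix(0, ncol(z), length(object$biomarkers),
                dimnames = list(colnames(z), object$biomarkers))
  for (b in seq_along(object$biomarkers)) {
    th <- object$theta[, b] * keep
    out[, b] <- estimate_risk(z, th, clip = object$control$clip)
  }
  out
}

#' Group-discrimination significance of an effect matrix
#'
#' Runs the per-protein two-group Welch test of [dea_test()] on an effect
#' matrix (independent `X` or synergetic `Z`) against one biomarker's
#' diagnosis labels and returns the `-log10` p-values — used to compare how
#' strongly the two effect representations separate the diagnostic groups.
#'
#' @param effects `d x n` matrix (`X` or `Z`).
#' @param y length-`n` 0/1 vector.
#' @return data frame from [dea_test()] (includes `neg_log10_p`).
#' @export
effect_significance <- function(effects, y) {
  dea_test(effects, y)
}

#' Per-protein report of a fitted model
#'
#' One row per target protein: propagation intensity, per-biomarker
#' estimation parameters, leave-one-out importance and major-protein flags.
#'
#' @param object a fitted `"gpnet"`.
#' @param importance optional precomputed [loo_importance()] result
#'   (computed if missing).
#' @param top_frac major-protein fraction; default `0.10`.
#' @return data frame.
#' @export
protein_report <- function(object, importance = NULL, top_frac = 0.10) {
  if (is.null(importance)) importance <- loo_importance(object)
  ids <- importance$protein_id
  out <- data.frame(protein_id = ids, phi = unname(object$phi),
                    stringsAsFactors = FALSE)
  for (b in object$biomarkers) out[[paste0("theta_", b)]] <- object$theta[, b]
  out$delta_auroc <- importance$delta_auroc
  for (b in object$biomarkers) {
    mp <- major_proteins(stats::setNames(object$theta[, b], ids),
                         importance$delta_auroc, top_frac, protein_ids = ids)
    out[[paste0("major_", b)]] <- ids %in% mp
  }
  out
}
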