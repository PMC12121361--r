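#' @export
print.gpnet <- function(x, ...) {
  cat("PPI-aware graph propagational risk model\n\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d proteins, %d samples, %d biomarkers (%s)\n",
              length(x$phi), nrow(x$fitted), length(x$biomarkers),
              paste(x$biomarkers, collapse = ", ")))
  cat(sprintf("Optimizer %s, eta = %g, delta = %g; %d epochs (%s)\n",
              x$control$optimizer, x$control$eta, x$delta, x$epochs,
              if (x$converged) "converged" else "max epochs reached"))
  cat(sprintf("Final objective: %.5f\n", utils::tail(x$loss_trace, 1)))
  if (!is.null(x$beta)) cat("Demographic covariates enabled\n")
  invisible(x)
}

#' Summarize a fitted graph propagational network
#'
#' Reports the loss trajectory, the distribution of the trained propagation
#' intensities, and the in-sample classification metrics per biomarker.
#'
#' @param object a fitted `"gpnet"` object.
#' @param ... unused.
#' @export
summary.gpnet <- function(object, ...) {
  mets <- t(vapply(object$biomarkers, function(b) {
    metric_set(object$fitted[, b], object$labels[, b])
  }, numeric(5)))
  out <- list(
    call = object$call,
    epochs = object$epochs,
    converged = object$converged,
    initial_loss = object$loss_trace[1],
    final_loss = utils::tail(object$loss_trace, 1),
    phi_summary = summary(object$phi),
    training_metrics = mets
  )
  class(out) <- "summary.gpnet"
  out
}

#' @export
print.summary.gpnet <- function(x, ...) {
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Objective: %.5f -> %.5f over %d epochs (%s)\n",
              x$initial_loss, x$final_loss, x$epochs,
              if (x$converged) "converged" else "max epochs reached"))
  cat("\nPropagation intensities (phi):\n")
  print(x$phi_summary)
  cat("\nIn-sample metrics (training data; optimistic):\n")
  print(round(x$training_metrics, 4))
  invisible(x)
}

#' Extract model coefficients
#'
#' Returns a `d x (1 + B)` matrix: the propagation intensity `phi` in the
#' first column and the per-biomarker estimation vectors in the remaining
#' columns. Covariate weights, when present, are attached as the
#' `"beta"` attribute.
#'
#' @param object a fitted `"gpnet"` object.
#' @param ... unused.
#' @export
coef.gpnet <- function(object, ...) {
  out <- cbind(phi = object$phi, object$theta)
  if (!is.null(object$beta)) attr(out, "beta") <- object$beta
  out
}

#' Predict biomarker risks for new samples
#'
#' Propagates the new expression columns through the trained network with the
#' fitted `phi` (propagation mixes proteins within a sample, never across
#' samples, so there is no label leakage), then applies each biomarker's
#' estimation vector.
#'
#' @param object a fitted `"gpnet"` object.
#' @param newdata `d x n_new` expression matrix with the training proteins in
#'   rows; defaults to the training data.
#' @param network weight matrix to propagate over; defaults to the training
#'   network.
#' @param covariates `n_new x c` covariate matrix, required when the model
#'   was fitted with covariates (standardized with the training constants).
#' @param type `"response"` for risks in `(0, 1)`, `"link"` for logits.
#' @param ... unused.
#' @return `n_new x B` matrix of risks (or logits).
#' @export
predict.gpnet <- function(object, newdata = NULL, network = NULL,
                          covariates = NULL, type = c("response", "link"),
                          ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) NULL else as.matrix(newdata)
  W <- if (is.null(network)) object$network else as_weight_matrix(network)

  if (is.null(x)) {
    z <- object$synergy
  } else {
    if (nrow(x) != length(object$phi))
      stop("newdata must have ", length(object$phi), " protein rows")
    if (!is.null(rownames(x)) && !is.null(object$protein_ids)) {
      missing_ids <- setdiff(object$protein_ids, rownames(x))
      if (length(missing_ids) > 0)
        stop("newdata is missing proteins: ",
             paste(utils::head(missing_ids, 5), collapse = ", "))
      x <- x[object$protein_ids, , drop = FALSE]
    }
    z <- propagate(x, W, object$phi)
  }

  C <- NULL
  if (!is.null(object$beta)) {
    if (is.null(covariates))
      stop("model was fitted with covariates; supply them for prediction")
    C <- scale(as.matrix(covariates), center = object$covariate_center,
               scale = object$covariate_scale)
  }

  B <- length(object$biomarkers)
  out <- matrix(0, ncol(z), B,
                dimnames = list(colnames(z), object$biomarkers))
  for (b in seq_len(B)) {
    bb <- if (is.null(object$beta)) NULL else object$beta[, b]
    p <- estimate_risk(z, object$theta[, b], C, bb, clip = object$control$clip)
    out[, b] <- if (type == "link") stats::qlogis(p) else p
  }
  out
}

#' @export
fitted.gpnet <- function(object, ...) object$fitted

#' Residuals of a fitted graph propagational network
#'
#' @param object a fitted `"gpnet"` object.
#' @param type `"response"` (`Y - P`) or `"deviance"`.
#' @param ... unused.
#' @export
residuals.gpnet <- function(object, type = c("response", "deviance"), ...) {
  type <- match.arg(type)
  r <- object$labels - object$fitted
  if (type == "response") return(r)
  d <- sqrt(-2 * (object$labels * log(object$fitted) +
                  (1 - object$labels) * log(1 - object$fitted)))
  sign(r) * d
}

#' Simulate diagnosis labels from the fitted risks
#'
#' Draws Bernoulli labels per sample and biomarker from the fitted risk
#' scores — the model's own generative form.
#'
#' @param object a fitted `"gpnet"` object.
#' @param nsim number of label matrices to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `n x B` 0/1 matrices of length `nsim`.
#' @export
simulate.gpnet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- object$fitted
  lapply(seq_len(nsim), function(i) {
    y <- matrix(stats::rbinom(length(P), 1, P), nrow(P), ncol(P),
                dimnames = dimnames(P))
    y
  })
}

#' Diagnostic plots for a fitted graph propagational network
#'
#' Left: objective trace over epochs. Right: distribution of the trained
#' propagation intensities `phi`.
#'
#' @param x a fitted `"gpnet"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gpnet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "objective",
                 main = "Training objective", ...)
  graphics::hist(x$phi, breaks = 20, xlab = expression(phi),
                 main = "Propagation intensities", col = "grey80")
  invisible(x)
}
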