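#' Logistic risk estimation from synergetic effects
#'
#' Maps the synergetic-effect matrix to per-sample risks through a linear
#' score followed by the logistic function: `P = 1 / (1 + exp(-theta' Z))`.
#' There is no intercept; an optional demographic-covariate term adds
#' `beta' c` to the logit (covariates are never propagated through the graph).
#'
#' @param z `d x n` synergetic-effect matrix (from [propagate()]).
#' @param theta numeric length-`d` estimation parameter vector.
#' @param covariates optional `n x c` numeric matrix of covariates.
#' @param beta optional length-`c` covariate weights; must be supplied
#'   together with `covariates`.
#' @param clip risks are clipped into `[clip, 1 - clip]` so that the
#'   cross-entropy loss stays finite. Default `1e-12`.
#' @return numeric length-`n` vector of risks in `(0, 1)`.
#' @export
estimate_risk <- function(z, theta, covariates = NULL, beta = NULL,
                          clip = 1e-12) {
  z <- as.matrix(z)
  if (length(theta) != nrow(z))
    stop("theta has length ", length(theta), " but z has ", nrow(z), " rows")
  if (is.null(covariates) != is.null(beta))
    stop("covariates and beta must be supplied together")
  eta <- as.vector(crossprod(z, theta))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != ncol(z))
      stop("covariates must have one row per sample (", ncol(z), ")")
    if (ncol(covariates) != length(beta))
      stop("beta must have one entry per covariate column")
    eta <- eta + as.vector(covariates %*% beta)
  }
  p <- stats::plogis(eta)
  pmin(pmax(p, clip), 1 - clip)
}

#' Binary cross-entropy loss
#'
#' `-(1/n) * (Y' log P + (1 - Y)' log(1 - P))`; nonnegative, zero only when
#' the risks match the labels exactly.
#'
#' @param p numeric risk vector with entries strictly inside `(0, 1)`.
#' @param y 0/1 label vector of the same length.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(p, y) {
  if (length(p) != length(y)) stop("p and y must have equal length")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Full training objective: summed cross-entropy plus ridge penalty
#'
#' `sum_b L_b + delta * (||phi||^2 + sum_b ||theta_b||^2)`, with each `L_b`
#' the binary cross-entropy of the biomarker's risks. When covariates are
#' enabled their weights join the ridge term.
#'
#' @param phi positive length-`d` propagation vector.
#' @param theta `d x B` matrix of estimation parameters (one column per
#'   biomarker) or a list of length-`d` vectors.
#' @param x `d x n` independent-effect matrix.
#' @param laplacian `"ppi_laplacian"` or weight matrix.
#' @param labels `n x B` 0/1 matrix (columns aligned with `theta`).
#' @param delta nonnegative ridge weight.
#' @param covariates,beta optional covariate matrix (`n x c`) and `c x B`
#'   weight matrix.
#' @param clip risk clipping bound passed to [estimate_risk()].
#' @return scalar objective value.
#' @export
total_objective <- function(phi, theta, x, laplacian, labels, delta,
                            covariates = NULL, beta = NULL, clip = 1e-12) {
  theta <- as_theta_matrix(theta)
  labels <- as.matrix(labels)
  B <- ncol(theta)
  if (ncol(labels) != B) stop("labels and theta disagree on task count")
  z <- propagate(x, laplacian, phi)
  loss <- 0
  for (b in seq_len(B)) {
    bb <- if (is.null(beta)) NULL else beta[, b]
    p <- estimate_risk(z, theta[, b], covariates, bb, clip = clip)
    loss <- loss + bce_loss(p, labels[, b])
  }
  reg <- sum(phi^2) + sum(theta^2)
  if (!is.null(beta)) reg <- reg + sum(beta^2)
  loss + delta * reg
}

#' Analytic gradient of the objective with respect to theta
#'
#' `(1/n) Z (P - Y) + 2 delta theta`: the data term contracts the synergetic
#' effects against the per-sample residuals.
#'
#' @param z `d x n` synergetic-effect matrix.
#' @param p,y length-`n` risk and 0/1 label vectors for one biomarker.
#' @param theta current length-`d` estimation vector.
#' @param delta ridge weight.
#' @return length-`d` gradient vector.
#' @export
grad_theta <- function(z, p, y, theta, delta) {
  n <- ncol(z)
  as.vector(z %*% (p - y)) / n + 2 * delta * theta
}

#' Analytic gradient of the objective with respect to phi
#'
#' Uses the implicit derivative of the closed-form propagation: with
#' `A = Phi + L`, `dZ/dphi_i = A^{-1} E_ii (X - Z)`, so the data term is
#' `grad_i = row_i(A^{-1} G) . row_i(X - Z)` where
#' `G = (1/n) sum_b theta_b (P_b - Y_b)'` is the loss gradient with respect
#' to `Z`. The ridge term adds `2 delta phi`.
#'
#' @param phi current positive propagation vector.
#' @param laplacian `"ppi_laplacian"` or weight matrix.
#' @param x `d x n` independent effects.
#' @param z current propagation of `x` under `phi` (recomputed if `NULL`).
#' @param theta `d x B` estimation matrix.
#' @param p_mat,y_mat `n x B` risk and label matrices.
#' @param delta ridge weight.
#' @return length-`d` gradient vector.
#' @export
grad_phi <- function(phi, laplacian, x, z, theta, p_mat, y_mat, delta) {
  L <- as_laplacian(laplacian)
  theta <- as_theta_matrix(theta)
  x <- as.matrix(x)
  if (is.null(z)) z <- propagate(x, L, phi)
  n <- ncol(x)
  resid <- as.matrix(p_mat) - as.matrix(y_mat)   # n x B
  G <- theta %*% t(resid) / n                    # d x n
  ch <- propagation_factor(L$matrix, phi)
  M <- chol_solve(ch, G)                         # A^{-1} G
  rowSums(M * (x - z)) + 2 * delta * phi
}

as_theta_matrix <- function(theta) {
  if (is.list(theta)) theta <- do.call(cbind, theta)
  as.matrix(theta)
}
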