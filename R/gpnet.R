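#' Control parameters for fitting a graph propagational network
#'
#' @param optimizer `"adam"` (default, the setting used for the reference
#'   experiments) or `"gd"` for plain full-batch gradient descent.
#' @param eta positive learning rate; default `0.001`.
#' @param delta nonnegative ridge weight on `phi` and every `theta_b`
#'   (and covariate weights when enabled); default `1e-3`.
#' @param max_epochs maximum number of full-batch epochs; default `2000`.
#' @param tol stopping tolerance on the relative change of the objective
#'   between epochs; default `1e-6`.
#' @param theta_init `"zeros"` (default; gives the analytically known
#'   starting loss `B * log 2`) or `"random"` for small seeded normal draws.
#' @param init_sd standard deviation of the random theta initialization.
#' @param phi_min positivity floor: `phi` is projected to `[phi_min, Inf)`
#'   after every update so `(Phi + L)` stays positive definite.
#' @param clip risk clipping bound, see [estimate_risk()].
#' @param seed optional integer seed (only consulted by the random
#'   initialization).
#' @return a list of class `"gpnet_control"`.
#' @export
gpnet_control <- function(optimizer = c("adam", "gd"), eta = 0.001,
                          delta = 1e-3, max_epochs = 2000, tol = 1e-6,
                          theta_init = c("zeros", "random"), init_sd = 0.01,
                          phi_min = 1e-6, clip = 1e-12, seed = NULL) {
  optimizer <- match.arg(optimizer)
  theta_init <- match.arg(theta_init)
  stopifnot(eta > 0, delta >= 0, max_epochs >= 1, tol >= 0, phi_min > 0)
  structure(list(optimizer = optimizer, eta = eta, delta = delta,
                 max_epochs = max_epochs, tol = tol, theta_init = theta_init,
                 init_sd = init_sd, phi_min = phi_min, clip = clip,
                 seed = seed),
            class = "gpnet_control")
}

#' Fit a PPI-aware graph propagational risk model
#'
#' Trains the two-layer model: a single graph-propagation layer turning
#' per-protein expression (independent effects `X`) into interaction-aware
#' synergetic effects `Z = (Phi + L)^{-1} Phi X`, followed by one logistic
#' estimation layer per biomarker, `P_b = logistic(theta_b' Z)`. The
#' per-protein propagation intensities `phi` and all estimation vectors
#' `theta_b` are optimized jointly by full-batch gradient descent (plain or
#' ADAM) on the summed binary cross-entropy plus a ridge penalty, using the
#' analytic gradients of the closed-form solve.
#'
#' Optionally, standardized demographic covariates (age, sex, education)
#' enter each biomarker's logit additively with their own weights; they are
#' never propagated through the graph.
#'
#' @param x `d x n` numeric matrix of preprocessed expression values in
#'   `[0, 1]`, proteins in rows (see [scale_expression()]). Row names are the
#'   protein identifiers, column names the sample identifiers.
#' @param network `d x d` symmetric nonnegative weight matrix with zero
#'   diagonal, rows aligned with `x` (checked by name when both are named).
#' @param labels `n x B` matrix (or data frame) of 0/1 diagnoses, one column
#'   per biomarker; column names name the biomarkers (default task set:
#'   Abeta, GFAP, NfL, pTau).
#' @param covariates optional `n x c` numeric covariate matrix; standardized
#'   internally (centering/scaling constants are stored for prediction).
#' @param control a [gpnet_control()] list.
#' @return An object of class `"gpnet"` with components `phi` (named),
#'   `theta` (`d x B` matrix), `beta` (`c x B` or `NULL`), `loss_trace`,
#'   `fitted` (`n x B` training risks), `network`, `converged`, `epochs`,
#'   and the usual bookkeeping. Supports `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot`.
#' @examples
#' sim <- synth_dataset(d = 12, n = 80, seed = 1)
#' fit <- gpnet(sim$x, sim$network, sim$labels,
#'              control = gpnet_control(max_epochs = 50))
#' fit
#' head(predict(fit))
#' @export
gpnet <- function(x, network, labels, covariates = NULL,
                  control = gpnet_control()) {
  cl <- match.call()
  x <- as.matrix(x)
  W <- as_weight_matrix(network)
  labels <- as.matrix(labels)
  if (is.null(colnames(labels)))
    colnames(labels) <- paste0("task", seq_len(ncol(labels)))
  d <- nrow(x); n <- ncol(x); B <- ncol(labels)
  if (nrow(W) != d)
    stop("network has ", nrow(W), " proteins but x has ", d, " rows")
  if (!is.null(rownames(x)) && !is.null(rownames(W)) &&
      !identical(rownames(x), rownames(W)))
    stop("protein identifiers of x and network disagree")
  if (nrow(labels) != n)
    stop("labels must have one row per sample (", n, ")")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(is.na(x))) stop("x contains missing values; impute first")

  cov_center <- cov_scale <- NULL
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariates must have one row per sample")
    cov_center <- colMeans(C)
    cov_scale <- apply(C, 2, stats::sd)
    cov_scale[cov_scale == 0] <- 1
    C <- scale(C, center = cov_center, scale = cov_scale)
  }

  L <- normalized_laplacian(W)
  delta <- control$delta
  eta <- control$eta

  phi <- rep(1, d)
  theta <- matrix(0, d, B, dimnames = list(rownames(x), colnames(labels)))
  if (control$theta_init == "random") {
    if (!is.null(control$seed)) set.seed(control$seed)
    theta[] <- stats::rnorm(d * B, sd = control$init_sd)
  }
  beta <- if (is.null(C)) NULL else
    matrix(0, ncol(C), B, dimnames = list(colnames(C), colnames(labels)))

  pack <- function() c(phi, theta, beta)
  npar <- length(pack())
  adam_m <- adam_v <- numeric(npar)
  adam_t <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  loss_trace <- numeric(control$max_epochs)
  prev_loss <- Inf
  epochs <- 0L
  converged <- FALSE

  for (epoch in seq_len(control$max_epochs)) {
    ch <- propagation_factor(L$matrix, phi)
    z <- chol_solve(ch, phi * x)
    P <- matrix(0, n, B)
    loss <- 0
    for (b in seq_len(B)) {
      bb <- if (is.null(beta)) NULL else beta[, b]
      P[, b] <- estimate_risk(z, theta[, b], C, bb, clip = control$clip)
      loss <- loss + bce_loss(P[, b], labels[, b])
    }
    reg <- sum(phi^2) + sum(theta^2) + if (is.null(beta)) 0 else sum(beta^2)
    loss <- loss + delta * reg
    if (!is.finite(loss))
      stop("training diverged (non-finite loss); try a smaller eta")
    loss_trace[epoch] <- loss
    epochs <- epoch

    if (is.finite(prev_loss) &&
        abs(prev_loss - loss) <= control$tol * max(1, abs(prev_loss))) {
      converged <- TRUE
      break
    }
    prev_loss <- loss

    resid <- P - labels                                  # n x B
    g_theta <- z %*% resid / n + 2 * delta * theta       # d x B
    G <- theta %*% t(resid) / n                          # d x n
    M <- chol_solve(ch, G)
    g_phi <- rowSums(M * (x - z)) + 2 * delta * phi
    g_beta <- if (is.null(beta)) NULL else
      crossprod(C, resid) / n + 2 * delta * beta

    g <- c(g_phi, g_theta, g_beta)
    if (control$optimizer == "adam") {
      adam_t <- adam_t + 1L
      adam_m <- b1 * adam_m + (1 - b1) * g
      adam_v <- b2 * adam_v + (1 - b2) * g^2
      mhat <- adam_m / (1 - b1^adam_t)
      vhat <- adam_v / (1 - b2^adam_t)
      step <- eta * mhat / (sqrt(vhat) + eps)
    } else {
      step <- eta * g
    }

    phi <- phi - step[seq_len(d)]
    theta[] <- theta - step[d + seq_len(d * B)]
    if (!is.null(beta))
      beta[] <- beta - step[(d + d * B + 1):npar]
    phi <- pmax(phi, control$phi_min)                    # positivity projection
  }

  # final feedforward with the trained parameters
  z <- propagate(x, L, phi)
  P <- matrix(0, n, B, dimnames = list(colnames(x), colnames(labels)))
  for (b in seq_len(B)) {
    bb <- if (is.null(beta)) NULL else beta[, b]
    P[, b] <- estimate_risk(z, theta[, b], C, bb, clip = control$clip)
  }

  names(phi) <- rownames(x)
  structure(list(
    phi = phi, theta = theta, beta = beta,
    covariate_center = cov_center, covariate_scale = cov_scale,
    biomarkers = colnames(labels), protein_ids = rownames(x),
    sample_ids = colnames(x),
    network = W, delta = delta,
    loss_trace = loss_trace[seq_len(epochs)],
    epochs = epochs, converged = converged,
    fitted = P, synergy = z, labels = labels,
    control = control, call = cl
  ), class = "gpnet")
}
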