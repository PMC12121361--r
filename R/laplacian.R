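#' Symmetric normalized graph Laplacian of a PPI weight matrix
#'
#' Computes `L = I - D^{-1/2} W D^{-1/2}` where `D` is the diagonal degree
#' matrix with `D_ii = sum_k W_ik`. Isolated nodes (zero degree) contribute an
#' identity row/column, so `L` is always well defined, symmetric and positive
#' semidefinite with eigenvalues in `[0, 2]`.
#'
#' @param network a `d x d` symmetric, nonnegative weight matrix with zero
#'   diagonal and entries in `[0, 1]`, as produced by [build_network()] or
#'   [synth_network()]. Row names, if present, identify the proteins.
#' @return An object of class `"ppi_laplacian"`: a list with components
#'   `matrix` (the `d x d` Laplacian), `degree` (row sums of `W`) and
#'   `protein_ids`.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.7
#' L <- normalized_laplacian(W)
#' eigen(L$matrix, symmetric = TRUE, only.values = TRUE)$values
#' @export
normalized_laplacian <- function(network) {
  W <- as_weight_matrix(network)
  validate_network(W)
  d <- nrow(W)
  deg <- rowSums(W)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  S <- W * tcrossprod(inv_sqrt)           # D^{-1/2} W D^{-1/2}
  L <- diag(d) - S
  # exact symmetry regardless of floating-point summation order
  L <- (L + t(L)) / 2
  structure(
    list(matrix = L, degree = deg, protein_ids = rownames(W)),
    class = "ppi_laplacian"
  )
}

#' @export
print.ppi_laplacian <- function(x, ...) {
  cat("Normalized graph Laplacian:", nrow(x$matrix), "proteins,",
      sum(x$degree > 0), "connected\n")
  invisible(x)
}

#' Graph propagation of independent effects into synergetic effects
#'
#' Solves the Laplacian-regularized smoothing problem
#' `min_Z tr(Z' L Z) + (Z - X)' Phi (Z - X)` in closed form:
#' `Z = (Phi + L)^{-1} Phi X`, where `Phi = diag(phi)` holds the per-protein
#' propagation intensities. Each sample column is propagated independently;
#' one Cholesky factorization of `(Phi + L)` is reused for all columns.
#'
#' @param x `d x n` matrix of (preprocessed) expression values, proteins in
#'   rows.
#' @param laplacian a `"ppi_laplacian"` object from [normalized_laplacian()],
#'   or a raw network weight matrix (converted internally).
#' @param phi strictly positive numeric vector of length `d`.
#' @return `d x n` matrix `Z` of synergetic effects, same dimnames as `x`.
#' @examples
#' W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.5
#' L <- normalized_laplacian(W)
#' propagate(matrix(c(1, 0), 2, 1), L, phi = c(1, 1))  # (2/3, 1/3)
#' @export
propagate <- function(x, laplacian, phi) {
  L <- as_laplacian(laplacian)
  x <- as.matrix(x)
  d <- nrow(L$matrix)
  if (nrow(x) != d)
    stop("x has ", nrow(x), " rows but the network has ", d, " proteins")
  if (length(phi) != d)
    stop("phi must have length ", d)
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("phi must be strictly positive; project small values to >= 1e-6")
  ch <- propagation_factor(L$matrix, phi)
  z <- chol_solve(ch, phi * x)
  dimnames(z) <- dimnames(x)
  z
}

# Cholesky factor of (Phi + L); shared by propagate() and grad_phi()
propagation_factor <- function(Lmat, phi) {
  A <- Lmat
  diag(A) <- diag(A) + phi
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    stop("(Phi + L) is numerically singular; ensure phi >= 1e-6 everywhere")
  ch
}

chol_solve <- function(ch, b) {
  backsolve(ch, backsolve(ch, as.matrix(b), transpose = TRUE))
}

as_laplacian <- function(laplacian) {
  if (inherits(laplacian, "ppi_laplacian")) return(laplacian)
  normalized_laplacian(laplacian)
}

as_weight_matrix <- function(network) {
  if (inherits(network, "ppi_laplacian"))
    stop("expected a weight matrix, not a Laplacian")
  as.matrix(network)
}

validate_network <- function(W) {
  if (nrow(W) != ncol(W)) stop("network weight matrix must be square")
  bad <- which(abs(W - t(W)) > 1e-10, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("network weights not symmetric at entry (", bad[1, 1], ", ",
         bad[1, 2], ")")
  neg <- which(W < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative network weight at entry (", neg[1, 1], ", ", neg[1, 2], ")")
  if (any(W > 1 + 1e-10))
    stop("network weights must lie in [0, 1]")
  if (any(diag(W) != 0))
    stop("network weight matrix must have a zero diagonal")
  invisible(W)
}
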