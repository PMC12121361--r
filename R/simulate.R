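#' Random weighted PPI network
#'
#' Draws a random graph at the requested edge density with independent
#' uniform weights in `(0, 1)`. `"erdos-renyi"` places edges uniformly;
#' `"planted-modules"` partitions the proteins into modules and makes
#' within-module edges five times likelier than between-module edges while
#' keeping the expected overall density, mimicking the modular, hierarchical
#' structure of real interaction networks.
#'
#' @param d number of proteins.
#' @param density expected edge density in `(0, 1]`; default `0.0547`, the
#'   density scale of a sparse STRING-derived target-protein network.
#' @param model `"erdos-renyi"` (default) or `"planted-modules"`.
#' @param n_modules module count for the planted-modules model; default `4`.
#' @param protein_ids optional identifiers (default `P001...`).
#' @param seed optional integer seed.
#' @return list: `weights` (`d x d` matrix) and `edge_list` (data frame
#'   `protein_a`, `protein_b`, `combined_score` with the weights serving as
#'   STRING-style combined scores).
#' @export
synth_network <- function(d, density = 0.0547,
                          model = c("erdos-renyi", "planted-modules"),
                          n_modules = 4, protein_ids = NULL, seed = NULL) {
  model <- match.arg(model)
  stopifnot(d >= 2, density > 0, density <= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- protein_ids %||% sprintf("P%03d", seq_len(d))
  W <- matrix(0, d, d, dimnames = list(ids, ids))
  ut <- which(upper.tri(W))
  if (model == "erdos-renyi") {
    p_edge <- rep(density, length(ut))
  } else {
    module <- rep_len(seq_len(n_modules), d)
    same <- outer(module, module, "==")[upper.tri(W)]
    f_within <- mean(same)
    # within-module edges 5x likelier, expected density preserved
    p_out <- density / (5 * f_within + (1 - f_within))
    p_edge <- ifelse(same, pmin(1, 5 * p_out), p_out)
  }
  has_edge <- stats::runif(length(ut)) < p_edge
  w <- stats::runif(sum(has_edge))
  W[ut[has_edge]] <- w
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edge_list <- data.frame(protein_a = ids[idx[, 1]], protein_b = ids[idx[, 2]],
                          combined_score = W[upper.tri(W) & W > 0],
                          stringsAsFactors = FALSE)
  list(weights = W, edge_list = edge_list)
}

#' Synthetic expression/label dataset from the model's own generative form
#'
#' Draws bounded expression values `X ~ U(0, 1)`, propagates them over a
#' random network with the planted intensities
#' (`Z = (Phi + L)^{-1} Phi X`), and samples diagnosis labels
#' `Y_b ~ Bernoulli(logistic(theta_b' Z))`. Planted effect vectors are
#' orthogonalized against the mean synergy profile so positivity is balanced
#' (there is no intercept in the model). Optionally punches missing entries
#' into an unbounded "raw" version of the matrix so the preprocessing stage
#' can be exercised end to end.
#'
#' @param d proteins; default `113` (the target-protein scale of the
#'   motivating cohort).
#' @param n samples; default `906` (the cohort size).
#' @param density network density; default `0.0547`.
#' @param graph_model passed to [synth_network()].
#' @param biomarkers task names; default `c("Abeta", "GFAP", "NfL", "pTau")`.
#' @param phi planted propagation intensities; default log-normal draws with
#'   median about 1.1 (matching intensities averaging near 1.25 with
#'   occasional values above 3 seen in fitted models).
#' @param theta planted `d x B` effect matrix; default normal draws with sd
#'   `signal`, orthogonalized against the mean synergy.
#' @param signal sd of the planted effects; default `1`.
#' @param missing_rate fraction of raw entries set missing; default `0.02`.
#' @param seed optional integer seed fixing everything.
#' @return list: `x` (`d x n`, in `(0, 1)`), `x_raw` (unbounded, with `NA`s),
#'   `network`, `edge_list`, `labels` (`n x B`), and `truth` with the planted
#'   `phi`, `theta`, the synergy `z`, per-task `logits` and the oracle AUROC
#'   attainable from the true logits.
#' @export
synth_dataset <- function(d = 113, n = 906, density = 0.0547,
                          graph_model = "erdos-renyi",
                          biomarkers = c("Abeta", "GFAP", "NfL", "pTau"),
                          phi = NULL, theta = NULL, signal = 1,
                          missing_rate = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  net <- synth_network(d, density, model = graph_model)
  ids <- rownames(net$weights)
  sample_ids <- sprintf("S%04d", seq_len(n))
  x <- matrix(stats::runif(d * n), d, n, dimnames = list(ids, sample_ids))
  if (is.null(phi)) phi <- stats::rlnorm(d, meanlog = log(1.1), sdlog = 0.4)
  L <- normalized_laplacian(net$weights)
  z <- propagate(x, L, phi)
  B <- length(biomarkers)
  m <- rowMeans(z)
  if (is.null(theta)) {
    theta <- matrix(stats::rnorm(d * B, sd = signal), d, B)
    # remove the component along the mean synergy: balanced positivity
    theta <- theta - m %*% crossprod(m, theta) / sum(m^2)
  }
  theta <- as.matrix(theta)
  dimnames(theta) <- list(ids, biomarkers)
  logits <- crossprod(z, theta)                 # n x B
  labels <- matrix(stats::rbinom(n * B, 1, stats::plogis(logits)), n, B,
                   dimnames = list(sample_ids, biomarkers))
  oracle <- vapply(seq_len(B), function(b) {
    if (length(unique(labels[, b])) < 2) return(NA_real_)
    auroc(logits[, b], labels[, b])
  }, numeric(1))
  names(oracle) <- biomarkers

  # unbounded "raw" values whose per-row z-score + logistic scaling is X
  x_raw <- stats::qlogis(x) * 2 + 10
  if (missing_rate > 0) {
    miss <- stats::runif(d * n) < missing_rate
    x_raw[miss] <- NA
  }
  list(x = x, x_raw = x_raw, network = net$weights,
       edge_list = net$edge_list, labels = labels,
       truth = list(phi = stats::setNames(phi, ids), theta = theta, z = z,
                    logits = logits, oracle_auroc = oracle))
}
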