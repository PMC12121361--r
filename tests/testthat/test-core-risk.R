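test_that("logistic risk estimation follows the zero, ln3 and symmetry identities", {
  inst <- tiny_instance(seed = 1)
  z <- propagate(inst$x, inst$W, inst$phi)
  n <- ncol(z)

  expect_equal(estimate_risk(z, rep(0, 8)), rep(0.5, n))

  # a column whose linear score is ln 3 must score 0.75
  z1 <- matrix(c(log(3), rep(0, 7)), 8, 1)
  expect_equal(estimate_risk(z1, c(1, rep(0, 7))), 0.75)

  th <- rnorm(8)
  expect_equal(estimate_risk(z, -th), 1 - estimate_risk(z, th))
})

test_that("risk estimation validates covariate wiring and clips", {
  z <- matrix(rnorm(12), 3, 4)
  expect_error(estimate_risk(z, rnorm(2)), "length")
  expect_error(estimate_risk(z, rnorm(3), covariates = matrix(1, 4, 1)),
               "together")
  C <- matrix(rnorm(8), 4, 2)
  beta <- c(0.5, -1)
  p <- estimate_risk(z, rep(0, 3), C, beta)
  expect_equal(p, plogis(drop(C %*% beta)))
  # extreme logits are clipped strictly inside (0, 1)
  p2 <- estimate_risk(matrix(1e4, 1, 1), 1)
  expect_lt(p2, 1)
  expect_equal(p2, 1 - 1e-12)
})

test_that("binary cross-entropy matches scalar log arithmetic and its bounds", {
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2))
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -log(0.9))
  expect_error(bce_loss(c(0.5, 0.5), c(1, 2)), "0/1")
  set.seed(1)
  for (i in 1:10) {
    y <- rbinom(6, 1, 0.5)
    p <- runif(6, 0.01, 0.99)
    expect_gte(bce_loss(p, y), 0)
  }
  # loss -> 0 as P -> Y
  y <- c(1, 0, 1)
  expect_lt(bce_loss(ifelse(y == 1, 1 - 1e-9, 1e-9), y), 1e-8)
})

test_that("total objective equals a from-scratch recomputation", {
  inst <- tiny_instance(seed = 7)
  L <- normalized_laplacian(inst$W)
  delta <- 0.05
  obj <- total_objective(inst$phi, inst$theta, inst$x, L, inst$y, delta)

  # independent recomputation: explicit solve, explicit logistic, explicit sums
  A <- diag(inst$phi) + L$matrix
  z <- solve(A, inst$phi * inst$x)
  ref <- 0
  for (b in 1:2) {
    eta <- as.vector(t(z) %*% inst$theta[, b])
    p <- 1 / (1 + exp(-eta))
    y <- inst$y[, b]
    ref <- ref - mean(y * log(p) + (1 - y) * log(1 - p))
  }
  ref <- ref + delta * (sum(inst$phi^2) + sum(inst$theta^2))
  expect_equal(obj, ref, tolerance = 1e-12)

  # zero-theta start: sum of uninformative losses plus phi penalty
  expect_equal(total_objective(inst$phi, matrix(0, 8, 4), inst$x, L,
                               cbind(inst$y, inst$y), 0),
               4 * log(2))
  expect_equal(total_objective(c(1, 1), matrix(0, 2, 1),
                               matrix(0.5, 2, 2), matrix(0, 2, 2),
                               matrix(c(0, 1), 2, 1), 0.5),
               log(2) + 1.0)
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:5) {
    inst <- tiny_instance(d = 8, n = 12, n_tasks = 2, seed = seed)
    L <- normalized_laplacian(inst$W)
    delta <- 1e-3
    z <- propagate(inst$x, L, inst$phi)
    P <- vapply(1:2, function(b) estimate_risk(z, inst$theta[, b]),
                numeric(12))

    g_phi <- grad_phi(inst$phi, L, inst$x, z, inst$theta, P, inst$y, delta)
    fd_phi <- finite_diff(function(ph)
      total_objective(ph, inst$theta, inst$x, L, inst$y, delta), inst$phi)
    expect_lt(max(abs(g_phi - fd_phi)) / max(abs(fd_phi)), 1e-5)

    g_th <- grad_theta(z, P[, 1], inst$y[, 1], inst$theta[, 1], delta)
    fd_th <- finite_diff(function(th) {
      theta2 <- inst$theta; theta2[, 1] <- th
      total_objective(inst$phi, theta2, inst$x, L, inst$y, delta)
    }, inst$theta[, 1])
    expect_lt(max(abs(g_th - fd_th)) / max(abs(fd_th)), 1e-5)
  }
})

test_that("gradients collapse to the ridge term when the data term vanishes", {
  inst <- tiny_instance(seed = 2)
  L <- normalized_laplacian(inst$W)
  delta <- 0.3
  # zero synergy: theta gradient is pure ridge
  th <- rnorm(8)
  expect_equal(grad_theta(matrix(0, 8, 12), rep(0.5, 12), inst$y[, 1],
                          th, delta),
               2 * delta * th)
  # zero theta: P = 0.5, G = 0, phi gradient is pure ridge
  z <- propagate(inst$x, L, inst$phi)
  P <- matrix(0.5, 12, 2)
  g <- grad_phi(inst$phi, L, inst$x, z, matrix(0, 8, 2), P, inst$y, delta)
  expect_equal(g, 2 * delta * inst$phi, ignore_attr = TRUE)
  # delta = 0, theta = 0: theta gradient is (1/n) Z (0.5 - Y)
  g0 <- grad_theta(z, rep(0.5, 12), inst$y[, 1], rep(0, 8), 0)
  expect_equal(g0, as.vector(z %*% (0.5 - inst$y[, 1])) / 12)
})

test_that("edgeless phi gradient matches the scalar calculus oracle", {
  # with L = I the solve is diagonal: z_ij = phi_i x_ij / (1 + phi_i),
  # so dz_ij/dphi_i = x_ij / (1 + phi_i)^2 and the chain rule is scalar
  d <- 5; n <- 9
  set.seed(3)
  x <- matrix(runif(d * n), d, n)
  phi <- runif(d, 0.3, 2)
  theta <- matrix(rnorm(d), d, 1)
  y <- matrix(rbinom(n, 1, 0.5), n, 1); y[1] <- 1; y[2] <- 0
  W0 <- matrix(0, d, d)
  z <- propagate(x, W0, phi)
  p <- estimate_risk(z, theta[, 1])
  delta <- 0.01
  g <- grad_phi(phi, W0, x, z, theta, matrix(p, n, 1), y, delta)
  dz <- x / (1 + phi)^2
  oracle <- as.vector((theta[, 1] * dz) %*% (p - y[, 1])) / n + 2 * delta * phi
  expect_equal(g, oracle, tolerance = 1e-10)
})

test_that("covariate-extended gradients also pass finite differences", {
  inst <- tiny_instance(seed = 9)
  C <- matrix(rnorm(12 * 2), 12, 2)
  beta <- matrix(rnorm(4) * 0.3, 2, 2)
  L <- normalized_laplacian(inst$W)
  delta <- 1e-3
  f <- function(ph) total_objective(ph, inst$theta, inst$x, L, inst$y, delta,
                                    covariates = C, beta = beta)
  z <- propagate(inst$x, L, inst$phi)
  P <- vapply(1:2, function(b)
    estimate_risk(z, inst$theta[, b], C, beta[, b]), numeric(12))
  g <- grad_phi(inst$phi, L, inst$x, z, inst$theta, P, inst$y, delta)
  expect_lt(max(abs(g - finite_diff(f, inst$phi))) /
              max(abs(finite_diff(f, inst$phi))), 1e-5)
})
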