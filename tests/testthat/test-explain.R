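fit_small <- function(seed = 1, d = 12, n = 120, signal = 1.5) {
  sim <- synth_dataset(d = d, n = n, density = 0.25, seed = seed,
                       signal = signal, missing_rate = 0)
  fit <- gpnet(sim$x, sim$network, sim$labels,
               control = gpnet_control(max_epochs = 150, eta = 0.05))
  list(sim = sim, fit = fit)
}

test_that("leave-one-out importance is zero for proteins with no effect path", {
  fs <- fit_small(seed = 1)
  fit <- fs$fit
  # force one protein's estimation parameters to zero across all biomarkers
  fit$theta[3, ] <- 0
  imp <- loo_importance(fit)
  expect_equal(imp$delta_auroc[3], 0)
  expect_equal(attr(imp, "baseline"),
               mean(sapply(seq_along(fit$biomarkers), function(b)
                 auroc(estimate_risk(fit$synergy, fit$theta[, b]),
                       fit$labels[, b]))))
})

test_that("a dominant planted protein gets the top importance", {
  set.seed(2)
  d <- 10; n <- 400
  net <- synth_network(d, density = 0.25, seed = 3)
  x <- matrix(runif(d * n), d, n, dimnames = list(rownames(net$weights), NULL))
  phi <- rep(1, d)
  z <- propagate(x, net$weights, phi)
  theta <- matrix(0, d, 2); theta[5, ] <- 6      # single dominant protein
  labels <- matrix(rbinom(n * 2, 1,
                          plogis(crossprod(z, theta) - mean(z[5, ]) * 6)),
                   n, 2, dimnames = list(NULL, c("A", "B")))
  fit <- gpnet(x, net$weights, labels,
               control = gpnet_control(max_epochs = 300, eta = 0.05))
  imp <- loo_importance(fit)
  expect_equal(which.max(imp$delta_auroc), 5)
})

test_that("excluding every protein collapses the scores to 0.5", {
  fs <- fit_small(seed = 4)
  z0 <- fs$fit$synergy; z0[] <- 0
  p <- estimate_risk(z0, fs$fit$theta[, 1])
  expect_true(all(p == 0.5))
  expect_error(auroc(p, fs$fit$labels[, 1]), NA)
  expect_equal(auroc(p, fs$fit$labels[, 1]), 0.5)
})

test_that("the re-propagation variant also runs and keeps alignment", {
  fs <- fit_small(seed = 5, d = 8, n = 60)
  imp <- loo_importance(fs$fit, x = fs$sim$x, repropagate = TRUE)
  expect_equal(nrow(imp), 8)
  expect_true(all(is.finite(imp$delta_auroc)))
})

test_that("major proteins intersect the top-decile rankings deterministically", {
  # d = 20: top-2 sets sharing exactly one protein
  ids <- sprintf("P%02d", 1:20)
  theta <- setNames(rep(0, 20), ids)
  theta[c("P01", "P02")] <- c(5, 4)
  imp <- setNames(rep(0, 20), ids)
  imp[c("P02", "P03")] <- c(5, 4)
  expect_equal(major_proteins(theta, imp, top_frac = 0.10), "P02")

  # identical rankings: the full top set
  v <- setNames(20:1, ids)
  expect_equal(major_proteins(v, v, 0.10), ids[1:2])

  # disjoint tops: empty
  a <- setNames(c(rep(1, 2), rep(0, 18)), ids)
  b <- setNames(c(rep(0, 18), rep(1, 2)), ids)
  expect_length(major_proteins(a, b, 0.10), 0)

  # invariant to positive rescaling of the importance scores
  set.seed(6)
  th <- setNames(rnorm(20), ids); im <- setNames(runif(20), ids)
  expect_equal(major_proteins(th, im, 0.2),
               major_proteins(th, 13.7 * im, 0.2))
})

test_that("subset risks reproduce predict and add on the logit scale", {
  fs <- fit_small(seed = 7, d = 9, n = 50)
  fit <- fs$fit
  ids <- fit$protein_ids
  full <- subset_risk(fit, ids)
  expect_equal(full, fit$fitted)

  empty <- subset_risk(fit, character(0))
  expect_true(all(empty == 0.5))

  # disjoint subsets: logits add to the full logit
  s1 <- ids[1:4]; s2 <- ids[5:9]
  l1 <- qlogis(subset_risk(fit, s1))
  l2 <- qlogis(subset_risk(fit, s2))
  expect_equal(l1 + l2, qlogis(full), tolerance = 1e-9)

  # hand computation on a 3-protein restriction
  s3 <- ids[c(2, 5, 8)]
  keep <- ids %in% s3
  manual <- plogis(as.vector(crossprod(fit$synergy, fit$theta[, 1] * keep)))
  expect_equal(unname(subset_risk(fit, s3)[, 1]), manual)

  expect_error(subset_risk(fit, "NOPE"), "unknown")
})

test_that("effect significance mirrors the Welch test on either effect matrix", {
  fs <- fit_small(seed = 8, d = 8, n = 80)
  y <- fs$fit$labels[, 1]
  sx <- effect_significance(fs$sim$x, y)
  sz <- effect_significance(fs$fit$synergy, y)
  expect_equal(effect_significance(fs$sim$x, y), sx)   # Z = X gives identical
  expect_equal(sx$neg_log10_p, -log10(sx$p_value))
  expect_equal(nrow(sz), 8)
})

test_that("the protein report assembles all explainability outputs", {
  fs <- fit_small(seed = 9, d = 10, n = 60)
  rep <- protein_report(fs$fit)
  expect_equal(nrow(rep), 10)
  expect_true(all(c("phi", "delta_auroc") %in% names(rep)))
  expect_true(all(paste0("theta_", fs$fit$biomarkers) %in% names(rep)))
  for (b in fs$fit$biomarkers) {
    flag <- rep[[paste0("major_", b)]]
    expect_lte(sum(flag), ceiling(0.1 * 10))
  }
})
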