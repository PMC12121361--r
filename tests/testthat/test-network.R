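test_that("network construction thresholds strictly and rescales weights", {
  ids <- c("A", "B", "C", "D")
  edges <- data.frame(protein_a = c("A", "A", "B"),
                      protein_b = c("B", "C", "C"),
                      combined_score = c(0.3, 0.4, 0.41))
  W <- build_network(edges, ids)
  # only the 0.41 edge survives the strict > 0.4 rule; single edge -> 0.5
  expect_equal(sum(W > 0) / 2, 1)
  expect_equal(W["B", "C"], 0.5)
  expect_equal(W["C", "B"], 0.5)
  expect_equal(diag(W), setNames(rep(0, 4), ids))

  # an edge whose score equals the mean of kept scores gets weight 0.5
  edges2 <- data.frame(protein_a = c("A", "A", "B"),
                       protein_b = c("B", "C", "D"),
                       combined_score = c(0.5, 0.6, 0.7))
  W2 <- build_network(edges2, ids)
  expect_equal(W2["A", "C"], 0.5)       # 0.6 is the mean of kept scores
  expect_true(W2["A", "B"] < 0.5 && W2["B", "D"] > 0.5)
  expect_equal(W2, t(W2))

  # duplicates collapse to the maximum score; foreign endpoints are dropped
  edges3 <- data.frame(protein_a = c("A", "B", "A", "X"),
                       protein_b = c("B", "A", "B", "A"),
                       combined_score = c(0.45, 0.8, 0.5, 0.9))
  expect_message(W3 <- build_network(edges3, ids), "dropped")
  expect_equal(sum(W3 > 0) / 2, 1)

  # nothing retained: warning and an empty network
  expect_warning(W0 <- build_network(
    data.frame(protein_a = "A", protein_b = "B", combined_score = 0.2),
    ids), "empty")
  expect_true(all(W0 == 0))
})

test_that("network statistics reproduce the printed density and degree", {
  # build any graph with 93 connected nodes and 234 edges
  set.seed(1)
  d <- 113
  ids <- sprintf("P%03d", 1:d)
  W <- matrix(0, d, d, dimnames = list(ids, ids))
  # ring over the first 93 nodes (93 edges) plus 141 extra random edges
  for (i in 1:93) {
    j <- if (i == 93) 1 else i + 1
    W[i, j] <- W[j, i] <- 0.5
  }
  added <- 0
  while (added < 141) {
    ij <- sample(93, 2)
    if (W[ij[1], ij[2]] == 0) {
      W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- 0.5
      added <- added + 1
    }
  }
  st <- network_stats(W)
  expect_equal(st$n_nodes_connected, 93)
  expect_equal(st$n_edges, 234)
  expect_equal(round(st$density_connected_pct, 2), 5.47)
  expect_equal(round(st$mean_degree_connected, 2), 5.03)

  # complete graph on 5 nodes: density 100%, mean degree 4
  K5 <- matrix(0.8, 5, 5); diag(K5) <- 0
  st5 <- network_stats(K5)
  expect_equal(st5$density_connected_pct, 100)
  expect_equal(st5$mean_degree_connected, 4)

  # edgeless network
  st0 <- network_stats(matrix(0, 4, 4))
  expect_equal(st0$n_nodes_connected, 0)
  expect_equal(st0$n_edges, 0)
  expect_true(is.na(st0$density_connected_pct))
})

test_that("edge subsampling is exact in count, seeded and monotone", {
  set.seed(2)
  inst <- tiny_instance(d = 25, n = 2, density = 0.4, seed = 2)
  E <- sum(inst$W > 0) / 2
  expect_identical(subsample_edges(inst$W, 1.0), inst$W)
  half <- subsample_edges(inst$W, 0.5, seed = 1)
  expect_equal(sum(half > 0) / 2, round(0.5 * E))
  expect_identical(subsample_edges(inst$W, 0.5, seed = 3),
                   subsample_edges(inst$W, 0.5, seed = 3))
  # kept edges retain their original weights and symmetry
  expect_true(all(half[half > 0] == inst$W[half > 0]))
  expect_equal(half, t(half))
  # monotone counts in the fraction
  for (f in c(0.2, 0.4, 0.8))
    expect_lte(sum(subsample_edges(inst$W, f, seed = 5) > 0),
               sum(subsample_edges(inst$W, f + 0.2, seed = 5) > 0))
})

test_that("each edge's inclusion frequency tracks the fraction", {
  inst <- tiny_instance(d = 12, n = 2, density = 0.5, seed = 3)
  idx <- which(upper.tri(inst$W) & inst$W > 0)
  counts <- numeric(length(idx))
  n_draw <- 200
  for (s in seq_len(n_draw)) {
    sub <- subsample_edges(inst$W, 0.4, seed = s)
    counts <- counts + (sub[idx] > 0)
  }
  freq <- counts / n_draw
  # actual kept fraction is round(0.4 E)/E; allow 4 binomial sds
  f_true <- round(0.4 * length(idx)) / length(idx)
  tol <- 4 * sqrt(f_true * (1 - f_true) / n_draw)
  expect_true(all(abs(freq - f_true) < tol))
})

test_that("highlighting sets chosen edges to one, idempotently", {
  inst <- tiny_instance(d = 10, n = 2, density = 0.5, seed = 4)
  W <- inst$W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)[1:3, ]
  sub <- data.frame(protein_a = rownames(W)[idx[, 1]],
                    protein_b = rownames(W)[idx[, 2]])
  H <- highlight_edges(W, sub)
  changed <- which(H != W)
  expect_length(changed, 6)             # 3 edges, both triangles
  expect_true(all(H[changed] == 1))
  expect_equal(highlight_edges(H, sub), H, ignore_attr = TRUE)
  expect_identical(highlight_edges(W, sub[0, ]), W)

  # unknown pairs go to the rejects report, not an error
  bad <- rbind(sub, data.frame(protein_a = "P01", protein_b = "NOPE"))
  expect_message(H2 <- highlight_edges(W, bad), "not found")
  expect_equal(nrow(attr(H2, "rejects")), 1)
})
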