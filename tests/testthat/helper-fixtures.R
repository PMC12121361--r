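# Small in-code fixtures shared across the suite.

# tiny random instance: bounded expression, sparse weighted graph, labels
tiny_instance <- function(d = 8, n = 12, n_tasks = 2, density = 0.3,
                          seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(d))
  W <- matrix(0, d, d, dimnames = list(ids, ids))
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < density
  W[ut[on]] <- runif(sum(on))
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  x <- matrix(runif(d * n), d, n,
              dimnames = list(ids, sprintf("S%02d", seq_len(n))))
  y <- matrix(rbinom(n * n_tasks, 1, 0.5), n, n_tasks,
              dimnames = list(colnames(x), paste0("task", seq_len(n_tasks))))
  # guarantee both classes per task
  for (b in seq_len(n_tasks)) {
    if (sum(y[, b]) == 0) y[1, b] <- 1
    if (sum(y[, b]) == n) y[1, b] <- 0
  }
  phi <- runif(d, 0.5, 2)
  theta <- matrix(rnorm(d * n_tasks), d, n_tasks)
  list(x = x, W = W, y = y, phi = phi, theta = theta, ids = ids)
}

# central finite differences of a scalar function, step h
finite_diff <- function(f, at, h = 1e-6) {
  vapply(seq_along(at), function(i) {
    e <- numeric(length(at)); e[i] <- h
    (f(at + e) - f(at - e)) / (2 * h)
  }, numeric(1))
}

# brute-force AUROC: explicit pair counting
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force average precision by explicit threshold enumeration
threshold_auprc <- function(scores, labels) {
  npos <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
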