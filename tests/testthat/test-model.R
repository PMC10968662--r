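# Learning core: adjacency normalization, GCN layer, attention, CRF
# layer and energy, losses, training and prediction.

test_that("normalized adjacency matches the hand-computed small cases", {
  # single isolated node: self-loop only
  A1 <- Matrix::Matrix(0, 1, 1, sparse = TRUE)
  expect_equal(as.matrix(normalize_adjacency(A1)), matrix(1), tolerance = 1e-15)
  # two nodes, one edge: D~ = diag(2, 2)
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(as.matrix(normalize_adjacency(A2)),
               matrix(0.5, 2, 2), tolerance = 1e-15)
  # path a-b-c: D~ = diag(2, 3, 2) so the a-b entry is 1/sqrt(6)
  A3 <- matrix(0, 3, 3); A3[1, 2] <- A3[2, 1] <- 1; A3[2, 3] <- A3[3, 2] <- 1
  expect_equal(as.matrix(normalize_adjacency(A3))[1, 2], 1 / sqrt(6),
               tolerance = 1e-12)
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(normalize_adjacency(diag(2)), "zero diagonal")
})

test_that("normalization and the GCN layer agree with dense linear algebra", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(4:20, 1)
    A <- random_adjacency(n)
    # dense oracle computed with plain base R
    At <- A + diag(n)
    Dm <- diag(1 / sqrt(rowSums(At)))
    Ahat_dense <- Dm %*% At %*% Dm
    Ahat <- normalize_adjacency(A)
    expect_lt(max(abs(as.matrix(Ahat) - Ahat_dense)), 1e-6)
    # spectral radius bounded by 1
    expect_lt(max(abs(eigen(Ahat_dense, only.values = TRUE)$values)), 1 + 1e-9)
    H <- matrix(rnorm(n * 3), n, 3)
    W <- matrix(rnorm(3 * 2), 3, 2)
    expect_lt(max(abs(gcn_layer(H, Ahat, W) - Ahat_dense %*% H %*% W)), 1e-6)
  }
})

test_that("GCN layer identity and degenerate cases behave", {
  H <- matrix(rnorm(12), 4, 3)
  I4 <- Matrix::Diagonal(4)
  expect_equal(gcn_layer(H, I4, diag(3)), H, tolerance = 1e-15)
  expect_equal(gcn_layer(H * 0, I4, diag(3), function(x) pmax(x, 0)),
               H * 0, tolerance = 1e-15)
  expect_error(gcn_layer(H, I4, diag(4)), "shape mismatch")
})

test_that("attention coefficients are a proper neighborhood softmax", {
  set.seed(21)
  h <- 3
  Wt <- matrix(rnorm(h * h), h, h)
  a <- rnorm(2 * h)
  # single neighbor: softmax of a singleton is 1
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  H <- matrix(rnorm(2 * h), 2, h)
  at <- attention_coefficients(H, Wt, a, A)
  expect_equal(at$g, c(1, 1), tolerance = 1e-15)
  # two neighbors with identical embeddings: equal scores -> (0.5, 0.5)
  A2 <- matrix(0, 3, 3); A2[1, 2] <- A2[2, 1] <- 1; A2[1, 3] <- A2[3, 1] <- 1
  H2 <- rbind(rnorm(h), c(1, 2, 3), c(1, 2, 3))
  at2 <- attention_coefficients(H2, Wt, a, A2)
  g12 <- at2$g[at2$src == 1]
  expect_equal(g12, c(0.5, 0.5), tolerance = 1e-12)
  # 5-node star: hub row matches a step-by-step softmax, all rows sum to 1
  A3 <- matrix(0, 5, 5); A3[1, 2:5] <- 1; A3[2:5, 1] <- 1
  H3 <- matrix(rnorm(5 * h), 5, h)
  at3 <- attention_coefficients(H3, Wt, a, A3)
  U <- H3 %*% Wt
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  e_hub <- vapply(2:5, function(j)
    lrelu(sum(a * c(U[1, ], U[j, ]))), numeric(1))
  expect_equal(at3$g[at3$src == 1], exp(e_hub) / sum(exp(e_hub)),
               tolerance = 1e-12)
  sums <- tapply(at3$g, at3$src, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("CRF update: identity at beta = 0, hand example, convergence", {
  Q <- matrix(rnorm(8), 4, 2)
  A <- random_adjacency(4, 0.5)
  H_id <- crf_update(Q, Matrix::Matrix(A / pmax(rowSums(A), 1), sparse = TRUE),
                     alpha = 1, beta = 0, iterations = 5L)
  expect_identical(H_id, Q)  # exact, not approximate
  expect_error(crf_update(Q, A, alpha = 0, beta = 0), "both be zero")

  # two connected nodes, Q = (0, 1), g = 1 both ways, one iteration
  G2 <- Matrix::Matrix(matrix(c(0, 1, 1, 0), 2, 2), sparse = TRUE)
  H1 <- crf_update(matrix(c(0, 1), 2, 1), G2, alpha = 1, beta = 1, iterations = 1L)
  expect_equal(as.numeric(H1), c(0.5, 0.5), tolerance = 1e-15)

  # fixed point: iterates converge geometrically and satisfy the update
  set.seed(3)
  n <- 6
  A6 <- random_adjacency(n, 0.5)
  graph <- graph_from_adjacency(A6)
  H0 <- matrix(rnorm(n * 3), n, 3)
  at <- attention_coefficients(H0, diag(3), rnorm(6), A6)
  H_inf <- crf_update(H0, at$G, alpha = 0.8, beta = 1.2, iterations = 200L)
  H_next <- crf_update(H_inf, at$G, alpha = 0.8, beta = 1.2, iterations = 1L)
  # residual of the self-consistency equation (H_next re-anchors to H_inf)
  r <- Matrix::rowSums(at$G)
  d <- 0.8 + 1.2 * r
  resid <- max(abs((0.8 * H0 + 1.2 * as.matrix(at$G %*% H_inf)) / d - H_inf))
  expect_lt(resid, 1e-8)
  # successive-change contraction
  H_t <- H0; deltas <- numeric(10)
  for (t in 1:10) {
    H_t1 <- (0.8 * H0 + 1.2 * as.matrix(at$G %*% H_t)) / d
    deltas[t] <- max(abs(H_t1 - H_t)); H_t <- H_t1
  }
  expect_true(all(diff(deltas) <= 1e-12))
})

test_that("CRF energy: hand value, zero cases, and near-optimality of the update", {
  G2 <- Matrix::Matrix(matrix(c(0, 1, 1, 0), 2, 2), sparse = TRUE)
  Q <- matrix(c(0, 1), 2, 1)
  H <- matrix(c(0.5, 0.5), 2, 1)
  expect_identical(crf_loss(H, Q, G2, alpha = 1, beta = 1), 0.5)
  expect_identical(crf_loss(Q, Q, G2 * 0, alpha = 1, beta = 0), 0)

  # brute-force minimizer on a 3-node instance reaches at most the T=10 energy
  set.seed(4)
  A3 <- matrix(0, 3, 3); A3[1, 2] <- A3[2, 1] <- 1; A3[2, 3] <- A3[3, 2] <- 1
  Q3 <- matrix(rnorm(6), 3, 2)
  at <- attention_coefficients(Q3, diag(2), rnorm(4), A3)
  H10 <- crf_update(Q3, at$G, alpha = 1, beta = 1, iterations = 10L)
  e10 <- crf_loss(H10, Q3, at$G, 1, 1)
  opt <- optim(as.numeric(Q3),
               function(v) crf_loss(matrix(v, 3, 2), Q3, at$G, 1, 1),
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  # the mean-field fixed point solves each node's local problem given its
  # neighbors but ignores incoming-edge terms of the global energy, so the
  # unconstrained minimizer can only be at or below it
  expect_lte(opt$value, e10 + 1e-10)
})

test_that("weighted cross-entropy matches its closed forms and monotonicity", {
  expect_equal(weighted_bce(0.5, 1, p = 1), log(2), tolerance = 1e-12)
  expect_equal(weighted_bce(0.5, 1, p = 3), 3 * log(2), tolerance = 1e-12)
  # the weight touches positives only
  for (p in c(1, 2, 5)) {
    expect_equal(weighted_bce(0.5, 0, p = p), log(2), tolerance = 1e-12)
  }
  # extreme probabilities are clamped, not infinite
  expect_true(is.finite(weighted_bce(c(0, 1), c(1, 0), p = 2)))
  # monotone non-decreasing in p; strictly increasing with a misclassified positive
  set.seed(6)
  h <- runif(20); y <- rbinom(20, 1, 0.4)
  l <- vapply(1:5, function(p) weighted_bce(h, y, p), numeric(1))
  expect_true(all(diff(l) > 0))
  h_neg_only <- h; y0 <- rep(0, 20)
  l0 <- vapply(1:5, function(p) weighted_bce(h_neg_only, y0, p), numeric(1))
  expect_true(all(abs(diff(l0)) < 1e-15))
})

test_that("forward pass: sigmoid range, CRF-off equivalence, eval determinism", {
  fx <- tiny_model_fixture()
  cfg <- dg_config(hidden_dim = 4L, dropout = 0, seed = 2L)
  prep <- driverGCN:::prep_graph(fx$graph)
  params <- driverGCN:::init_params(ncol(fx$X), 4L, 2L)
  fw <- driverGCN:::dg_forward(params, fx$X, prep, cfg)
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # beta = 0 reduces to the plain 2-layer GCN with the same weights
  cfg0 <- dg_config(hidden_dim = 4L, dropout = 0, crf_beta = 0, seed = 2L)
  fw0 <- driverGCN:::dg_forward(params, fx$X, prep, cfg0)
  plain <- gcn_layer(gcn_layer(fx$X, prep$A_hat, params$W1,
                               function(x) pmax(x, 0)),
                     prep$A_hat, params$W2)
  expect_equal(fw0$prob, drop(1 / (1 + exp(-plain))), tolerance = 1e-12)
  expect_identical(fw0$l_crf, 0)
  # two eval-mode passes are identical
  fw2 <- driverGCN:::dg_forward(params, fx$X, prep, cfg)
  expect_identical(fw$prob, fw2$prob)
  # attention rows are stochastic on every forward pass
  sums <- tapply(fw$at$g, prep$edges$src, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("analytic gradients match numeric differentiation", {
  fx <- tiny_model_fixture(seed = 5L, n = 6L, f = 4L)
  cfg <- dg_config(hidden_dim = 3L, dropout = 0, positive_weight = 2,
                   crf_alpha = 0.7, crf_beta = 1.3, crf_iterations = 2L, seed = 3L)
  prep <- driverGCN:::prep_graph(fx$graph)
  params <- driverGCN:::init_params(4L, 3L, 11L)
  labels <- fx$graph$labels; mask <- fx$graph$train_mask
  lg <- driverGCN:::dg_loss_and_grad(params, fx$X, prep, cfg, labels, mask)
  eps <- 1e-6
  for (key in names(params)) {
    ng <- params[[key]]
    for (i in seq_along(ng)) {
      pp <- params; pp[[key]][i] <- pp[[key]][i] + eps
      pm <- params; pm[[key]][i] <- pm[[key]][i] - eps
      ng[i] <- (driverGCN:::dg_forward(pp, fx$X, prep, cfg, labels, mask)$l_total -
                driverGCN:::dg_forward(pm, fx$X, prep, cfg, labels, mask)$l_total) /
        (2 * eps)
    }
    denom <- max(abs(ng), 1e-8)
    expect_lt(max(abs(ng - as.matrix(lg$grads[[key]]))) / denom, 1e-4)
  }
})

test_that("training descends, is seed-deterministic, and grid search argmaxes", {
  fx <- tiny_model_fixture(seed = 30L, n = 16L, f = 6L)
  cfg <- dg_config(hidden_dim = 5L, epochs = 100L, seed = 12L, cv_folds = 2L)
  m1 <- driver_gcn(fx$graph, fx$X, cfg)
  expect_lt(m1$loss_trace$l_total[100], m1$loss_trace$l_total[1])
  m2 <- driver_gcn(fx$graph, fx$X, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  # grid over two learning rates returns the argmax of mean CV AUPR
  cfg_g <- dg_config(hidden_dim = 4L, epochs = 40L, seed = 12L, cv_folds = 2L)
  mg <- driver_gcn(fx$graph, fx$X, cfg_g,
                   grid = list(learning_rate = c(0.001, 0.05)))
  best <- mg$cv$learning_rate[which.max(mg$cv$mean_cv_aupr)]
  expect_identical(mg$config$learning_rate, best)
})

test_that("prediction is equivariant, bounded, and honest about mismatches", {
  fx <- tiny_model_fixture(seed = 9L, n = 14L, f = 5L)
  cfg <- dg_config(hidden_dim = 4L, epochs = 50L, seed = 7L)
  model <- driver_gcn(fx$graph, fx$X, cfg)
  sc <- predict(model, fx$graph, fx$X)
  expect_true(all(sc$score > 0 & sc$score < 1))
  # permuting node order permutes scores identically
  perm <- sample(nrow(fx$X))
  gperm <- fx$graph
  gperm$nodes <- fx$graph$nodes[perm, ]
  gperm$adjacency <- fx$graph$adjacency[perm, perm]
  sc_perm <- predict(model, gperm, fx$X[perm, , drop = FALSE])
  expect_equal(sc_perm$score, sc$score[perm], tolerance = 1e-12)
  # zero output head -> sigmoid(0) = 0.5 everywhere
  m0 <- model; m0$params$W2[] <- 0
  expect_true(all(predict(m0, fx$graph, fx$X)$score == 0.5))
  expect_error(predict(model, fx$graph, fx$X[, 1:3]), "dimension mismatch")
  # checkpoint round-trip reproduces scores bit-identically
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  expect_identical(predict(load_model(path), fx$graph, fx$X)$score, sc$score)
})
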