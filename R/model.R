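# The learning core: a two-layer graph convolutional network over the
# symmetrically normalized adjacency, with an attention-weighted
# conditional random field (CRF) refinement layer between the two
# convolutions. The CRF appears twice, consistently: as a differentiable
# mean-field update of the hidden embedding, and as an energy term added
# to the classification loss. Training minimizes
#   l_total = l_CRF + l_theta
# with Adam, where l_theta is a positive-weighted binary cross-entropy
# over the training-mask nodes and l_CRF is computed over all nodes
# (unsupervised smoothing). All gradients are analytic (manual
# backpropagation); a numeric gradient check guards the implementation.

sigmoid <- function(x) 1 / (1 + exp(-x))
leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes A_hat = D~^(-1/2) (A + I) D~^(-1/2) where D~ is the degree
#' matrix of A + I. Self-loops preserve each node's own signal; an
#' isolated node gets A_hat[i, i] = 1.
#'
#' @param A symmetric binary adjacency with zero diagonal (sparse or dense).
#' @return sparse symmetric `A_hat`.
#' @export
normalize_adjacency <- function(A) {
  A <- as(as(A, "CsparseMatrix"), "generalMatrix")
  if (!Matrix::isSymmetric(A)) dg_stop("adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0)) dg_stop("adjacency must have a zero diagonal")
  n <- nrow(A)
  A_tilde <- A + Matrix::Diagonal(n)
  d <- Matrix::rowSums(A_tilde)
  d_inv_sqrt <- 1 / sqrt(d)
  Matrix::Diagonal(n, d_inv_sqrt) %*% A_tilde %*% Matrix::Diagonal(n, d_inv_sqrt)
}

#' One graph convolution layer
#'
#' H_out = activation(A_hat %*% H_in %*% W).
#'
#' @param H_in nodes x f input matrix (the feature matrix X for the first
#'   layer).
#' @param A_hat normalized adjacency from [normalize_adjacency()].
#' @param W f x h weight matrix.
#' @param activation elementwise function (default identity).
#' @return nodes x h output matrix.
#' @export
gcn_layer <- function(H_in, A_hat, W, activation = identity) {
  if (ncol(H_in) != nrow(W))
    dg_stop("shape mismatch in GCN layer: input has ", ncol(H_in),
            " columns but W has ", nrow(W), " rows")
  activation(as.matrix(A_hat %*% H_in %*% W))
}

# Directed edge list (both directions) of an adjacency, with scatter
# operators precomputed once and reused across epochs. S_src / S_dst are
# n x E indicator matrices: S_src %*% v sums per-edge values into their
# source (resp. destination) rows.
edge_index <- function(A) {
  T <- as(as(A, "TsparseMatrix"), "generalMatrix")
  keep <- T@i != T@j
  src <- T@i[keep] + 1L
  dst <- T@j[keep] + 1L
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]
  E <- length(src)
  n <- nrow(A)
  list(src = src, dst = dst, n = n,
       idx_by_row = split(seq_len(E), src),
       S_src = Matrix::sparseMatrix(i = src, j = seq_len(E), x = 1,
                                    dims = c(n, max(E, 1L))),
       S_dst = Matrix::sparseMatrix(i = dst, j = seq_len(E), x = 1,
                                    dims = c(n, max(E, 1L))))
}

# scatter-sum per-edge values (vector or matrix) into node rows through a
# precomputed indicator operator
scatter_sum <- function(values, S) {
  out <- as.matrix(S %*% values)
  if (ncol(out) == 1L) drop(out) else out
}

#' Self-attention coefficients over graph neighborhoods
#'
#' GAT-style scorer: both endpoint embeddings are transformed by the shared
#' matrix `Wt`, concatenated, scored by the learnable vector `a` through a
#' LeakyReLU (slope 0.2), and the scores are softmax-normalized over each
#' node's neighborhood (max-subtraction for stability). Rows without
#' neighbors stay empty.
#'
#' @param H nodes x h embedding matrix.
#' @param Wt h x h shared transform.
#' @param a attention vector of length 2h.
#' @param edges edge list from `edge_index()` or a symmetric adjacency
#'   matrix (neighborhoods exclude self).
#' @return list with `g` (per-edge coefficient), `src`, `dst`, and `G`
#'   (sparse row-stochastic matrix of the coefficients).
#' @export
attention_coefficients <- function(H, Wt, a, edges) {
  if (!is.list(edges)) edges <- edge_index(edges)
  at <- attention_forward(H, Wt, a, edges, build_G = TRUE)
  list(g = at$g, src = edges$src, dst = edges$dst, G = at$G)
}

# internal: attention with intermediates kept for backprop; the sparse
# coefficient matrix is only materialized on request (build_G) — the
# training loop works directly on the edge list
attention_forward <- function(H, Wt, a, ed, build_G = FALSE) {
  h <- ncol(H)
  if (length(a) != 2L * h)
    dg_stop("attention vector must have length 2 * ncol(H)")
  a1 <- a[seq_len(h)]; a2 <- a[h + seq_len(h)]
  U <- H %*% Wt
  s1 <- drop(U %*% a1)
  s2 <- drop(U %*% a2)
  pre <- s1[ed$src] + s2[ed$dst]
  eact <- leaky_relu(pre)
  mx <- vapply(ed$idx_by_row, function(ix) max(eact[ix]), numeric(1))
  mx_full <- numeric(ed$n)
  mx_full[as.integer(names(ed$idx_by_row))] <- mx
  ex <- exp(eact - mx_full[ed$src])
  denom <- scatter_sum(ex, ed$S_src)
  g <- ex / denom[ed$src]
  G <- if (build_G)
    Matrix::sparseMatrix(i = ed$src, j = ed$dst, x = g, dims = c(ed$n, ed$n))
  list(g = g, G = G, U = U, pre = pre, a1 = a1, a2 = a2)
}

# (G %*% H) via the edge list: row i accumulates g_ij * H[j, ];
# transpose = TRUE computes t(G) %*% H instead
g_matmul <- function(ed, g, H, transpose = FALSE) {
  if (transpose) {
    as.matrix(ed$S_dst %*% (g * H[ed$src, , drop = FALSE]))
  } else {
    as.matrix(ed$S_src %*% (g * H[ed$dst, , drop = FALSE]))
  }
}

#' CRF mean-field refinement of node embeddings
#'
#' Starting from the GCN embedding Q, iterates
#' H_i <- (alpha Q_i + beta sum_j g_ij H_j) / (alpha + beta sum_j g_ij)
#' for `iterations` steps. Each step solves every node's local CRF
#' problem given its neighbors' current embeddings (a Jacobi-style
#' mean-field sweep), contracting geometrically to a fixed point; the
#' operator is differentiable end-to-end. Nodes without neighbors keep
#' H_i = Q_i, and beta = 0 collapses the update to the identity.
#'
#' @param Q nodes x h anchor embedding (from the GCN layer).
#' @param G sparse row-stochastic attention matrix (e.g. from
#'   [attention_coefficients()]).
#' @param alpha,beta balance factors (not both zero).
#' @param iterations number of update steps T.
#' @return nodes x h refined embedding.
#' @export
crf_update <- function(Q, G, alpha = 1, beta = 1, iterations = 2L) {
  if (alpha == 0 && beta == 0) dg_stop("alpha and beta cannot both be zero")
  if (beta == 0 || iterations == 0L) return(Q)
  r <- Matrix::rowSums(G)
  d <- alpha + beta * r
  H <- Q
  for (t in seq_len(iterations)) H <- (alpha * Q + beta * as.matrix(G %*% H)) / d
  H
}

#' CRF energy of a refined embedding
#'
#' `l_CRF = sum_i ( alpha ||H_i - Q_i||^2 +
#'                  beta sum_{j in M_i} g_ij ||H_i - H_j||^2 )`.
#'
#' @param H refined embedding.
#' @param Q anchor embedding.
#' @param G sparse attention-coefficient matrix.
#' @param alpha,beta balance factors.
#' @return scalar energy.
#' @export
crf_loss <- function(H, Q, G, alpha = 1, beta = 1) {
  T <- as(as(G, "TsparseMatrix"), "generalMatrix")
  pair <- if (length(T@x)) {
    diff <- H[T@i + 1L, , drop = FALSE] - H[T@j + 1L, , drop = FALSE]
    sum(T@x * rowSums(diff^2))
  } else 0
  alpha * sum((H - Q)^2) + beta * pair
}

#' Positive-weighted binary cross-entropy
#'
#' l_theta = -mean over masked nodes of
#' p * y * log(h) + (1 - y) * log(1 - h): positives are up-weighted by the
#' factor p to counter class imbalance, negatives are untouched.
#' Probabilities are clamped to [1e-7, 1 - 1e-7] before the logs.
#'
#' @param h predicted probabilities in (0, 1).
#' @param y binary labels.
#' @param p positive-class weight (>= 1).
#' @param mask logical/index vector of nodes entering the mean (default all).
#' @return scalar loss.
#' @export
weighted_bce <- function(h, y, p = 1, mask = NULL) {
  if (!is.null(mask)) { h <- h[mask]; y <- y[mask] }
  if (length(h) == 0L) dg_stop("empty mask in weighted_bce")
  h <- clamp_prob(h)
  -mean(p * y * log(h) + (1 - y) * log(1 - h))
}

# ---- parameter handling -----------------------------------------------

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

init_params <- function(n_features, hidden_dim, seed) {
  with_seed(seed, list(
    W1 = glorot(n_features, hidden_dim),
    W2 = glorot(hidden_dim, 1L),
    Wt = glorot(hidden_dim, hidden_dim),
    a = runif(2L * hidden_dim, -sqrt(6 / (2 * hidden_dim + 1)),
              sqrt(6 / (2 * hidden_dim + 1)))
  ))
}

prep_graph <- function(graph) {
  list(A_hat = normalize_adjacency(graph$adjacency),
       edges = edge_index(graph$adjacency))
}

# ---- forward / backward -----------------------------------------------

# Full forward pass keeping every intermediate needed for backprop.
# drop_mask_x / drop_mask_h: binary dropout masks (NULL in eval mode).
dg_forward <- function(params, X, prep, cfg, labels = NULL, mask = NULL,
                       drop_mask_x = NULL, drop_mask_h = NULL) {
  keep <- 1 - cfg$dropout
  Xd <- if (!is.null(drop_mask_x)) X * drop_mask_x / keep else X
  AX <- as.matrix(prep$A_hat %*% Xd)
  S1 <- AX %*% params$W1
  H1 <- pmax(S1, 0)

  use_crf <- cfg$crf_beta > 0 && length(prep$edges$src) > 0L
  if (use_crf) {
    ed <- prep$edges
    at <- attention_forward(H1, params$Wt, params$a, ed)
    r <- scatter_sum(at$g, ed$S_src)
    d <- cfg$crf_alpha + cfg$crf_beta * r
    Hs <- vector("list", cfg$crf_iterations + 1L)
    Hs[[1L]] <- H1
    H <- H1
    if (cfg$crf_iterations >= 1L) {
      for (t in seq_len(cfg$crf_iterations)) {
        H <- (cfg$crf_alpha * H1 +
                cfg$crf_beta * g_matmul(ed, at$g, H)) / d
        Hs[[t + 1L]] <- H
      }
    }
    # the objective uses the per-node mean energy so that l_CRF and the
    # per-node mean cross-entropy live on the same scale; the layer update
    # is unaffected (it depends only on the alpha:beta ratio)
    diffH <- H[ed$src, , drop = FALSE] - H[ed$dst, , drop = FALSE]
    l_crf <- (cfg$crf_alpha * sum((H - H1)^2) +
                cfg$crf_beta * sum(at$g * rowSums(diffH^2))) / nrow(X)
  } else {
    at <- NULL; Hs <- NULL; d <- NULL
    H <- H1
    l_crf <- 0
  }

  Hd <- if (!is.null(drop_mask_h)) H * drop_mask_h / keep else H
  AH <- as.matrix(prep$A_hat %*% Hd)
  z <- drop(AH %*% params$W2)
  prob <- sigmoid(z)

  l_theta <- if (!is.null(labels)) {
    weighted_bce(prob, labels, cfg$positive_weight, mask)
  } else NA_real_

  list(prob = prob, z = z, l_crf = l_crf, l_theta = l_theta,
       l_total = l_crf + l_theta,
       AX = AX, S1 = S1, H1 = H1, H = H, Hd = Hd, AH = AH,
       at = at, Hs = Hs, d = d, use_crf = use_crf,
       diffH = if (use_crf) diffH,
       drop_mask_x = drop_mask_x, drop_mask_h = drop_mask_h)
}

dg_backward <- function(fw, params, X, prep, cfg, labels, mask) {
  ed <- prep$edges
  n <- ed$n
  keep <- 1 - cfg$dropout
  p <- cfg$positive_weight
  M <- if (is.logical(mask)) sum(mask) else length(mask)
  y <- labels
  h <- clamp_prob(fw$prob)

  # d l_theta / d z (mean over masked nodes)
  dz <- numeric(n)
  dz[mask] <- (-(p * y * (1 - h)) + (1 - y) * h)[mask] / M

  dW2 <- crossprod(fw$AH, dz)
  dAH <- outer(dz, drop(params$W2))     # n x h
  dHd <- as.matrix(prep$A_hat %*% dAH)  # A_hat symmetric
  dH <- if (!is.null(fw$drop_mask_h)) dHd * fw$drop_mask_h / keep else dHd

  if (fw$use_crf) {
    at <- fw$at
    g <- at$g
    Hf <- fw$H
    Q <- fw$H1
    alpha <- cfg$crf_alpha; beta <- cfg$crf_beta

    # l_CRF terms (per-node mean energy: every term scaled by 1/n)
    diff <- fw$diffH
    dH_crf <- 2 * alpha * (Hf - Q) / n
    r_out <- scatter_sum(g, ed$S_src)
    r_in <- scatter_sum(g, ed$S_dst)
    GH <- g_matmul(ed, g, Hf)
    GtH <- g_matmul(ed, g, Hf, transpose = TRUE)
    dH_pair <- 2 * beta * ((r_out + r_in) * Hf - GH - GtH) / n
    dQ <- -2 * alpha * (Hf - Q) / n
    dg <- beta * rowSums(diff^2) / n

    # back through the T mean-field iterations
    dHcur <- dH + dH_crf + dH_pair
    if (cfg$crf_iterations >= 1L) {
      for (t in rev(seq_len(cfg$crf_iterations))) {
        tmp <- dHcur / fw$d
        dQ <- dQ + alpha * tmp
        Hprev <- fw$Hs[[t]]
        dg <- dg + beta * rowSums(tmp[ed$src, , drop = FALSE] *
                                    Hprev[ed$dst, , drop = FALSE])
        dHcur <- beta * g_matmul(ed, g, tmp, transpose = TRUE)
      }
    }
    dQ <- dQ + dHcur

    # softmax rows: de = g * (dg - sum_k g_ik dg_ik)
    sg <- scatter_sum(g * dg, ed$S_src)
    de <- g * (dg - sg[ed$src])
    dpre <- de * ((fw$at$pre > 0) + 0.2 * (fw$at$pre <= 0))
    ds1 <- scatter_sum(dpre, ed$S_src)
    ds2 <- scatter_sum(dpre, ed$S_dst)
    da1 <- drop(crossprod(at$U, ds1))
    da2 <- drop(crossprod(at$U, ds2))
    dU <- outer(ds1, at$a1) + outer(ds2, at$a2)
    dWt <- crossprod(fw$H1, dU)
    dH1 <- dQ + dU %*% t(params$Wt)
    da <- c(da1, da2)
  } else {
    dH1 <- dH
    dWt <- matrix(0, nrow(params$Wt), ncol(params$Wt))
    da <- numeric(length(params$a))
  }

  dS1 <- dH1 * (fw$S1 > 0)
  dW1 <- crossprod(fw$AX, dS1)
  list(W1 = dW1, W2 = dW2, Wt = dWt, a = da)
}

# loss + gradient in one call (used by the trainer and the gradient check)
dg_loss_and_grad <- function(params, X, prep, cfg, labels, mask,
                             drop_mask_x = NULL, drop_mask_h = NULL) {
  fw <- dg_forward(params, X, prep, cfg, labels, mask, drop_mask_x, drop_mask_h)
  gr <- dg_backward(fw, params, X, prep, cfg, labels, mask)
  list(loss = fw$l_total, l_crf = fw$l_crf, l_theta = fw$l_theta,
       grads = gr, prob = fw$prob)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    gk <- grads[[k]] + weight_decay * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- fitting ----------------------------------------------------------

train_loop <- function(X, prep, cfg, labels, train_mask, seed) {
  n <- nrow(X)
  params <- init_params(ncol(X), cfg$hidden_dim, seed)
  opt <- adam_init(params)
  trace <- matrix(NA_real_, cfg$epochs, 3L,
                  dimnames = list(NULL, c("l_total", "l_crf", "l_theta")))
  with_seed(seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      dmx <- dmh <- NULL
      if (cfg$dropout > 0) {
        dmx <- matrix(rbinom(n * ncol(X), 1L, 1 - cfg$dropout), n, ncol(X))
        dmh <- matrix(rbinom(n * cfg$hidden_dim, 1L, 1 - cfg$dropout),
                      n, cfg$hidden_dim)
      }
      lg <- dg_loss_and_grad(params, X, prep, cfg, labels, train_mask, dmx, dmh)
      if (!is.finite(lg$loss))
        dg_stop("non-finite training loss at epoch ", epoch,
                " (l_crf = ", format(lg$l_crf), ", l_theta = ",
                format(lg$l_theta), "); try a lower learning rate")
      trace[epoch, ] <- c(lg$loss, lg$l_crf, lg$l_theta)
      upd <- adam_step(params, lg$grads, opt, cfg$learning_rate, cfg$weight_decay)
      params <- upd$params
      opt <- upd$state
    }
  })
  list(params = params, trace = as.data.frame(trace))
}

#' Fit the GCN-CRF driver-gene model
#'
#' Trains the two-layer GCN with the attention-weighted CRF refinement
#' layer on the training-mask nodes of a labeled sample-gene graph,
#' minimizing l_total = l_CRF + l_theta with Adam. When `grid` is given
#' (a named list of candidate vectors over `learning_rate`,
#' `weight_decay`, `dropout` and/or `epochs`), the combination with the
#' best mean validation AUPR under stratified k-fold cross-validation on
#' the training nodes is selected before the final fit.
#'
#' @param graph a labeled, split `sample_gene_graph`.
#' @param features a `node_features` object from [build_node_features()]
#'   (or a plain numeric matrix with one row per node).
#' @param config a [dg_config()].
#' @param grid optional named list of hyperparameter candidates.
#' @return an object of class `driver_gcn` with elements `params`,
#'   `config`, `loss_trace`, `cv` (grid-search table or NULL), `seed`,
#'   `n_features`, `block_spec`, `bounds`.
#' @seealso [predict.driver_gcn()], [rank_predictions()]
#' @export
driver_gcn <- function(graph, features, config = dg_config(), grid = NULL) {
  stopifnot(inherits(graph, "sample_gene_graph"))
  if (is.null(graph$labels)) dg_stop("graph has no labels; call assign_labels()")
  if (is.null(graph$train_mask)) dg_stop("graph has no split; call split_nodes()")
  X <- if (inherits(features, "node_features")) features$X else as.matrix(features)
  if (nrow(X) != nrow(graph$nodes))
    dg_stop("feature matrix has ", nrow(X), " rows but the graph has ",
            nrow(graph$nodes), " nodes")
  cfg <- config
  prep <- prep_graph(graph)
  labels <- graph$labels
  cv_table <- NULL

  if (!is.null(grid)) {
    sel <- grid_search_cv(X, prep, cfg, labels, graph$train_mask, grid)
    cfg <- sel$config
    cv_table <- sel$table
  }

  fit <- train_loop(X, prep, cfg, labels, graph$train_mask, cfg$seed)
  structure(list(params = fit$params,
                 config = cfg,
                 loss_trace = fit$trace,
                 cv = cv_table,
                 seed = cfg$seed,
                 n_features = ncol(X),
                 block_spec = if (inherits(features, "node_features"))
                   features$block_spec else NULL,
                 bounds = if (inherits(features, "node_features"))
                   features$bounds else NULL),
            class = "driver_gcn")
}

grid_search_cv <- function(X, prep, cfg, labels, train_mask, grid) {
  tunable <- c("learning_rate", "weight_decay", "dropout", "epochs")
  bad <- setdiff(names(grid), tunable)
  if (length(bad)) dg_stop("grid can only tune ", paste(tunable, collapse = ", "),
                           "; got ", paste(bad, collapse = ", "))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  train_idx <- which(train_mask)
  folds <- with_seed(cfg$seed + 1000L, {
    f <- integer(length(train_idx))
    for (lab in c(0L, 1L)) {
      sel <- which(labels[train_idx] == lab)
      f[sel] <- sample(rep(seq_len(cfg$cv_folds), length.out = length(sel)))
    }
    f
  })
  scores <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    cfg_ci <- cfg
    for (nm in names(combos)) cfg_ci[[nm]] <- combos[[nm]][ci]
    validate_config(cfg_ci)
    auprs <- numeric(cfg$cv_folds)
    for (k in seq_len(cfg$cv_folds)) {
      fold_train <- rep(FALSE, length(labels))
      fold_train[train_idx[folds != k]] <- TRUE
      fold_val <- train_idx[folds == k]
      fit <- train_loop(X, prep, cfg_ci, labels, fold_train, cfg$seed)
      fw <- dg_forward(fit$params, X, prep, cfg_ci)
      auprs[k] <- compute_metrics(fw$prob, labels, fold_val)["aupr"]
    }
    scores[ci] <- mean(auprs)
    dg_log("grid combo ", ci, "/", nrow(combos), ": mean CV AUPR = ",
           format(scores[ci], digits = 4), level = "debug")
  }
  best <- which.max(scores)
  cfg_best <- cfg
  for (nm in names(combos)) cfg_best[[nm]] <- combos[[nm]][best]
  list(config = cfg_best,
       table = cbind(combos, mean_cv_aupr = scores))
}

#' Predict node scores with a fitted model
#'
#' Evaluation-mode forward pass (dropout off); scores are the sigmoid
#' output in (0, 1), attached to the graph's (sample, gene) node
#' identities.
#'
#' @param object a fitted `driver_gcn`.
#' @param graph the `sample_gene_graph` to score.
#' @param features a `node_features` object or matrix; must have the same
#'   feature dimension the model was trained with (use the training
#'   bounds via [apply_normalization()] for new raw features).
#' @param ... unused.
#' @return data.frame with columns `sample_id`, `gene`, `score`.
#' @export
predict.driver_gcn <- function(object, graph, features, ...) {
  stopifnot(inherits(graph, "sample_gene_graph"))
  X <- if (inherits(features, "node_features")) features$X else as.matrix(features)
  if (ncol(X) != object$n_features)
    dg_stop("feature dimension mismatch: model trained with ",
            object$n_features, " features, got ", ncol(X))
  if (nrow(X) != nrow(graph$nodes))
    dg_stop("feature rows (", nrow(X), ") != graph nodes (", nrow(graph$nodes), ")")
  prep <- prep_graph(graph)
  fw <- dg_forward(object$params, X, prep, object$config)
  data.frame(sample_id = graph$nodes$sample_id,
             gene = graph$nodes$gene,
             score = fw$prob,
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive of the full fitted object
#' (parameter matrices, configuration, loss trace, feature block spec and
#' normalization bounds, seed); loading reproduces `predict()`
#' bit-identically on the same platform.
#'
#' @param model a `driver_gcn`.
#' @param path checkpoint file.
#' @return `path` (save) or the restored `driver_gcn` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "driver_gcn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "driver_gcn")) dg_stop("not a driver_gcn checkpoint: ", path)
  model
}
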