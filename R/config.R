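#' Run configuration for the driver-gene pipeline
#'
#' Collects every tunable of the method in one validated list: node2vec
#' walk/embedding settings, the STRING-style interaction score cutoff, DEG
#' thresholds, model architecture, CRF balance factors, the positive-class
#' weight of the loss, and the Adam training schedule.
#'
#' Defaults follow the method's published training regime: learning rate
#' 0.001, weight decay 0.005, dropout 0.1, 3000 epochs, a 75/25
#' train/test split and 5-fold cross-validation for grid search, and a
#' 20-dimensional node2vec block.
#'
#' @param node2vec_dim embedding dimension d (0 disables the structural
#'   block, used by ablations).
#' @param walk_length,walks_per_node,window,return_p,inout_q,negative_samples,node2vec_epochs
#'   node2vec random-walk and skip-gram settings.
#' @param string_score_threshold minimum interaction score kept when loading
#'   the PPI table (STRING "high confidence" convention is 700).
#' @param deg_alpha BH-adjusted p-value cutoff for DEG calling.
#' @param deg_lfc absolute log2 fold-change cutoff for DEG calling.
#' @param hidden_dim width of the hidden GCN layer.
#' @param crf_alpha,crf_beta CRF balance factors: alpha anchors each node to
#'   its GCN embedding, beta pulls it toward its attention-weighted
#'   neighborhood mean. beta = 0 disables the CRF layer.
#' @param crf_iterations number of CRF mean-field update iterations T.
#' @param positive_weight multiplicative weight p attached to positive nodes
#'   in the cross-entropy loss (>= 1).
#' @param learning_rate,weight_decay,dropout,epochs Adam training schedule.
#' @param test_fraction held-out fraction of labeled nodes.
#' @param split_by "gene" (all nodes of one gene share a partition) or
#'   "node" (nodes split independently).
#' @param cv_folds folds for grid-search cross-validation.
#' @param seed integer seed controlling every random draw downstream.
#' @return a validated list of class `dg_config`.
#' @export
dg_config <- function(node2vec_dim = 20L,
                      walk_length = 80L,
                      walks_per_node = 10L,
                      window = 5L,
                      return_p = 1,
                      inout_q = 1,
                      negative_samples = 5L,
                      node2vec_epochs = 5L,
                      string_score_threshold = 700,
                      deg_alpha = 0.05,
                      deg_lfc = 2.0,
                      hidden_dim = 64L,
                      crf_alpha = 1,
                      crf_beta = 1,
                      crf_iterations = 2L,
                      positive_weight = 1,
                      learning_rate = 0.001,
                      weight_decay = 0.005,
                      dropout = 0.1,
                      epochs = 3000L,
                      test_fraction = 0.25,
                      split_by = c("gene", "node"),
                      cv_folds = 5L,
                      seed = 1L) {
  cfg <- list(
    node2vec_dim = as.integer(node2vec_dim),
    walk_length = as.integer(walk_length),
    walks_per_node = as.integer(walks_per_node),
    window = as.integer(window),
    return_p = as.numeric(return_p),
    inout_q = as.numeric(inout_q),
    negative_samples = as.integer(negative_samples),
    node2vec_epochs = as.integer(node2vec_epochs),
    string_score_threshold = as.numeric(string_score_threshold),
    deg_alpha = as.numeric(deg_alpha),
    deg_lfc = as.numeric(deg_lfc),
    hidden_dim = as.integer(hidden_dim),
    crf_alpha = as.numeric(crf_alpha),
    crf_beta = as.numeric(crf_beta),
    crf_iterations = as.integer(crf_iterations),
    positive_weight = as.numeric(positive_weight),
    learning_rate = as.numeric(learning_rate),
    weight_decay = as.numeric(weight_decay),
    dropout = as.numeric(dropout),
    epochs = as.integer(epochs),
    test_fraction = as.numeric(test_fraction),
    split_by = match.arg(split_by),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "dg_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) dg_stop("invalid configuration: ", what)
  chk(cfg$node2vec_dim >= 0L, "node2vec_dim must be >= 0")
  chk(cfg$walk_length >= 1L && cfg$walks_per_node >= 1L, "walk settings must be >= 1")
  chk(cfg$return_p > 0 && cfg$inout_q > 0, "node2vec return_p and inout_q must be > 0")
  chk(cfg$deg_alpha > 0 && cfg$deg_alpha <= 1, "deg_alpha must lie in (0, 1]")
  chk(cfg$deg_lfc >= 0, "deg_lfc must be >= 0")
  chk(cfg$hidden_dim >= 1L, "hidden_dim must be >= 1")
  chk(cfg$crf_alpha >= 0 && cfg$crf_beta >= 0, "crf_alpha and crf_beta must be >= 0")
  chk(cfg$crf_iterations >= 0L, "crf_iterations must be >= 0")
  chk(cfg$positive_weight >= 1, "positive_weight must be >= 1")
  chk(cfg$learning_rate > 0 && cfg$learning_rate <= 1, "learning_rate must lie in (0, 1]")
  chk(cfg$weight_decay >= 0, "weight_decay must be >= 0")
  chk(cfg$dropout >= 0 && cfg$dropout < 1, "dropout must lie in [0, 1)")
  chk(cfg$epochs >= 1L, "epochs must be >= 1")
  chk(cfg$test_fraction >= 0 && cfg$test_fraction < 1, "test_fraction must lie in [0, 1)")
  chk(cfg$cv_folds >= 2L, "cv_folds must be >= 2")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their [dg_config()] defaults; unknown keys
#' are rejected so typos do not pass silently.
#'
#' @param path YAML file with flat `key: value` pairs mirroring [dg_config()].
#' @param overrides named list applied on top of the file (CLI flags).
#' @return a `dg_config`.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- if (!is.null(path)) {
    if (!file.exists(path)) dg_stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else list()
  if (is.null(vals)) vals <- list()
  vals <- modifyList(vals, overrides)
  known <- names(formals(dg_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) dg_stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(dg_config, vals)
}

#' Write a run configuration to YAML
#' @param cfg a `dg_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "dg_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.dg_config <- function(x, ...) {
  cat("driver-gene run configuration\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
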