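# Node feature assembly: a 4-column molecular block (mutation, expression,
# methylation, copy number for that node's sample), an 18-column block of
# system-level gene properties, and a d-column node2vec structural block.
# The blocks are concatenated and min-max normalized to [0, 1] globally
# over all nodes.

#' Molecular feature block
#'
#' For node i = (sample s, gene g), the row is
#' (mutation[s,g], expression[s,g], methylation[s,g], cnv[s,g]).
#'
#' @param graph a `sample_gene_graph`.
#' @param cohort a `cohort_data`.
#' @return nodes x 4 numeric matrix.
#' @export
molecular_features <- function(graph, cohort) {
  stopifnot(inherits(graph, "sample_gene_graph"), inherits(cohort, "cohort_data"))
  si <- match(graph$nodes$sample_id, cohort$sample_ids)
  gi <- match(graph$nodes$gene, cohort$gene_ids)
  bad <- which(is.na(si) | is.na(gi))
  if (length(bad))
    dg_stop("nodes absent from the cohort matrices: ",
            paste(sprintf("(%s,%s)", graph$nodes$sample_id[bad[seq_len(min(5, length(bad)))]],
                          graph$nodes$gene[bad[seq_len(min(5, length(bad)))]]),
                  collapse = ", "))
  idx <- cbind(si, gi)
  out <- cbind(mutation = cohort$mutation[idx],
               expression = cohort$expression[idx],
               methylation = cohort$methylation[idx],
               cnv = as.numeric(cohort$cnv[idx]))
  out
}

#' System-level feature block
#'
#' Each node receives the 18-vector of global properties of its gene;
#' genes absent from the table get an all-zero row (their count is
#' logged), so the node set always matches the graph.
#'
#' @param graph a `sample_gene_graph`.
#' @param table a [load_system_features()] matrix.
#' @return nodes x 18 numeric matrix.
#' @export
system_features <- function(graph, table) {
  stopifnot(inherits(graph, "sample_gene_graph"))
  gi <- match(graph$nodes$gene, rownames(table))
  out <- matrix(0, nrow = nrow(graph$nodes), ncol = ncol(table),
                dimnames = list(NULL, colnames(table)))
  hit <- !is.na(gi)
  out[hit, ] <- table[gi[hit], , drop = FALSE]
  n_missing <- sum(!hit)
  if (n_missing > 0L)
    dg_log(n_missing, " node(s) with gene absent from the system feature table; ",
           "zero-filled")
  out
}

#' node2vec structural embedding of the cohort graph
#'
#' Runs second-order biased random walks (return parameter p, in-out
#' parameter q) on the full disjoint-union graph — `walks_per_node` walks
#' of length `walk_length` from every node — and trains a skip-gram model
#' with negative sampling over the walk windows. Walks never cross
#' samples because the graph has no cross-sample edge. Degree-0 nodes
#' receive the zero vector. Fully deterministic given the seed.
#'
#' @param graph a `sample_gene_graph`.
#' @param dim embedding dimension d (>= 1).
#' @param walk_length,walks_per_node,window,return_p,inout_q,negative_samples,epochs
#'   node2vec and skip-gram settings (reference defaults).
#' @param seed integer RNG seed.
#' @return nodes x dim numeric matrix.
#' @export
node2vec_embed <- function(graph, dim = 20L, walk_length = 80L,
                           walks_per_node = 10L, window = 5L,
                           return_p = 1, inout_q = 1,
                           negative_samples = 5L, epochs = 5L, seed = 1L) {
  stopifnot(inherits(graph, "sample_gene_graph"))
  if (dim < 1L) dg_stop("node2vec dimension must be >= 1")
  n <- nrow(graph$nodes)
  adj <- as(graph$adjacency, "TsparseMatrix")
  # 0-based sorted neighbor lists for the C++ walker
  nb <- split(adj@j, factor(adj@i, levels = 0:(n - 1L)))
  nb <- lapply(nb, function(v) as.integer(sort(v)))
  emb <- node2vec_embed_cpp(nb, as.integer(dim), as.integer(walk_length),
                            as.integer(walks_per_node), as.integer(window),
                            as.numeric(return_p), as.numeric(inout_q),
                            as.integer(negative_samples), as.integer(epochs),
                            as.integer(seed))
  deg <- Matrix::rowSums(graph$adjacency)
  emb[deg == 0, ] <- 0
  emb
}

#' Concatenate feature blocks and min-max normalize
#'
#' Blocks are bound column-wise and every column is scaled to [0, 1] by
#' x' = (x - min) / (max - min); constant columns map to 0. The recorded
#' per-column bounds allow re-applying the identical transform at
#' prediction time.
#'
#' @param blocks named list of matrices with equal row counts.
#' @return object of class `node_features`: list with `X` (normalized
#'   matrix), `block_spec` (column index ranges per block) and `bounds`
#'   (2 x p matrix of per-column min/max).
#' @export
concat_normalize <- function(blocks) {
  rows <- vapply(blocks, nrow, integer(1))
  if (length(unique(rows)) != 1L)
    dg_stop("row-count mismatch across feature blocks: ",
            paste(rows, collapse = ", "))
  X_raw <- do.call(cbind, blocks)
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  block_spec <- Map(function(s, e) c(start = s, end = e), starts, ends)
  names(block_spec) <- names(blocks)
  lo <- apply(X_raw, 2L, min)
  hi <- apply(X_raw, 2L, max)
  bounds <- rbind(min = lo, max = hi)
  X <- apply_normalization(X_raw, bounds)
  structure(list(X = X, block_spec = block_spec, bounds = bounds),
            class = "node_features")
}

#' Apply recorded min-max bounds to a raw feature matrix
#'
#' @param X_raw matrix with the same columns the bounds were recorded on.
#' @param bounds 2 x p matrix (rows `min`, `max`).
#' @return normalized matrix; constant columns (max == min) map to 0.
#' @export
apply_normalization <- function(X_raw, bounds) {
  if (ncol(X_raw) != ncol(bounds))
    dg_stop("feature dimension mismatch: ", ncol(X_raw), " columns vs ",
            ncol(bounds), " recorded bounds")
  rng <- bounds["max", ] - bounds["min", ]
  rng[rng == 0] <- 1  # constant columns: numerator is 0, map to 0
  X <- sweep(X_raw, 2L, bounds["min", ], "-")
  X <- sweep(X, 2L, rng, "/")
  X
}

#' Assemble the full node feature matrix for a graph
#'
#' Convenience wrapper building the molecular, system and (unless
#' `node2vec_dim` is 0) node2vec blocks and normalizing them together.
#'
#' @param graph a `sample_gene_graph`.
#' @param cohort a `cohort_data`.
#' @param sys_table a [load_system_features()] matrix.
#' @param config a [dg_config()].
#' @return a `node_features` object.
#' @export
build_node_features <- function(graph, cohort, sys_table, config = dg_config()) {
  blocks <- list(molecular = molecular_features(graph, cohort),
                 system = system_features(graph, sys_table))
  if (config$node2vec_dim > 0L) {
    blocks$structural <- node2vec_embed(
      graph, dim = config$node2vec_dim, walk_length = config$walk_length,
      walks_per_node = config$walks_per_node, window = config$window,
      return_p = config$return_p, inout_q = config$inout_q,
      negative_samples = config$negative_samples,
      epochs = config$node2vec_epochs, seed = config$seed)
  }
  concat_normalize(blocks)
}

#' Write a node feature matrix and its sidecar metadata
#'
#' `features.tsv` holds the node index plus the normalized matrix;
#' `features_meta.json` records the block column ranges and the min-max
#' bounds needed to reproduce the transform at inference time.
#'
#' @param features a `node_features` object.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_node_features <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- features$X
  colnames(X) <- if (is.null(colnames(X))) paste0("f", seq_len(ncol(X))) else colnames(X)
  df <- data.frame(node_index = seq_len(nrow(X)) - 1L, X, check.names = FALSE)
  fpath <- file.path(dir, "features.tsv")
  write.table(df, fpath, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(block_spec = features$block_spec,
               bounds = list(min = unname(features$bounds["min", ]),
                             max = unname(features$bounds["max", ])))
  mpath <- file.path(dir, "features_meta.json")
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(fpath, mpath))
}
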