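# Per-patient sample-gene network construction: each patient contributes
# the PPI subgraph induced on their mutated genes united with the
# cohort-level DEGs; the cohort graph is the disjoint union of these
# subnetworks, so nodes are (sample, gene) pairs and no edge crosses
# samples.

#' Build one patient's induced subnetwork
#'
#' The patient's gene subset is the union of their mutated genes and the
#' cohort DEG set (restricted to the cohort gene universe); edges are the
#' PPI edges with both endpoints inside the subset. Genes without any
#' retained interaction stay as degree-0 nodes.
#'
#' @param sample_id patient identifier.
#' @param mutation_row named binary vector over the gene universe.
#' @param deg_set character vector of cohort DEG symbols.
#' @param ppi a [load_ppi()] table.
#' @return object of class `sample_subnet`: list with `sample_id`, `genes`
#'   (sorted) and `edges` (2-column character matrix).
#' @export
build_sample_subnet <- function(sample_id, mutation_row, deg_set, ppi) {
  if (is.null(names(mutation_row))) dg_stop("mutation_row must be named by gene")
  universe <- names(mutation_row)
  genes <- sort(union(universe[mutation_row == 1], intersect(deg_set, universe)))
  if (length(genes) == 0L) {
    warning("sample ", sample_id, " has no mutated genes and no DEGs; ",
            "it contributes zero nodes", call. = FALSE)
    edges <- matrix(character(0), ncol = 2L)
  } else {
    keep <- ppi$gene_a %in% genes & ppi$gene_b %in% genes
    edges <- cbind(ppi$gene_a[keep], ppi$gene_b[keep])
  }
  structure(list(sample_id = sample_id, genes = genes, edges = edges),
            class = "sample_subnet")
}

#' Assemble the cohort sample-gene interaction graph
#'
#' Disjoint union of per-sample subnetworks: node i carries a (sample,
#' gene) identity, the adjacency matrix is block-diagonal (symmetric,
#' zero diagonal), and the same gene mutated in two patients yields two
#' distinct nodes.
#'
#' @param subnets list of [build_sample_subnet()] results.
#' @return object of class `sample_gene_graph`: list with `nodes`
#'   (data.frame sample_id, gene), sparse `adjacency`, and empty label/mask
#'   slots.
#' @export
build_cohort_graph <- function(subnets) {
  if (length(subnets) == 0L) dg_stop("need at least one subnetwork")
  sizes <- vapply(subnets, function(s) length(s$genes), integer(1))
  if (sum(sizes) == 0L) dg_stop("all subnetworks are empty")
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  nodes <- data.frame(
    sample_id = rep(vapply(subnets, function(s) s$sample_id, character(1)), sizes),
    gene = unlist(lapply(subnets, function(s) s$genes), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  ii <- integer(0); jj <- integer(0)
  for (k in seq_along(subnets)) {
    s <- subnets[[k]]
    if (nrow(s$edges) == 0L) next
    ia <- offsets[k] + match(s$edges[, 1L], s$genes)
    ib <- offsets[k] + match(s$edges[, 2L], s$genes)
    ii <- c(ii, ia, ib)
    jj <- c(jj, ib, ia)
  }
  n <- nrow(nodes)
  adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  adj@x[] <- 1  # collapse any duplicated edge entries to binary
  structure(list(nodes = nodes, adjacency = adj,
                 labels = NULL, train_mask = NULL, test_mask = NULL),
            class = "sample_gene_graph")
}

#' @export
print.sample_gene_graph <- function(x, ...) {
  n_edges <- Matrix::nnzero(x$adjacency) / 2
  cat("sample-gene interaction graph:", nrow(x$nodes), "nodes,",
      n_edges, "edges,", length(unique(x$nodes$sample_id)), "samples\n")
  if (!is.null(x$labels))
    cat("  labels:", sum(x$labels == 1L), "positive /", sum(x$labels == 0L),
        "negative nodes\n")
  if (!is.null(x$train_mask))
    cat("  split:", sum(x$train_mask), "train /", sum(x$test_mask), "test\n")
  invisible(x)
}

#' Label graph nodes against a driver catalogue
#'
#' A node is positive (1) when its gene symbol belongs to the positive
#' driver catalogue, negative (0) otherwise — the negative set is everything
#' left after filtering out the positives.
#'
#' @param graph a `sample_gene_graph`.
#' @param catalogue a [load_labels()] catalogue (or character vector of
#'   positive symbols).
#' @return the graph with `labels` filled.
#' @export
assign_labels <- function(graph, catalogue) {
  stopifnot(inherits(graph, "sample_gene_graph"))
  positives <- toupper(as.character(catalogue))
  labels <- as.integer(graph$nodes$gene %in% positives)
  if (sum(labels == 1L) == 0L)
    dg_stop("zero positives: no graph gene appears in the driver catalogue; ",
            "the model is untrainable")
  if (sum(labels == 0L) == 0L)
    dg_stop("zero negatives: every graph gene is in the driver catalogue; ",
            "the model is untrainable")
  graph$labels <- labels
  dg_log("labels assigned: ", sum(labels == 1L), " positive / ",
         sum(labels == 0L), " negative nodes")
  graph
}

#' Split labeled nodes into train and test sets
#'
#' Stratified random split preserving the positive/negative ratio in both
#' partitions. With `by = "gene"` (the default) the split is stratified
#' over genes and every node of a gene inherits its gene's partition, so no
#' gene contributes nodes to both sides; with `by = "node"` nodes are split
#' independently.
#'
#' @param graph labeled `sample_gene_graph`.
#' @param test_fraction fraction held out (default 0.25).
#' @param seed RNG seed; the same seed always yields the same masks.
#' @param by "gene" or "node" stratification unit.
#' @return the graph with logical `train_mask` and `test_mask` filled
#'   (disjoint, exhaustive).
#' @export
split_nodes <- function(graph, test_fraction = 0.25, seed = 1L,
                        by = c("gene", "node")) {
  stopifnot(inherits(graph, "sample_gene_graph"))
  by <- match.arg(by)
  if (is.null(graph$labels)) dg_stop("labels must be assigned before splitting")
  if (test_fraction < 0 || test_fraction >= 1)
    dg_stop("test_fraction must lie in [0, 1)")
  n <- nrow(graph$nodes)
  if (test_fraction == 0) {
    warning("test_fraction is 0: all nodes assigned to training", call. = FALSE)
    graph$train_mask <- rep(TRUE, n)
    graph$test_mask <- rep(FALSE, n)
    return(graph)
  }
  if (by == "node") {
    units <- seq_len(n)
    unit_label <- graph$labels
    node_unit <- units
  } else {
    genes <- sort(unique(graph$nodes$gene))
    units <- seq_along(genes)
    unit_label <- as.integer(genes %in% graph$nodes$gene[graph$labels == 1L])
    node_unit <- match(graph$nodes$gene, genes)
  }
  test_units <- with_seed(seed, {
    out <- integer(0)
    for (lab in c(0L, 1L)) {
      stratum <- units[unit_label == lab]
      if (length(stratum) < 2L)
        dg_stop("stratum with label ", lab, " has fewer than 2 ", by, "s (",
                length(stratum), "); cannot split")
      n_test <- round(length(stratum) * test_fraction)
      out <- c(out, sample(stratum, n_test))
    }
    out
  })
  graph$test_mask <- node_unit %in% test_units
  graph$train_mask <- !graph$test_mask
  dg_log("split (", by, "-level): ", sum(graph$train_mask), " train / ",
         sum(graph$test_mask), " test nodes")
  graph
}

#' Export a graph as plain-text node and edge tables
#'
#' Writes `nodes.tsv` (sample_id, gene, label, mask) and `edges.tsv`
#' (0-based node index pairs, one row per undirected edge).
#'
#' @param graph a `sample_gene_graph`.
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask <- if (is.null(graph$train_mask)) NA_character_
          else ifelse(graph$train_mask, "train", "test")
  nodes <- data.frame(graph$nodes,
                      label = if (is.null(graph$labels)) NA_integer_ else graph$labels,
                      mask = mask, stringsAsFactors = FALSE)
  node_path <- file.path(dir, "nodes.tsv")
  write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tri <- Matrix::triu(graph$adjacency)
  idx <- Matrix::which(tri != 0, arr.ind = TRUE)
  edges <- data.frame(node_index_a = idx[, 1L] - 1L, node_index_b = idx[, 2L] - 1L)
  edges <- edges[order(edges$node_index_a, edges$node_index_b), , drop = FALSE]
  edge_path <- file.path(dir, "edges.tsv")
  write.table(edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(node_path, edge_path))
}
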