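# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures.

options(driverGCN.verbose = 0)

# a tiny sample-gene graph from an explicit adjacency matrix
graph_from_adjacency <- function(A, sample_id = "s1",
                                 genes = sprintf("g%d", seq_len(nrow(A)))) {
  structure(list(nodes = data.frame(sample_id = sample_id, gene = genes,
                                    stringsAsFactors = FALSE),
                 adjacency = Matrix::Matrix(A, sparse = TRUE),
                 labels = NULL, train_mask = NULL, test_mask = NULL),
            class = "sample_gene_graph")
}

# random symmetric binary adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1L, p)
  A + t(A)
}

# adjacency of two disjoint k-cliques
two_clique_adjacency <- function(k = 5L) {
  A <- matrix(0, 2L * k, 2L * k)
  A[seq_len(k), seq_len(k)] <- 1
  A[k + seq_len(k), k + seq_len(k)] <- 1
  diag(A) <- 0
  A
}

# a small labeled + split graph with features, for model-level tests
tiny_model_fixture <- function(seed = 42L, n = 12L, f = 5L) {
  set.seed(seed)
  A <- random_adjacency(n, 0.35)
  graph <- graph_from_adjacency(A)
  graph$labels <- rep_len(c(1L, 0L, 0L), n)
  graph$train_mask <- rep_len(c(TRUE, TRUE, TRUE, FALSE), n)
  graph$test_mask <- !graph$train_mask
  X <- matrix(runif(n * f), n, f)
  list(graph = graph, X = X)
}

# write a samples x genes matrix as the TSV dialect the loaders read
write_tsv_matrix <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal cohort TSV file set in a temp dir; returns the paths
write_tiny_cohort_files <- function(dir,
                                    samples = c("s1", "s2", "s3"),
                                    genes = c("g1", "g2", "g3", "g4")) {
  ns <- length(samples); ng <- length(genes)
  set.seed(7)
  mk <- function(gen) {
    m <- matrix(gen(ns * ng), ns, ng, dimnames = list(samples, genes))
    m
  }
  paths <- list(
    mutation = file.path(dir, "mutation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    cnv = file.path(dir, "cnv.tsv")
  )
  write_tsv_matrix(mk(function(k) rbinom(k, 1, 0.3)), paths$mutation)
  write_tsv_matrix(mk(function(k) round(rnorm(k, 6, 1), 6)), paths$expression)
  write_tsv_matrix(mk(function(k) round(runif(k), 6)), paths$methylation)
  write_tsv_matrix(mk(function(k) sample(-2:2, k, replace = TRUE)), paths$cnv)
  paths
}
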