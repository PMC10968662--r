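# Evaluation and ranking: threshold metrics on masked nodes, per-sample
# ranked driver lists, top-k overlap with a reference catalogue,
# per-sample hit counts and rare-driver flagging.

#' Accuracy, AUC and AUPR on masked nodes
#'
#' Accuracy is computed at the given threshold; AUC is the area under the
#' ROC curve by the trapezoidal rule over all score thresholds (equal to
#' the normalized Mann-Whitney U statistic, ties counted half); AUPR is
#' the area under the precision-recall curve with step-wise
#' interpolation, the convention for imbalanced classes.
#'
#' @param scores numeric node scores.
#' @param labels binary labels.
#' @param mask logical or index vector selecting the evaluated nodes
#'   (default all).
#' @param threshold classification cutoff for accuracy (default 0.5).
#' @return named numeric vector `c(acc, auc, aupr)`.
#' @export
compute_metrics <- function(scores, labels, mask = NULL, threshold = 0.5) {
  if (!is.null(mask)) { scores <- scores[mask]; labels <- labels[mask] }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    dg_stop("AUC/AUPR undefined: mask holds a single class (",
            n_pos, " positives, ", n_neg, " negatives)")
  acc <- mean((scores >= threshold) == (labels == 1))

  # sweep thresholds from high to low, grouping tied scores
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_last <- which(s != c(s[-1L], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(1 - y)[grp_last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)

  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  aupr <- sum(diff(c(0, rec)) * prec)

  c(acc = acc, auc = auc, aupr = aupr)
}

#' Rank genes per sample and at the population level
#'
#' Each sample's genes are ranked by descending score with ties broken
#' lexicographically by gene symbol. The population-level gene ranking
#' aggregates each gene's node scores across samples (`"max"` by default:
#' a gene driving any one patient strongly ranks high; `"mean"`
#' available).
#'
#' @param scores data.frame from [predict.driver_gcn()] (columns
#'   sample_id, gene, score).
#' @param aggregate "max" or "mean" population aggregation.
#' @return object of class `prediction_result`: list with `per_sample`
#'   (named list of ranked data.frames), `population` (ranked data.frame
#'   gene/score), and `scores` (the input).
#' @export
rank_predictions <- function(scores, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("sample_id", "gene", "score") %in% names(scores)))
  per_sample <- lapply(split(scores, scores$sample_id), function(df) {
    df <- df[order(-df$score, df$gene), c("gene", "score"), drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    df
  })
  agg_fun <- if (aggregate == "max") max else mean
  pop <- vapply(split(scores$score, scores$gene), agg_fun, numeric(1))
  population <- data.frame(gene = names(pop), score = unname(pop),
                           stringsAsFactors = FALSE)
  population <- population[order(-population$score, population$gene), , drop = FALSE]
  population$rank <- seq_len(nrow(population))
  rownames(population) <- NULL
  structure(list(per_sample = per_sample, population = population,
                 scores = scores, aggregate = aggregate),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("driver-gene predictions:", nrow(x$scores), "nodes over",
      length(x$per_sample), "samples;", nrow(x$population),
      "genes in the population ranking (", x$aggregate, "aggregation )\n")
  cat("top population genes:",
      paste(head(x$population$gene, 5L), collapse = ", "), "\n")
  invisible(x)
}

#' Top-k precision, recall and F1 against a reference catalogue
#'
#' P = |top-k intersect reference| / k, R = |top-k intersect reference| /
#' |reference|, F1 = 2PR / (P + R) with the defined limit 0 when
#' P = R = 0.
#'
#' @param ranked_genes character vector in rank order.
#' @param reference character vector of reference driver genes (non-empty).
#' @param k list length cut (k <= length(ranked_genes)).
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
topk_overlap <- function(ranked_genes, reference, k) {
  if (length(reference) == 0L) dg_stop("reference gene set is empty")
  if (k > length(ranked_genes))
    dg_stop("k = ", k, " exceeds the ranked list length ", length(ranked_genes))
  hits <- length(intersect(ranked_genes[seq_len(k)], reference))
  p <- hits / k
  r <- hits / length(unique(reference))
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Per-sample reference hits in the top-k
#'
#' For each sample and each k, the number of genes among the sample's
#' top-k that belong to the reference catalogue. Samples with fewer than
#' k genes use their whole list (noted in the log).
#'
#' @param result a [rank_predictions()] object.
#' @param reference character vector of reference driver genes.
#' @param k_list integer vector of list cuts (default c(50, 100)).
#' @return data.frame with columns `sample_id`, `k`, `n_genes`, `hits`.
#' @export
per_sample_hits <- function(result, reference, k_list = c(50L, 100L)) {
  stopifnot(inherits(result, "prediction_result"))
  reference <- unique(toupper(reference))
  rows <- list()
  short_noted <- FALSE
  for (sid in names(result$per_sample)) {
    genes <- result$per_sample[[sid]]$gene
    for (k in k_list) {
      kk <- min(k, length(genes))
      if (kk < k && !short_noted) {
        dg_log("some samples have fewer than ", k,
               " genes; their full lists are used")
        short_noted <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, k = k, n_genes = length(genes),
        hits = length(intersect(genes[seq_len(kk)], reference)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Flag rare predicted drivers
#'
#' A gene appearing in any sample's top-k is a rare driver when its
#' cohort mutation frequency (# mutated samples / # samples) is below
#' `frequency_threshold` (default 2%) while being mutated in at least one
#' sample — unmutated DEG-only genes are never flagged.
#'
#' @param result a [rank_predictions()] object.
#' @param mutation_matrix the cohort's samples x genes binary mutation
#'   matrix.
#' @param frequency_threshold rare cutoff on the mutation frequency
#'   (default 0.02).
#' @param k per-sample list cut defining candidacy (default 50).
#' @return data.frame with columns `gene`, `mutation_frequency`,
#'   `n_samples_mutated`, `n_samples_topk`, `rare`.
#' @export
flag_rare_drivers <- function(result, mutation_matrix,
                              frequency_threshold = 0.02, k = 50L) {
  stopifnot(inherits(result, "prediction_result"))
  topk_genes <- lapply(result$per_sample, function(df)
    df$gene[seq_len(min(k, nrow(df)))])
  candidates <- sort(unique(unlist(topk_genes)))
  n_samples <- nrow(mutation_matrix)
  gi <- match(candidates, colnames(mutation_matrix))
  n_mut <- ifelse(is.na(gi), 0L, colSums(mutation_matrix)[gi])
  freq <- n_mut / n_samples
  n_topk <- vapply(candidates, function(g)
    sum(vapply(topk_genes, function(v) g %in% v, logical(1))), integer(1))
  out <- data.frame(gene = candidates,
                    mutation_frequency = freq,
                    n_samples_mutated = as.integer(n_mut),
                    n_samples_topk = n_topk,
                    rare = freq < frequency_threshold & n_mut > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Full evaluation report
#'
#' Bundles threshold metrics on train and test masks, top-k
#' precision/recall/F1 of the population ranking against the reference,
#' per-sample hit counts, and the rare-driver table.
#'
#' @param result a [rank_predictions()] object.
#' @param graph the labeled, split `sample_gene_graph` the scores came from.
#' @param reference character vector of reference driver genes.
#' @param mutation_matrix cohort binary mutation matrix.
#' @param k_list cuts for top-k metrics (default c(50, 100)).
#' @param rare_k list cut for rare-driver candidacy (default 50).
#' @param frequency_threshold rare-driver mutation-frequency cutoff.
#' @return object of class `evaluation_report` (list of data.frames).
#' @export
evaluate_predictions <- function(result, graph, reference, mutation_matrix,
                                 k_list = c(50L, 100L), rare_k = 50L,
                                 frequency_threshold = 0.02) {
  stopifnot(inherits(result, "prediction_result"),
            inherits(graph, "sample_gene_graph"))
  scores <- result$scores$score
  metrics <- rbind(
    data.frame(set = "train",
               t(compute_metrics(scores, graph$labels, graph$train_mask))),
    if (any(graph$test_mask))
      data.frame(set = "test",
                 t(compute_metrics(scores, graph$labels, graph$test_mask)))
  )
  pop <- result$population$gene
  topk <- do.call(rbind, lapply(k_list, function(k) {
    kk <- min(k, length(pop))
    data.frame(k = k, t(topk_overlap(pop, reference, kk)))
  }))
  hits <- per_sample_hits(result, reference, k_list)
  rare <- flag_rare_drivers(result, mutation_matrix,
                            frequency_threshold = frequency_threshold, k = rare_k)
  structure(list(metrics = metrics, topk = topk, per_sample_hits = hits,
                 rare_drivers = rare),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation report\n")
  print(x$metrics, row.names = FALSE)
  cat("population top-k vs reference:\n")
  print(x$topk, row.names = FALSE)
  cat(sum(x$rare_drivers$rare), "rare driver gene(s) flagged of",
      nrow(x$rare_drivers), "top-k candidates\n")
  invisible(x)
}

#' Write evaluation reports and ranked lists as plain text
#'
#' Emits `metrics.tsv`, `topk_overlap.tsv`, `per_sample_hits.tsv`,
#' `rare_drivers.tsv`, `rankings.tsv` (sample_id, rank, gene, score) and
#' a JSON `summary.json`.
#'
#' @param report an `evaluation_report`.
#' @param result the matching `prediction_result`.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_reports <- function(report, result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$metrics, "metrics.tsv")
  wr(report$topk, "topk_overlap.tsv")
  wr(report$per_sample_hits, "per_sample_hits.tsv")
  wr(report$rare_drivers, "rare_drivers.tsv")
  rankings <- do.call(rbind, lapply(names(result$per_sample), function(sid) {
    df <- result$per_sample[[sid]]
    data.frame(sample_id = sid, rank = df$rank, gene = df$gene,
               score = df$score, stringsAsFactors = FALSE)
  }))
  wr(rankings, "rankings.tsv")
  summ <- list(
    metrics = split(report$metrics[, c("acc", "auc", "aupr")], report$metrics$set),
    topk = report$topk,
    n_rare_drivers = sum(report$rare_drivers$rare)
  )
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, jp, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths <- c(paths, jp)
  invisible(paths)
}
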