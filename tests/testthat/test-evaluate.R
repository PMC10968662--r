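# Metrics, rankings, top-k overlap, per-sample hits, rare drivers.

test_that("threshold metrics match a brute-force confusion table", {
  scores <- c(0.9, 0.8, 0.3, 0.1)
  labels <- c(1, 0, 1, 0)
  m <- compute_metrics(scores, labels, threshold = 0.5)
  # confusion at 0.5: TP=1 (0.9), FP=1 (0.8), FN=1 (0.3), TN=1 (0.1)
  expect_equal(unname(m["acc"]), 0.5)
  scores2 <- c(0.9, 0.8, 0.6, 0.1)
  m2 <- compute_metrics(scores2, c(1, 0, 1, 0), threshold = 0.5)
  expect_equal(unname(m2["acc"]), 0.75)  # TP=2, FP=1, TN=1, FN=0
  # perfect separation
  mp <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(mp["auc"]), 1)
  expect_equal(unname(mp["aupr"]), 1)
  expect_error(compute_metrics(scores, c(1, 1, 1, 1)), "single class")
})

test_that("trapezoidal AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    # granular scores force ties into the comparison
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    auc <- unname(compute_metrics(scores, labels)["auc"])
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    u <- sum(vapply(pos, function(s) sum(s > neg) + 0.5 * sum(s == neg),
                    numeric(1)))
    expect_lt(abs(auc - u / (length(pos) * length(neg))), 1e-10)
  }
})

test_that("random scores give AUC near one half", {
  set.seed(15)
  aucs <- replicate(200, {
    labels <- rep(c(1, 0), c(30, 70))
    compute_metrics(runif(100), labels)["auc"]
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("top-k overlap implements the P/R/F1 formulas and limits", {
  reference <- sprintf("R%03d", 1:719)
  ranked <- c(sprintf("R%03d", 1:30), sprintf("X%03d", 1:70))
  m <- topk_overlap(ranked, reference, 100)
  expect_equal(unname(m["precision"]), 0.300, tolerance = 1e-12)
  expect_equal(unname(m["recall"]), 30 / 719, tolerance = 1e-12)
  expect_equal(unname(m["f1"]), 2 * 0.3 * (30 / 719) / (0.3 + 30 / 719),
               tolerance = 1e-12)
  expect_equal(unname(m["recall"]), 0.04172, tolerance = 1e-3)
  expect_equal(unname(m["f1"]), 0.07325, tolerance = 1e-3)
  # top-k entirely inside the reference with k = |reference|
  all_in <- topk_overlap(reference, reference, 719)
  expect_identical(unname(all_in), c(1, 1, 1))
  # zero hits: defined limit F1 = 0
  expect_identical(unname(topk_overlap(c("A", "B"), c("C"), 2)), c(0, 0, 0))
  expect_error(topk_overlap(ranked, character(0), 10), "empty")
  expect_error(topk_overlap(ranked, reference, 1000), "exceeds")
})

test_that("top-k precision/recall monotonicity holds", {
  set.seed(16)
  reference <- sprintf("R%02d", 1:40)
  # reference-prefix-ordered list: precision non-increasing in k
  ranked <- c(sample(reference, 25), sprintf("X%02d", 1:40))
  prec <- vapply(1:60, function(k) topk_overlap(ranked, reference, k)["precision"],
                 numeric(1))
  expect_true(all(diff(prec) <= 1e-12))
  # recall non-decreasing in k for any list
  shuffled <- sample(c(reference, sprintf("X%02d", 1:40)))
  rec <- vapply(1:80, function(k) topk_overlap(shuffled, reference, k)["recall"],
                numeric(1))
  expect_true(all(diff(rec) >= -1e-12))
})

test_that("per-sample ranked lists are score-sorted permutations with ties by symbol", {
  scores <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    gene = c("GB", "GA", "GC", "GZ", "GY", "GX"),
    score = c(0.5, 0.5, 0.9, 0.2, 0.8, 0.8))
  res <- rank_predictions(scores)
  expect_identical(res$per_sample$s1$gene, c("GC", "GA", "GB"))  # tie -> GA first
  expect_identical(res$per_sample$s2$gene, c("GX", "GY", "GZ"))
  expect_true(all(diff(res$per_sample$s1$score) <= 0))
  # population aggregation: max by default, mean on request
  expect_equal(res$population$score[res$population$gene == "GA"], 0.5)
  res_mean <- rank_predictions(scores, aggregate = "mean")
  expect_equal(res_mean$population$score[res_mean$population$gene == "GA"], 0.5)
})

test_that("per-sample hit counts equal brute-force set intersections", {
  set.seed(18)
  samples <- sprintf("s%02d", 1:20)
  genes <- sprintf("G%03d", 1:60)
  scores <- do.call(rbind, lapply(samples, function(s) {
    gs <- sample(genes, sample(5:15, 1))
    data.frame(sample_id = s, gene = gs, score = runif(length(gs)))
  }))
  reference <- sample(genes, 12)
  res <- rank_predictions(scores)
  hits <- per_sample_hits(res, reference, k_list = c(5L, 50L))
  for (i in seq_len(nrow(hits))) {
    sid <- hits$sample_id[i]; k <- hits$k[i]
    lst <- res$per_sample[[sid]]$gene
    oracle <- length(intersect(lst[seq_len(min(k, length(lst)))], reference))
    expect_identical(hits$hits[i], oracle)
  }
  # k beyond the list length falls back to the full list
  expect_true(all(hits$hits[hits$k == 50] <=
                    hits$n_genes[hits$k == 50]))
  # disjoint reference: all zero
  hits0 <- per_sample_hits(res, c("NOPE"), k_list = 5L)
  expect_true(all(hits0$hits == 0L))
})

test_that("rare-driver flagging applies the <2% mutation-frequency rule", {
  # 77-sample cohort: 1 mutated sample -> 1.3% -> rare
  mut77 <- matrix(0, 77, 2, dimnames = list(sprintf("s%02d", 1:77), c("GR", "GD")))
  mut77[1, "GR"] <- 1
  scores <- data.frame(sample_id = "s01", gene = c("GR", "GD"),
                       score = c(0.9, 0.8))
  res <- rank_predictions(scores)
  tab <- flag_rare_drivers(res, mut77, frequency_threshold = 0.02, k = 50L)
  expect_true(tab$rare[tab$gene == "GR"])
  expect_equal(tab$mutation_frequency[tab$gene == "GR"], 1 / 77, tolerance = 1e-12)
  # unmutated gene in the top-k is never flagged
  expect_false(tab$rare[tab$gene == "GD"])
  # 66-sample cohort: 2 mutated samples -> 3.0% -> not rare
  mut66 <- matrix(0, 66, 1, dimnames = list(sprintf("s%02d", 1:66), "GF"))
  mut66[1:2, "GF"] <- 1
  scores66 <- data.frame(sample_id = "s01", gene = "GF", score = 0.7)
  tab66 <- flag_rare_drivers(rank_predictions(scores66), mut66)
  expect_false(tab66$rare[1])
  expect_equal(tab66$mutation_frequency[1], 2 / 66, tolerance = 1e-12)
})

test_that("report numbers are invariant to sample relabeling", {
  set.seed(19)
  sim <- sim_config(n_samples = 8L, n_genes = 60L, n_drivers = 10L, seed = 23L)
  bundle <- simulate_cohort(sim)
  cfg <- dg_config(seed = 23L, epochs = 30L, hidden_dim = 8L,
                   node2vec_dim = 4L, walk_length = 10L, walks_per_node = 2L,
                   node2vec_epochs = 1L)
  run <- run_pipeline(sim, cfg)
  # relabel samples bijectively and recompute the evaluation
  map <- setNames(sprintf("Z%03d", seq_along(bundle$cohort$sample_ids)),
                  bundle$cohort$sample_ids)
  scores2 <- run$scores
  scores2$sample_id <- unname(map[scores2$sample_id])
  graph2 <- run$graph
  graph2$nodes$sample_id <- unname(map[graph2$nodes$sample_id])
  mut2 <- run$bundle$cohort$mutation
  rownames(mut2) <- unname(map[rownames(mut2)])
  rep2 <- evaluate_predictions(rank_predictions(scores2), graph2,
                               as.character(bundle$labels), mut2)
  expect_equal(rep2$metrics, run$report$metrics, tolerance = 1e-12)
  expect_equal(rep2$topk, run$report$topk, tolerance = 1e-12)
  expect_identical(sort(rep2$per_sample_hits$hits),
                   sort(run$report$per_sample_hits$hits))
  expect_equal(rep2$rare_drivers$rare, run$report$rare_drivers$rare)
})
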