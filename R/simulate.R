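# Synthetic multi-omics cohort generator with planted driver signal.
# Emulates the shapes of the real inputs (four tumor omics matrices,
# control expression, a STRING-style edge list, an 18-column gene
# property table, a positive gene list) so the whole pipeline runs with
# no external download. Drivers carry correlated multi-omics signal —
# elevated mutation rate, expression/methylation shifts in mutated
# samples, copy-number events, offset system-level properties and
# preferential hub placement in the interaction network — and every
# channel can be nulled independently.

SYSTEM_FEATURE_NAMES <- c(
  "gene_length", "protein_length", "domain_count", "gene_age",
  "essentiality", "expression_breadth", "replication_time", "gc_content",
  "exon_count", "paralog_count", "conservation_score", "dnds_ratio",
  "promoter_cpg", "complex_membership", "regulator_count", "mirna_sites",
  "protein_abundance", "halflife")

#' Simulation configuration
#'
#' Defaults define a 20-sample, 300-gene cohort with 30 planted drivers:
#' drivers are mutated at rate 0.4 against a 0.02 background, gain a +3
#' log2 expression shift and a +0.2 methylation shift in samples where
#' they are mutated, carry copy-number events with probability 0.3, have
#' their 18 system-level properties offset by +1 SD, and attach to the
#' scale-free interaction network with 3x hub weight.
#'
#' @param n_samples,n_genes,n_drivers cohort dimensions (n_drivers < n_genes).
#' @param ppi_m preferential-attachment edges added per gene.
#' @param driver_hub_boost extra attachment weight for driver genes.
#' @param driver_mutation_rate,background_mutation_rate Bernoulli mutation
#'   rates.
#' @param expression_shift mean log2 expression shift of a mutated driver.
#' @param methylation_shift beta-value shift of a mutated driver.
#' @param cnv_driver_prob probability of a nonzero copy-number category in
#'   a driver entry (background events are rare regardless).
#' @param system_offset mean offset of the drivers' 18 system features.
#' @param n_controls control expression samples for DEG calling.
#' @param noise_sd expression noise standard deviation.
#' @param seed mandatory integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20L, n_genes = 300L, n_drivers = 30L,
                       ppi_m = 3L, driver_hub_boost = 3,
                       driver_mutation_rate = 0.4,
                       background_mutation_rate = 0.02,
                       expression_shift = 3,
                       methylation_shift = 0.2,
                       cnv_driver_prob = 0.3,
                       system_offset = 1,
                       n_controls = 20L,
                       noise_sd = 0.5,
                       seed) {
  if (missing(seed)) dg_stop("sim_config requires an explicit seed")
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_drivers = as.integer(n_drivers), ppi_m = as.integer(ppi_m),
              driver_hub_boost = as.numeric(driver_hub_boost),
              driver_mutation_rate = as.numeric(driver_mutation_rate),
              background_mutation_rate = as.numeric(background_mutation_rate),
              expression_shift = as.numeric(expression_shift),
              methylation_shift = as.numeric(methylation_shift),
              cnv_driver_prob = as.numeric(cnv_driver_prob),
              system_offset = as.numeric(system_offset),
              n_controls = as.integer(n_controls),
              noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed))
  with(cfg, {
    if (n_drivers >= n_genes) dg_stop("n_drivers must be < n_genes")
    if (n_drivers < 0L || n_samples < 1L || n_genes < 2L)
      dg_stop("invalid cohort dimensions")
    if (ppi_m >= n_genes) dg_stop("infeasible config: ppi_m >= n_genes")
    rates <- c(driver_mutation_rate, background_mutation_rate, cnv_driver_prob)
    if (any(rates < 0 | rates >= 1)) dg_stop("rates must lie in [0, 1)")
    if (noise_sd < 0) dg_stop("noise_sd must be >= 0")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Null-signal variant of a simulation configuration
#'
#' Sets every driver-specific signal channel to its background value:
#' drivers mutate at the common rate, no expression/methylation shift, no
#' excess copy-number events, no system-feature offset, no hub boost.
#' The common mutation rate is raised so the graph keeps a comparable
#' node count and enough positive test nodes for a stable AUC estimate.
#'
#' @param config a `sim_config` to null (defaults applied if missing).
#' @param mutation_rate the common mutation rate for all genes.
#' @return a `sim_config`.
#' @export
null_config <- function(config = sim_config(seed = 0L), mutation_rate = 0.3) {
  config$driver_mutation_rate <- mutation_rate
  config$background_mutation_rate <- mutation_rate
  config$expression_shift <- 0
  config$methylation_shift <- 0
  config$cnv_driver_prob <- 0
  config$system_offset <- 0
  config$driver_hub_boost <- 1
  config
}

# weighted preferential attachment; drivers get boosted attachment weight
simulate_ppi <- function(genes, drivers, m, boost) {
  n <- length(genes)
  is_driver <- genes %in% drivers
  order_in <- sample.int(n)  # insertion order
  weight <- numeric(n)       # (degree + 1) * boost factor
  boost_f <- ifelse(is_driver, boost, 1)
  edges_a <- integer(0); edges_b <- integer(0)
  seed_n <- min(m + 1L, n)
  first <- order_in[seq_len(seed_n)]
  # seed clique
  for (i in seq_len(seed_n - 1L)) {
    edges_a <- c(edges_a, rep(first[i], seed_n - i))
    edges_b <- c(edges_b, first[(i + 1L):seed_n])
  }
  deg <- tabulate(c(edges_a, edges_b), n)
  weight[first] <- (deg[first] + 1) * boost_f[first]
  if (n > seed_n) {
    for (k in (seed_n + 1L):n) {
      v <- order_in[k]
      existing <- order_in[seq_len(k - 1L)]
      w <- weight[existing]
      n_new <- min(m, length(existing))
      targets <- existing[sample.int(length(existing), n_new, prob = w)]
      edges_a <- c(edges_a, rep(v, n_new))
      edges_b <- c(edges_b, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- n_new
      weight[targets] <- (deg[targets] + 1) * boost_f[targets]
      weight[v] <- (deg[v] + 1) * boost_f[v]
    }
  }
  data.frame(gene_a = genes[pmin(edges_a, edges_b)],
             gene_b = genes[pmax(edges_a, edges_b)],
             score = round(runif(length(edges_a), 700, 999), 1),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Generates aligned omics matrices, a control expression matrix, a
#' scale-free interaction table, the 18-column system feature table, the
#' planted driver catalogue and a ground-truth record, all reproducible
#' from the config seed.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (`cohort_data`), `ppi`
#'   (`ppi_table`), `system_features`, `labels` (`label_catalogue`) and
#'   `truth` (driver genes, per-sample mutated drivers, config echo).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    samples <- sprintf("S%03d", seq_len(cfg$n_samples))
    controls <- sprintf("C%03d", seq_len(cfg$n_controls))
    drivers <- sort(sample(genes, cfg$n_drivers))
    is_driver <- genes %in% drivers

    # mutation
    rate <- ifelse(is_driver, cfg$driver_mutation_rate, cfg$background_mutation_rate)
    mutation <- matrix(rbinom(cfg$n_samples * cfg$n_genes, 1L,
                              rep(rate, each = cfg$n_samples)),
                       cfg$n_samples, cfg$n_genes,
                       dimnames = list(samples, genes))
    storage.mode(mutation) <- "double"

    # expression: per-gene baseline + driver shift where mutated + noise
    baseline <- rnorm(cfg$n_genes, mean = 6, sd = 1)
    expr <- matrix(rep(baseline, each = cfg$n_samples),
                   cfg$n_samples, cfg$n_genes, dimnames = list(samples, genes))
    shift <- mutation * rep(is_driver * cfg$expression_shift, each = cfg$n_samples)
    expr <- expr + shift + matrix(rnorm(length(expr), 0, cfg$noise_sd),
                                  nrow(expr), ncol(expr))
    ctrl <- matrix(rep(baseline, each = cfg$n_controls),
                   cfg$n_controls, cfg$n_genes, dimnames = list(controls, genes)) +
      matrix(rnorm(cfg$n_controls * cfg$n_genes, 0, cfg$noise_sd),
             cfg$n_controls, cfg$n_genes)

    # methylation: Beta(2, 2) baseline, shifted for mutated drivers, clipped
    meth <- matrix(rbeta(cfg$n_samples * cfg$n_genes, 2, 2),
                   cfg$n_samples, cfg$n_genes, dimnames = list(samples, genes))
    meth <- meth + mutation * rep(is_driver * cfg$methylation_shift,
                                  each = cfg$n_samples)
    meth <- pmin(pmax(meth, 0), 1)

    # copy number: rare background events, driver events at cnv_driver_prob
    cnv_cats <- c(-2L, -1L, 1L, 2L)
    p_event <- ifelse(is_driver, cfg$cnv_driver_prob, 0.02)
    event <- matrix(rbinom(cfg$n_samples * cfg$n_genes, 1L,
                           rep(p_event, each = cfg$n_samples)),
                    cfg$n_samples, cfg$n_genes)
    cats <- matrix(sample(cnv_cats, cfg$n_samples * cfg$n_genes, replace = TRUE),
                   cfg$n_samples, cfg$n_genes)
    cnv <- event * cats
    dimnames(cnv) <- list(samples, genes)
    storage.mode(cnv) <- "double"

    # system-level properties: standard normal, drivers offset
    sysfeat <- matrix(rnorm(cfg$n_genes * 18L), cfg$n_genes, 18L,
                      dimnames = list(genes, SYSTEM_FEATURE_NAMES))
    sysfeat[is_driver, ] <- sysfeat[is_driver, ] + cfg$system_offset
    class(sysfeat) <- c("system_features", class(sysfeat))

    ppi <- simulate_ppi(genes, drivers, cfg$ppi_m, cfg$driver_hub_boost)
    ppi <- ppi[order(ppi$gene_a, ppi$gene_b), , drop = FALSE]
    rownames(ppi) <- NULL
    attr(ppi, "score_threshold") <- 0
    class(ppi) <- c("ppi_table", "data.frame")

    cohort <- structure(list(sample_ids = samples, gene_ids = genes,
                             mutation = mutation, expression = expr,
                             methylation = meth, cnv = cnv,
                             control_expression = ctrl),
                        class = "cohort_data")
    labels <- structure(drivers, class = "label_catalogue")
    mutated_drivers <- lapply(samples, function(s)
      drivers[mutation[s, drivers] == 1])
    names(mutated_drivers) <- samples
    truth <- list(driver_genes = drivers,
                  mutated_drivers = mutated_drivers,
                  config = unclass(cfg))
    list(cohort = cohort, ppi = ppi, system_features = sysfeat,
         labels = labels, truth = truth)
  })
}

#' Write a simulated cohort bundle to disk
#'
#' Produces exactly the formats the loaders read — `mutation.tsv`,
#' `expression.tsv`, `methylation.tsv`, `cnv.tsv`,
#' `control_expression.tsv`, `ppi.tsv`, `system_features.tsv`,
#' `driver_genes.txt` — plus `truth.json` and a `manifest.json` listing
#' every file with its row/column counts.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) dg_stop("cannot create output directory ", dir)
  }
  co <- bundle$cohort
  paths <- c(
    mutation = file.path(dir, "mutation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    cnv = file.path(dir, "cnv.tsv"),
    control_expression = file.path(dir, "control_expression.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    system_features = file.path(dir, "system_features.tsv"),
    driver_genes = file.path(dir, "driver_genes.txt"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "manifest.json")
  )
  write_matrix_tsv(co$mutation, paths["mutation"])
  write_matrix_tsv(co$expression, paths["expression"])
  write_matrix_tsv(co$methylation, paths["methylation"])
  write_matrix_tsv(co$cnv, paths["cnv"])
  write_matrix_tsv(co$control_expression, paths["control_expression"])
  write.table(bundle$ppi, paths["ppi"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(unclass(bundle$system_features), paths["system_features"],
                   id_col = "gene")
  writeLines(as.character(bundle$labels), paths["driver_genes"])
  jsonlite::write_json(bundle$truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  manifest <- lapply(names(paths), function(nm) {
    p <- paths[[nm]]
    entry <- list(file = basename(p))
    if (nm %in% c("mutation", "expression", "methylation", "cnv")) {
      entry$rows <- nrow(co[[nm]]); entry$cols <- ncol(co[[nm]])
    } else if (nm == "control_expression") {
      entry$rows <- nrow(co$control_expression); entry$cols <- ncol(co$control_expression)
    } else if (nm == "ppi") {
      entry$rows <- nrow(bundle$ppi); entry$cols <- 3L
    } else if (nm == "system_features") {
      entry$rows <- nrow(bundle$system_features); entry$cols <- 18L
    } else if (nm == "driver_genes") {
      entry$rows <- length(bundle$labels); entry$cols <- 1L
    }
    entry
  })
  names(manifest) <- names(paths)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
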