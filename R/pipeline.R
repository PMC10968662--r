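# End-to-end orchestration: simulate (or load) -> DEGs -> per-sample
# subnetworks -> cohort graph -> labels/split -> features -> fit ->
# predict -> evaluate. Used by the command-line interface, the examples
# and the acceptance runs.

#' Build the labeled cohort graph from loaded inputs
#'
#' Calls the cohort DEGs (when a control matrix is present), builds one
#' induced subnetwork per patient, takes the disjoint union, assigns
#' labels from the driver catalogue and splits the nodes.
#'
#' @param cohort a `cohort_data`.
#' @param ppi a `ppi_table`.
#' @param labels a `label_catalogue` (or character vector).
#' @param config a [dg_config()].
#' @param deg_genes optional externally supplied DEG list bypassing the
#'   internal caller.
#' @return a labeled, split `sample_gene_graph` with the DEG result as
#'   attribute `"degs"`.
#' @export
build_labeled_graph <- function(cohort, ppi, labels, config = dg_config(),
                                deg_genes = NULL) {
  degs <- NULL
  if (is.null(deg_genes)) {
    if (!is.null(cohort$control_expression)) {
      degs <- call_degs(cohort$expression, cohort$control_expression,
                        config$deg_alpha, config$deg_lfc)
      deg_genes <- deg_set(degs)
    } else {
      dg_log("no control expression available: gene subsets use mutated genes only")
      deg_genes <- character(0)
    }
  }
  subnets <- lapply(cohort$sample_ids, function(s)
    build_sample_subnet(s, cohort$mutation[s, ], deg_genes, ppi))
  graph <- build_cohort_graph(subnets)
  graph <- assign_labels(graph, labels)
  graph <- split_nodes(graph, config$test_fraction, config$seed,
                       by = config$split_by)
  attr(graph, "degs") <- degs
  graph
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort, builds the labeled sample-gene graph, assembles
#' node features, fits the GCN-CRF model, scores every node and
#' evaluates against the planted driver catalogue.
#'
#' @param sim a [sim_config()].
#' @param config a [dg_config()].
#' @param out_dir optional directory for report files
#'   ([write_reports()]).
#' @return list with `bundle`, `graph`, `features`, `model`, `scores`,
#'   `result`, `report`.
#' @export
run_pipeline <- function(sim, config = dg_config(), out_dir = NULL) {
  bundle <- simulate_cohort(sim)
  run_pipeline_on(bundle$cohort, bundle$ppi, bundle$system_features,
                  bundle$labels, config, out_dir = out_dir, bundle = bundle)
}

#' Run the pipeline on loaded (non-simulated) inputs
#'
#' @param cohort,ppi,sys_table,labels loaded inputs.
#' @param config a [dg_config()].
#' @param out_dir optional report directory.
#' @param bundle internal (simulated bundle pass-through).
#' @return same structure as [run_pipeline()].
#' @export
run_pipeline_on <- function(cohort, ppi, sys_table, labels,
                            config = dg_config(), out_dir = NULL,
                            bundle = NULL) {
  graph <- build_labeled_graph(cohort, ppi, labels, config)
  features <- build_node_features(graph, cohort, sys_table, config)
  model <- driver_gcn(graph, features, config)
  scores <- predict(model, graph, features)
  result <- rank_predictions(scores)
  report <- evaluate_predictions(result, graph, as.character(labels),
                                 cohort$mutation)
  if (!is.null(out_dir)) write_reports(report, result, out_dir)
  list(bundle = bundle, graph = graph, features = features, model = model,
       scores = scores, result = result, report = report)
}
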