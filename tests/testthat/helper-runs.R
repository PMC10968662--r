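# Cached end-to-end pipeline runs shared by the recovery and ablation
# tests (each run is expensive; several tests consume the same seeds).

.run_cache <- new.env(parent = emptyenv())

pipeline_metrics <- function(kind, seed, epochs = 500L) {
  key <- paste(kind, seed, epochs)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  sim <- switch(kind,
    signal = sim_config(seed = seed),
    null = null_config(sim_config(seed = seed)),
    stop("unknown kind"))
  cfg <- switch(kind,
    signal = dg_config(epochs = epochs, seed = seed),
    null = dg_config(epochs = epochs, seed = seed))
  run <- run_pipeline(sim, cfg)
  out <- run$report$metrics
  .run_cache[[key]] <- out
  out
}

# plain-GCN ablation (no CRF layer, no structural block) on the same cohort
pipeline_metrics_gcn <- function(seed, epochs = 500L) {
  key <- paste("gcn", seed, epochs)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  run <- run_pipeline(sim_config(seed = seed),
                      dg_config(epochs = epochs, seed = seed,
                                crf_beta = 0, node2vec_dim = 0L))
  out <- run$report$metrics
  .run_cache[[key]] <- out
  out
}
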