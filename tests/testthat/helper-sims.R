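# Shared simulation runs, memoized so several test files can reuse the same
# replication tables.  The master seed is fixed at 1 for the whole suite.
TEST_MASTER_SEED <- 1L

.sim_cache <- new.env(parent = emptyenv())

get_sim <- function(scenario_id, dgm_variant, n_reps,
                    master_seed = TEST_MASTER_SEED) {
  key <- paste(scenario_id, dgm_variant, n_reps, master_seed, sep = "|")
  if (is.null(.sim_cache[[key]])) {
    cfg <- scenario_config(scenario_id, dgm_variant)
    .sim_cache[[key]] <- run_scenario(cfg, n_reps, master_seed)
  }
  .sim_cache[[key]]
}

get_summary <- function(scenario_id, dgm_variant, n_reps,
                        master_seed = TEST_MASTER_SEED) {
  summarize_replications(get_sim(scenario_id, dgm_variant, n_reps,
                                 master_seed),
                         scenario_config(scenario_id, dgm_variant))
}

pick_metric <- function(s, model, estimation, ci_method, col) {
  v <- s[[col]][s$model == model & s$estimation == estimation &
                  s$ci_method == ci_method]
  stopifnot(length(v) == 1L)
  v
}
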