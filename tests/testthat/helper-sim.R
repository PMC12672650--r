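# Shared simulated fixtures, built once per test run and memoized.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, builder(), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# small two-condition experiment with planted relocalizers
sim_small <- function() cached("small", function() {
  simulate_experiment(simulation_config(
    n_proteins = 300, n_relocalizers = 20, n_abundance_changers = 30,
    seed = 7))
})

# moderate steady-state map used for classification tests
sim_map <- function() cached("map", function() {
  simulate_experiment(simulation_config(
    n_proteins = 720, n_relocalizers = 0, n_abundance_changers = 0,
    seed = 3), conditions = "control")
})

map_profiles_cached <- function() cached("map_profiles", function() {
  concatenated_profiles(sim_map()$table, "control")
})

# large null comparison (no planted shifts) for calibration checks
null_sim_2000 <- function() cached("null2000", function() {
  simulate_experiment(simulation_config(
    n_proteins = 2000, n_relocalizers = 0, n_abundance_changers = 0,
    seed = 11))
})

null_mr_2000 <- function() cached("null2000_mr", function() {
  mr_analysis(null_sim_2000()$table, "control", "DTT")
})

# tiny hand-built experiment table: 2 proteins x (1 condition, 1 replicate)
tiny_table <- function(intensity_rows, count_rows = NULL,
                       fractions = PELLET_FRACTIONS) {
  n <- nrow(intensity_rows)
  if (is.null(count_rows))
    count_rows <- matrix(5, n, length(fractions))
  samples <- data.frame(condition = "control", replicate = 1L,
                        fraction = fractions, stringsAsFactors = FALSE)
  experiment_table(sprintf("T%02d", seq_len(n)), sprintf("G%02d", seq_len(n)),
                   intensity_rows, count_rows, samples)
}
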