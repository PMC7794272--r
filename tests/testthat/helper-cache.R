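# Full-scale pipeline runs are expensive (~30 s each), so they are computed
# once per session and shared across test files. `center = TRUE` runs model a
# single cohort whose mean lines equal the ground truth (the package
# default); `center = FALSE` runs redraw an i.i.d. cohort per seed, as when
# replicating the whole study.
.pf_test_cache <- new.env(parent = emptyenv())

memoise_run <- function(key, fn) {
  if (is.null(.pf_test_cache[[key]])) .pf_test_cache[[key]] <- fn()
  .pf_test_cache[[key]]
}

# 14 binocular observers at the full trial counts (default model/schedule).
cached_binocular_run <- function(seed, center = TRUE) {
  memoise_run(paste0("bino_", seed, "_", center), function() {
    trials <- simulate_experiment(n_observers = 14, seed = seed,
                                  center_observers = center)
    collapsed <- collapse_hemifields(trials)
    list(trials = collapsed,
         estimates = estimate_locations(collapsed))
  })
}

# 7 observers under monocular viewing with the per-condition line table.
cached_monocular_run <- function(seed, center = TRUE) {
  memoise_run(paste0("mono_", seed, "_", center), function() {
    model <- performance_field_model(pf_lines_by_condition())
    trials <- simulate_experiment(model, n_observers = 7,
                                  conditions = "monocular", seed = seed,
                                  center_observers = center)
    collapsed <- collapse_hemifields(trials)
    list(trials = collapsed,
         estimates = estimate_locations(collapsed))
  })
}

# One session's worth of blocks: every rotation once.
small_schedule <- function() {
  schedule_blocks(n_sessions = 1, blocks_per_session = 7)
}
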