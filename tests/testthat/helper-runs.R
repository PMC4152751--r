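# Shared simulation runs, cached so expensive end-to-end fixtures are
# built once per test session.

.run_cache <- new.env(parent = emptyenv())

# the full default-design study (the study conditions)
default_run <- function() {
  if (is.null(.run_cache$default))
    .run_cache$default <- run_simulated_study(simulation_design(), seed = 1L)
  .run_cache$default
}

# a small, fast design for property-style tests
small_design <- function(...) {
  args <- utils::modifyList(
    list(reads_per_library = 4000L, genome_length = 40000L,
         n_known = 4L, n_novel = 3L, n_pseudo_stable = 2L,
         n_pseudo_loose = 2L, n_hotspots = 12L),
    list(...))
  do.call(simulation_design, args)
}

small_sim <- function() {
  if (is.null(.run_cache$small)) {
    d <- small_design()
    sim <- simulate_genome(d, 11L)
    libs <- simulate_libraries(sim$genome, sim$manifest, d, 12L)
    .run_cache$small <- list(design = d, sim = sim, libs = libs)
  }
  .run_cache$small
}
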