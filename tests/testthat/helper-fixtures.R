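# Shared fixtures. The reference simulation (the package's default study
# conditions) is expensive, so it is built lazily once per test run and
# cached, together with its encoded example sets and per-cell-line models.

.fixture_cache <- new.env(parent = emptyenv())

ref_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <-
      simulate_regulatory_landscape(simulation_config(rng_seed = 11L))
  }
  .fixture_cache$sim
}

ref_examples <- function() {
  if (is.null(.fixture_cache$examples)) {
    sim <- ref_sim()
    cls <- names(sim$tracks)
    exs <- lapply(cls, function(cl) simulated_examples(sim, cl, rng_seed = 5L))
    names(exs) <- cls
    .fixture_cache$examples <- exs
  }
  .fixture_cache$examples
}

ref_models <- function() {
  if (is.null(.fixture_cache$models)) {
    exs <- ref_examples()
    models <- lapply(seq_along(exs), function(i)
      train_rf(exs[[i]], rng_seed = 20 + i))
    names(models) <- names(exs)
    .fixture_cache$models <- models
  }
  .fixture_cache$models
}

ref_cv <- function() {
  if (is.null(.fixture_cache$cv)) {
    .fixture_cache$cv <- cross_validate(ref_examples()[["CL1"]], "RF",
                                        k = 10, rng_seed = 2L)
  }
  .fixture_cache$cv
}

# a small, fast landscape for module-level tests
small_sim <- function(seed = 7L) {
  simulate_regulatory_landscape(simulation_config(
    n_cell_lines = 2, chrom_lengths = c(chr1 = 2e6), n_tss = 40,
    n_enhancers = 150, rng_seed = seed))
}

# a track built inline from coordinate triples
make_track <- function(chrom, start, end, score = 1,
                       dataset = "CTCF", cell_line = "CL1") {
  peak_track(data.frame(chrom = chrom, start = start, end = end,
                        score = score), dataset, cell_line)
}

# planted AND-rule example table: label = x1 & x2 among `d` binary features
planted_and_examples <- function(n = 400, d = 8, noise = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(n * d, 1, 0.5), n, d,
                dimnames = list(NULL, paste0("f", seq_len(d))))
    y <- as.integer(X[, 1] == 1 & X[, 2] == 1)
    flip <- rbinom(n, 1, noise) == 1
    y[flip] <- 1L - y[flip]
    ex <- as.data.frame(X)
    ex$label <- y
    attr(ex, "feature_names") <- colnames(X)
    ex
  })
}
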