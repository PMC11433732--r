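# Shared fixtures. Expensive default-resolution simulations are memoized so
# several test files can reuse them within one test run.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(group, dose = if (group == "severe") 27 else 162,
                       n_nodes = 40, t_end = 120, rtol = 1e-8) {
  key <- paste(group, dose, n_nodes, t_end, rtol, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    p <- load_parameter_set(group)
    mod <- assemble(p, regimen = dose_regimen("oral-ER", dose),
                    grid = make_grid(n_nodes))
    .sim_cache[[key]] <- simulate_model(mod, t_end = t_end, rtol = rtol)
  }
  .sim_cache[[key]]
}

# A parameter list with selected raw keys overridden, revalidated.
params_with <- function(overrides, group = "healthy") {
  p <- load_parameter_set(group)
  raw <- unclass(p)[c("group", nalpbpk:::.param_numeric_keys)]
  raw[names(overrides)] <- overrides
  as_parameter_set(raw)
}

# Small, fast model for property tests.
quick_model <- function(group = "healthy", dose = 162, n_nodes = 8, ...) {
  assemble(load_parameter_set(group),
           regimen = dose_regimen("oral-ER", dose),
           grid = make_grid(n_nodes), ...)
}
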