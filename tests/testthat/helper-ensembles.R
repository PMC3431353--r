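# Shared simulated ensembles for the slower checks: built once per test
# run, reused across test files. Sizes are desk-scale reproductions of the
# study conditions (the published analyses used 1000-4000 trajectories).

.ens_cache <- new.env(parent = emptyenv())

acc_ensemble <- function(name) {
  if (!is.null(.ens_cache[[name]])) return(.ens_cache[[name]])
  res <- switch(name,
    rs = analyze_ensemble(
      canonical_config("rs"), 250, base_seed = 2024,
      windows = list(I = c(100, 300), II = c(350, 550), III = c(700, 900)),
      reversions = TRUE),
    stiff = analyze_ensemble(
      canonical_config("stiff"), 250, base_seed = 2025,
      windows = list(w = c(300, 500)), reversions = TRUE),
    set1 = analyze_ensemble(canonical_config("set1"), 150, base_seed = 2026),
    set2 = analyze_ensemble(canonical_config("set2"), 150, base_seed = 2027),
    imbalanced = analyze_ensemble(canonical_config("imbalanced"), 120,
                                  base_seed = 2028),
    stop("unknown ensemble ", name))
  .ens_cache[[name]] <- res
  res
}

# a short RS ensemble for structural (non-quantitative) checks
small_rs <- function(n = 8, seed = 99) {
  key <- paste0("small", n, "_", seed)
  if (is.null(.ens_cache[[key]]))
    .ens_cache[[key]] <- simulate_ensemble(referential_set(), n, seed)
  .ens_cache[[key]]
}
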