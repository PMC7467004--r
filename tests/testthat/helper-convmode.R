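# Shared fixture builders. All data are generated in code at test time.

# Small, fast context: 6 populations, 40 selected-region sites, reduced
# grids. Deterministic given `seed`.
tiny_context <- function(seed = 11, n_selected = 40, n_neutral = 400,
                         sels = c(0.01, 0.05, 0.1), migs = c(0.001, 0.1),
                         times = c(0, 100), gs = c(0.001, 0.01),
                         sources = c(1, 3, 5), n_sites = 4,
                         num_bins = 100, cholesky = TRUE) {
  scn <- simulation_scenario(seed = seed, n_selected = n_selected,
                             n_neutral = n_neutral)
  dat <- simulate_scenario(scn)
  cfg <- run_config(Ne = scn$Ne, rec = scn$rec,
                    selected_pops = scn$selected_pops,
                    n_sites = n_sites, num_bins = num_bins,
                    sels = sels, migs = migs, times = times, gs = gs,
                    sources = sources, cholesky = cholesky)
  suppressMessages(build_context(dat$neutral, dat$selected, cfg))
}

# A deterministic positive semi-definite coancestry matrix with
# heterogeneous structure (block-correlated populations).
test_coancestry <- function(k = 6, scale = 0.1) {
  B <- outer(seq_len(k), seq_len(3), function(i, j) {
    sin(i * j) / j
  })
  Ft <- scale * tcrossprod(B) / max(tcrossprod(B))
  (Ft + t(Ft)) / 2
}

# Parameter list covering every mode's needs at one grid point.
full_params <- function(s = 0.05, m = 0.1, t = 100, g = 0.01, source = 1) {
  list(s = s, m = m, t = t, g = g, source = as.integer(source))
}

expect_symmetric <- function(M, tol = 0) {
  expect_true(max(abs(M - t(M))) <= tol)
}
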