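#' Centered compound-symmetric coancestry matrix
#'
#' Convenience truth matrix for simulations: `drift * (I - J/k)`, the
#' coancestry of mean-centered deviations when all populations drift
#' equally and independently. It is symmetric, positive semi-definite, and
#' centered (`A F A' = F`), which is the natural scale on which the
#' likelihood's neutral coancestry lives.
#'
#' @param k Number of populations.
#' @param drift Per-population drift variance (diagonal is
#'   `drift * (1 - 1/k)`).
#' @return A k x k matrix.
#' @export
centered_coancestry <- function(k, drift = 0.1) {
  drift * (diag(k) - matrix(1 / k, k, k))
}

#' Define a simulation scenario
#'
#' Describes the conditions under which synthetic allele-frequency data are
#' generated: population count and true coancestry, the mode of convergent
#' adaptation and its sweep parameters, the true selected position, site
#' positions, and sampling depths. Defaults reproduce the package's
#' reference example: six populations of which three (indices 1, 3, 5)
#' independently mutated to the selected allele at position 0, with
#' selection coefficient 0.05, positions spanning `[0, 1]`, haploid sample
#' sizes of 10, `Ne = 10000` and `rec = 0.005`.
#'
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @param k Number of populations.
#' @param F_true True k x k coancestry matrix (symmetric PSD).
#' @param mode Mode generating the selected region: one of `"neutral"`,
#'   `"independent"`, `"standing"`, `"standing_source"`, `"migration"`.
#' @param s,m,t,g,source True sweep parameters (used as the mode requires).
#' @param selected_pops Indices of the selected populations.
#' @param true_site True position of the selected site.
#' @param positions Selected-region site positions; default `n_selected`
#'   evenly spaced positions on `[0, 1]`.
#' @param n_selected Number of selected-region sites when `positions` is
#'   not given.
#' @param n_neutral Number of unlinked neutral sites.
#' @param sample_sizes Haploid sample sizes per population.
#' @param Ne,rec Effective population size and per-base recombination rate.
#' @return An object of class `sim_scenario`.
#' @export
simulation_scenario <- function(seed,
                                k = 6,
                                F_true = centered_coancestry(k),
                                mode = "independent",
                                s = 0.05, m = 0.1, t = 100, g = 0.01,
                                source = 1,
                                selected_pops = c(1, 3, 5),
                                true_site = 0,
                                positions = NULL,
                                n_selected = 200,
                                n_neutral = 1000,
                                sample_sizes = rep(10L, k),
                                Ne = 10000, rec = 0.005) {
  if (missing(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a single integer seed is mandatory", call. = FALSE)
  }
  F_true <- as.matrix(F_true)
  stopifnot(nrow(F_true) == k, isSymmetric(F_true, tol = 1e-10))
  ev <- eigen((F_true + t(F_true)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("F_true must be positive semi-definite", call. = FALSE)
  }
  if (is.null(positions)) {
    positions <- seq(0, 1, length.out = n_selected)
  }
  if (true_site < min(positions) || true_site > max(positions)) {
    stop("true_site must lie within the range of positions", call. = FALSE)
  }
  stopifnot(all(selected_pops >= 1), all(selected_pops <= k),
            length(sample_sizes) == k, all(sample_sizes >= 1))
  mode <- match.arg(mode, c("neutral", "independent", "standing",
                            "standing_source", "migration"))
  structure(
    list(seed = as.integer(seed), k = k, F_true = F_true, mode = mode,
         s = s, m = m, t = t, g = g, source = as.integer(source),
         selected_pops = as.integer(selected_pops),
         true_site = true_site, positions = as.numeric(positions),
         n_neutral = as.integer(n_neutral),
         sample_sizes = as.integer(sample_sizes), Ne = Ne, rec = rec),
    class = "sim_scenario"
  )
}

# k x rank factor B with B B' = F (eigendecomposition; tolerates PSD rank
# deficiency, which chol() does not).
psd_factor <- function(F) {
  e <- eigen((F + t(F)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-12
  e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
}

# Draw one frequency matrix: for each site j, ancestral frequency eps_j,
# deviations ~ N(0, eps_j (1 - eps_j) * F_j), clamped to [0, 1], then
# binomial sampling at the given depths.
draw_freqs <- function(cov_factors, cov_index, eps, sample_sizes) {
  k <- nrow(cov_factors[[1]])
  m <- length(eps)
  x <- matrix(NA_real_, k, m)
  for (ci in seq_along(cov_factors)) {
    cols <- which(cov_index == ci)
    B <- cov_factors[[ci]]
    dev <- B %*% matrix(stats::rnorm(ncol(B) * length(cols)),
                        ncol = length(cols))
    x[, cols] <- dev
  }
  x <- sweep(x, 2, sqrt(eps * (1 - eps)), "*")
  x <- sweep(x, 2, eps, "+")
  x <- pmin(pmax(x, 0), 1)
  counts <- stats::rbinom(k * m, size = rep(sample_sizes, m),
                          prob = as.vector(x))
  matrix(counts / rep(sample_sizes, m), k, m)
}

#' Simulate neutral allele frequencies
#'
#' Per site: the ancestral frequency is drawn from Uniform(0.05, 0.95),
#' deviations are jointly Gaussian with covariance
#' `eps (1 - eps) * F_true`, clamped to `[0, 1]`, and binomial sampling
#' noise at the scenario's sample sizes is applied. Deterministic given the
#' scenario seed.
#'
#' @param scenario A [simulation_scenario()].
#' @return A [frequency_matrix()] with `n_neutral` sites.
#' @export
simulate_neutral <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  eps <- stats::runif(scenario$n_neutral, 0.05, 0.95)
  freqs <- draw_freqs(list(psd_factor(scenario$F_true)),
                      rep(1L, scenario$n_neutral), eps,
                      scenario$sample_sizes)
  frequency_matrix(freqs, sample_sizes = scenario$sample_sizes)
}

#' Simulate the selected region under the scenario's mode
#'
#' Per site at recombination distance `r` from the true selected position,
#' deviations are drawn with covariance `eps (1 - eps) * F'(r)`, where
#' `F'(r)` is the scenario mode's kernel applied to `F_true` — the exact
#' generative mirror of the covariance the composite likelihood assumes.
#'
#' The neutral-drift background is Gaussian as in [simulate_neutral()]. The
#' sweep-added coancestry is generated through its coalescent meaning: with
#' probability `a_i = (F'[i,i] - F[i,i]) / (1 - F[i,i])` the sampled
#' lineages of selected population `i` coalesced on the sweeping haplotype,
#' and the population frequency *is* that haplotype's ancestral allele
#' (Bernoulli(`eps`), exactly 0 or 1); otherwise the population carries its
#' neutral drift deviation. Coalesced populations share one haplotype
#' allele with mode-dependent probabilities fitted to the kernel's
#' cross-population coancestry. This reproduces the model's diagonal
#' covariance `eps (1 - eps) F'(r)` exactly within `[0, 1]` — a clamped
#' Gaussian at sweep-scale variance would lose roughly half the hitchhiking
#' signal to truncation and bias selection-strength estimates downward.
#' Cross-population terms are exact for independent sweeps and matched by a
#' rank-one fit for the shared-haplotype modes.
#'
#' @param scenario A [simulation_scenario()].
#' @return A [frequency_matrix()] with positions attached.
#' @export
simulate_selected_region <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed + 1L)
  pos <- scenario$positions
  k <- scenario$k
  m <- length(pos)
  sel <- scenario$selected_pops
  r <- scenario$rec * abs(pos - scenario$true_site)
  r_unique <- unique(r)
  params <- list(s = scenario$s, m = scenario$m, t = scenario$t,
                 g = scenario$g, source = scenario$source)
  mix <- lapply(r_unique, function(ri) {
    Fp <- single_mode_cov(scenario$F_true, ri, scenario$mode, params,
                          sel, scenario$Ne)
    sweep_mixture(scenario$F_true, Fp, sel)
  })
  B0 <- psd_factor(scenario$F_true)
  eps <- stats::runif(m, 0.05, 0.95)
  dev <- B0 %*% matrix(stats::rnorm(ncol(B0) * m), ncol = m)
  x <- sweep(dev, 2, sqrt(eps * (1 - eps)), "*")
  x <- sweep(x, 2, eps, "+")
  x <- pmin(pmax(x, 0), 1)
  mix_index <- match(r, r_unique)
  for (j in seq_len(m)) {
    mx <- mix[[mix_index[j]]]
    if (all(mx$a == 0)) next
    switched <- stats::runif(length(sel)) < mx$a
    if (!any(switched)) next
    shared_allele <- stats::rbinom(1L, 1L, eps[j])
    use_shared <- stats::runif(length(sel)) < mx$c
    own_allele <- stats::rbinom(length(sel), 1L, eps[j])
    allele <- ifelse(use_shared, shared_allele, own_allele)
    x[sel[switched], j] <- allele[switched]
  }
  counts <- stats::rbinom(k * m, size = rep(scenario$sample_sizes, m),
                          prob = as.vector(x))
  freqs <- matrix(counts / rep(scenario$sample_sizes, m), k, m)
  frequency_matrix(freqs, sample_sizes = scenario$sample_sizes,
                   positions = pos)
}

# Mixture weights for the sweep component at one distance: switch
# probabilities a_i reproduce the kernel diagonal exactly; shared-allele
# probabilities c_i are a rank-one least-squares fit (in logs) to the
# kernel's added cross-population coancestry, c_i c_j a_i a_j ~ delta_ij.
sweep_mixture <- function(F0, Fp, sel) {
  d <- Fp - F0
  a <- diag(d)[sel] / pmax(1 - diag(F0)[sel], 1e-12)
  a <- pmin(pmax(a, 0), 1)
  p <- length(sel)
  c_share <- numeric(p)
  if (p > 1 && any(a > 1e-12)) {
    off <- d[sel, sel, drop = FALSE]
    diag(off) <- 0
    if (max(off) > 1e-12) {
      # log M_ij = log c_i + log c_j with M_ij = delta_ij / (a_i a_j),
      # solved for pops participating in shared events
      act <- which(a > 1e-12 & apply(off, 1, max) > 1e-12)
      if (length(act) == 1) {
        c_share[act] <- 1
      } else {
        pairs <- utils::combn(act, 2)
        rhs <- log(pmax(off[t(pairs)], 1e-300) /
                     (a[pairs[1, ]] * a[pairs[2, ]]))
        A <- matrix(0, ncol(pairs), p)
        A[cbind(seq_len(ncol(pairs)), pairs[1, ])] <- 1
        A[cbind(seq_len(ncol(pairs)), pairs[2, ])] <- 1
        lc <- qr.solve(A[, act, drop = FALSE], rhs)
        c_share[act] <- pmin(exp(lc), 1)
      }
    }
  }
  list(a = a, c = c_share)
}

#' Simulate a full scenario (neutral panel plus selected region)
#'
#' @param scenario A [simulation_scenario()].
#' @return List with elements `neutral` and `selected`
#'   ([frequency_matrix()] objects).
#' @export
simulate_scenario <- function(scenario) {
  list(neutral = simulate_neutral(scenario),
       selected = simulate_selected_region(scenario))
}

#' Grid vectors of the reference example configuration
#'
#' The parameter grid used by the package's reference example: 23 selection
#' coefficients spanning 1e-4 to 0.6, 9 standing times from 0 to 1e6
#' generations, 5 standing frequencies from 1/(2 Ne) to 0.1, 5 migration
#' rates from 1e-5 to 1, and the three selected populations as candidate
#' sources.
#'
#' @param Ne Effective population size (sets the lowest standing
#'   frequency, one copy: `1 / (2 Ne)`).
#' @return Named list with `sels`, `times`, `gs`, `migs`, `sources`.
#' @export
example_grid <- function(Ne = 10000) {
  list(
    sels = c(1e-4, 1e-3, 0.01, seq(0.02, 0.14, by = 0.01),
             seq(0.15, 0.3, by = 0.05), seq(0.4, 0.6, by = 0.1)),
    times = c(0, 5, 25, 50, 100, 500, 1000, 1e4, 1e6),
    gs = c(1 / (2 * Ne), 10^-(4:1)),
    migs = c(10^-(seq(5, 1, by = -2)), 0.5, 1),
    sources = c(1L, 3L, 5L)
  )
}

#' Write the reference example fixture to disk
#'
#' Simulates the reference scenario (six populations, selected indices
#' 1, 3, 5, true site at position 0, `s = 0.05`) and writes
#' `neutral_freqs.csv`, `selected_freqs.csv`, `positions.txt` and
#' `config.yaml` (with the [example_grid()] parameter vectors, `Ne = 10000`,
#' `rec = 0.005`, `n_sites = 10`, `num_bins = 1000`, sample sizes 10) into
#' a directory. The files read back through [read_frequency_table()],
#' [read_positions()] and [load_config()].
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_example_fixture <- function(dir, seed) {
  scn <- simulation_scenario(seed = seed)
  dat <- simulate_scenario(scn)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    neutral = file.path(dir, "neutral_freqs.csv"),
    selected = file.path(dir, "selected_freqs.csv"),
    positions = file.path(dir, "positions.txt"),
    config = file.path(dir, "config.yaml")
  )
  write_matrix_csv <- function(mat, path) {
    writeLines(apply(mat, 1, paste, collapse = ","), path)
  }
  write_matrix_csv(dat$neutral$freqs, paths[["neutral"]])
  write_matrix_csv(dat$selected$freqs, paths[["selected"]])
  writeLines(format(dat$selected$positions, trim = TRUE, digits = 15),
             paths[["positions"]])
  grid <- example_grid(Ne = scn$Ne)
  cfg <- run_config(
    Ne = scn$Ne, rec = scn$rec, selected_pops = scn$selected_pops,
    n_sites = 10, num_bins = 1000,
    sels = grid$sels, migs = grid$migs, times = grid$times, gs = grid$gs,
    sources = grid$sources, sample_sizes = scn$sample_sizes,
    locus_name = "test_locus", cholesky = TRUE
  )
  write_config(cfg, paths[["config"]])
  invisible(paths)
}
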