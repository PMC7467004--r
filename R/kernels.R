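#' Probability of staying linked through a sweep
#'
#' A neutral lineage at recombination distance `r` from the selected site
#' stays associated with the beneficial background through a hard sweep with
#' probability `y = exp(-r * ln(4 Ne s) / s)`, using the classical sweep
#' duration `ln(4 Ne s) / s` generations. `y(0) = 1` and `y` decays
#' monotonically with distance.
#'
#' @param r Recombination distance (Morgans/generation), `>= 0`. Vectorized.
#' @param s Selection coefficient, `> 0` with `4 * Ne * s > 1`.
#' @param Ne Effective population size.
#' @return Retention probability in `(0, 1]`.
#' @export
sweep_retention <- function(r, s, Ne) {
  stopifnot(all(r >= 0), s > 0)
  if (4 * Ne * s <= 1) {
    stop("4*Ne*s must exceed 1 for the sweep approximation (got ",
         format(4 * Ne * s), ")", call. = FALSE)
  }
  exp(-(r / s) * log(4 * Ne * s))
}

#' Coalescence probability during the standing phase
#'
#' While the beneficial variant segregates at frequency `g` for `t`
#' generations before selection begins, two lineages on its background
#' coalesce at rate `kappa = 1 / (2 Ne g)` and each escapes by recombination
#' at rate `r`. Competing exponentials give the probability that they
#' coalesce before either recombines off within `t` generations:
#' `p = kappa / (kappa + 2 r) * (1 - exp(-(kappa + 2 r) t))`.
#'
#' @param r Recombination distance (Morgans/generation), `>= 0`.
#' @param g Standing frequency in `(0, 1)`.
#' @param t Standing time in generations, `>= 0`.
#' @param Ne Effective population size.
#' @return Coalescence probability in `[0, 1]`.
#' @export
standing_phase_coalescence <- function(r, g, t, Ne) {
  stopifnot(all(r >= 0), g > 0, g < 1, t >= 0)
  kappa <- 1 / (2 * Ne * g)
  (kappa / (kappa + 2 * r)) * (1 - exp(-(kappa + 2 * r) * t))
}

#' Mode kernels: model covariance at a recombination distance
#'
#' Each kernel takes the neutral coancestry matrix `F` and returns the model
#' covariance of standardized frequency deviations at recombination distance
#' `r` from the proposed selected site, under one mode of convergent
#' adaptation. Entries for non-selected populations are never modified, all
#' kernels return `F` itself in the limit `r -> Inf`, and results are exactly
#' symmetric.
#'
#' * `kernel_neutral()`: identity, no selection.
#' * `kernel_independent()`: each selected population swept on its own
#'   mutation; diagonals gain `y^2 * (1 - F[i,i])`.
#' * `kernel_standing()`: the variant stood at frequency `g` for `t`
#'   generations; within-population coancestry gains coalescence on the
#'   standing background (`p_coal`, which includes continuation into the
#'   shared ancestral standing haplotype), between selected populations
#'   lineages meet on the shared standing haplotype (`p_shared`). With a
#'   source, the source population's diagonal takes the independent-sweep
#'   form.
#' * `kernel_migration()`: the allele arose in `source` and migrated; a
#'   recipient lineage retained through its own sweep traces into the
#'   source with probability `q = y * exp(-r / m)`, creating source-recipient
#'   and recipient-recipient coancestry.
#'
#' @param F k x k neutral coancestry matrix.
#' @param y Sweep retention probability from [sweep_retention()].
#' @param sel Integer indices of the selected populations.
#' @param p_coal Total within-population coalescence probability on the
#'   standing background: [standing_phase_coalescence()] at the proposal's
#'   `g`, `t`, plus the probability of entering (and coalescing in) the
#'   ancestral standing phase, `exp(-(kappa + 2 r) t) * p_shared`. Always
#'   `>= p_shared * exp(-(kappa + 2 r) t)`, so the model covariance keeps
#'   its diagonal at or above the selected off-diagonals.
#' @param p_shared Unbounded-time coalescence probability on the shared
#'   standing haplotype, `kappa / (kappa + 2 r)`.
#' @param source Source population index (must be in `sel`).
#' @param q Probability a recipient lineage traces into the source,
#'   `y * exp(-r / m)`.
#' @return A k x k symmetric model covariance matrix.
#' @name mode_kernels
NULL

#' @rdname mode_kernels
#' @export
kernel_neutral <- function(F) F

#' @rdname mode_kernels
#' @export
kernel_independent <- function(F, y, sel) {
  stopifnot(y >= 0, y <= 1, length(sel) >= 1)
  y2 <- y^2
  Fp <- F
  d <- diag(Fp)
  d[sel] <- y2 + (1 - y2) * d[sel]
  diag(Fp) <- d
  Fp
}

#' @rdname mode_kernels
#' @export
kernel_standing <- function(F, y, p_coal, p_shared, sel, source = NULL) {
  stopifnot(y >= 0, y <= 1, p_coal >= 0, p_coal <= 1,
            p_shared >= 0, p_shared <= 1)
  y2 <- y^2
  Fp <- F
  for (i in sel) {
    Fp[i, i] <- y2 * (p_coal + (1 - p_coal) * F[i, i]) + (1 - y2) * F[i, i]
  }
  if (length(sel) > 1) {
    pairs <- utils::combn(sel, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      v <- y2 * (p_shared + (1 - p_shared) * F[i, j]) + (1 - y2) * F[i, j]
      Fp[i, j] <- v
      Fp[j, i] <- v
    }
  }
  if (!is.null(source)) {
    if (!source %in% sel) stop("source must be in sel", call. = FALSE)
    Fp[source, source] <- y2 + (1 - y2) * F[source, source]
  }
  Fp
}

#' @rdname mode_kernels
#' @export
kernel_migration <- function(F, y, q, sel, source) {
  stopifnot(y >= 0, y <= 1, q >= 0, q <= 1, source %in% sel)
  y2 <- y^2
  Fp <- F
  # every selected population (source and recipients) sweeps on a single
  # haplotype: within-sweep coalescence takes the independent form
  for (i in sel) Fp[i, i] <- y2 + (1 - y2) * F[i, i]
  recips <- setdiff(sel, source)
  for (i in recips) {
    v <- q * (y * 1 + (1 - y) * F[i, source]) + (1 - q) * F[i, source]
    Fp[i, source] <- v
    Fp[source, i] <- v
  }
  if (length(recips) > 1) {
    pairs <- utils::combn(recips, 2)
    q2 <- q * q
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      v <- q2 * 1 + (1 - q2) * F[i, j]
      Fp[i, j] <- v
      Fp[j, i] <- v
    }
  }
  Fp
}

#' Mixed-mode kernel
#'
#' Applies one kernel per group of selected populations on the shared
#' neutral coancestry `F`; groups are modeled as independent convergence
#' events, so no coancestry beyond `F` is added between populations of
#' different groups.
#'
#' @inheritParams mode_kernels
#' @param r Recombination distance (Morgans/generation).
#' @param params Named list of proposal values: `s`, and as needed by the
#'   group modes, `m`, `t`, `g`, `source`.
#' @param sets List of integer vectors partitioning the selected
#'   populations.
#' @param modes Character vector, one mode label per set, each of
#'   `"independent"`, `"standing"`, `"standing_source"`, `"migration"`.
#' @param Ne Effective population size.
#' @return A k x k symmetric model covariance matrix.
#' @export
kernel_multi <- function(F, r, params, sets, modes, Ne) {
  spec <- validate_mode_spec(sets, modes, sort(unlist(lapply(sets, as.integer))))
  Fp <- F
  for (gi in seq_along(spec$sets)) {
    grp <- spec$sets[[gi]]
    mode <- spec$modes[gi]
    Fg <- single_mode_cov(F, r, mode, params, grp, Ne)
    # copy only the rows/columns this group owns (cross-group stays F)
    Fp[grp, grp] <- Fg[grp, grp]
  }
  Fp
}

# Dispatch a single-mode kernel at distance r for the given selected set.
single_mode_cov <- function(F, r, mode, params, sel, Ne) {
  switch(
    mode,
    neutral = F,
    independent = {
      y <- sweep_retention(r, params$s, Ne)
      kernel_independent(F, y, sel)
    },
    standing = ,
    standing_source = {
      y <- sweep_retention(r, params$s, Ne)
      kappa <- 1 / (2 * Ne * params$g)
      p_shared <- kappa / (kappa + 2 * r)
      # within a population, lineages that neither coalesce nor recombine
      # during the t-generation standing phase continue into the shared
      # ancestral standing haplotype, where they coalesce with the same
      # unbounded-time probability as lineages from different populations;
      # this keeps the diagonal >= the off-diagonal (equal at t = 0)
      p_coal <- standing_phase_coalescence(r, params$g, params$t, Ne)
      p_within <- p_coal + exp(-(kappa + 2 * r) * params$t) * p_shared
      src <- if (identical(mode, "standing_source")) params$source else NULL
      kernel_standing(F, y, p_within, p_shared, sel, source = src)
    },
    migration = {
      if (is.null(params$m) || params$m <= 0) {
        stop("migration rate m must be > 0", call. = FALSE)
      }
      y <- sweep_retention(r, params$s, Ne)
      q <- y * exp(-r / params$m)
      kernel_migration(F, y, q, sel, params$source)
    },
    stop("unknown mode: ", mode, call. = FALSE)
  )
}

# Model covariance for any mode label including "multi".
mode_covariance <- function(F, r, mode, params, sel, Ne,
                            sets = NULL, modes = NULL) {
  if (identical(mode, "multi")) {
    kernel_multi(F, r, params, sets, modes, Ne)
  } else {
    single_mode_cov(F, r, mode, params, sel, Ne)
  }
}
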