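ALL_MODES <- c("neutral", "independent", "migration", "standing",
               "standing_source", "multi")

# Canonical order of grid parameter axes in the results table; rows follow
# nested-loop order with selected_sites outermost and sources innermost.
GRID_AXES <- c("sels", "migs", "times", "gs", "sources")

RESULT_COLUMNS <- c("selected_sites", GRID_AXES, "cle", "selected_pops",
                    "locus_name", "model")

# Which grid axes a mode consumes. For "multi" the union over group modes,
# with the sources axis restricted to members of the (single)
# source-requiring set.
mode_axes <- function(ctx, mode) {
  axes <- list(selected_sites = ctx$proposed_sites)
  used <- switch(
    mode,
    neutral = character(0),
    independent = "sels",
    migration = c("sels", "migs", "sources"),
    standing = c("sels", "times", "gs"),
    standing_source = c("sels", "times", "gs", "sources"),
    multi = {
      u <- "sels"
      if ("migration" %in% ctx$modes) u <- c(u, "migs")
      if (any(ctx$modes %in% c("standing", "standing_source"))) {
        u <- c(u, "times", "gs")
      }
      if (any(ctx$modes %in% c("migration", "standing_source"))) {
        u <- c(u, "sources")
      }
      u
    }
  )
  for (nm in GRID_AXES) {
    if (!nm %in% used) next
    vals <- ctx[[nm]]
    if (nm == "sources" && mode == "multi") {
      src_set <- ctx$sets[[which(ctx$modes %in%
                                   c("migration", "standing_source"))]]
      vals <- vals[vals %in% src_set]
      if (length(vals) == 0) {
        stop("no configured source lies in the source-requiring set {",
             paste(src_set, collapse = ","), "}", call. = FALSE)
      }
    }
    axes[[nm]] <- vals
  }
  axes
}

# Short per-population label for mixed-mode results, mirroring the
# one-token-per-selected-population convention (e.g. "stdvar_src-stdvar_src-ind").
multi_label <- function(ctx) {
  abbr <- c(independent = "ind", migration = "mig", standing = "stdvar",
            standing_source = "stdvar_src")
  per_pop <- character(length(ctx$selected_pops))
  ord <- sort(ctx$selected_pops)
  for (gi in seq_along(ctx$sets)) {
    per_pop[match(ctx$sets[[gi]], ord)] <- abbr[[ctx$modes[gi]]]
  }
  paste(per_pop, collapse = "-")
}

#' Fit one mode of convergent adaptation over the parameter grid
#'
#' Evaluates the composite log-likelihood at every point of the mode's
#' parameter grid and returns a tidy table with a fixed 10-column schema,
#' identical across modes so that results from different modes can be
#' concatenated with `dplyr::bind_rows()`. Grid parameters a mode does not
#' use are `NA`.
#'
#' Grid axes per mode: neutral uses proposed sites only (the constant
#' composite log-likelihood is replicated per site); independent crosses
#' sites x sels; migration sites x sels x migs x sources; standing
#' sites x sels x times x gs; standing_source additionally x sources;
#' multi takes the union of its group modes' axes. Rows follow the
#' deterministic nested order selected_sites (outer), sels, migs, times,
#' gs, sources (inner).
#'
#' @param ctx A `model_context` from [build_context()]; `"multi"` requires
#'   a mode assignment from [update_mode()].
#' @param mode One of `"neutral"`, `"independent"`, `"migration"`,
#'   `"standing"`, `"standing_source"`, `"multi"`.
#' @return A tibble of class `cle_fit` with columns `selected_sites`,
#'   `sels`, `migs`, `times`, `gs`, `sources`, `cle`, `selected_pops`,
#'   `locus_name`, `model`.
#' @examples
#' scn <- simulation_scenario(seed = 1, n_selected = 40, n_neutral = 300)
#' dat <- simulate_scenario(scn)
#' cfg <- run_config(Ne = 10000, rec = 0.005, selected_pops = c(1, 3, 5),
#'                   n_sites = 5, num_bins = 100, sels = c(0.01, 0.05, 0.1),
#'                   migs = 0.1, times = c(0, 100), gs = 0.01,
#'                   sources = c(1, 3, 5))
#' ctx <- build_context(dat$neutral, dat$selected, cfg)
#' fit_mode(ctx, "independent")
#' @export
fit_mode <- function(ctx, mode) {
  stopifnot(inherits(ctx, "model_context"))
  mode <- match.arg(mode, ALL_MODES)
  if (mode == "multi" && is.null(ctx$sets)) {
    stop("mode 'multi' requires a mode assignment: call update_mode() first",
         call. = FALSE)
  }
  axes <- mode_axes(ctx, mode)
  grid <- tidyr::expand_grid(!!!axes)
  d <- nrow(ctx$C)

  cle <- numeric(nrow(grid))
  if (mode == "neutral") {
    # kernel is the identity: one evaluation serves every proposed site
    bins <- bin_distances(ctx$positions_used, ctx$proposed_sites[1],
                          ctx$rec, ctx$num_bins)
    stats <- bin_statistics(ctx$W, bins)
    val <- accumulate_cle(stats, function(r) ctx$F, ctx$D, ctx$C,
                          ctx$cholesky, d)
    cle[] <- val
  } else {
    n_inner <- nrow(grid) / length(ctx$proposed_sites)
    col_or_na <- function(nm) {
      if (nm %in% names(grid)) grid[[nm]] else rep(NA_real_, nrow(grid))
    }
    g_sels <- col_or_na("sels"); g_migs <- col_or_na("migs")
    g_times <- col_or_na("times"); g_gs <- col_or_na("gs")
    g_sources <- col_or_na("sources")
    for (si in seq_along(ctx$proposed_sites)) {
      bins <- bin_distances(ctx$positions_used, ctx$proposed_sites[si],
                            ctx$rec, ctx$num_bins)
      stats <- bin_statistics(ctx$W, bins)
      rows <- seq.int((si - 1) * n_inner + 1, si * n_inner)
      for (ri in rows) {
        params <- list(s = g_sels[ri], m = g_migs[ri], t = g_times[ri],
                       g = g_gs[ri], source = as.integer(g_sources[ri]))
        cov_fun <- function(r) {
          mode_covariance(ctx$F, r, mode, params, ctx$selected_pops,
                          ctx$Ne, sets = ctx$sets, modes = ctx$modes)
        }
        cle[ri] <- accumulate_cle(stats, cov_fun, ctx$D, ctx$C,
                                  ctx$cholesky, d)
      }
    }
  }

  out <- grid
  for (nm in GRID_AXES) {
    if (is.null(out[[nm]])) {
      out[[nm]] <- if (nm == "sources") NA_integer_ else NA_real_
    }
  }
  out$sources <- as.integer(out$sources)
  out$cle <- cle
  out$selected_pops <- paste(ctx$selected_pops, collapse = "-")
  out$locus_name <- ctx$locus_name
  out$model <- if (mode == "multi") multi_label(ctx) else mode
  out <- out[, RESULT_COLUMNS]
  class(out) <- c("cle_fit", class(out))
  out
}

#' Maximum composite-likelihood estimates per model
#'
#' For each model label in a (possibly concatenated) results table, returns
#' the grid row attaining the maximum composite log-likelihood. Ties are
#' broken deterministically by first occurrence in grid order.
#'
#' @param results A results tibble from [fit_mode()] (or several bound with
#'   `dplyr::bind_rows()`).
#' @return One row per model, same 10-column schema.
#' @export
mcle_summary <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  results |>
    dplyr::group_by(.data$model) |>
    dplyr::filter(.data$cle == max(.data$cle)) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Composite-likelihood profile along one grid axis
#'
#' Groups the results by one grid parameter (and model) and reports the
#' maximum composite log-likelihood relative to the neutral reference,
#' `max(cle) - neutral_cle` — the quantity plotted in likelihood-profile
#' figures.
#'
#' @param results A results tibble from [fit_mode()].
#' @param neutral_cle Scalar neutral composite log-likelihood, e.g.
#'   `unique(fit_mode(ctx, "neutral")$cle)`.
#' @param axis One of `"selected_sites"`, `"sels"`, `"migs"`, `"times"`,
#'   `"gs"`.
#' @return Tibble with columns `model`, the axis, and `mcle`.
#' @export
cle_profile <- function(results, neutral_cle,
                        axis = c("selected_sites", "sels", "migs",
                                 "times", "gs")) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(results), is.numeric(neutral_cle),
            length(neutral_cle) == 1)
  all_na <- results |>
    dplyr::group_by(.data$model) |>
    dplyr::summarize(drop = all(is.na(.data[[axis]])), .groups = "drop")
  if (any(all_na$drop)) {
    warning("axis '", axis, "' is unused by model(s): ",
            paste(all_na$model[all_na$drop], collapse = ", "),
            "; omitted from profile", call. = FALSE)
  }
  kept <- results |>
    dplyr::semi_join(all_na[!all_na$drop, "model"], by = "model") |>
    dplyr::filter(!is.na(.data[[axis]]))
  if (nrow(kept) == 0) {
    empty <- tibble::tibble(model = character(), axis_value = numeric(),
                            mcle = numeric())
    names(empty)[2] <- axis
    return(empty)
  }
  kept |>
    dplyr::group_by(.data$model, .data[[axis]]) |>
    dplyr::summarize(mcle = max(.data$cle) - neutral_cle,
                     .groups = "drop")
}
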