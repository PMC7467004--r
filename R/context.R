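#' Build the shared model context for all mode fits
#'
#' Precomputes every quantity reused across model fits: the neutral
#' coancestry matrix, standardized selected-region deviations and their
#' per-bin scatter statistics, the centering projection, the sampling-noise
#' diagonal, the proposed selected sites, and the parameter grids. All
#' subsequent fits ([fit_mode()]) consume this context as their only data
#' input, so nothing is re-estimated between modes.
#'
#' @param neutral A [frequency_matrix()] of unlinked neutral sites.
#' @param selected A [frequency_matrix()] for the putatively selected
#'   region; must carry positions.
#' @param config A [run_config()].
#' @return An object of class `model_context`.
#' @export
build_context <- function(neutral, selected, config) {
  stopifnot(inherits(neutral, "freq_matrix"),
            inherits(selected, "freq_matrix"),
            inherits(config, "run_config"))
  k <- nrow(neutral$freqs)
  if (nrow(selected$freqs) != k) {
    stop("neutral and selected matrices must have the same populations ",
         "(rows): ", k, " vs ", nrow(selected$freqs), call. = FALSE)
  }
  if (is.null(selected$positions)) {
    stop("the selected-region matrix must carry site positions",
         call. = FALSE)
  }
  if (any(config$selected_pops > k)) {
    stop("selected_pops index exceeds the number of populations (", k, ")",
         call. = FALSE)
  }
  sample_sizes <- selected$sample_sizes %||% config$sample_sizes
  if (is.null(sample_sizes)) {
    stop("sample_sizes must be supplied (on the frequency matrix or in ",
         "the config)", call. = FALSE)
  }
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) != k || any(sample_sizes < 1)) {
    stop("sample_sizes must be ", k, " positive integers", call. = FALSE)
  }

  neutral$sample_sizes <- neutral$sample_sizes %||% sample_sizes
  coan <- estimate_neutral_coancestry(neutral)
  std <- standardize_matrix(selected$freqs)
  if (ncol(std$z) == 0) {
    stop("no usable (polymorphic) selected-region sites", call. = FALSE)
  }
  if (std$n_dropped > 0) {
    rlang::inform(paste0("dropped ", std$n_dropped,
                         " monomorphic selected-region site(s)"))
  }
  positions_used <- selected$positions[std$usable]

  if (!is.null(config$n_sites)) {
    if (config$n_sites > length(selected$positions)) {
      stop("n_sites (", config$n_sites, ") must be <= the number of ",
           "selected-region sites (", length(selected$positions), ")",
           call. = FALSE)
    }
    proposed_sites <- seq(min(selected$positions), max(selected$positions),
                          length.out = config$n_sites)
  } else {
    proposed_sites <- config$sel_sites
    rng <- range(selected$positions)
    if (any(proposed_sites < rng[1] | proposed_sites > rng[2])) {
      stop("sel_sites must lie within the range of the region's positions",
           call. = FALSE)
    }
  }

  C <- centering_projection(k)
  ctx <- structure(
    list(
      F = coan$F, k = k, n_neutral_used = coan$n_sites_used,
      Z = std$z, W = C %*% std$z, positions_used = positions_used,
      eps = std$eps,
      C = C, D = diag(1 / sample_sizes),
      proposed_sites = proposed_sites,
      sels = config$sels, migs = config$migs, times = config$times,
      gs = config$gs, sources = config$sources,
      Ne = config$Ne, rec = config$rec, num_bins = config$num_bins,
      sample_sizes = sample_sizes,
      selected_pops = config$selected_pops,
      locus_name = config$locus_name, cholesky = config$cholesky,
      sets = NULL, modes = NULL
    ),
    class = "model_context"
  )
  if (!is.null(config$sets)) {
    ctx <- update_mode(ctx, config$sets, config$modes)
  }
  ctx
}

#' Attach a mixed-mode assignment to an existing context
#'
#' Groups the selected populations into sets and assigns one mode of
#' convergence per set, for fitting with `fit_mode(ctx, "multi")`. All
#' precomputed quantities are reused; calling again replaces the previous
#' assignment.
#'
#' @param ctx A `model_context` from [build_context()].
#' @param sets List of integer vectors partitioning the selected
#'   populations.
#' @param modes Character vector of mode labels, one per set
#'   (`"independent"`, `"standing"`, `"standing_source"`, `"migration"`).
#' @return The context with the mode assignment attached.
#' @export
update_mode <- function(ctx, sets, modes) {
  stopifnot(inherits(ctx, "model_context"))
  spec <- validate_mode_spec(sets, modes, ctx$selected_pops)
  ctx$sets <- spec$sets
  ctx$modes <- spec$modes
  ctx
}

#' @export
print.model_context <- function(x, ...) {
  cat("<model_context> ", x$k, " populations (selected: ",
      paste(x$selected_pops, collapse = ","), "), ",
      ncol(x$Z), " selected-region sites, neutral F from ",
      x$n_neutral_used, " sites\n",
      "  ", length(x$proposed_sites), " proposed sites, ",
      x$num_bins, " distance bins, Ne=", format(x$Ne),
      ", rec=", format(x$rec), "\n", sep = "")
  if (!is.null(x$sets)) {
    cat("  mixed modes: ",
        paste(vapply(seq_along(x$sets), function(i) {
          paste0("{", paste(x$sets[[i]], collapse = ","), "}:",
                 x$modes[i])
        }, character(1)), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
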