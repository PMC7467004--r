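#' Run configuration for a convergent-adaptation fit
#'
#' Bundles the scalar population-genetic quantities (effective population
#' size `Ne`, per-base recombination rate `rec`), the identity of the
#' selected populations, the proposed-selected-site placement, the
#' distance-binning resolution and the parameter grid vectors shared by all
#' model fits.
#'
#' Population indices (`selected_pops`, `sources`) are 1-based, matching how
#' practitioners label populations in their frequency matrices.
#'
#' @param Ne Effective population size (diploid individuals), assumed equal
#'   across populations.
#' @param rec Per-base recombination rate for the selected region
#'   (Morgans per position unit per generation).
#' @param selected_pops Integer indices of the populations that experienced
#'   selection (rows of the frequency matrices).
#' @param n_sites Number of sites to propose as the selected site, placed
#'   uniformly from `min(positions)` to `max(positions)`. Exactly one of
#'   `n_sites` and `sel_sites` must be given.
#' @param sel_sites Explicit vector of positions to propose as the selected
#'   site. Exactly one of `n_sites` and `sel_sites` must be given.
#' @param num_bins Number of bins for recombination distances from each
#'   proposed selected site.
#' @param sels Grid of proposed selection coefficients (all `> 0`).
#' @param migs Grid of proposed migration rates (proportion of individuals
#'   of migrant origin per generation; all `> 0`, zero is not a valid rate).
#' @param times Grid of proposed times (generations) the variant is standing
#'   before selection (all `>= 0`).
#' @param gs Grid of proposed initial frequencies of the standing variant
#'   (all in `(0, 1)`).
#' @param sources Population indices to propose as the source of the
#'   beneficial allele; every entry must lie in `selected_pops`.
#' @param sample_sizes Optional haploid sample sizes per population
#'   (twice the diploid count); may instead travel with the frequency
#'   matrices.
#' @param locus_name Label carried into the results table. Default
#'   `"locus"`.
#' @param cholesky Use Cholesky factorization for the covariance inverse and
#'   determinant (fast path). `TRUE` by default; on failure the fit falls
#'   back to the pseudo-inverse (`MASS::ginv`) automatically.
#' @param sets,modes Optional mixed-mode assignment: `sets` is a list of
#'   disjoint vectors partitioning `selected_pops`, `modes` one mode label
#'   per set (see [update_mode()]).
#'
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(Ne, rec, selected_pops,
                       n_sites = NULL, sel_sites = NULL,
                       num_bins = 1000,
                       sels, migs, times, gs, sources,
                       sample_sizes = NULL,
                       locus_name = "locus", cholesky = TRUE,
                       sets = NULL, modes = NULL) {
  if (!is.numeric(Ne) || length(Ne) != 1 || Ne <= 0) {
    stop("Ne must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(rec) || length(rec) != 1 || rec <= 0) {
    stop("rec must be a single positive number", call. = FALSE)
  }
  selected_pops <- as.integer(selected_pops)
  if (length(selected_pops) < 1 || any(selected_pops < 1) ||
      anyDuplicated(selected_pops)) {
    stop("selected_pops must be distinct positive indices", call. = FALSE)
  }
  if (is.null(n_sites) == is.null(sel_sites)) {
    stop("exactly one of n_sites and sel_sites must be given ",
         "(they cannot be combined)", call. = FALSE)
  }
  if (!is.null(n_sites)) {
    n_sites <- as.integer(n_sites)
    if (length(n_sites) != 1 || n_sites < 1) {
      stop("n_sites must be a single positive integer", call. = FALSE)
    }
  }
  if (!is.null(sel_sites)) sel_sites <- as.numeric(sel_sites)
  num_bins <- as.integer(num_bins)
  if (length(num_bins) != 1 || num_bins < 1) {
    stop("num_bins must be a positive integer", call. = FALSE)
  }
  sels <- as.numeric(sels)
  if (any(sels <= 0)) stop("all sels must be > 0", call. = FALSE)
  migs <- as.numeric(migs)
  if (any(migs <= 0)) {
    stop("migration rates cannot be 0 (or negative)", call. = FALSE)
  }
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  gs <- as.numeric(gs)
  if (any(gs <= 0 | gs >= 1)) {
    stop("standing frequencies gs must lie strictly in (0, 1)",
         call. = FALSE)
  }
  sources <- as.integer(sources)
  if (!all(sources %in% selected_pops)) {
    stop("every source must be one of the populations in selected_pops",
         call. = FALSE)
  }
  if (!is.null(sample_sizes)) sample_sizes <- as.integer(sample_sizes)
  stopifnot(is.character(locus_name), length(locus_name) == 1,
            is.logical(cholesky), length(cholesky) == 1)
  cfg <- structure(
    list(Ne = Ne, rec = rec, selected_pops = selected_pops,
         n_sites = n_sites, sel_sites = sel_sites, num_bins = num_bins,
         sels = sels, migs = migs, times = times, gs = gs,
         sources = sources, sample_sizes = sample_sizes,
         locus_name = locus_name, cholesky = cholesky,
         sets = NULL, modes = NULL),
    class = "run_config"
  )
  if (!is.null(sets) || !is.null(modes)) {
    spec <- validate_mode_spec(sets, modes, selected_pops)
    cfg$sets <- spec$sets
    cfg$modes <- spec$modes
  }
  cfg
}

# Shared validation of the mixed-mode assignment: sets must partition the
# selected populations, one recognised mode label per set, and at most one
# set may use a mode that needs a source (a grid point carries one source).
validate_mode_spec <- function(sets, modes, selected_pops) {
  if (is.null(sets) || is.null(modes)) {
    stop("sets and modes must be given together", call. = FALSE)
  }
  if (!is.list(sets)) sets <- list(sets)
  sets <- lapply(sets, as.integer)
  modes <- as.character(modes)
  allowed <- c("independent", "standing", "standing_source", "migration")
  if (length(modes) != length(sets)) {
    stop("modes must supply one label per set", call. = FALSE)
  }
  if (!all(modes %in% allowed)) {
    stop("unknown mode label(s): ",
         paste(setdiff(modes, allowed), collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")",
         call. = FALSE)
  }
  flat <- unlist(sets)
  if (anyDuplicated(flat) || !setequal(flat, selected_pops)) {
    stop("sets must be disjoint and together cover exactly selected_pops (",
         paste(selected_pops, collapse = ", "), ")", call. = FALSE)
  }
  needs_source <- modes %in% c("standing_source", "migration")
  if (sum(needs_source) > 1) {
    stop("at most one set may use a source-requiring mode ",
         "(migration or standing_source): a grid point carries a single ",
         "source index", call. = FALSE)
  }
  list(sets = sets, modes = modes)
}

#' Load a run configuration from a YAML file
#'
#' The file is a flat key-value document whose keys match the arguments of
#' [run_config()]; grid vectors are written as explicit YAML lists. All
#' [run_config()] invariants are enforced on load.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  required <- c("Ne", "rec", "selected_pops", "sels", "migs", "times",
                "gs", "sources")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  keep <- !vapply(config, is.null, logical(1))
  yaml::write_yaml(unclass(config)[keep], path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> Ne=", format(x$Ne), ", rec=", format(x$rec),
      ", selected pops {", paste(x$selected_pops, collapse = ","), "}\n",
      "  grid: ", length(x$sels), " sels x ", length(x$migs), " migs x ",
      length(x$times), " times x ", length(x$gs), " gs x ",
      length(x$sources), " sources; ",
      if (!is.null(x$n_sites)) paste0(x$n_sites, " proposed sites")
      else paste0(length(x$sel_sites), " explicit proposed sites"),
      "; ", x$num_bins, " bins\n", sep = "")
  invisible(x)
}
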