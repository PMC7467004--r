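#' Tidy a composite-likelihood fit
#'
#' Returns the maximum composite-likelihood row(s), one per model label —
#' the fit's parameter estimates.
#'
#' @param x A `cle_fit` from [fit_mode()].
#' @param ... Unused.
#' @return A tibble, one row per model, with the 10-column results schema.
#' @export
tidy.cle_fit <- function(x, ...) {
  mcle_summary(x)
}

#' Glance at a composite-likelihood fit
#'
#' @param x A `cle_fit` from [fit_mode()].
#' @param ... Unused.
#' @return One-row tibble: `model`, `n_grid` (grid points evaluated),
#'   `max_cle`, `mcle_site`, `mcle_sels`, `locus_name`.
#' @export
glance.cle_fit <- function(x, ...) {
  best <- mcle_summary(x)
  tibble::tibble(
    model = paste(unique(x$model), collapse = ";"),
    n_grid = nrow(x),
    max_cle = max(x$cle),
    mcle_site = best$selected_sites[which.max(best$cle)],
    mcle_sels = best$sels[which.max(best$cle)],
    locus_name = paste(unique(x$locus_name), collapse = ";")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
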