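#' Write a results table to CSV
#'
#' Writes the fixed 10-column schema with header
#' `selected_sites,sels,migs,times,gs,sources,cle,selected_pops,locus_name,model`.
#' Unused grid parameters are written as empty fields; numeric values keep
#' full round-trip precision, so [read_results()] recovers the table
#' exactly.
#'
#' @param results A results tibble from [fit_mode()] (possibly several
#'   modes bound together). An empty table yields a header-only file.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  missing_cols <- setdiff(RESULT_COLUMNS, names(results))
  if (length(missing_cols) > 0) {
    stop("results table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- results[, RESULT_COLUMNS]
  # 17 significant digits: doubles survive the round trip bit-exactly
  for (nm in c("selected_sites", "sels", "migs", "times", "gs", "cle")) {
    out[[nm]] <- ifelse(is.na(out[[nm]]), NA_character_,
                        sprintf("%.17g", out[[nm]]))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to a results CSV.
#' @return A tibble with the 10-column results schema.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- readr::read_csv(
    path, na = "",
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!identical(names(out), RESULT_COLUMNS)) {
    stop("unexpected results schema in ", path, call. = FALSE)
  }
  # numeric conversion via base strtod, which is correctly rounded, so the
  # 17-digit representation written by write_results() round-trips exactly
  for (nm in c("selected_sites", "sels", "migs", "times", "gs", "cle")) {
    out[[nm]] <- as.numeric(out[[nm]])
  }
  out$sources <- as.integer(out$sources)
  out
}
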