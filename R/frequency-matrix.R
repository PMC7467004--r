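#' Population-by-site allele frequency matrix
#'
#' Container for sample allele frequencies with one row per population and
#' one column per site. The selected-region matrix additionally carries the
#' genomic position of every site (base pairs, or any monotone coordinate:
#' positions are used verbatim, never rescaled). `sample_sizes` are haploid
#' allele counts, i.e. twice the number of diploid individuals sampled per
#' population.
#'
#' @param freqs Numeric matrix of allele frequencies in `[0, 1]`,
#'   populations in rows, sites in columns.
#' @param sample_sizes Positive integer vector, one entry per population
#'   (row). May be `NULL` at construction and supplied later (e.g. from a
#'   run configuration) before model fitting.
#' @param positions Numeric vector of site coordinates, one per column.
#'   Required for the selected-region matrix, optional for neutral sites.
#'   Columns are reordered so positions are strictly increasing.
#' @param pop_labels Character vector of population names; defaults to
#'   `pop1, pop2, ...`.
#'
#' @return An object of class `freq_matrix`: a list with elements `freqs`,
#'   `positions`, `sample_sizes` and `pop_labels`.
#' @seealso [read_frequency_table()], [build_context()]
#' @export
frequency_matrix <- function(freqs, sample_sizes = NULL, positions = NULL,
                             pop_labels = NULL) {
  freqs <- as.matrix(freqs)
  storage.mode(freqs) <- "double"
  dimnames(freqs) <- NULL
  if (anyNA(freqs)) {
    bad <- which(is.na(freqs), arr.ind = TRUE)[1, ]
    stop("missing frequency at row ", bad[1], ", column ", bad[2],
         call. = FALSE)
  }
  out_of_range <- which(freqs < 0 | freqs > 1, arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    stop("frequency outside [0, 1] at row ", out_of_range[1, 1],
         ", column ", out_of_range[1, 2], " (value ",
         format(freqs[out_of_range[1, 1], out_of_range[1, 2]]), ")",
         call. = FALSE)
  }
  k <- nrow(freqs)
  if (!is.null(positions)) {
    positions <- as.numeric(positions)
    if (length(positions) != ncol(freqs)) {
      stop("length(positions) (", length(positions),
           ") must equal the number of sites (", ncol(freqs), ")",
           call. = FALSE)
    }
    ord <- order(positions)
    positions <- positions[ord]
    freqs <- freqs[, ord, drop = FALSE]
    if (any(diff(positions) <= 0)) {
      stop("positions must be distinct (strictly increasing after sorting)",
           call. = FALSE)
    }
  }
  if (!is.null(sample_sizes)) {
    sample_sizes <- as.integer(sample_sizes)
    if (length(sample_sizes) != k || any(is.na(sample_sizes)) ||
        any(sample_sizes < 1)) {
      stop("sample_sizes must be ", k, " positive integers", call. = FALSE)
    }
  }
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_len(k))
  stopifnot(length(pop_labels) == k)
  structure(
    list(freqs = freqs, positions = positions,
         sample_sizes = sample_sizes, pop_labels = as.character(pop_labels)),
    class = "freq_matrix"
  )
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat("<freq_matrix> ", nrow(x$freqs), " populations x ", ncol(x$freqs),
      " sites", if (!is.null(x$positions)) " (with positions)", "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.freq_matrix <- function(x) dim(x$freqs)

#' Read an allele-frequency table from delimited text
#'
#' Reads a rectangular numeric table (populations in rows, sites in
#' columns). An optional header row gives per-site genomic positions;
#' alternatively positions can be passed directly (e.g. from a one-column
#' positions file).
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator, `","` by default.
#' @param header Logical; if `TRUE` the first row is read as numeric site
#'   positions.
#' @param positions,sample_sizes,pop_labels Passed to [frequency_matrix()];
#'   `positions` may not be combined with `header = TRUE`.
#' @return A validated [frequency_matrix()] with rows in file order.
#' @export
read_frequency_table <- function(path, delimiter = ",", header = FALSE,
                                 positions = NULL, sample_sizes = NULL,
                                 pop_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty frequency table: ", path, call. = FALSE)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  if (header) {
    if (!is.null(positions)) {
      stop("give positions in the header or as an argument, not both",
           call. = FALSE)
    }
    positions <- suppressWarnings(as.numeric(trimws(cells[[1]])))
    if (anyNA(positions)) {
      stop("non-numeric position in header row of ", path, call. = FALSE)
    }
    cells <- cells[-1]
  }
  widths <- lengths(cells)
  if (length(unique(widths)) != 1) {
    stop("ragged table in ", path, ": row ",
         which(widths != widths[1])[1], " has ",
         widths[widths != widths[1]][1], " fields, expected ", widths[1],
         call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = length(cells), ncol = widths[1])
  for (i in seq_along(cells)) {
    row <- suppressWarnings(as.numeric(trimws(cells[[i]])))
    if (anyNA(row)) {
      stop("non-numeric value at row ", i, ", column ",
           which(is.na(row))[1], " of ", path, call. = FALSE)
    }
    mat[i, ] <- row
  }
  frequency_matrix(mat, sample_sizes = sample_sizes, positions = positions,
                   pop_labels = pop_labels)
}

#' Read a one-column positions file
#'
#' @param path Path to a text file with one numeric position per line.
#' @return Numeric vector of positions.
#' @export
read_positions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  pos <- suppressWarnings(as.numeric(lines))
  if (length(pos) == 0 || anyNA(pos)) {
    stop("non-numeric or empty positions file: ", path, call. = FALSE)
  }
  pos
}
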