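#' Standardize allele frequencies at one site
#'
#' The across-population mean frequency serves as a proxy for the ancestral
#' frequency: each population's deviation from it is divided by the binomial
#' scale `sqrt(eps * (1 - eps))`. Sites monomorphic across all populations
#' (mean exactly 0 or 1) cannot be standardized and are flagged unusable
#' rather than raising an error.
#'
#' @param x Numeric vector of per-population frequencies in `[0, 1]`.
#' @return A list with `z` (standardized deviations, `NA` when unusable),
#'   `eps` (mean frequency) and `usable` (logical).
#' @export
standardize_site <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0 & x <= 1))
  eps <- mean(x)
  if (eps <= 0 || eps >= 1) {
    return(list(z = rep(NA_real_, length(x)), eps = eps, usable = FALSE))
  }
  list(z = (x - eps) / sqrt(eps * (1 - eps)), eps = eps, usable = TRUE)
}

# Vectorized standardization of a k x m frequency matrix.
# Returns z (k x m_usable), eps (per usable site), usable (length m), and
# the count of dropped monomorphic sites.
standardize_matrix <- function(freqs) {
  eps <- colMeans(freqs)
  usable <- eps > 0 & eps < 1
  z <- sweep(freqs[, usable, drop = FALSE], 2, eps[usable], "-")
  z <- sweep(z, 2, sqrt(eps[usable] * (1 - eps[usable])), "/")
  list(z = z, eps = eps[usable], usable = usable,
       n_dropped = sum(!usable))
}

#' Estimate the neutral coancestry matrix
#'
#' Averages outer products of standardized frequency deviations over all
#' usable (polymorphic) neutral sites: `F[i, j] = mean(z_i * z_j)`. Because
#' deviations are taken from the across-population mean, the estimate is the
#' coancestry of mean-centered deviations. With `correct_sampling = TRUE`
#' the expected binomial sampling contribution is removed from the estimate,
#' since the likelihood adds `diag(1/n)` to every model covariance and the
#' noise must be counted exactly once.
#'
#' @param neutral A [frequency_matrix()] of putatively neutral, unlinked
#'   sites across all populations.
#' @param correct_sampling Subtract the expected binomial sampling-noise
#'   contribution `A diag(1/n) A'` (with `A = I - J/k` the centering
#'   matrix) from the raw average of outer products, so that the estimate
#'   targets the drift coancestry itself and the model's `diag(1/n)` term
#'   counts sampling noise exactly once. Default `TRUE` when sample sizes
#'   are available.
#' @return An object of class `coancestry`: list with `F` (k x k symmetric
#'   matrix), `k`, and `n_sites_used`.
#' @export
estimate_neutral_coancestry <- function(neutral,
                                        correct_sampling =
                                          !is.null(neutral$sample_sizes)) {
  stopifnot(inherits(neutral, "freq_matrix"))
  k <- nrow(neutral$freqs)
  if (k < 2) stop("need at least 2 populations", call. = FALSE)
  std <- standardize_matrix(neutral$freqs)
  m <- ncol(std$z)
  if (m == 0) {
    stop("no usable (polymorphic) neutral sites: cannot estimate coancestry",
         call. = FALSE)
  }
  if (std$n_dropped > 0) {
    rlang::inform(paste0("dropped ", std$n_dropped,
                         " monomorphic neutral site(s)"))
  }
  F_hat <- tcrossprod(std$z) / m
  F_hat <- (F_hat + t(F_hat)) / 2
  if (correct_sampling) {
    if (is.null(neutral$sample_sizes)) {
      stop("correct_sampling = TRUE requires sample_sizes on the matrix",
           call. = FALSE)
    }
    A <- diag(k) - matrix(1 / k, k, k)
    F_hat <- F_hat - A %*% diag(1 / neutral$sample_sizes) %*% A
  }
  structure(list(F = F_hat, k = k, n_sites_used = m), class = "coancestry")
}

#' @export
print.coancestry <- function(x, ...) {
  cat("<coancestry> ", x$k, " populations, estimated from ",
      x$n_sites_used, " sites\n", sep = "")
  print(round(x$F, 4))
  invisible(x)
}

#' Mean-centering projection matrix
#'
#' Standardized deviations sum to zero across populations, so their k x k
#' covariance is singular. Projecting through the first `k - 1` rows of the
#' centering matrix `I - J/k` restores full rank, enabling the Cholesky fast
#' path of the likelihood.
#'
#' @param k Number of populations (`>= 2`).
#' @return A `(k-1) x k` matrix `C` with `C %*% rep(1, k) == 0`.
#' @export
centering_projection <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 2) {
    stop("k must be an integer >= 2", call. = FALSE)
  }
  C <- diag(k) - matrix(1 / k, k, k)
  C[seq_len(k - 1), , drop = FALSE]
}
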