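#' Bin sites by recombination distance from a proposed selected site
#'
#' Distances are `r = rec * |position - proposed_site|`. When the number of
#' distinct distances does not exceed `num_bins`, every distinct distance
#' becomes its own bin with midpoint equal to the distance itself, so
#' binning is lossless. Otherwise distances are grouped into `num_bins`
#' uniform right-closed intervals over `[0, max(r)]` and evaluated at the
#' interval midpoints.
#'
#' @param positions Numeric site positions.
#' @param proposed_site Proposed position of the selected site.
#' @param rec Per-base recombination rate.
#' @param num_bins Maximum number of bins, `>= 1`.
#' @return A list of class `binned_distances`: `bin_index` (per site),
#'   `midpoints` (recombination distance per occupied bin, indexed by bin
#'   id), `r` (per-site distance), `num_bins`, and `lossless`.
#' @export
bin_distances <- function(positions, proposed_site, rec, num_bins) {
  stopifnot(rec > 0, num_bins >= 1, length(positions) >= 1)
  r <- rec * abs(positions - proposed_site)
  distinct <- sort(unique(r))
  if (length(distinct) <= num_bins) {
    idx <- match(r, distinct)
    midpoints <- distinct
    lossless <- TRUE
  } else {
    r_max <- max(r)
    width <- r_max / num_bins
    idx <- pmin(pmax(ceiling(r / width), 1L), num_bins)
    midpoints <- (seq_len(num_bins) - 0.5) * width
    lossless <- FALSE
  }
  structure(
    list(bin_index = idx, midpoints = midpoints, r = r,
         num_bins = as.integer(num_bins), lossless = lossless),
    class = "binned_distances"
  )
}

# Factor a model covariance for the likelihood. Returns log|Sigma| and the
# precision matrix, trying Cholesky first (when requested), then one round
# of diagonal jitter, then the pseudo-inverse (MASS::ginv) with the
# log-determinant taken over nonzero eigenvalues. Never aborts a fit.
factor_sigma <- function(Sigma, cholesky = TRUE) {
  if (cholesky) {
    U <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(U)) {
      jitter <- 1e-10 * sum(diag(Sigma)) / nrow(Sigma)
      U <- tryCatch(chol(Sigma + diag(jitter, nrow(Sigma))),
                    error = function(e) NULL)
    }
    if (!is.null(U)) {
      return(list(logdet = 2 * sum(log(diag(U))), prec = chol2inv(U),
                  path = "cholesky"))
    }
    rlang::inform("Cholesky factorization failed; using pseudo-inverse",
                  .frequency = "once", .frequency_id = "convmode_pinv")
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(abs(ev)) * nrow(Sigma) * .Machine$double.eps
  list(logdet = sum(log(ev[ev > tol])), prec = MASS::ginv(Sigma),
       path = "pseudoinverse")
}

#' Per-site Gaussian log-likelihood of centered frequency deviations
#'
#' Builds the model covariance of the observed deviations,
#' `Sigma = C (F_model + diag(1/n)) C'`, where `diag(1/n)` is the binomial
#' sampling noise on the standardized scale and `C` the mean-centering
#' projection, then evaluates the zero-mean multivariate normal log-density
#' of `w = C z`.
#'
#' @param z Length-k standardized deviation vector (a usable site).
#' @param F_model k x k model covariance from a mode kernel.
#' @param sample_sizes Haploid sample sizes per population.
#' @param C Centering projection from [centering_projection()].
#' @param path `"cholesky"` (fast, falls back automatically) or
#'   `"pseudoinverse"`.
#' @return Log-likelihood (scalar).
#' @export
site_loglik <- function(z, F_model, sample_sizes, C,
                        path = c("cholesky", "pseudoinverse")) {
  path <- match.arg(path)
  Sigma <- C %*% (F_model + diag(1 / sample_sizes)) %*% t(C)
  fac <- factor_sigma(Sigma, cholesky = identical(path, "cholesky"))
  w <- drop(C %*% z)
  d <- nrow(C)
  -0.5 * (d * log(2 * pi) + fac$logdet + drop(w %*% fac$prec %*% w))
}

# Precompute, for one proposed site, the per-bin sufficient statistics:
# scatter matrices S_b = W_b W_b' of centered deviations and site counts.
# The composite likelihood then needs only trace(prec %*% S_b) per bin.
bin_statistics <- function(W, bins) {
  occupied <- sort(unique(bins$bin_index))
  stats <- lapply(occupied, function(b) {
    Wb <- W[, bins$bin_index == b, drop = FALSE]
    list(S = tcrossprod(Wb), n = ncol(Wb), r = bins$midpoints[b])
  })
  stats
}

# Core accumulation: sum of site log-likelihoods over all bins for one
# kernel configuration. `cov_fun(r)` returns the model covariance at
# distance r; D is diag(1/n); C the centering projection.
accumulate_cle <- function(stats, cov_fun, D, C, cholesky, d) {
  total <- 0
  const <- d * log(2 * pi)
  for (st in stats) {
    Sigma <- C %*% (cov_fun(st$r) + D) %*% t(C)
    fac <- factor_sigma(Sigma, cholesky = cholesky)
    total <- total - 0.5 * (st$n * (const + fac$logdet) +
                              sum(fac$prec * st$S))
  }
  total
}

#' Composite log-likelihood of the selected region under one model
#'
#' Sums the per-site Gaussian log-likelihood of standardized, mean-centered
#' allele-frequency deviations over all usable selected-region sites, with
#' each site's model covariance evaluated at its distance bin's midpoint
#' (one kernel evaluation per occupied bin).
#'
#' @param ctx A model context from [build_context()].
#' @param proposed_site Proposed position of the selected site.
#' @param mode One of `"neutral"`, `"independent"`, `"standing"`,
#'   `"standing_source"`, `"migration"`, `"multi"`.
#' @param s,m,t,g,source Proposal values for the grid parameters used by
#'   `mode` (ignored otherwise).
#' @return Composite log-likelihood (scalar).
#' @export
composite_loglik <- function(ctx, proposed_site, mode,
                             s = NA, m = NA, t = NA, g = NA, source = NA) {
  stopifnot(inherits(ctx, "model_context"))
  bins <- bin_distances(ctx$positions_used, proposed_site, ctx$rec,
                        ctx$num_bins)
  stats <- bin_statistics(ctx$W, bins)
  params <- list(s = s, m = m, t = t, g = g,
                 source = if (is.na(source)) NA_integer_ else as.integer(source))
  cov_fun <- function(r) {
    mode_covariance(ctx$F, r, mode, params, ctx$selected_pops, ctx$Ne,
                    sets = ctx$sets, modes = ctx$modes)
  }
  accumulate_cle(stats, cov_fun, ctx$D, ctx$C, ctx$cholesky, nrow(ctx$C))
}
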