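#' Variance components of the bivariate measurement-error model
#'
#' On the square-root scale, a diameter reading decomposes additively into a
#' fixed phase mean, a lesion effect, a reader effect, a lesion-by-reader
#' interaction and a residual, each a mean-zero bivariate normal over the
#' (baseline, post-treatment) pair. This object carries the fixed means and
#' the four 2x2 covariance matrices.
#'
#' @param mu length-2 numeric, fixed means (baseline, post) on the sqrt(mm)
#'   scale.
#' @param cov_lesion,cov_reader,cov_interaction,cov_residual 2x2 symmetric
#'   positive semi-definite covariance matrices on the sqrt(mm) scale.
#' @return An object of class `variance_components`.
#' @seealso [intra_error_cov()], [inter_error_cov()], [fit_bivariate_model()]
#' @export
variance_components <- function(mu, cov_lesion, cov_reader, cov_interaction,
                                cov_residual) {
  mu <- as.numeric(mu)
  if (length(mu) != 2) stop("mu must have length 2 (baseline, post)", call. = FALSE)
  mats <- list(cov_lesion = cov_lesion, cov_reader = cov_reader,
               cov_interaction = cov_interaction, cov_residual = cov_residual)
  for (nm in names(mats)) {
    if (!is_psd2(mats[[nm]])) {
      stop(nm, " must be a symmetric positive semi-definite 2x2 matrix",
           call. = FALSE)
    }
  }
  structure(c(list(mu = setNames(mu, c("b", "p"))), mats),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Bivariate measurement-error variance components (sqrt-mm scale)\n")
  cat(sprintf("  mu: baseline %.3f, post %.3f\n", x$mu[1], x$mu[2]))
  for (nm in c("cov_lesion", "cov_reader", "cov_interaction", "cov_residual")) {
    m <- x[[nm]]
    cat(sprintf("  %-16s var_b %.4f  var_p %.4f  cov %.4f\n",
                sub("cov_", "", nm), m[1, 1], m[2, 2], m[1, 2]))
  }
  invisible(x)
}

cov2 <- function(v_b, v_p, cov_bp) {
  matrix(c(v_b, cov_bp, cov_bp, v_p), 2L, 2L)
}

#' Default ground-truth variance components
#'
#' Reference parameter sets for simulation and testing, on the sqrt(mm)
#' scale. They are chosen so that a hypothetical second reading of a typical
#' burden by another reader changes its size by less than about 10% relative
#' to the first reading, the magnitude reported for repeat imaging of
#' single-tumor burdens. Lesion effects dominate (true size variation across
#' lesions), reader and interaction effects are small, and baseline/post
#' effects are positively correlated. The short-axis set is slightly tighter
#' than the long-axis set, mirroring the smaller percent-change variance of
#' short-axis readings.
#'
#' @param axis `"long"` or `"short"`.
#' @return A [variance_components()] object.
#' @export
default_variance_components <- function(axis = c("long", "short")) {
  axis <- match.arg(axis)
  if (axis == "long") {
    variance_components(
      mu = c(6.0, 5.5),
      cov_lesion      = cov2(1.60^2, 1.60^2, 0.95 * 1.60 * 1.60),
      cov_reader      = cov2(0.08^2, 0.08^2, 0.80 * 0.08 * 0.08),
      cov_interaction = cov2(0.08^2, 0.08^2, 0.50 * 0.08 * 0.08),
      cov_residual    = cov2(0.10^2, 0.10^2, 0.30 * 0.10 * 0.10))
  } else {
    variance_components(
      mu = c(4.5, 4.2),
      cov_lesion      = cov2(1.10^2, 1.10^2, 0.95 * 1.10 * 1.10),
      cov_reader      = cov2(0.06^2, 0.06^2, 0.80 * 0.06 * 0.06),
      cov_interaction = cov2(0.06^2, 0.06^2, 0.50 * 0.06 * 0.06),
      cov_residual    = cov2(0.08^2, 0.08^2, 0.30 * 0.08 * 0.08))
  }
}

#' Intra-reader measurement-error distribution
#'
#' The residual term of the fitted model is the disagreement of one reader
#' with themself across sessions, given a lesion: the intra-reader error.
#'
#' @param vc a [variance_components()] object.
#' @return An object of class `error_distribution` with `mode = "intra"` and
#'   `cov = cov_residual` (mean identically zero).
#' @export
intra_error_cov <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  structure(list(mode = "intra", cov = vc$cov_residual),
            class = "error_distribution")
}

#' Inter-reader measurement-error distribution
#'
#' Disagreement between two distinct readers of the same lesion combines the
#' reader effect, the lesion-by-reader interaction, and half the residual
#' variance:
#' `cov = cov_reader + cov_interaction + cov_residual / 2`, elementwise.
#'
#' @param vc a [variance_components()] object.
#' @return An object of class `error_distribution` with `mode = "inter"`.
#' @export
inter_error_cov <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  structure(list(mode = "inter",
                 cov = vc$cov_reader + vc$cov_interaction + vc$cov_residual / 2),
            class = "error_distribution")
}

#' @export
print.error_distribution <- function(x, ...) {
  cat(sprintf("%s-reader error distribution (sqrt-mm scale, mean zero)\n", x$mode))
  cat(sprintf("  var_b %.4f  var_p %.4f  cov %.4f\n",
              x$cov[1, 1], x$cov[2, 2], x$cov[1, 2]))
  invisible(x)
}

# Build an error_distribution directly from a covariance matrix.
error_distribution <- function(mode, cov) {
  stopifnot(mode %in% c("intra", "inter"), is_psd2(cov))
  structure(list(mode = mode, cov = cov), class = "error_distribution")
}
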