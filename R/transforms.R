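#' nth-root transform of a measurement
#'
#' Root transforms stabilise the size-dependency of radiologic measurement
#' error: on the root scale the error spread is approximately constant,
#' while on the original scale it grows with lesion size.
#'
#' @param value non-negative numeric vector (millimetres).
#' @param n_root 1 (identity), 2 (square root) or 3 (cube root).
#' @return `value^(1/n_root)`.
#' @export
nth_root <- function(value, n_root) {
  n_root <- as.integer(n_root)
  if (!n_root %in% 1:3) stop("n_root must be 1, 2 or 3", call. = FALSE)
  if (any(value < 0, na.rm = TRUE)) {
    stop("nth_root is defined for non-negative values only", call. = FALSE)
  }
  value^(1 / n_root)
}

#' Bland-Altman limits of agreement on a transformed scale
#'
#' Differences between paired measurements are computed after an nth-root
#' (or log) transform; the limits of agreement are
#' `mean(diff) +/- 1.96 sd(diff)` with the n-1 denominator for the SD. The
#' conventional 1.96 multiplier is used, not a t quantile.
#'
#' @param x,y paired positive measurement vectors (first and second
#'   measurements of the same quantities).
#' @param n_root root order passed to [nth_root()]; ignored when
#'   `use_log = TRUE`.
#' @param use_log compute differences on the natural-log scale instead
#'   (transform-comparison mode only; downstream modelling uses the square
#'   root).
#' @return An object of class `loa_result`: a list with `n_root`, `use_log`,
#'   `mean_diff_trans`, `sd_diff_trans`, `loa_trans` (lower, upper) and a
#'   `data` frame of per-pair transformed means and differences.
#' @examples
#' ba <- bland_altman(c(100, 121, 144), c(81, 100, 121), n_root = 2)
#' ba$loa_trans  # degenerate (1, 1): all sqrt differences equal 1
#' @export
bland_altman <- function(x, y, n_root = 1L, use_log = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) {
    stop("at least 3 measurement pairs are required for limits of agreement",
         call. = FALSE)
  }
  if (any(c(x, y) <= 0)) stop("measurements must be positive", call. = FALSE)
  if (use_log) {
    tx <- log(x); ty <- log(y)
  } else {
    tx <- nth_root(x, n_root); ty <- nth_root(y, n_root)
  }
  d <- tx - ty
  m <- mean(d)
  s <- sd(d)
  structure(list(n_root = as.integer(n_root), use_log = use_log,
                 mean_diff_trans = m, sd_diff_trans = s,
                 loa_trans = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
                 data = data.frame(mean_trans = (tx + ty) / 2, diff_trans = d)),
            class = "loa_result")
}

#' @export
print.loa_result <- function(x, ...) {
  scale_lab <- if (x$use_log) "log" else switch(x$n_root, "original", "square-root", "cube-root")
  cat(sprintf("Limits of agreement (%s scale, n = %d): %.4f +/- 1.96 x %.4f -> (%.4f, %.4f)\n",
              scale_lab, nrow(x$data), x$mean_diff_trans, x$sd_diff_trans,
              x$loa_trans[1], x$loa_trans[2]))
  invisible(x)
}

#' Back-transform limits of agreement to the original scale
#'
#' A limit `L` on the nth-root scale corresponds, at a measurement pair with
#' mean `m` on the original scale, to a difference of
#' `D(m, L) = (m^(1/n) + L/2)^n - (m^(1/n) - L/2)^n`,
#' assuming the two transformed measurements straddle `m^(1/n)`
#' symmetrically. For `n = 1` this reduces to `L`; for `n = 2` the cross
#' terms cancel and `D(m, L) = 2 sqrt(m) L` exactly, so the limits fan out
#' with the measurement size. If the inner term `m^(1/n) - |L|/2` would be
#' negative it is clamped at zero with a warning.
#'
#' @param mean_value positive mean measurement(s) on the original scale.
#' @param loa_trans numeric vector of limits on the transformed scale
#'   (typically the two limits from [bland_altman()]).
#' @param n_root root order (1, 2 or 3).
#' @return A matrix with one row per `mean_value` and one column per limit:
#'   original-scale difference limits at that mean.
#' @export
loa_original_scale <- function(mean_value, loa_trans, n_root) {
  n_root <- as.integer(n_root)
  if (!n_root %in% 1:3) stop("n_root must be 1, 2 or 3", call. = FALSE)
  if (any(mean_value <= 0)) stop("mean_value must be positive", call. = FALSE)
  a <- mean_value^(1 / n_root)
  out <- vapply(loa_trans, function(L) {
    lo <- a - abs(L) / 2
    if (any(lo < 0)) {
      warning("transformed limit exceeds twice the root-scale mean; ",
              "inner term clamped at 0", call. = FALSE)
      lo <- pmax(lo, 0)
    }
    # restore the sign convention: D(m, -L) = -D(m, L)
    sign(L) * ((a + abs(L) / 2)^n_root - lo^n_root)
  }, numeric(length(mean_value)))
  out <- matrix(out, nrow = length(mean_value))
  dimnames(out) <- list(NULL, names(loa_trans))
  out
}

#' Bland-Altman panel with limits of agreement for candidate transforms
#'
#' Plots transformed-scale differences against pair means on the original
#' scale, with the original-scale limits of each candidate transform drawn
#' as fanning curves. Used to choose the transform whose limits track the
#' size-dependency of the data.
#'
#' @param x,y paired positive measurements.
#' @param n_roots root orders to overlay (subset of 1:3).
#' @param use_log also overlay the log-scale limits.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_bland_altman <- function(x, y, n_roots = c(1L, 2L, 3L), use_log = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot_bland_altman", call. = FALSE)
  }
  m_raw <- (x + y) / 2
  pts <- data.frame(mean_mm = m_raw, diff_mm = x - y)
  grid <- seq(max(min(m_raw), 1e-6), max(m_raw), length.out = 200)
  curves <- list()
  for (n in n_roots) {
    ba <- bland_altman(x, y, n_root = n)
    lim <- loa_original_scale(grid, ba$loa_trans, n)
    curves[[length(curves) + 1]] <- data.frame(
      mean_mm = rep(grid, 2),
      limit_mm = c(lim[, 1], lim[, 2]),
      which_limit = rep(c("lower", "upper"), each = length(grid)),
      transform = switch(n, "identity", "square root", "cube root"))
  }
  if (use_log) {
    ba <- bland_altman(x, y, use_log = TRUE)
    # log-scale limit L maps to a difference m*(exp(L/2) - exp(-L/2)) at mean m
    lim <- outer(grid, ba$loa_trans, function(m, L) m * (exp(L / 2) - exp(-L / 2)))
    curves[[length(curves) + 1]] <- data.frame(
      mean_mm = rep(grid, 2), limit_mm = c(lim[, 1], lim[, 2]),
      which_limit = rep(c("lower", "upper"), each = length(grid)),
      transform = "log")
  }
  curves <- do.call(rbind, curves)
  curves$grp <- interaction(curves$transform, curves$which_limit)
  ggplot2::ggplot(pts, ggplot2::aes(x = mean_mm, y = diff_mm)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = limit_mm, linetype = transform, group = grp)) +
    ggplot2::labs(x = "Mean of paired measurements (mm)",
                  y = "Difference between measurements (mm)",
                  linetype = "Transform")
}
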