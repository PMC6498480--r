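# Reassessment simulation: artificial tumor burdens, sqrt-scale
# perturbation, designation probabilities and scenario tables.

#' Simulation scenario
#'
#' A scenario fixes the burden composition (numbers of solid lesions and
#' lymph nodes), the first-reading percent change `c`, the reader mode, and
#' — for single-lesion burdens only — the baseline diameter. Solid lesions
#' are measured on the long axis (grid 10-150 mm) and lymph nodes on the
#' short axis (grid 10-80 mm); `c` lives on a 0.01 grid in `[-1, 1]`.
#'
#' @param n_solid number of solid lesions (0-5).
#' @param n_lymph number of lymph nodes (0-2); `n_solid + n_lymph` in 1-5.
#' @param c fractional percent change in `[-1, 1]`.
#' @param baseline_mm baseline diameter in mm; required for single-lesion
#'   scenarios and disallowed otherwise (multi-lesion burdens draw sizes
#'   from the empirical log-normal).
#' @param reader_mode `"inter"` (another reader) or `"intra"` (same reader).
#' @return A one-row data frame (class `scenario`).
#' @seealso [scenario_grid()], [estimate_probabilities()]
#' @export
scenario <- function(n_solid, n_lymph = 0L, c, baseline_mm = NULL,
                     reader_mode = c("inter", "intra")) {
  reader_mode <- match.arg(reader_mode)
  n_solid <- as.integer(n_solid); n_lymph <- as.integer(n_lymph)
  n <- n_solid + n_lymph
  if (n_solid < 0 || n_solid > 5 || n_lymph < 0 || n_lymph > 2 || n < 1 || n > 5) {
    stop("composition must satisfy 0 <= n_solid <= 5, 0 <= n_lymph <= 2, ",
         "1 <= n_solid + n_lymph <= 5", call. = FALSE)
  }
  if (c < -1 || c > 1) stop("c must lie in [-1, 1]", call. = FALSE)
  if (n == 1) {
    if (is.null(baseline_mm) || baseline_mm <= 0) {
      stop("single-lesion scenarios require a positive baseline_mm", call. = FALSE)
    }
  } else if (!is.null(baseline_mm)) {
    stop("baseline_mm applies to single-lesion scenarios only", call. = FALSE)
  }
  structure(data.frame(n_solid = n_solid, n_lymph = n_lymph,
                       baseline_mm = baseline_mm %||% NA_real_,
                       c = c, reader_mode = reader_mode,
                       stringsAsFactors = FALSE),
            class = c("scenario", "data.frame"))
}

#' Build a grid of scenarios
#'
#' Cartesian product of compositions, baselines (single-lesion only) and
#' percent changes, ready for [build_probability_table()]. The full
#' single-lesion reference grids are `baseline_mm = 10:150` (long axis) or
#' `10:80` (short axis) with `c = seq(-1, 1, by = 0.01)`; reduced grids are
#' fine for targeted evaluations.
#'
#' @param n_solid,n_lymph composition (scalars).
#' @param baseline_mm numeric vector of baselines (single-lesion only;
#'   use `NA` otherwise).
#' @param c numeric vector of fractional changes in `[-1, 1]`.
#' @param reader_mode `"inter"`, `"intra"`, or both.
#' @return Data frame of scenario rows.
#' @export
scenario_grid <- function(n_solid, n_lymph = 0L, baseline_mm = NA_real_,
                          c = round(seq(-1, 1, by = 0.01), 2),
                          reader_mode = "inter") {
  g <- expand.grid(n_solid = as.integer(n_solid), n_lymph = as.integer(n_lymph),
                   baseline_mm = baseline_mm, c = c,
                   reader_mode = reader_mode,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  single <- g$n_solid + g$n_lymph == 1
  if (any(single & is.na(g$baseline_mm))) {
    stop("single-lesion scenarios require baseline_mm", call. = FALSE)
  }
  if (any(!single & !is.na(g$baseline_mm))) {
    stop("baseline_mm applies to single-lesion scenarios only", call. = FALSE)
  }
  g
}

# Default fraction-scale variance of per-lesion percent changes around the
# burden-level change, estimated from multi-lesion burdens: 0.17 for
# long-axis (solid) and 0.10 for short-axis (lymph) lesions.
default_change_var <- c(long = 0.17, short = 0.10)

# Default empirical baseline size distribution (log-normal, mm scale).
default_size_dist <- c(meanlog = 3.55, sdlog = 0.53)

# Truncated log-normal sampler on [lo, hi] via inverse CDF.
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi = Inf) {
  u <- runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog))
  qlnorm(u, meanlog, sdlog)
}

#' Sample a set of artificial tumor burdens for a scenario
#'
#' Builds `n_burdens` first-reading burdens with the scenario's composition
#' and burden-level percent change `c`. Single-lesion burdens use the fixed
#' `baseline_mm`; multi-lesion baselines are drawn from a log-normal
#' truncated to the measurable range (>= 10 mm on the long axis, 10-80 mm
#' on the short axis). Because lesions within a burden do not change
#' uniformly, per-lesion changes `c_x` are drawn from
#' `Normal(c, change_var)` and then shifted by a common size-weighted
#' discrepancy so that `sum(c_x * Y_bx) = c * sum(Y_bx)` holds exactly;
#' changes are floored at -1 (a lesion cannot lose more than its whole
#' size), with the deficit redistributed over the remaining lesions so the
#' restriction survives the floor. Post sizes `Y_bx (1 + c_x)` are clamped
#' at 0.
#'
#' @param scn a [scenario()] or one-row data frame with the same columns.
#' @param n_burdens number of burdens (default 100).
#' @param size_dist named vector `c(meanlog, sdlog)` of the baseline
#'   log-normal.
#' @param change_var fraction-scale variance(s) of per-lesion changes:
#'   named vector with entries `long` and/or `short` (defaults 0.17, 0.10).
#' @param seed optional seed.
#' @return An object of class `burden_set`: list with `organ` (length-n
#'   character), `Yb` and `Yp` (`n_burdens` x n matrices, mm).
#' @export
sample_burden_set <- function(scn, n_burdens = 100L,
                              size_dist = default_size_dist,
                              change_var = default_change_var, seed = NULL) {
  stopifnot(n_burdens >= 1)
  organ <- c(rep("solid", scn$n_solid), rep("lymph", scn$n_lymph))
  n_les <- length(organ)
  cv <- change_var_for(organ, change_var)
  with_seed_maybe(seed, {
    if (n_les == 1) {
      Yb <- matrix(scn$baseline_mm, n_burdens, 1L)
    } else {
      Yb <- vapply(organ, function(o) {
        if (o == "solid") rlnorm_trunc(n_burdens, size_dist["meanlog"],
                                       size_dist["sdlog"], lo = 10)
        else rlnorm_trunc(n_burdens, size_dist["meanlog"], size_dist["sdlog"],
                          lo = 10, hi = 80)
      }, numeric(n_burdens))
      Yb <- matrix(Yb, nrow = n_burdens)
    }
    if (n_les == 1) {
      cx <- matrix(scn$c, n_burdens, 1L)
    } else {
      cx <- vapply(seq_len(n_les),
                   function(j) rnorm(n_burdens, scn$c, sqrt(cv[j])),
                   numeric(n_burdens))
      cx <- matrix(cx, nrow = n_burdens)
      for (i in seq_len(n_burdens)) {
        cx[i, ] <- constrain_changes(cx[i, ], Yb[i, ], scn$c)
      }
    }
    Yp <- pmax(Yb * (1 + cx), 0)
    structure(list(organ = organ, Yb = Yb, Yp = Yp), class = "burden_set")
  })
}

# Enforce the size-weighted restriction sum(cx * Yb) = c * sum(Yb) exactly
# while respecting the physical floor cx >= -1 (a lesion cannot shrink by
# more than 100%). Free per-lesion changes are shifted by a common amount;
# changes pinned at -1 stay there and their deficit is redistributed over
# the remaining lesions (at most n passes; feasible whenever c >= -1).
constrain_changes <- function(cx, yb, c_target) {
  total <- sum(yb)
  for (pass in seq_len(length(cx) + 1L)) {
    cx <- pmax(cx, -1)
    resid <- c_target * total - sum(cx * yb)
    if (abs(resid) < 1e-12 * max(1, total)) return(cx)
    if (resid > 0) {
      cx <- cx + resid / total  # moving up never violates the floor
    } else {
      free <- cx > -1
      if (!any(free)) return(cx)  # c_target = -1: all pinned, exact
      cx[free] <- cx[free] + resid / sum(yb[free])
    }
  }
  cx
}

change_var_for <- function(organ, change_var) {
  if (length(change_var) == 1 && is.null(names(change_var))) {
    return(rep(as.numeric(change_var), length(organ)))
  }
  axis <- ifelse(organ == "solid", "long", "short")
  unname(change_var[axis])
}

#' Perturb burdens with measurement error (hypothetical second assessment)
#'
#' For each lesion, a correlated (baseline, post) error pair is drawn from
#' the sqrt-scale error distribution and added to the square roots of the
#' first-reading sizes; the sums are then squared:
#' `Y' = (sqrt(Y) + eps)^2`. Perturbed square roots below 0 are clamped at
#' 0 before squaring, so sizes never go negative. Errors are drawn
#' independently across the lesions of a burden, each from the error model
#' matching the lesion's axis.
#'
#' @param burdens a `burden_set` from [sample_burden_set()].
#' @param err an `error_distribution` (applied to every lesion), or a named
#'   list `list(long = ..., short = ...)` for mixed burdens.
#' @param seed optional seed.
#' @return A `burden_set` of second-assessment sizes.
#' @export
perturb_burden <- function(burdens, err, seed = NULL) {
  stopifnot(inherits(burdens, "burden_set"))
  n <- nrow(burdens$Yb)
  with_seed_maybe(seed, {
    Yb2 <- burdens$Yb; Yp2 <- burdens$Yp
    for (j in seq_along(burdens$organ)) {
      cov_j <- err_cov_for(err, burdens$organ[j])
      eps <- rmvn2(n, cov_j)
      Yb2[, j] <- perturb_sqrt(burdens$Yb[, j], eps[, 1])
      Yp2[, j] <- perturb_sqrt(burdens$Yp[, j], eps[, 2])
    }
    structure(list(organ = burdens$organ, Yb = Yb2, Yp = Yp2),
              class = "burden_set")
  })
}

perturb_sqrt <- function(y, eps) pmax(sqrt(y) + eps, 0)^2

err_cov_for <- function(err, organ) {
  if (inherits(err, "error_distribution")) return(err$cov)
  axis <- if (organ == "solid") "long" else "short"
  e <- err[[axis]]
  if (is.null(e)) stop("no error distribution supplied for the ", axis,
                       " axis", call. = FALSE)
  e$cov
}

#' Estimate designation probabilities upon reassessment
#'
#' Builds a burden set for the scenario, perturbs each burden once with the
#' error distribution, and estimates as proportions the probability that the
#' second-assessment percent change would be designated an objective
#' response (`<= -0.3`) or progression (`>= 0.2`). A perturbed baseline
#' burden of exactly 0 is redrawn (count recorded in the `n_redrawn`
#' attribute).
#'
#' @inheritParams sample_burden_set
#' @param err see [perturb_burden()].
#' @return Named numeric `c(p_response, p_progression)`.
#' @export
estimate_probabilities <- function(scn, err, n_burdens = 100L,
                                   size_dist = default_size_dist,
                                   change_var = default_change_var,
                                   seed = NULL) {
  with_seed_maybe(seed, {
    first <- sample_burden_set(scn, n_burdens, size_dist, change_var)
    second <- perturb_burden(first, err)
    sb <- rowSums(second$Yb); sp <- rowSums(second$Yp)
    n_redrawn <- 0L
    while (any(bad <- sb == 0) && n_redrawn < 100L * n_burdens) {
      idx <- which(bad)
      n_redrawn <- n_redrawn + length(idx)
      redo_first <- sample_burden_set(scn, length(idx), size_dist, change_var)
      redo <- perturb_burden(redo_first, err)
      sb[idx] <- rowSums(redo$Yb); sp[idx] <- rowSums(redo$Yp)
    }
    cprime <- (sp - sb) / sb
    structure(c(p_response = mean(cprime <= -0.3),
                p_progression = mean(cprime >= 0.2)),
              n_redrawn = n_redrawn)
  })
}

#' Build a scenario-indexed probability table
#'
#' For each scenario, the burden construction + perturbation + probability
#' estimation cycle is iterated `n_iter` times, each iteration under the
#' error covariance implied by a randomly drawn posterior sample of the
#' variance components; the stored entry is the median of the `n_iter`
#' probability estimates. Solid lesions use the long-axis posterior, lymph
#' nodes the short-axis posterior; the reader mode of each scenario selects
#' the intra- or inter-reader covariance of the draw.
#'
#' With a single-draw (REML) posterior the effective iteration count is 1
#' and the entry is that iteration's estimate.
#'
#' @param grid data frame of scenario rows (see [scenario_grid()]).
#' @param posterior_long `posterior_draws` from the long-axis fit (needed
#'   when any scenario has solid lesions).
#' @param posterior_short `posterior_draws` from the short-axis fit (needed
#'   when any scenario has lymph nodes).
#' @param n_iter posterior iterations per scenario (default 100, capped at
#'   the number of available draws).
#' @param n_burdens burdens per iteration (default 100).
#' @inheritParams sample_burden_set
#' @return A `probability_table`: the grid with `p_response` and
#'   `p_progression` columns and `n_iter`/`n_burdens` attributes.
#' @export
build_probability_table <- function(grid, posterior_long = NULL,
                                    posterior_short = NULL, n_iter = 100L,
                                    n_burdens = 100L,
                                    size_dist = default_size_dist,
                                    change_var = default_change_var,
                                    seed = NULL) {
  if (nrow(grid) == 0) stop("empty scenario grid", call. = FALSE)
  if (any(grid$n_solid > 0) && is.null(posterior_long)) {
    stop("scenarios with solid lesions require posterior_long", call. = FALSE)
  }
  if (any(grid$n_lymph > 0) && is.null(posterior_short)) {
    stop("scenarios with lymph nodes require posterior_short", call. = FALSE)
  }
  n_avail <- min(if (is.null(posterior_long)) Inf else length(posterior_long$draws),
                 if (is.null(posterior_short)) Inf else length(posterior_short$draws))
  n_iter_eff <- as.integer(min(n_iter, n_avail))
  with_seed_maybe(seed, {
    p <- matrix(NA_real_, nrow(grid), 2L)
    for (s in seq_len(nrow(grid))) {
      scn <- grid[s, , drop = FALSE]
      est <- matrix(NA_real_, n_iter_eff, 2L)
      for (it in seq_len(n_iter_eff)) {
        err <- list()
        if (scn$n_solid > 0) {
          d <- posterior_long$draws[[sample.int(length(posterior_long$draws), 1)]]
          err$long <- if (scn$reader_mode == "intra") intra_error_cov(d) else inter_error_cov(d)
        }
        if (scn$n_lymph > 0) {
          d <- posterior_short$draws[[sample.int(length(posterior_short$draws), 1)]]
          err$short <- if (scn$reader_mode == "intra") intra_error_cov(d) else inter_error_cov(d)
        }
        est[it, ] <- estimate_probabilities(scn, err, n_burdens,
                                            size_dist, change_var)
      }
      p[s, ] <- apply(est, 2, median)
    }
    out <- grid
    out$p_response <- p[, 1]
    out$p_progression <- p[, 2]
    structure(out, n_iter = n_iter_eff, n_burdens = as.integer(n_burdens),
              class = c("probability_table", "data.frame"))
  })
}

#' Look up reassessment probabilities for patient burden summaries
#'
#' Matches each patient to a table entry: the percent change is converted to
#' the fractional scale, clamped to `[-1, 1]` (growth beyond +100% is
#' designated progression with probability ~1, so the clamp is benign) and
#' matched to the nearest tabulated `c`; single-lesion burdens are matched
#' to the nearest tabulated baseline (clamped to the covered range, with a
#' warning); multi-lesion burdens are matched by composition only.
#'
#' @param table a `probability_table`.
#' @param summary per-patient burden summaries from [summarize_burden()].
#' @param reader_mode `"inter"` or `"intra"`; must be present in the table.
#' @return Data frame: `patient_id`, `p_response`, `p_progression`.
#' @export
lookup_probability <- function(table, summary, reader_mode = c("inter", "intra")) {
  stopifnot(inherits(table, "probability_table"))
  reader_mode <- match.arg(reader_mode)
  out <- summary[, "patient_id", drop = FALSE]
  out$p_response <- NA_real_
  out$p_progression <- NA_real_
  for (i in seq_len(nrow(summary))) {
    row <- summary[i, ]
    sub <- table[table$n_solid == row$n_solid & table$n_lymph == row$n_lymph &
                   table$reader_mode == reader_mode, , drop = FALSE]
    if (nrow(sub) == 0) {
      avail <- unique(table[, c("n_solid", "n_lymph", "reader_mode")])
      stop("no table entries for patient ", row$patient_id, " (", row$n_solid,
           " solid, ", row$n_lymph, " lymph, ", reader_mode,
           " mode); available compositions:\n",
           paste(utils::capture.output(print(avail)), collapse = "\n"),
           call. = FALSE)
    }
    c_frac <- row$percent_change / 100
    if (c_frac > 1) {
      warning("percent change above +100% for patient ", row$patient_id,
              "; clamped to +100%", call. = FALSE)
      c_frac <- 1
    }
    c_frac <- round(max(c_frac, -1), 2)
    if (row$n_solid + row$n_lymph == 1) {
      b <- row$burden_baseline_mm
      rng <- range(sub$baseline_mm)
      # within half the 1 mm grid step of an edge is nearest-matching,
      # not clamping
      if (b < rng[1] - 0.5 || b > rng[2] + 0.5) {
        warning("baseline ", b, " mm for patient ", row$patient_id,
                " outside the tabulated range [", rng[1], ", ", rng[2],
                "]; clamped", call. = FALSE)
        b <- min(max(b, rng[1]), rng[2])
      }
      sub <- sub[abs(sub$baseline_mm - b) == min(abs(sub$baseline_mm - b)), ,
                 drop = FALSE]
    }
    hit <- sub[abs(sub$c - c_frac) == min(abs(sub$c - c_frac)), , drop = FALSE]
    out$p_response[i] <- hit$p_response[1]
    out$p_progression[i] <- hit$p_progression[1]
  }
  out
}

#' Write / read a probability table as CSV
#'
#' Table construction is slow relative to trial evaluation; serializing the
#' table decouples the two.
#'
#' @param table a `probability_table`.
#' @param path CSV path.
#' @return `path` (write) or the `probability_table` (read).
#' @export
write_probability_table <- function(table, path) {
  stopifnot(inherits(table, "probability_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_probability_table
#' @export
read_probability_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("n_solid", "n_lymph", "baseline_mm", "c", "reader_mode",
           "p_response", "p_progression")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("probability table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("probability_table", "data.frame"))
}
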