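# Trial-level evaluation: 95% central ranges of reassessed rates,
# coverage validation, and the simulation-study runner.

evaluation_result <- function(rates, kind) {
  cr <- central_range_95(rates)
  structure(list(rates = rates, median = median(rates),
                 central_range_95 = cr, kind = kind,
                 n_reps = length(rates)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  lab <- if (x$kind == "ORR") "objective response rate" else "progression rate"
  cat(sprintf("Reassessed %s over %d simulated trials:\n", lab, x$n_reps))
  cat(sprintf("  median %.1f%%, 95%% central range (%.1f%%, %.1f%%)\n",
              x$median, x$central_range_95[1], x$central_range_95[2]))
  invisible(x)
}

#' Evaluate the impact of measurement variability on a trial's rates
#'
#' For each patient, the probability that a hypothetical reassessment would
#' designate an objective response (and, separately, progression) is looked
#' up from the probability table. Each simulated repetition of the trial
#' draws a Bernoulli event per patient at those probabilities; definitive
#' progression patients (unequivocal radiologic progression, symptomatic
#' progression, or death) contribute progression = 1 and response = 0 with
#' certainty and are counted in both denominators. Repeating the trial
#' `n_reps` times yields the simulated distribution of the reassessed ORR
#' and progression rate, summarised by the median and the 95% central range
#' (2.5th-97.5th percentiles, linear interpolation). Response and
#' progression events are drawn independently; this affects no marginal
#' rate summary.
#'
#' @param trial a [trial_dataset()].
#' @param table a `probability_table` covering every patient's composition.
#' @param reader_mode `"inter"` or `"intra"`.
#' @param n_reps number of simulated trial repetitions (default 1000).
#' @param seed optional seed.
#' @return List with `orr` and `progression` (`evaluation_result` objects),
#'   `probabilities` (per-patient lookup), and `n_patients` (denominator).
#' @export
evaluate_trial <- function(trial, table, reader_mode = c("inter", "intra"),
                           n_reps = 1000L, seed = NULL) {
  stopifnot(inherits(trial, "trial_dataset"), n_reps >= 1)
  reader_mode <- match.arg(reader_mode)
  summary <- summarize_burden(trial)
  n_def <- n_definitive_progression(trial)
  n_eval <- nrow(summary)
  n_total <- n_eval + n_def
  if (n_total == 0) stop("trial has no patients", call. = FALSE)
  probs <- if (n_eval > 0) {
    lookup_probability(table, summary, reader_mode)
  } else {
    data.frame(patient_id = character(), p_response = numeric(),
               p_progression = numeric())
  }
  with_seed_maybe(seed, {
    if (n_eval > 0) {
      resp <- matrix(rbinom(n_eval * n_reps, 1L, rep(probs$p_response, n_reps)),
                     nrow = n_eval)
      prog <- matrix(rbinom(n_eval * n_reps, 1L, rep(probs$p_progression, n_reps)),
                     nrow = n_eval)
      resp_counts <- colSums(resp)
      prog_counts <- colSums(prog) + n_def
    } else {
      resp_counts <- rep(0L, n_reps)
      prog_counts <- rep(n_def, n_reps)
    }
    list(orr = evaluation_result(100 * resp_counts / n_total, "ORR"),
         progression = evaluation_result(100 * prog_counts / n_total,
                                         "progression"),
         probabilities = probs, n_patients = n_total)
  })
}

#' 95% central ranges of hypothetical second burden readings
#'
#' For each patient, the first-reading burden is perturbed `n_sims` times
#' with the error distribution (per lesion, on the sqrt scale) and the
#' 2.5th-97.5th percentile interval of the resulting burden sizes is
#' reported per phase. Used to validate the fitted error distribution
#' against actual repeat readings.
#'
#' @param trial a [trial_dataset()] (first readings).
#' @param err an `error_distribution`, or `list(long = , short = )` for
#'   mixed-axis burdens.
#' @param n_sims simulated second readings per burden (>= 100; default
#'   1000).
#' @param seed optional seed.
#' @return Data frame with one row per (patient, phase): `patient_id`,
#'   `phase`, `observed_mm`, `lower_mm`, `upper_mm`.
#' @export
burden_second_reading_ranges <- function(trial, err, n_sims = 1000L,
                                         seed = NULL) {
  stopifnot(inherits(trial, "trial_dataset"))
  if (n_sims < 100) stop("n_sims must be at least 100", call. = FALSE)
  ids <- unique(trial$patient_id)
  with_seed_maybe(seed, {
    rows <- lapply(ids, function(id) {
      les <- trial[trial$patient_id == id, , drop = FALSE]
      first <- structure(list(
        organ = les$organ,
        Yb = matrix(les$baseline_mm, n_sims, nrow(les), byrow = TRUE),
        Yp = matrix(les$post_mm, n_sims, nrow(les), byrow = TRUE)),
        class = "burden_set")
      second <- perturb_burden(first, err)
      qb <- central_range_95(rowSums(second$Yb))
      qp <- central_range_95(rowSums(second$Yp))
      data.frame(patient_id = id, phase = c("baseline", "post"),
                 observed_mm = c(sum(les$baseline_mm), sum(les$post_mm)),
                 lower_mm = c(qb[1], qp[1]), upper_mm = c(qb[2], qp[2]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

coverage_report <- function(n_total, n_covered) {
  structure(list(n_total = as.integer(n_total),
                 n_covered = as.integer(n_covered),
                 coverage_percent = 100 * n_covered / n_total),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage: %d of %d (%.1f%%)\n", x$n_covered, x$n_total,
              x$coverage_percent))
  invisible(x)
}

#' Coverage of second-reading central ranges over actual second readings
#'
#' A burden counts as covered, per phase, when the actual second-reading
#' size lies inside the simulated 95% central range; the report pools the
#' baseline and post phases. Coverage near 95% indicates that the fitted
#' error distribution is calibrated.
#'
#' @param ranges output of [burden_second_reading_ranges()].
#' @param actual_second a [trial_dataset()] of the actual second readings
#'   (same patients).
#' @return A `coverage_report`: `n_total`, `n_covered`, `coverage_percent`.
#' @export
coverage_of_second_readings <- function(ranges, actual_second) {
  stopifnot(inherits(actual_second, "trial_dataset"))
  s2 <- summarize_burden(actual_second)
  miss <- setdiff(unique(ranges$patient_id), s2$patient_id)
  extra <- setdiff(s2$patient_id, unique(ranges$patient_id))
  if (length(miss) > 0 || length(extra) > 0) {
    stop("patient IDs do not align between ranges and second readings",
         call. = FALSE)
  }
  m <- match(ranges$patient_id, s2$patient_id)
  actual <- ifelse(ranges$phase == "baseline",
                   s2$burden_baseline_mm[m], s2$burden_post_mm[m])
  covered <- actual >= ranges$lower_mm & actual <= ranges$upper_mm
  coverage_report(length(covered), sum(covered))
}

#' Bootstrap coverage of the reassessed-ORR central range
#'
#' Draws `n_boot` patient-level resamples (with replacement) of the paired
#' first/second-reading datasets. Per resample, the 95% central range of
#' simulated reassessed ORRs is computed from the first readings and the
#' observed ORR from the second readings of the same resampled patients;
#' the report gives the fraction of resamples whose range covers the
#' observed second-reading ORR. The definitive-progression count of the
#' first-reading dataset is held fixed across resamples.
#'
#' @param trial_first,trial_second paired [trial_dataset()]s sharing
#'   patient IDs.
#' @param table a `probability_table` covering the compositions.
#' @param reader_mode `"inter"` or `"intra"`.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param n_reps simulated repetitions per resample (default 1000).
#' @param seed optional seed.
#' @return A `coverage_report`.
#' @export
bootstrap_orr_coverage <- function(trial_first, trial_second, table,
                                   reader_mode = c("inter", "intra"),
                                   n_boot = 100L, n_reps = 1000L,
                                   seed = NULL) {
  stopifnot(inherits(trial_first, "trial_dataset"),
            inherits(trial_second, "trial_dataset"), n_boot >= 1)
  reader_mode <- match.arg(reader_mode)
  ids <- unique(trial_first$patient_id)
  if (!setequal(ids, unique(trial_second$patient_id))) {
    stop("first and second datasets must share patient IDs", call. = FALSE)
  }
  n_def <- n_definitive_progression(trial_first)
  s2 <- summarize_burden(trial_second)
  with_seed_maybe(seed, {
    covered <- logical(n_boot)
    for (bt in seq_len(n_boot)) {
      idx <- sample(ids, length(ids), replace = TRUE)
      first_b <- resample_patients(trial_first, idx, n_def)
      fit <- evaluate_trial(first_b, table, reader_mode, n_reps = n_reps)
      rng <- fit$orr$central_range_95
      c2 <- s2$percent_change[match(idx, s2$patient_id)] / 100
      obs_orr <- 100 * sum(c2 <= -0.3) / (length(idx) + n_def)
      covered[bt] <- obs_orr >= rng[1] && obs_orr <= rng[2]
    }
    coverage_report(n_boot, sum(covered))
  })
}

# Patient-level resample; duplicated draws of the same patient are kept
# distinct by suffixing the id.
resample_patients <- function(trial, idx, n_def) {
  rows <- lapply(seq_along(idx), function(k) {
    les <- trial[trial$patient_id == idx[k], , drop = FALSE]
    les$patient_id <- paste0(idx[k], "#", k)
    les
  })
  trial_dataset(do.call(rbind, rows), n_def)
}

#' Minimal probability table covering one trial
#'
#' Builds scenarios only at the (composition, baseline, percent change)
#' points the trial's patients actually occupy — baselines rounded to the
#' nearest mm and clamped to the reference grid (10-150 mm long axis,
#' 10-80 mm short axis), changes rounded to the nearest 0.01 and clamped to
#' `[-1, 1]` — instead of tabulating the full reference grid. Evaluation
#' through [lookup_probability()] then matches exactly.
#'
#' @param trial a [trial_dataset()].
#' @inheritParams build_probability_table
#' @param reader_mode reader mode(s) to tabulate.
#' @return A `probability_table`.
#' @export
probability_table_for_trial <- function(trial, posterior_long = NULL,
                                        posterior_short = NULL,
                                        reader_mode = "inter",
                                        n_iter = 100L, n_burdens = 100L,
                                        size_dist = default_size_dist,
                                        change_var = default_change_var,
                                        seed = NULL) {
  summary <- summarize_burden(trial)
  if (nrow(summary) == 0) stop("trial has no lesion rows", call. = FALSE)
  single <- summary$n_solid + summary$n_lymph == 1
  base <- ifelse(single,
                 ifelse(summary$n_solid == 1,
                        pmin(pmax(round(summary$burden_baseline_mm), 10), 150),
                        pmin(pmax(round(summary$burden_baseline_mm), 10), 80)),
                 NA_real_)
  cc <- round(pmin(pmax(summary$percent_change / 100, -1), 1), 2)
  grids <- lapply(reader_mode, function(rm) {
    g <- unique(data.frame(n_solid = summary$n_solid,
                           n_lymph = summary$n_lymph,
                           baseline_mm = base, c = cc,
                           reader_mode = rm, stringsAsFactors = FALSE))
    g
  })
  grid <- do.call(rbind, grids)
  build_probability_table(grid, posterior_long, posterior_short,
                          n_iter = n_iter, n_burdens = n_burdens,
                          size_dist = size_dist, change_var = change_var,
                          seed = seed)
}

#' Run a reproducibility simulation study
#'
#' For each configuration, trials of single-lesion solid burdens are
#' generated, and per replicate the observed ORR with its exact
#' (Clopper-Pearson) 95% confidence interval is contrasted with the median
#' and 95% central range of the reassessed ORR. Central ranges widen when
#' baselines are small and percent changes cluster near the -30% cutoff,
#' and tighten onto the CI when baselines are large and changes sit far
#' from the cutoff.
#'
#' @param configs a [trial_gen_config()] or list of them.
#' @param posterior_long `posterior_draws` from the long-axis fit.
#' @param reader_mode `"inter"` or `"intra"`.
#' @param n_replicates generated trials per configuration.
#' @param n_reps simulated repetitions per trial evaluation.
#' @param n_iter,n_burdens table-building settings (see
#'   [build_probability_table()]).
#' @param seed optional seed.
#' @return Data frame with one row per (configuration, replicate):
#'   observed ORR, exact 95% CI, reassessed median and 95% central range
#'   (all percent), and the central-range width.
#' @export
run_simulation_study <- function(configs, posterior_long,
                                 reader_mode = c("inter", "intra"),
                                 n_replicates = 1L, n_reps = 1000L,
                                 n_iter = 100L, n_burdens = 100L,
                                 seed = NULL) {
  reader_mode <- match.arg(reader_mode)
  if (inherits(configs, "trial_gen_config")) configs <- list(configs)
  with_seed_maybe(seed, {
    rows <- list()
    for (ci in seq_along(configs)) {
      cfg <- configs[[ci]]
      for (rep_i in seq_len(n_replicates)) {
        trial <- generate_trial(cfg)
        summary <- summarize_burden(trial)
        n <- nrow(summary)
        n_resp <- sum(summary$percent_change / 100 <= -0.3)
        ci95 <- as.numeric(binom.test(n_resp, n)$conf.int)
        tab <- probability_table_for_trial(trial, posterior_long,
                                           reader_mode = reader_mode,
                                           n_iter = n_iter,
                                           n_burdens = n_burdens)
        res <- evaluate_trial(trial, tab, reader_mode, n_reps = n_reps)
        cr <- res$orr$central_range_95
        rows[[length(rows) + 1]] <- data.frame(
          config = cfg$name %||% paste0("config_", ci), replicate = rep_i,
          n_patients = n, true_orr = cfg$true_orr %||% NA_real_,
          observed_orr = 100 * n_resp / n,
          ci_lower = 100 * ci95[1], ci_upper = 100 * ci95[2],
          reassessed_median = res$orr$median,
          cr_lower = cr[1], cr_upper = cr[2], cr_width = cr[2] - cr[1],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
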