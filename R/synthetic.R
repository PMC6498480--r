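# Synthetic-data generators with known ground truth: repeated readings from
# given variance components, trial datasets with controlled ORR and change
# distributions, and paired second readings from an error distribution.

#' Generate repeated readings from known variance components
#'
#' Builds sqrt-scale reading pairs additively as
#' `z_ijk = mu + alpha_i + beta_j + gamma_ij + eps_ijk`, with each effect
#' drawn from its bivariate normal, then squares them to millimetres
#' (negative sqrt-scale values are clamped at 0). The default shape mirrors
#' a reading study in which every target lesion is read by six radiologists
#' twice at baseline and twice after treatment.
#'
#' @param vc_true a [variance_components()] object (the ground truth).
#' @param n_lesions,n_readers,n_sessions design size (defaults 249, 6, 2;
#'   at least 2 lesions and 2 readers).
#' @param axis `"long"` or `"short"`; sets the record axis and organ
#'   (`"solid"` for long, `"lymph"` for short).
#' @param lesions_per_patient lesions are grouped into patients of this
#'   size (patient labels only; the model has no patient level).
#' @param seed optional seed.
#' @return A [reading_dataset()] of
#'   `n_lesions * n_readers * n_sessions * 2` records.
#' @export
generate_readings <- function(vc_true, n_lesions = 249L, n_readers = 6L,
                              n_sessions = 2L, axis = c("long", "short"),
                              lesions_per_patient = 3L, seed = NULL) {
  stopifnot(inherits(vc_true, "variance_components"))
  axis <- match.arg(axis)
  if (n_lesions < 2 || n_readers < 2 || n_sessions < 1) {
    stop("need n_lesions >= 2, n_readers >= 2, n_sessions >= 1", call. = FALSE)
  }
  organ <- if (axis == "long") "solid" else "lymph"
  with_seed_maybe(seed, {
    a <- rmvn2(n_lesions, vc_true$cov_lesion)
    b <- rmvn2(n_readers, vc_true$cov_reader)
    g <- rmvn2(n_lesions * n_readers, vc_true$cov_interaction)
    idx <- expand.grid(lesion = seq_len(n_lesions), reader = seq_len(n_readers),
                       session = seq_len(n_sessions))
    cell <- (idx$reader - 1L) * n_lesions + idx$lesion
    e <- rmvn2(nrow(idx), vc_true$cov_residual)
    z_b <- vc_true$mu[1] + a[idx$lesion, 1] + b[idx$reader, 1] + g[cell, 1] + e[, 1]
    z_p <- vc_true$mu[2] + a[idx$lesion, 2] + b[idx$reader, 2] + g[cell, 2] + e[, 2]
    lesion_id <- sprintf("L%03d", idx$lesion)
    patient_id <- sprintf("P%03d", (idx$lesion - 1L) %/% lesions_per_patient + 1L)
    reader_id <- sprintf("R%d", idx$reader)
    rec <- function(phase, z) {
      data.frame(lesion_id = lesion_id, patient_id = patient_id,
                 reader_id = reader_id, session = idx$session, phase = phase,
                 axis = axis, organ = organ,
                 diameter_mm = pmax(z, 0)^2, stringsAsFactors = FALSE)
    }
    out <- rbind(rec("baseline", z_b), rec("post", z_p))
    bad <- out$diameter_mm <= 0
    if (any(bad)) out$diameter_mm[bad] <- 1e-6  # clamp: keep records valid
    reading_dataset(out)
  })
}

#' Configuration for generating a synthetic trial
#'
#' Describes a trial of single-lesion solid-organ patients: baseline sizes
#' from a log-normal truncated to the measurable range (>= 10 mm) or fixed,
#' and percent changes from a normal distribution on the percent scale
#' (mean around -30 in the reference settings). When `true_orr` is set, the
#' change distribution is replaced by the mixture of its two truncated
#' components — below vs above the -30% cutoff — weighted so the expected
#' observed ORR equals `true_orr` exactly while the component shapes are
#' preserved.
#'
#' @param n_patients number of patients (default 50).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline size in mm (defaults 3.55, 0.53).
#' @param baseline_fixed_mm if set, all baselines are this size and the
#'   log-normal is ignored.
#' @param change_mean,change_sd percent-scale normal parameters of the
#'   percent change (defaults -30, 5).
#' @param true_orr known true ORR in percent, or `NULL`.
#' @param name optional label carried into study outputs.
#' @return An object of class `trial_gen_config`.
#' @export
trial_gen_config <- function(n_patients = 50L, baseline_meanlog = 3.55,
                             baseline_sdlog = 0.53, baseline_fixed_mm = NULL,
                             change_mean = -30, change_sd = 5,
                             true_orr = NULL, name = NULL) {
  stopifnot(n_patients >= 1, change_sd >= 0, baseline_sdlog > 0)
  if (!is.null(true_orr) && (true_orr < 0 || true_orr > 100)) {
    stop("true_orr must be a percentage in [0, 100]", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 baseline_fixed_mm = baseline_fixed_mm,
                 change_mean = change_mean, change_sd = change_sd,
                 true_orr = true_orr, name = name),
            class = "trial_gen_config")
}

# Normal truncated to (lo, hi], inverse-CDF; used for the true_orr mixture.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic trial dataset
#'
#' @param config a [trial_gen_config()].
#' @param seed optional seed.
#' @return A [trial_dataset()] of single-lesion solid-organ patients with
#'   `n_definitive_progression = 0`. Percent changes are floored at -100%
#'   (post size clamped at 0).
#' @export
generate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "trial_gen_config"))
  n <- config$n_patients
  with_seed_maybe(seed, {
    baseline <- if (!is.null(config$baseline_fixed_mm)) {
      rep(config$baseline_fixed_mm, n)
    } else {
      rlnorm_trunc(n, config$baseline_meanlog, config$baseline_sdlog, lo = 10)
    }
    if (is.null(config$true_orr)) {
      change <- rnorm(n, config$change_mean, config$change_sd)
    } else {
      resp <- runif(n) < config$true_orr / 100
      change <- numeric(n)
      change[resp] <- rnorm_trunc(sum(resp), config$change_mean,
                                  config$change_sd, hi = -30)
      change[!resp] <- rnorm_trunc(sum(!resp), config$change_mean,
                                   config$change_sd, lo = -30)
    }
    change <- pmax(change, -100)
    trial_dataset(data.frame(
      patient_id = sprintf("S%04d", seq_len(n)), organ = "solid",
      baseline_mm = baseline,
      post_mm = pmax(baseline * (1 + change / 100), 0),
      stringsAsFactors = FALSE), 0L)
  })
}

#' Generate paired second readings of a trial
#'
#' Perturbs every lesion's baseline and post sizes through the sqrt-scale
#' error mechanism (identical to [perturb_burden()]) to emulate a full
#' re-read of the trial by the same or another reader.
#'
#' @param trial a [trial_dataset()].
#' @param err an `error_distribution` or `list(long = , short = )`.
#' @param seed optional seed.
#' @return A [trial_dataset()] with the same patients and the
#'   definitive-progression count carried over.
#' @export
generate_second_readings <- function(trial, err, seed = NULL) {
  stopifnot(inherits(trial, "trial_dataset"))
  with_seed_maybe(seed, {
    out <- as.data.frame(trial)
    for (i in seq_len(nrow(out))) {
      cov_i <- err_cov_for(err, out$organ[i])
      eps <- rmvn2(1L, cov_i)
      out$baseline_mm[i] <- perturb_sqrt(out$baseline_mm[i], eps[1])
      out$post_mm[i] <- perturb_sqrt(out$post_mm[i], eps[2])
    }
    # a perturbed baseline of exactly 0 is not a valid lesion row; nudge
    out$baseline_mm <- pmax(out$baseline_mm, 1e-6)
    trial_dataset(out, n_definitive_progression(trial))
  })
}
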