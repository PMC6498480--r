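# Shared fixtures: built in code, no files on disk beyond temp CSVs.

zero2 <- matrix(0, 2, 2)

# Components with no measurement error at all (lesion variation only).
noise_free_vc <- function() {
  variance_components(mu = c(6, 5.5),
                      cov_lesion = diag(c(1.5^2, 1.5^2)),
                      cov_reader = zero2, cov_interaction = zero2,
                      cov_residual = zero2)
}

# A degenerate error distribution (no perturbation).
zero_err <- function(mode = "inter") {
  recistvar:::error_distribution(mode, zero2)
}

# Small diagonal error distribution with given sqrt-scale SDs.
diag_err <- function(sd_b, sd_p = sd_b, mode = "inter") {
  recistvar:::error_distribution(mode, diag(c(sd_b^2, sd_p^2)))
}

# Hand-built probability table (bypasses simulation) for evaluation tests.
make_table <- function(df) {
  structure(df, class = c("probability_table", "data.frame"))
}

# Minimal single-composition table with constant probabilities.
const_table <- function(p_response, p_progression, n_solid = 1L,
                        n_lymph = 0L, baseline_mm = 30,
                        reader_mode = "inter") {
  df <- expand.grid(n_solid = n_solid, n_lymph = n_lymph,
                    baseline_mm = baseline_mm,
                    c = round(seq(-1, 1, by = 0.01), 2),
                    reader_mode = reader_mode,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$p_response <- p_response
  df$p_progression <- p_progression
  make_table(df)
}

# Simple valid trial: one solid lesion per patient at given sizes.
simple_trial <- function(baseline, post, n_def = 0L) {
  trial_dataset(data.frame(
    patient_id = sprintf("P%02d", seq_along(baseline)), organ = "solid",
    baseline_mm = baseline, post_mm = post, stringsAsFactors = FALSE), n_def)
}
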