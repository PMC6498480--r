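#' Trim outlying readings by standardized residual
#'
#' A small fraction of repeated readings originates from misperception of
#' lesion boundaries rather than ordinary measurement error. Per phase, a
#' univariate mixed model with lesion, reader and lesion-by-reader random
#' effects is fitted on the square-root-transformed diameters, and the
#' `fraction` of records with the largest absolute standardized residuals is
#' removed (single pass, `floor(fraction * n)` records per phase). When one
#' phase's record of a (lesion, reader, session) pair is removed, the
#' partner record in the other phase is removed as well, so the bivariate
#' model sees complete pairs.
#'
#' @param data a [reading_dataset()] with at least 2 lesions and 2 readers.
#' @param fraction fraction in `[0, 0.5)` of per-phase records to remove
#'   (default 0.05).
#' @return The reduced [reading_dataset()], with a `trim_log` attribute: a
#'   data frame of removed records with a `reason` column (`"outlier"` or
#'   `"pair_completion"`).
#' @export
trim_outliers <- function(data, fraction = 0.05) {
  stopifnot(inherits(data, "reading_dataset"))
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction < 0 ||
      fraction >= 0.5) {
    stop("fraction must lie in [0, 0.5)", call. = FALSE)
  }
  empty_log <- data.frame(lesion_id = character(), reader_id = character(),
                          session = integer(), phase = character(),
                          diameter_mm = numeric(), reason = character(),
                          stringsAsFactors = FALSE)
  if (fraction == 0) {
    attr(data, "trim_log") <- empty_log
    return(data)
  }
  if (length(unique(data$lesion_id)) < 2 || length(unique(data$reader_id)) < 2) {
    stop("trimming requires at least 2 lesions and 2 readers", call. = FALSE)
  }
  df <- as.data.frame(data)
  df$.row <- seq_len(nrow(df))
  drop_idx <- integer(0)
  for (ph in c("baseline", "post")) {
    sub <- df[df$phase == ph, , drop = FALSE]
    if (nrow(sub) == 0) next
    n_remove <- floor(fraction * nrow(sub))
    if (n_remove == 0) next
    sr <- abs(standardized_residuals(sub))
    worst <- order(sr, decreasing = TRUE)[seq_len(n_remove)]
    drop_idx <- c(drop_idx, sub$.row[worst])
  }
  outlier <- df$.row %in% drop_idx
  key <- paste(df$lesion_id, df$reader_id, df$session, sep = "\r")
  partner <- key %in% key[outlier] & !outlier
  keep <- !(outlier | partner)
  log_df <- df[outlier | partner,
               c("lesion_id", "reader_id", "session", "phase", "diameter_mm")]
  if (nrow(log_df) > 0) {
    log_df$reason <- ifelse((outlier)[outlier | partner], "outlier", "pair_completion")
    rownames(log_df) <- NULL
  } else {
    log_df <- empty_log
  }
  out <- reading_dataset(df[keep, setdiff(names(df), ".row"), drop = FALSE])
  attr(out, "trim_log") <- log_df
  out
}

# |standardized residual| of a one-phase readings subset under the
# lesion + reader + interaction random-effects model on the sqrt scale.
# Residuals are scaled by the model's residual SD.
standardized_residuals <- function(sub) {
  sub$z <- sqrt(sub$diameter_mm)
  fit <- suppressMessages(suppressWarnings(lme4::lmer(
    z ~ 1 + (1 | lesion_id) + (1 | reader_id) + (1 | lesion_id:reader_id),
    data = sub,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))))
  r <- residuals(fit)
  s <- stats::sigma(fit)
  if (s <= 0) s <- sd(r)
  r / s
}
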