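#' RECIST response categorization from percent change
#'
#' Categorizes the fractional change `c` of the tumor burden from baseline:
#' complete response (CR) at exactly -1 (-100%), partial response (PR) for
#' -1 < c <= -0.3, stable disease (SD) for -0.3 < c < 0.2, and progression
#' (PD) for c >= 0.2. The categories partition `[-1, Inf)`: -30% is the
#' largest change still designated PR and +20% the smallest designated PD.
#'
#' @param c numeric vector of fractional changes (e.g. -0.30 for -30%).
#' @return Factor with levels `CR`, `PR`, `SD`, `PD`.
#' @examples
#' categorize_response(c(-1, -0.3, 0, 0.2))  # CR PR SD PD
#' @export
categorize_response <- function(c) {
  if (any(c < -1, na.rm = TRUE)) {
    stop("percent change below -100% is impossible: burden sizes are non-negative",
         call. = FALSE)
  }
  out <- character(length(c))
  out[c == -1] <- "CR"
  out[c > -1 & c <= -0.3] <- "PR"
  out[c > -0.3 & c < 0.2] <- "SD"
  out[c >= 0.2] <- "PD"
  out[is.na(c)] <- NA
  factor(out, levels = c("CR", "PR", "SD", "PD"))
}
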