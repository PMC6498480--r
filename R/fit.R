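#' Fit the bivariate hierarchical measurement-error model
#'
#' On the square-root scale, the (baseline, post) reading pair of lesion i
#' by reader j in session k is modelled as
#' `z_ijk = mu + alpha_i + beta_j + gamma_ij + eps_ijk`,
#' with lesion, reader, interaction and residual terms each a mean-zero
#' bivariate normal. The residual covariance is the intra-reader error; the
#' inter-reader error combines reader, interaction and half the residual
#' covariance (see [inter_error_cov()]). Fit one dataset per axis.
#'
#' Two routes are provided:
#' \describe{
#'   \item{`"reml"` (default)}{Three univariate lme4 REML fits (baseline,
#'     post, and their sum); each cross-covariance is recovered as
#'     `(Var(b+p) - Var(b) - Var(p)) / 2` and clamped onto the PSD cone.
#'     Deterministic and fast; the result is a single "draw".}
#'   \item{`"mcmc"`}{The full Bayesian fit via JAGS with weakly informative
#'     priors: half-normal(1) on component SDs (diffuse on the sqrt-mm
#'     scale, where values are O(1-12)) and uniform(-1, 1) on each 2x2
#'     correlation. Returns retained posterior draws from `n_chains`
#'     chains with split-chain convergence diagnostics; any R-hat above 1.1
#'     attaches a warning to the result rather than failing.}
#' }
#'
#' @param data a [reading_dataset()], normally after [trim_outliers()].
#'   Records are paired by (lesion, reader, session) across phases;
#'   incomplete pairs are dropped with a message.
#' @param method `"reml"` or `"mcmc"`.
#' @param n_chains,n_warmup,n_iter MCMC settings (ignored for `"reml"`):
#'   number of chains, adaptation+burn-in iterations, and retained
#'   iterations per chain.
#' @param seed optional integer seed (drives the MCMC chains).
#' @return An object of class `posterior_draws`: list with `draws` (a list
#'   of [variance_components()]), `n_chains`, `method`, `diagnostics` (data
#'   frame of per-parameter R-hat for `"mcmc"`, else `NULL`) and
#'   `convergence_warning`.
#' @export
fit_bivariate_model <- function(data, method = c("reml", "mcmc"),
                                n_chains = 4L, n_warmup = 1000L,
                                n_iter = 1000L, seed = NULL) {
  stopifnot(inherits(data, "reading_dataset"))
  method <- match.arg(method)
  if (length(unique(data$reader_id)) < 2) {
    stop("only one reader in the dataset: the reader and interaction ",
         "components are not identifiable; fit an intra-reader-only model ",
         "from session replicates instead", call. = FALSE)
  }
  if (length(unique(data$lesion_id)) < 2) {
    stop("at least 2 lesions are required", call. = FALSE)
  }
  wide <- pair_phases(data)
  if (method == "reml") fit_reml(wide) else {
    fit_mcmc(wide, n_chains = n_chains, n_warmup = n_warmup,
             n_iter = n_iter, seed = seed)
  }
}

# Long-to-wide: one row per (lesion, reader, session) with sqrt-scale
# baseline (z_b) and post (z_p) readings; incomplete pairs dropped.
pair_phases <- function(data) {
  df <- as.data.frame(data)
  df$z <- sqrt(df$diameter_mm)
  key <- interaction(df$lesion_id, df$reader_id, df$session, drop = TRUE)
  b <- df[df$phase == "baseline", ]
  p <- df[df$phase == "post", ]
  kb <- paste(b$lesion_id, b$reader_id, b$session, sep = "\r")
  kp <- paste(p$lesion_id, p$reader_id, p$session, sep = "\r")
  common <- intersect(kb, kp)
  n_drop <- (nrow(b) - length(common)) + (nrow(p) - length(common))
  if (n_drop > 0) {
    message("dropping ", n_drop, " unpaired single-phase record(s)")
  }
  b <- b[match(common, kb), ]
  p <- p[match(common, kp), ]
  data.frame(lesion_id = factor(b$lesion_id), reader_id = factor(b$reader_id),
             session = b$session, z_b = b$z, z_p = p$z,
             stringsAsFactors = FALSE)
}

fit_reml <- function(wide) {
  wide$z_s <- wide$z_b + wide$z_p
  one_fit <- function(resp) {
    f <- stats::as.formula(paste(
      resp, "~ 1 + (1 | lesion_id) + (1 | reader_id) + (1 | lesion_id:reader_id)"))
    fit <- suppressMessages(suppressWarnings(lme4::lmer(
      f, data = wide,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    grab <- function(grp) vcs$vcov[vcs$grp == grp][1]
    list(mu = unname(lme4::fixef(fit)[1]),
         lesion = grab("lesion_id"), reader = grab("reader_id"),
         interaction = grab("lesion_id:reader_id"), residual = grab("Residual"))
  }
  fb <- one_fit("z_b"); fp <- one_fit("z_p"); fs <- one_fit("z_s")
  comp_cov <- function(comp) {
    cb <- fb[[comp]]; cp <- fp[[comp]]
    off <- (fs[[comp]] - cb - cp) / 2
    clamp_psd2(cov2(cb, cp, off))
  }
  vc <- variance_components(
    mu = c(fb$mu, fp$mu),
    cov_lesion = comp_cov("lesion"), cov_reader = comp_cov("reader"),
    cov_interaction = comp_cov("interaction"),
    cov_residual = comp_cov("residual"))
  structure(list(draws = list(vc), n_chains = 0L, method = "reml",
                 diagnostics = NULL, convergence_warning = FALSE),
            class = "posterior_draws")
}

jags_model_string <- "
model {
  for (i in 1:N) {
    z[i, 1:2] ~ dmnorm(m[i, 1:2], prec_e[1:2, 1:2])
    m[i, 1] <- mu[1] + a[lesion[i], 1] + b[reader[i], 1] + g[cell[i], 1]
    m[i, 2] <- mu[2] + a[lesion[i], 2] + b[reader[i], 2] + g[cell[i], 2]
  }
  for (l in 1:L) { a[l, 1:2] ~ dmnorm(zero2, prec_a[1:2, 1:2]) }
  for (r in 1:R) { b[r, 1:2] ~ dmnorm(zero2, prec_b[1:2, 1:2]) }
  for (c in 1:C) { g[c, 1:2] ~ dmnorm(zero2, prec_g[1:2, 1:2]) }
  mu[1] ~ dnorm(0, 1.0E-4)
  mu[2] ~ dnorm(0, 1.0E-4)
  for (k in 1:2) {
    sd_a[k] ~ dnorm(0, 1) T(0,)
    sd_b[k] ~ dnorm(0, 1) T(0,)
    sd_g[k] ~ dnorm(0, 1) T(0,)
    sd_e[k] ~ dnorm(0, 1) T(0,)
  }
  rho_a ~ dunif(-1, 1)
  rho_b ~ dunif(-1, 1)
  rho_g ~ dunif(-1, 1)
  rho_e ~ dunif(-1, 1)
  cov_a[1, 1] <- sd_a[1]^2
  cov_a[2, 2] <- sd_a[2]^2
  cov_a[1, 2] <- rho_a * sd_a[1] * sd_a[2]
  cov_a[2, 1] <- cov_a[1, 2]
  cov_b[1, 1] <- sd_b[1]^2
  cov_b[2, 2] <- sd_b[2]^2
  cov_b[1, 2] <- rho_b * sd_b[1] * sd_b[2]
  cov_b[2, 1] <- cov_b[1, 2]
  cov_g[1, 1] <- sd_g[1]^2
  cov_g[2, 2] <- sd_g[2]^2
  cov_g[1, 2] <- rho_g * sd_g[1] * sd_g[2]
  cov_g[2, 1] <- cov_g[1, 2]
  cov_e[1, 1] <- sd_e[1]^2
  cov_e[2, 2] <- sd_e[2]^2
  cov_e[1, 2] <- rho_e * sd_e[1] * sd_e[2]
  cov_e[2, 1] <- cov_e[1, 2]
  prec_a <- inverse(cov_a)
  prec_b <- inverse(cov_b)
  prec_g <- inverse(cov_g)
  prec_e <- inverse(cov_e)
}
"

fit_mcmc <- function(wide, n_chains, n_warmup, n_iter, seed) {
  if (!requireNamespace("rjags", quietly = TRUE) ||
      !requireNamespace("coda", quietly = TRUE)) {
    stop("the 'mcmc' route requires the rjags and coda packages", call. = FALSE)
  }
  lesion <- as.integer(wide$lesion_id)
  reader <- as.integer(wide$reader_id)
  cell <- as.integer(interaction(wide$lesion_id, wide$reader_id, drop = TRUE))
  jd <- list(z = cbind(wide$z_b, wide$z_p), lesion = lesion, reader = reader,
             cell = cell, N = nrow(wide), L = max(lesion), R = max(reader),
             C = max(cell), zero2 = c(0, 0))
  base_seed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else as.integer(seed)
  inits <- lapply(seq_len(n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (base_seed + ch - 1L) %% 2147483647L)
  })
  jm <- rjags::jags.model(textConnection(jags_model_string), data = jd,
                          inits = inits, n.chains = n_chains,
                          n.adapt = max(100L, n_warmup %/% 2L), quiet = TRUE)
  stats::update(jm, n.iter = n_warmup, progress.bar = "none")
  pars <- c("mu", "sd_a", "sd_b", "sd_g", "sd_e",
            "rho_a", "rho_b", "rho_g", "rho_e")
  samp <- rjags::coda.samples(jm, pars, n.iter = n_iter, progress.bar = "none")
  mat <- do.call(rbind, lapply(samp, as.matrix))
  draws <- lapply(seq_len(nrow(mat)), function(i) {
    r <- mat[i, ]
    mk <- function(tag) {
      s1 <- r[paste0("sd_", tag, "[1]")]
      s2 <- r[paste0("sd_", tag, "[2]")]
      rho <- r[paste0("rho_", tag)]
      cov2(s1^2, s2^2, rho * s1 * s2)
    }
    variance_components(mu = c(r["mu[1]"], r["mu[2]"]),
                        cov_lesion = mk("a"), cov_reader = mk("b"),
                        cov_interaction = mk("g"), cov_residual = mk("e"))
  })
  diag_df <- NULL
  conv_warn <- FALSE
  if (n_chains >= 2) {
    gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) {
      diag_df <- data.frame(parameter = rownames(gd$psrf),
                            rhat = gd$psrf[, 1], row.names = NULL)
      conv_warn <- any(diag_df$rhat > 1.1, na.rm = TRUE)
      if (conv_warn) {
        warning("MCMC convergence: R-hat > 1.1 for ",
                paste(diag_df$parameter[diag_df$rhat > 1.1], collapse = ", "),
                call. = FALSE)
      }
    }
  }
  structure(list(draws = draws, n_chains = as.integer(n_chains),
                 method = "mcmc", diagnostics = diag_df,
                 convergence_warning = conv_warn),
            class = "posterior_draws")
}

#' Wrap known variance components as a single-draw posterior
#'
#' Useful when the components are known (simulation ground truth) or come
#' from an external fit: downstream table construction treats the point
#' value as a degenerate posterior.
#'
#' @param vc a [variance_components()] object.
#' @return A `posterior_draws` object with one draw.
#' @export
posterior_from_components <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  structure(list(draws = list(vc), n_chains = 0L, method = "fixed",
                 diagnostics = NULL, convergence_warning = FALSE),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior of variance components: %d draw(s), method '%s'",
              length(x$draws), x$method))
  if (x$method == "mcmc") cat(sprintf(", %d chains", x$n_chains))
  cat("\n")
  if (isTRUE(x$convergence_warning)) cat("  (convergence warning: R-hat > 1.1)\n")
  print(posterior_median(x))
  invisible(x)
}

#' Posterior median of the variance components
#'
#' Elementwise medians over the draws, re-clamped onto the PSD cone.
#' For a single-draw (REML) posterior this is the point estimate itself.
#'
#' @param posterior a `posterior_draws` object.
#' @return A [variance_components()] object.
#' @export
posterior_median <- function(posterior) {
  stopifnot(inherits(posterior, "posterior_draws"))
  if (length(posterior$draws) == 1) return(posterior$draws[[1]])
  med_mat <- function(nm) {
    arr <- vapply(posterior$draws, function(d) d[[nm]], matrix(0, 2, 2))
    clamp_psd2(apply(arr, c(1, 2), median))
  }
  mu <- apply(vapply(posterior$draws, function(d) d$mu, numeric(2)), 1, median)
  variance_components(mu, med_mat("cov_lesion"), med_mat("cov_reader"),
                      med_mat("cov_interaction"), med_mat("cov_residual"))
}

#' Serialize posterior draws to a columnar CSV
#'
#' One row per draw; columns `mu_b, mu_p` plus `var_b`, `var_p`, `cov_bp`
#' for each of the lesion, reader, interaction and residual components.
#'
#' @param posterior a `posterior_draws` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(posterior, path) {
  stopifnot(inherits(posterior, "posterior_draws"))
  rows <- lapply(posterior$draws, function(d) {
    out <- c(mu_b = unname(d$mu[1]), mu_p = unname(d$mu[2]))
    for (nm in c("lesion", "reader", "interaction", "residual")) {
      m <- d[[paste0("cov_", nm)]]
      out <- c(out, setNames(c(m[1, 1], m[2, 2], m[1, 2]),
                             paste0(nm, c("_var_b", "_var_p", "_cov_bp"))))
    }
    as.data.frame(as.list(out))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior draws from a columnar CSV
#'
#' Inverse of [write_posterior_csv()]. The chain structure is not
#' recoverable from the flat file; the result carries `n_chains = 0` and no
#' diagnostics.
#'
#' @param path CSV path written by [write_posterior_csv()].
#' @return A `posterior_draws` object (method `"csv"`).
#' @export
read_posterior_csv <- function(path) {
  df <- read.csv(path)
  draws <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    mk <- function(nm) cov2(r[[paste0(nm, "_var_b")]], r[[paste0(nm, "_var_p")]],
                            r[[paste0(nm, "_cov_bp")]])
    variance_components(c(r$mu_b, r$mu_p), mk("lesion"), mk("reader"),
                        mk("interaction"), mk("residual"))
  })
  structure(list(draws = draws, n_chains = 0L, method = "csv",
                 diagnostics = NULL, convergence_warning = FALSE),
            class = "posterior_draws")
}
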