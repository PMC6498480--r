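test_that("trimming removes exactly the requested per-phase fraction, plus phase partners", {
  vc <- default_variance_components("long")
  rd <- generate_readings(vc, n_lesions = 50, n_readers = 5, n_sessions = 2,
                          seed = 11)  # 500 records per phase
  out <- trim_outliers(rd, fraction = 0.05)
  log <- attr(out, "trim_log")
  expect_equal(sum(log$reason == "outlier" & log$phase == "baseline"), 25)
  expect_equal(sum(log$reason == "outlier" & log$phase == "post"), 25)
  expect_equal(nrow(rd) - nrow(out), nrow(log))
  # every surviving (lesion, reader, session) pair is complete
  key <- paste(out$lesion_id, out$reader_id, out$session)
  expect_true(all(table(key) == 2))

  same <- trim_outliers(rd, fraction = 0)
  expect_equal(as.data.frame(same), as.data.frame(rd), ignore_attr = TRUE)
  expect_error(trim_outliers(rd, 0.5), "fraction")
})

test_that("planted gross measurement errors are the records trimmed first", {
  vc <- default_variance_components("long")
  rd <- generate_readings(vc, n_lesions = 25, n_readers = 5, n_sessions = 2,
                          seed = 21)  # 250 records per phase
  df <- as.data.frame(rd)
  base_rows <- which(df$phase == "baseline")
  planted <- base_rows[c(3, 77, 180)]
  df$diameter_mm[planted] <- df$diameter_mm[planted] * 10
  rd2 <- reading_dataset(df)
  out <- trim_outliers(rd2, fraction = 0.05)  # 12 baseline outliers removed
  log <- attr(out, "trim_log")
  removed_keys <- paste(log$lesion_id, log$reader_id, log$session, log$phase)[
    log$reason == "outlier"]
  planted_keys <- paste(df$lesion_id, df$reader_id, df$session, df$phase)[planted]
  expect_true(all(planted_keys %in% removed_keys))
})

test_that("REML route recovers a noise-free design and errors on degenerate ones", {
  rd <- generate_readings(noise_free_vc(), n_lesions = 30, n_readers = 3,
                          n_sessions = 2, seed = 31)
  fit <- fit_bivariate_model(rd, method = "reml")
  vc <- posterior_median(fit)
  expect_lt(vc$cov_residual[1, 1], 1e-3)
  expect_lt(vc$cov_residual[2, 2], 1e-3)

  one_reader <- reading_dataset(as.data.frame(rd)[rd$reader_id == "R1", ])
  expect_error(fit_bivariate_model(one_reader), "intra")
})

test_that("residual covariance agrees with the within-cell session-difference moments oracle", {
  vc_true <- default_variance_components("long")
  rd <- generate_readings(vc_true, n_lesions = 150, n_readers = 6,
                          n_sessions = 2, seed = 41)
  fit <- fit_bivariate_model(rd, method = "reml")
  est <- posterior_median(fit)$cov_residual
  # half the variance of session differences within (lesion, reader, phase)
  # estimates the residual variance of that phase
  df <- as.data.frame(rd)
  df$z <- sqrt(df$diameter_mm)
  oracle <- sapply(c("baseline", "post"), function(ph) {
    sub <- df[df$phase == ph, ]
    w <- stats::reshape(sub[, c("lesion_id", "reader_id", "session", "z")],
                        idvar = c("lesion_id", "reader_id"),
                        timevar = "session", direction = "wide")
    var(w$z.1 - w$z.2) / 2
  })
  expect_equal(est[1, 1], unname(oracle["baseline"]), tolerance = 0.2)
  expect_equal(est[2, 2], unname(oracle["post"]), tolerance = 0.2)
})

test_that("intra and inter error covariances follow the component algebra", {
  vc <- variance_components(mu = c(6, 5.5),
                            cov_lesion = diag(2), cov_reader = diag(2),
                            cov_interaction = diag(2), cov_residual = diag(2))
  expect_equal(intra_error_cov(vc)$cov, diag(2))
  inter <- inter_error_cov(vc)
  expect_equal(diag(inter$cov), c(2.5, 2.5))
  expect_equal(inter$cov[1, 2], 0)

  vc2 <- default_variance_components("long")
  inter2 <- inter_error_cov(vc2)
  expect_equal(inter2$cov - vc2$cov_reader - vc2$cov_interaction,
               vc2$cov_residual / 2)
  # inter variance dominates half the intra variance on both diagonals
  expect_true(all(diag(inter2$cov) >= diag(intra_error_cov(vc2)$cov) / 2))
  # pass-through contract of the residual
  vc3 <- variance_components(c(6, 5.5), diag(2), matrix(0, 2, 2),
                             matrix(0, 2, 2),
                             matrix(c(0.04, 0.03, 0.03, 0.09), 2))
  expect_equal(intra_error_cov(vc3)$cov,
               matrix(c(0.04, 0.03, 0.03, 0.09), 2))
})

test_that("fitting is invariant to relabeling readers and lesions", {
  vc_true <- default_variance_components("long")
  rd <- generate_readings(vc_true, n_lesions = 30, n_readers = 4,
                          n_sessions = 2, seed = 51)
  df <- as.data.frame(rd)
  perm_l <- setNames(sample(unique(df$lesion_id)), unique(df$lesion_id))
  perm_r <- setNames(sample(unique(df$reader_id)), unique(df$reader_id))
  df$lesion_id <- unname(perm_l[df$lesion_id])
  df$reader_id <- unname(perm_r[df$reader_id])
  f1 <- posterior_median(fit_bivariate_model(rd))
  f2 <- posterior_median(fit_bivariate_model(reading_dataset(df)))
  # identical up to optimizer tolerance (lme4 restarts from permuted data)
  for (nm in c("cov_lesion", "cov_reader", "cov_interaction", "cov_residual")) {
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-3)
  }
})

test_that("estimator calibration: central 90% of replicate estimates brackets the truth", {
  vc_true <- default_variance_components("long")
  truth <- c(vc_true$cov_lesion[1, 1], vc_true$cov_lesion[2, 2],
             vc_true$cov_reader[1, 1], vc_true$cov_reader[2, 2],
             vc_true$cov_interaction[1, 1], vc_true$cov_interaction[2, 2],
             vc_true$cov_residual[1, 1], vc_true$cov_residual[2, 2])
  set.seed(61)
  ests <- replicate(20, {
    rd <- generate_readings(vc_true, n_lesions = 100, n_readers = 6,
                            n_sessions = 2)
    vc <- posterior_median(fit_bivariate_model(rd))
    c(vc$cov_lesion[1, 1], vc$cov_lesion[2, 2],
      vc$cov_reader[1, 1], vc$cov_reader[2, 2],
      vc$cov_interaction[1, 1], vc$cov_interaction[2, 2],
      vc$cov_residual[1, 1], vc$cov_residual[2, 2])
  })
  for (k in seq_along(truth)) {
    q <- quantile(ests[k, ], c(0.05, 0.95))
    expect_true(q[1] <= truth[k] && truth[k] <= q[2],
                label = paste("diagonal component", k, "bracketed"))
  }
})

test_that("MCMC route returns valid diagnosed draws and is seed-reproducible", {
  skip_if_not_installed("rjags")
  vc_true <- default_variance_components("long")
  rd <- generate_readings(vc_true, n_lesions = 15, n_readers = 3,
                          n_sessions = 2, seed = 71)
  fit <- suppressWarnings(
    fit_bivariate_model(rd, method = "mcmc", n_chains = 2,
                        n_warmup = 800, n_iter = 200, seed = 5))
  expect_equal(length(fit$draws), 400)
  expect_s3_class(fit$draws[[1]], "variance_components")
  expect_true(all(c("mu[1]", "rho_e") %in% fit$diagnostics$parameter))
  med <- posterior_median(fit)
  expect_gt(med$cov_residual[1, 1], 0)
  # every draw satisfies the inter >= intra/2 diagonal ordering
  ok <- vapply(fit$draws, function(d) {
    all(diag(inter_error_cov(d)$cov) >= diag(intra_error_cov(d)$cov) / 2)
  }, logical(1))
  expect_true(all(ok))

  fit2 <- suppressWarnings(
    fit_bivariate_model(rd, method = "mcmc", n_chains = 2,
                        n_warmup = 800, n_iter = 200, seed = 5))
  expect_equal(posterior_median(fit2)$cov_residual, med$cov_residual)
})

test_that("posterior draws serialize to CSV and back", {
  pd <- posterior_from_components(default_variance_components("long"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_posterior_csv(pd, path)
  back <- read_posterior_csv(path)
  expect_equal(length(back$draws), 1)
  expect_equal(back$draws[[1]]$cov_residual, pd$draws[[1]]$cov_residual,
               tolerance = 1e-8)
  expect_equal(unname(back$draws[[1]]$mu), unname(pd$draws[[1]]$mu))
})
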