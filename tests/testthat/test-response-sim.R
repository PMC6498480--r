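test_that("RECIST categorization partitions percent change at the printed cut points", {
  expect_equal(as.character(categorize_response(-0.30)), "PR")
  expect_equal(as.character(categorize_response(0.20)), "PD")
  expect_equal(as.character(categorize_response(-1)), "CR")
  expect_equal(as.character(categorize_response(0)), "SD")
  expect_equal(as.character(categorize_response(c(-1, -0.999, -0.3, -0.299, 0.199, 0.2, 5))),
               c("CR", "PR", "PR", "SD", "SD", "PD", "PD"))
  expect_error(categorize_response(-1.01), "impossible")
})

test_that("burden sets honour the fixed baseline and the size-weighted change restriction", {
  scn1 <- scenario(1, 0, c = -0.3, baseline_mm = 30)
  bs <- sample_burden_set(scn1, n_burdens = 50, seed = 1)
  expect_true(all(bs$Yb == 30))
  expect_true(all(abs(bs$Yp - 21) < 1e-12))

  scn3 <- scenario(3, 0, c = -0.3)
  bs3 <- sample_burden_set(scn3, n_burdens = 200, seed = 2)
  achieved <- rowSums(bs3$Yp) / rowSums(bs3$Yb) - 1
  expect_equal(achieved, rep(-0.3, 200), tolerance = 1e-12)
  # lesions change non-uniformly within a burden
  cx <- bs3$Yp / bs3$Yb - 1
  expect_gt(mean(apply(cx, 1, sd)), 0.05)
  # baselines respect the measurable range
  expect_true(all(bs3$Yb >= 10))
  mix <- sample_burden_set(scenario(1, 1, c = 0), n_burdens = 100, seed = 3)
  expect_true(all(mix$Yb[, 2] <= 80 & mix$Yb[, 2] >= 10))
})

test_that("sqrt-scale perturbation squares the perturbed root and never goes negative", {
  scn <- scenario(1, 0, c = -0.3, baseline_mm = 30)
  bs <- sample_burden_set(scn, n_burdens = 20, seed = 4)
  same <- perturb_burden(bs, zero_err())
  expect_equal(same$Yb, bs$Yb)
  expect_equal(same$Yp, bs$Yp)

  # forced error of +0.5 on a 100 mm lesion: (10.5)^2
  expect_equal(recistvar:::perturb_sqrt(100, 0.5), 110.25)
  # a vanished lesion re-measured with error eps becomes eps^2, never negative
  expect_equal(recistvar:::perturb_sqrt(0, 0.3), 0.09)
  expect_equal(recistvar:::perturb_sqrt(25, -6), 0)

  # distributional check: sqrt(Y') - sqrt(Y) ~ Normal(0, s)
  err <- diag_err(0.2)
  p <- perturb_burden(structure(list(organ = "solid",
                                     Yb = matrix(100, 5000, 1),
                                     Yp = matrix(100, 5000, 1)),
                                class = "burden_set"), err, seed = 5)
  d <- sqrt(p$Yb[, 1]) - 10
  expect_equal(mean(d), 0, tolerance = 0.02)
  expect_equal(sd(d), 0.2, tolerance = 0.02)
})

test_that("designation probabilities hit the deterministic and asymptotic limits", {
  scn <- scenario(1, 0, c = -0.5, baseline_mm = 30)
  p0 <- estimate_probabilities(scn, zero_err(), n_burdens = 100, seed = 6)
  expect_equal(unname(p0), c(1, 0), ignore_attr = TRUE)

  # complete disappearance is designated response with near certainty
  err <- inter_error_cov(default_variance_components("long"))
  pc <- estimate_probabilities(scenario(1, 0, c = -1, baseline_mm = 30), err,
                               n_burdens = 2000, seed = 7)
  expect_gte(pc["p_response"], 0.99)

  # Monte Carlo consistency against a large-sample rerun
  scn2 <- scenario(1, 0, c = -0.32, baseline_mm = 30)
  big <- estimate_probabilities(scn2, err, n_burdens = 100000, seed = 8)
  small <- estimate_probabilities(scn2, err, n_burdens = 500, seed = 9)
  se <- sqrt(big["p_response"] * (1 - big["p_response"]) / 500)
  expect_lt(abs(small["p_response"] - big["p_response"]), 3 * se)
})

test_that("probability tables reduce to deterministic categorization without error and respect ordering invariants", {
  zero_pd <- posterior_from_components(noise_free_vc())
  grid <- rbind(
    scenario_grid(1, 0, baseline_mm = 30, c = c(-0.5), reader_mode = "inter"),
    scenario_grid(3, 0, baseline_mm = NA, c = c(-0.5), reader_mode = "inter"),
    scenario_grid(1, 1, baseline_mm = NA, c = c(-0.5), reader_mode = "inter"))
  tab <- build_probability_table(grid, posterior_long = zero_pd,
                                 posterior_short = zero_pd,
                                 n_iter = 1, n_burdens = 50, seed = 10)
  expect_equal(tab$p_response, rep(1, 3))
  expect_equal(tab$p_progression, rep(0, 3))

  # intra-mode probabilities are at least as extreme as inter-mode
  pd <- posterior_from_components(default_variance_components("long"))
  g2 <- scenario_grid(1, 0, baseline_mm = 30, c = c(-0.4, 0.25),
                      reader_mode = c("inter", "intra"))
  t2 <- build_probability_table(g2, pd, n_iter = 1, n_burdens = 4000, seed = 11)
  p_int <- t2[t2$reader_mode == "inter", ]
  p_itr <- t2[t2$reader_mode == "intra", ]
  expect_gte(p_itr$p_response[p_itr$c == -0.4],
             p_int$p_response[p_int$c == -0.4] - 0.01)
  expect_gte(p_itr$p_progression[p_itr$c == 0.25],
             p_int$p_progression[p_int$c == 0.25] - 0.01)
  # probabilities are coherent
  expect_true(all(t2$p_response + t2$p_progression <= 1))
})

test_that("larger single lesions show a steeper response-probability transition", {
  pd <- posterior_from_components(default_variance_components("long"))
  g <- scenario_grid(1, 0, baseline_mm = c(30, 120), c = c(-0.35, -0.25))
  tab <- build_probability_table(g, pd, n_iter = 1, n_burdens = 4000, seed = 12)
  p <- function(b, cc) tab$p_response[tab$baseline_mm == b & tab$c == cc]
  # below the cutoff the big lesion is more certainly PR; above, less likely
  expect_gt(p(120, -0.35), p(30, -0.35))
  expect_lt(p(120, -0.25), p(30, -0.25))
  # transition amplitude (steepness proxy) larger at 120 mm
  expect_gt(p(120, -0.35) - p(120, -0.25), p(30, -0.35) - p(30, -0.25))
})

test_that("probability lookup rounds, clamps and reports available compositions", {
  tab <- make_table(expand.grid(
    n_solid = 1L, n_lymph = 0L, baseline_mm = c(10, 30, 50),
    c = round(seq(-1, 1, by = 0.01), 2), reader_mode = "inter",
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  tab$p_response <- round(stats::plogis(-(tab$c + 0.3) * 20), 3)
  tab$p_progression <- 0

  s <- summarize_burden(simple_trial(30, 30 * (1 - 0.304)))
  hit <- lookup_probability(tab, s, "inter")
  expect_equal(hit$p_response,
               tab$p_response[tab$baseline_mm == 30 & tab$c == -0.30][1])

  # grid endpoint: post burden 0 uses the c = -1 entry
  s2 <- summarize_burden(simple_trial(30, 0))
  hit2 <- lookup_probability(tab, s2, "inter")
  expect_equal(hit2$p_response,
               tab$p_response[tab$baseline_mm == 30 & tab$c == -1][1])

  # 7 mm baseline clamps to the 10 mm grid entry with a warning
  s3 <- summarize_burden(simple_trial(7, 4.9))
  expect_warning(hit3 <- lookup_probability(tab, s3, "inter"), "clamped")
  expect_equal(hit3$p_response,
               tab$p_response[tab$baseline_mm == 10 & tab$c == -0.30][1])

  # unknown composition errors and lists what the table covers
  s4 <- summarize_burden(trial_dataset(data.frame(
    patient_id = "P1", organ = c("solid", "lymph"),
    baseline_mm = c(30, 15), post_mm = c(21, 12))))
  expect_error(lookup_probability(tab, s4, "inter"), "available compositions")
})

test_that("probability tables round-trip through CSV", {
  tab <- const_table(0.5, 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_probability_table(tab, path)
  back <- read_probability_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_error(read_probability_table({
    p2 <- withr::local_tempfile(fileext = ".csv")
    writeLines("a,b", p2); p2
  }), "missing column")
})
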