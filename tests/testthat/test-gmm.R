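test_that("the mixture recovers known trimodal parameters and labels by mean", {
  fx <- trimodal_fixture(seed = 61, total_frames = 9001)
  fit <- quick_fit(fx$trace, seed = 8, n_restarts = 40)
  comp <- tidy(fit)
  expect_identical(comp$component, c("motion", "ambiguous", "freezing"))
  expect_equal(comp$mean, c(0.955, 0.975, 0.995), tolerance = 2e-3)
  # occupancy from the generator schedule is the weight ground truth
  st <- schedule_score_states(fx$schedule)
  occ <- as.numeric(table(factor(st, c("motion", "ambiguous", "freezing")))) /
    length(st)
  expect_equal(comp$weight, occ, tolerance = 0.05)
  expect_true(glance(fit)$converged)
  expect_false(fit$edge_case)
})

test_that("fits are seed-deterministic and the winner dominates every restart", {
  fx <- trimodal_fixture(seed = 62, total_frames = 2001)
  f1 <- quick_fit(fx$trace, seed = 5, n_restarts = 20)
  f2 <- quick_fit(fx$trace, seed = 5, n_restarts = 20)
  expect_identical(f1$components, f2$components)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_true(all(f1$log_likelihood >= f1$restart_logliks))
  # different seeds land on the same well-separated optimum
  f3 <- quick_fit(fx$trace, seed = 99, n_restarts = 20)
  expect_equal(f3$log_likelihood, f1$log_likelihood, tolerance = 1e-6)
})

test_that("degenerate and collapsed sessions are refused or flagged", {
  expect_error(fit_mixture(rep(0.99, 200)), class = "stillframe_degeneracy_error")
  expect_error(fit_mixture(runif(10)), class = "stillframe_input_error")

  # two well-separated clusters only: one component collapses or starves
  set.seed(63)
  bimodal <- c(rnorm(600, 0.955, 0.003), rnorm(600, 0.995, 0.002))
  bim_fit <- quick_fit(pmin(pmax(bimodal, 0), 1), seed = 4, n_restarts = 40)
  expect_true(bim_fit$edge_case)
  expect_gt(length(bim_fit$edge_case_reasons), 0)
})

test_that("mclust agrees with the EM core on a seeded trace", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  fx <- trimodal_fixture(seed = 64, total_frames = 6001)
  fit <- quick_fit(fx$trace, seed = 3, n_restarts = 30)
  mc <- mclust::Mclust(fx$trace$score, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$components$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1e-3)
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 1)
})

test_that("manual override sets point estimates and relabels by mean", {
  fx <- trimodal_fixture(seed = 65, total_frames = 2001)
  fit <- quick_fit(fx$trace, seed = 2, n_restarts = 15)
  ov <- override_components(fit, means = c(0.99, 0.90, 0.96))
  expect_true(ov$manual_override)
  expect_identical(ov$components$component, c("motion", "ambiguous", "freezing"))
  expect_equal(ov$components$mean, c(0.90, 0.96, 0.99))
  # omitted sds and weights keep the fitted values
  expect_equal(ov$components$sd, fit$components$sd)
  expect_equal(ov$components$weight, fit$components$weight)

  expect_error(override_components(fit, means = c(0.5, 0.5, 0.9)),
               class = "stillframe_input_error")
  expect_error(override_components(fit, means = c(-0.1, 0.5, 0.9)),
               class = "stillframe_input_error")
  expect_error(override_components(fit, means = c(0.1, 0.5, 0.9),
                                   weights = c(0.5, 0.5, 0.5)),
               class = "stillframe_input_error")
})

test_that("override on an all-still session classifies every frame as freezing", {
  still <- similarity_trace(rep(0.998, 400))
  ov <- override_components(NULL, means = c(0.90, 0.95, 0.998), trace = still)
  post <- posterior_trace(ov, still)
  expect_true(all(post$p_freezing > 0.99))
})

test_that("posteriors match a brute-force density computation and sum to one", {
  model <- reference_model()
  set.seed(66)
  x <- pmin(pmax(rnorm(1000, 0.975, 0.015), 0), 1)
  post <- posterior_trace(model, x)
  # independent oracle: direct density ratios
  comp <- model$components
  dens <- sapply(1:3, function(k) comp$weight[k] * dnorm(x, comp$mean[k], comp$sd[k]))
  oracle <- dens / rowSums(dens)
  expect_equal(post$p_motion, oracle[, 1], tolerance = 1e-10)
  expect_equal(post$p_ambiguous, oracle[, 2], tolerance = 1e-10)
  expect_equal(post$p_freezing, oracle[, 3], tolerance = 1e-10)
  expect_equal(post$p_motion + post$p_ambiguous + post$p_freezing,
               rep(1, 1000), tolerance = 1e-9)

  # dominant component at its own mean; symmetry between equidistant components
  sym <- override_components(NULL, means = c(0.2, 0.5, 0.8),
                             sds = rep(0.05, 3), weights = rep(1 / 3, 3),
                             trace = similarity_trace(c(0.2, 0.5, 0.8)))
  at_mid <- posterior_trace(sym, 0.35)
  expect_equal(at_mid$p_motion, at_mid$p_ambiguous, tolerance = 1e-12)
  at_freeze <- posterior_trace(reference_model(), 0.995)
  expect_gt(at_freeze$p_freezing, 0.99)

  # extreme scores never produce NaN
  far <- posterior_trace(model, c(0, 1))
  expect_false(anyNA(far))
})

test_that("models round-trip through JSON", {
  fx <- trimodal_fixture(seed = 67, total_frames = 1501)
  fit <- quick_fit(fx$trace, seed = 1, n_restarts = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_mixture_json(fit, f)
  back <- read_mixture_json(f)
  expect_equal(back$components, fit$components, tolerance = 1e-12)
  expect_equal(back$log_likelihood, fit$log_likelihood)
})
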