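test_that("segment sampling respects class membership, disjointness and seed", {
  flags <- c(rep(FALSE, 300), rep(TRUE, 900), rep(FALSE, 600))  # one 30 s bout
  bouts <- detect_bouts(flags, fps = 30)
  segs <- sample_segments(bouts, n_scores = 1800, fps = 30, n_per_class = 2,
                          segment_s = 3, seed = 5)
  expect_equal(nrow(segs), 4)
  expect_equal(segs$end_index - segs$start_index + 1, rep(90L, 4))
  inside <- bout_membership(bouts, 1800)
  for (i in 1:4) {
    span <- inside[segs$start_index[i]:segs$end_index[i]]
    if (segs$class[i] == "freezing") expect_true(all(span)) else
      expect_false(any(span))
  }
  # pairwise disjoint
  ord <- segs[order(segs$start_index), ]
  expect_true(all(ord$start_index[-1] > ord$end_index[-4]))
  # deterministic under the seed
  expect_identical(segs, sample_segments(bouts, n_scores = 1800, fps = 30,
                                         n_per_class = 2, segment_s = 3,
                                         seed = 5))
  # requesting more freezing segments than the bout can hold fails
  expect_error(sample_segments(bouts, n_scores = 1800, fps = 30,
                               n_per_class = 15, segment_s = 3, seed = 5),
               class = "stillframe_sampling_error")
})

test_that("consensus is the majority label with ties coded non-freezing", {
  expect_equal(consensus(cbind(c(1, 1, 0), c(0, 1, 0), c(0, 1, 1))),
               c(0L, 1L, 0L))
  expect_equal(consensus(cbind(1, 1)), 1L)
  expect_equal(consensus(cbind(c(1, 0), c(0, 1))), c(0L, 0L))
  expect_error(consensus(matrix(1, 3, 1)), class = "stillframe_input_error")
})

test_that("Cohen's kappa matches the contingency-table definition", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  expect_equal(cohen_kappa(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_error(cohen_kappa(c(1, 0), c(1, 0, 1)), class = "stillframe_input_error")

  # independent oracle: explicit 2x2 table computation on seeded vectors
  set.seed(91)
  for (i in 1:10) {
    a <- rbinom(80, 1, 0.45)
    b <- ifelse(runif(80) < 0.7, a, rbinom(80, 1, 0.5))
    tab <- table(factor(a, 0:1), factor(b, 0:1)) / 80
    po <- sum(diag(tab))
    pe <- sum(rowSums(tab) * colSums(tab))
    expect_equal(cohen_kappa(a, b), (po - pe) / (1 - pe), tolerance = 1e-12)
    # symmetry and consistent-relabel invariance
    expect_equal(cohen_kappa(a, b), cohen_kappa(b, a), tolerance = 1e-12)
    expect_equal(cohen_kappa(a, b), cohen_kappa(1 - a, 1 - b), tolerance = 1e-12)
    # kappa never exceeds raw agreement when chance agreement is positive
    expect_lte(cohen_kappa(a, b), mean(a == b) + 1e-12)
  }
})

test_that("kappa agrees with e1071's implementation on seeded labels", {
  skip_if_not_installed("e1071")
  set.seed(92)
  a <- rbinom(200, 1, 0.4)
  b <- ifelse(runif(200) < 0.8, a, 1 - a)
  ca <- e1071::classAgreement(table(a, b))
  expect_equal(cohen_kappa(a, b), ca$kappa, tolerance = 1e-12)
})

test_that("sensitivity and specificity come from the confusion matrix", {
  truth <- c(1, 1, 0, 0, 1, 0)
  expect_equal(sensitivity_specificity(truth, truth),
               list(sensitivity = 1, specificity = 1))
  expect_equal(sensitivity_specificity(1 - truth, truth),
               list(sensitivity = 0, specificity = 0))
  expect_error(sensitivity_specificity(c(1, 0), c(1, 1)),
               class = "stillframe_undefined_metric_error")

  set.seed(93)
  pred <- rbinom(80, 1, 0.5)
  ref <- rbinom(80, 1, 0.5)
  ss <- sensitivity_specificity(pred, ref)
  tp <- sum(pred == 1 & ref == 1); fn <- sum(pred == 0 & ref == 1)
  tn <- sum(pred == 0 & ref == 0); fp <- sum(pred == 1 & ref == 0)
  expect_identical(ss$sensitivity, tp / (tp + fn))
  expect_identical(ss$specificity, tn / (tn + fp))
})

test_that("round-robin IRR averages all rater pairs", {
  same <- cbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1))
  expect_equal(round_robin(same), 1)

  set.seed(94)
  a <- rbinom(60, 1, 0.5)
  c3 <- cbind(a, a, rbinom(60, 1, 0.5))
  oracle <- mean(c(cohen_kappa(c3[, 1], c3[, 2]),
                   cohen_kappa(c3[, 1], c3[, 3]),
                   cohen_kappa(c3[, 2], c3[, 3])))
  expect_equal(round_robin(c3), oracle, tolerance = 1e-12)

  two <- cbind(rbinom(40, 1, 0.5), rbinom(40, 1, 0.5))
  expect_equal(round_robin(two), cohen_kappa(two[, 1], two[, 2]))
})

test_that("validation reports tie the pieces together", {
  set.seed(95)
  truth <- rep(c(1, 0), each = 40)
  raters <- sapply(1:3, function(i) ifelse(runif(80) < 0.9, truth, 1 - truth))
  cls <- ifelse(runif(80) < 0.88, truth, 1 - truth)
  rep_ <- validation_report(raters, cls)
  expect_equal(rep_$n_segments, 80)
  expect_equal(nrow(rep_$pairwise_kappas), 3)
  expect_equal(rep_$mean_pairwise_kappa, mean(rep_$pairwise_kappas$kappa))
  expect_equal(rep_$kappa_vs_consensus,
               cohen_kappa(cls, consensus(raters)), tolerance = 1e-12)
  expect_true(rep_$sensitivity >= 0 && rep_$sensitivity <= 1)
  perm <- kappa_permutation_test(cls, consensus(raters), n_perm = 199, seed = 9)
  expect_lt(perm$p.value, 0.05)
})

test_that("classifier beats shuffled ground truth in kappa on synthetic sessions", {
  for (seed in c(96, 97)) {
    fx <- trimodal_fixture(seed = seed, total_frames = 3001)
    den <- denoise(fx$trace)
    fit <- quick_fit(den, seed = seed, n_restarts = 25)
    post <- posterior_trace(fit, den)
    flags <- qualifying_frames(post, fit, den)
    pred <- as.integer(bout_membership(detect_bouts(flags, fps = 30), nrow(den)))
    truth <- as.integer(schedule_score_states(fx$schedule) == "freezing")
    k_true <- cohen_kappa(pred, truth)
    set.seed(seed)
    k_shuf <- cohen_kappa(pred, sample(truth))
    expect_gt(k_true, k_shuf)
  }
})

test_that("rater label CSVs round-trip into matrices", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- expand.grid(segment_id = 1:6, rater_id = c("r1", "r2"))
  d$label <- rbinom(12, 1, 0.5)
  readr::write_csv(d, f)
  m <- read_rater_labels(f)
  expect_equal(dim(m), c(6, 2))
  expect_equal(sort(colnames(m)), c("r1", "r2"))
})
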