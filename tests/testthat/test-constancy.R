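test_that("smoothing is a centered moving average with symmetric boundaries", {
  expect_equal(smooth_trace(rep(3, 10)), rep(3, 10))
  expect_equal(smooth_trace(c(0, 0, 0, 0, 5, 0, 0, 0, 0))[5], 1.0)
  x <- c(4, 2, 7, 1, 9, 3)
  expect_equal(smooth_trace(x, 1), x)
  # hand-computed width-5 means with truncation: ends identity, second
  # point a width-3 mean
  s <- smooth_trace(x, 5)
  expect_equal(s[1], 4)
  expect_equal(s[2], mean(x[1:3]))
  expect_equal(s[3], mean(x[1:5]))
  expect_equal(s[6], 3)
  expect_error(smooth_trace(x, 4), "odd")
})

test_that("range over mean matches direct arithmetic and its invariances", {
  expect_equal(range_over_mean(c(8, 10, 12))$value, 0.4)
  expect_equal(range_over_mean(rep(5, 8))$value, 0)
  x <- abs(rnorm(40, 10, 2))
  r <- range_over_mean(x)$value
  expect_equal(range_over_mean(3.7 * x)$value, r, tolerance = 1e-12)
  expect_equal(range_over_mean(rev(x))$value, r, tolerance = 1e-12)
  expect_error(range_over_mean(c(5)), "2 points")
  expect_error(range_over_mean(rep(0, 10)), "mean")
})

test_that("similarity index is the cosine of the configuration angle", {
  g <- c(1, 5, 2, 8)
  expect_equal(similarity_index(g, g), 1.0)
  expect_equal(similarity_index(g, 0.37 * g), 1.0)
  expect_equal(similarity_index(c(1, 0), c(0, 1)), 0)
  h <- c(2, 1, 7, 3)
  expect_equal(similarity_index(g, h), similarity_index(h, g))
  expect_lte(similarity_index(g, h), 1)
  expect_gt(similarity_index(g, h), 0)
  expect_error(similarity_index(g, h[1:3]), "length")
  expect_error(similarity_index(g, rep(0, 4)), "zero")
})

test_that("shuffle floor equals the exhaustive rotation mean (oracle)", {
  # hand-computable length-3 case: both nonzero rotations give 11/14
  expect_equal(shuffled_si_floor(c(1, 2, 3), c(1, 2, 3)), 11 / 14)
  # oracle equivalence for all lengths up to 8 (offsets are exhaustive
  # whenever n - 1 <= n_shuffles)
  for (n in 3:8) {
    g0 <- abs(rnorm(n, 10, 3)) + 0.1
    gl <- abs(rnorm(n, 10, 3)) + 0.1
    expect_equal(shuffled_si_floor(g0, gl),
                 brute_force_rotation_floor(g0, gl), tolerance = 1e-12)
  }
  # rotation-invariant vector: floor equals SI against the constant vector
  g0 <- c(3, 1, 4, 1, 5)
  expect_equal(shuffled_si_floor(g0, rep(2, 5)),
               similarity_index(g0, rep(1, 5)), tolerance = 1e-12)
  expect_lte(shuffled_si_floor(g0, c(9, 9, 1, 3, 2)), 1)
  expect_error(shuffled_si_floor(c(1, 2), c(1, 2)), "length >= 3")
})

test_that("sampled shuffle offsets are seeded and within the nonzero set", {
  g0 <- abs(rnorm(20)) + 0.5
  gl <- abs(rnorm(20)) + 0.5
  a <- shuffled_si_floor(g0, gl, n_shuffles = 10, seed = 5)
  expect_identical(a, shuffled_si_floor(g0, gl, n_shuffles = 10, seed = 5))
  expect_lte(a, 1)
})

test_that("normalized SI curve starts at 1 and is 1 throughout for frozen data", {
  pop <- simulate_trace_population(quiet_params(n_puncta = 8,
                                                n_timepoints = 10,
                                                seed = 4), "wt")
  si <- normalized_si_curve(pop$traces)
  expect_equal(si$si_raw[1], 1)
  expect_equal(si$si_norm[1], 1)
  expect_equal(si$si_norm, rep(1, 10), tolerance = 1e-9)

  # shared bleaching factor leaves every raw SI value unchanged
  pop2 <- simulate_trace_population(sim_params(n_puncta = 8,
                                               n_timepoints = 10,
                                               measurement_noise_sd = 0,
                                               bleach_rate = 0, seed = 4),
                                    "wt")
  tr <- pop2$traces
  bleached <- tr
  bleached$fluorescence <- tr$fluorescence * exp(-0.005 * tr$t_min)
  expect_equal(normalized_si_curve(bleached)$si_raw,
               normalized_si_curve(tr)$si_raw, tolerance = 1e-12)
})

test_that("a rotated final configuration is pulled to the shuffle floor", {
  # final vector is a cyclic rotation of g0: raw SI drops while the
  # exhaustive floor includes the aligning offset, so SI_norm clips to ~0
  g0 <- c(10, 2, 7, 1, 5)
  f <- cbind(g0, g0, c(g0[2:5], g0[1]))
  si <- normalized_si_curve(traces_from_matrix(f))
  expect_equal(si$si_norm[1], 1)
  expect_lt(si$si_norm[3], 0.05)
})

test_that("SI requires at least 3 fully tracked puncta", {
  f <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  st <- matrix("tracked", 3, 2)
  st[3, 2] <- "lost"
  expect_error(normalized_si_curve(traces_from_matrix(f, status = st)),
               "3 puncta")
})

test_that("loss rate counts lost over eligible puncta, excluding rejects", {
  f <- matrix(1, 10, 4)
  st <- matrix("tracked", 10, 4)
  expect_equal(loss_rate(traces_from_matrix(f, status = st)), 0)
  st[1, 3:4] <- "lost"
  expect_equal(loss_rate(traces_from_matrix(f, status = st)), 0.1)
  st[2, ] <- "rejected_split_merge"
  expect_equal(loss_rate(traces_from_matrix(f, status = st)), 1 / 9)
  st[] <- "rejected_split_merge"
  expect_error(loss_rate(traces_from_matrix(f, status = st)), "eligible")
})

test_that("loss-rate estimator agrees with generator ground truth", {
  p <- sim_params(n_puncta = 1000, n_timepoints = 15, loss_prob = 0.09,
                  seed = 21)
  pop <- simulate_trace_population(p, "wt")
  est <- loss_rate(pop$traces)
  expect_lt(abs(est - 0.09), 3 * sqrt(0.09 * 0.91 / 1000))
})

test_that("KS comparison handles identical, disjoint and shifted samples", {
  x <- rnorm(50)
  same <- compare_distributions(x, x)
  expect_equal(same$statistic, 0)
  disj <- compare_distributions(1:10, 101:110)
  expect_equal(disj$statistic, 1)
  set.seed(31)
  shifted <- compare_distributions(runif(1000), runif(1000) + 0.5)
  expect_equal(shifted$statistic, 0.5, tolerance = 0.06)
  expect_error(compare_distributions(1, 1:5), "2 values")
  expect_output(print(same), "KS comparison")
})

test_that("SI-curve comparison pools per-neuron endpoint means", {
  mk <- function(vals) {
    cu <- data.frame(t_min = seq_along(vals), si_raw = vals,
                     si_norm = vals)
    class(cu) <- c("si_curve", "data.frame")
    cu
  }
  a <- list(mk(c(1, 0.9, 0.8, 0.7)), mk(c(1, 0.8, 0.7, 0.6)))
  res <- compare_si_curves(a, a)
  expect_equal(res$statistic, 0)
  expect_equal(res$values[[1]], c(0.8, 0.7))
  expect_error(compare_si_curves(a, a[1]), "2 curves")
})

test_that("SI decays faster in expectation as reconfiguration grows", {
  end_si <- function(rec, s) {
    p <- sim_params(n_puncta = 40, n_timepoints = 37,
                    reconfiguration_sd = rec, seed = s)
    pop <- simulate_trace_population(p, "g", 3)
    mean(sapply(unique(pop$traces$neuron), function(nrn)
      tail(normalized_si_curve(
        pop$traces[pop$traces$neuron == nrn, ])$si_norm, 1)))
  }
  lo <- sapply(1:4, function(s) end_si(0.005, s))
  hi <- sapply(1:4, function(s) end_si(0.06, 100 + s))
  expect_true(all(hi < lo))
})
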