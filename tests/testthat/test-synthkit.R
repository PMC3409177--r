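test_that("parameter validation names the offending field", {
  expect_error(sim_params(n_puncta = 1), "n_puncta")
  expect_error(sim_params(dt = 0), "dt")
  expect_error(sim_params(loss_prob = 1.2), "loss_prob")
  expect_error(sim_params(fluctuation_sd = -0.1), "fluctuation_sd")
})

test_that("identical params and seed give bit-identical output", {
  p <- sim_params(n_puncta = 10, n_timepoints = 20, seed = 42)
  a <- simulate_trace_population(p, "wt", 2)
  b <- simulate_trace_population(p, "wt", 2)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth$setpoints, b$truth$setpoints)
  p2 <- sim_params(n_puncta = 10, n_timepoints = 20, seed = 43)
  expect_false(identical(simulate_trace_population(p2, "wt", 2)$traces,
                         a$traces))
})

test_that("with all stochastic terms off, traces equal setpoint times bleach factor", {
  p <- quiet_params(n_puncta = 5, n_timepoints = 12, bleach_rate = 0.002,
                    seed = 3)
  pop <- simulate_trace_population(p, "wt")
  tv <- sort(unique(pop$traces$t_min))
  expected <- pop$truth$setpoints[[1]] *
    rep(exp(-0.002 * tv), each = 5)
  got <- matrix(pop$traces$fluorescence[order(pop$traces$punctum,
                                              pop$traces$t_min)],
                nrow = 5, byrow = TRUE)
  expect_equal(got, expected, ignore_attr = TRUE)
  expect_true(all(pop$traces$status == "tracked"))
})

test_that("flagged loss fraction is binomially consistent with loss_prob", {
  p <- sim_params(n_puncta = 1000, n_timepoints = 20, loss_prob = 0.1,
                  seed = 7)
  pop <- simulate_trace_population(p, "wt")
  lost <- tapply(pop$traces$status, pop$traces$punctum,
                 function(s) any(s == "lost"))
  frac <- mean(lost)
  tol <- 3 * sqrt(0.1 * 0.9 / 1000)
  expect_lt(abs(frac - 0.1), tol)
  expect_equal(sum(!is.na(pop$truth$loss_times[[1]])), sum(lost))

  p0 <- sim_params(n_puncta = 50, n_timepoints = 10, loss_prob = 0, seed = 1)
  expect_false(any(simulate_trace_population(p0, "wt")$traces$status ==
                     "lost"))
})

test_that("per-step log-SD of a fluctuation-only configuration matches the knob", {
  p <- sim_params(n_puncta = 250, n_timepoints = 41, fluctuation_sd = 0.05,
                  reversion_rate = 0, reconfiguration_sd = 0,
                  bleach_rate = 0, loss_prob = 0, measurement_noise_sd = 0,
                  seed = 11)
  pop <- simulate_trace_population(p, "wt")
  f <- sapply(split(pop$traces, pop$traces$punctum),
              function(d) d$fluorescence[order(d$t_min)])
  steps <- diff(log(f))  # 40 steps x 250 puncta = 10^4 increments
  expect_lt(abs(sd(as.vector(steps)) - 0.05) / 0.05, 0.10)
})

test_that("FRAP forward model honours the two-pool recovery semantics", {
  tt <- c(0, 10, 30, 60, 120, 1e6)
  truth <- list(F_bl = 0.2, P_f = 0.4, tau_f = 15, tau_s = 200)
  rec <- simulate_frap_experiment(truth, tt, noise_sd = 0,
                                  bleach_rate = 0, seed = 1)
  curve <- bleach_correct(rec)
  expect_equal(curve$value[1], 0.2, tolerance = 1e-10)
  expect_equal(curve$value[length(tt)], 1.0, tolerance = 1e-6)
  # single-exponential special case evaluated at t = tau
  v <- frap_model(18, F_bl = 0, P_f = 1, tau_f = 18, tau_s = 18)
  expect_equal(v, 1 - exp(-1), tolerance = 1e-12)
})

test_that("FRAP simulation validates schedule and noise", {
  truth <- frap_presets("ko")
  expect_error(simulate_frap_experiment(truth, numeric(0)), "schedule")
  expect_error(simulate_frap_experiment(truth, c(0, 10, 5)),
               "increasing")
  expect_error(simulate_frap_experiment(truth, c(0, 10), noise_sd = -1),
               "noise_sd")
  expect_error(simulate_frap_experiment(truth, c(0, 10), n_reference = 5),
               "n_reference")
})

test_that("rendered spots sit at the ground-truth centroid and add linearly", {
  tr <- traces_from_matrix(matrix(c(500, 500, 500, 0, 0, 0), 2, 3,
                                  byrow = TRUE))
  stack <- render_image_stack(tr[tr$punctum == "p0001", ], dim = c(48, 48),
                              psf_sd = 1.5, background = 0, noise_sd = 0,
                              seed = 5)
  fr <- stack$frames[, , 1]
  cx <- sum(col(fr) * fr) / sum(fr)
  cy <- sum(row(fr) * fr) / sum(fr)
  expect_lt(abs(cx - stack$positions[1, 1, 1]), 0.1)
  expect_lt(abs(cy - stack$positions[1, 2, 1]), 0.1)

  # doubling the trace doubles the background-subtracted integrated signal
  tr2 <- tr[tr$punctum == "p0001", ]
  tr2$fluorescence <- tr2$fluorescence * 2
  stack2 <- render_image_stack(tr2, dim = c(48, 48), psf_sd = 1.5,
                               background = 20, noise_sd = 0, seed = 5)
  sig1 <- sum(stack$frames[, , 1])
  sig2 <- sum(stack2$frames[, , 1]) - 20 * 48 * 48
  expect_equal(sig2 / sig1, 2, tolerance = 1e-6)
})

test_that("zero puncta renders pure background", {
  tr <- traces_from_matrix(matrix(numeric(0), 0, 3))
  stack <- render_image_stack(tr, dim = c(16, 16), background = 30,
                              noise_sd = 0, t_min = c(0, 10, 20), seed = 1)
  expect_true(all(stack$frames == 30))
})

test_that("genotype presets encode the published orderings and are stable", {
  wt <- genotype_presets("wt"); ko <- genotype_presets("ko")
  expect_gt(ko$fluctuation_sd, wt$fluctuation_sd)
  expect_gt(ko$reconfiguration_sd, wt$reconfiguration_sd)
  expect_gt(ko$loss_prob, wt$loss_prob)
  expect_lt(genotype_presets("ko_blocked")$fluctuation_sd,
            genotype_presets("wt_blocked")$fluctuation_sd)
  expect_identical(genotype_presets("wt"), genotype_presets("wt"))
  # presets differ only in the three condition knobs
  same <- setdiff(names(wt), c("fluctuation_sd", "reconfiguration_sd",
                               "loss_prob"))
  expect_identical(wt[same], ko[same])
  expect_error(genotype_presets("het"), "unknown preset")
})

test_that("trace CSV round trip preserves data and validates schema", {
  pop <- simulate_trace_population(sim_params(n_puncta = 5,
                                              n_timepoints = 6, seed = 2),
                                   "wt")
  path <- tempfile(fileext = ".csv")
  write_trace_csv(pop$traces, path)
  back <- read_trace_csv(path)
  expect_equal(back$fluorescence, pop$traces$fluorescence,
               tolerance = 1e-12)
  bad <- pop$traces
  bad$status[3] <- "gone"
  expect_error(write_trace_csv(bad, tempfile(fileext = ".csv")), "row")
})

test_that("image stack TIFF round trip preserves frames and ground truth", {
  pop <- simulate_trace_population(sim_params(n_puncta = 3,
                                              n_timepoints = 4, seed = 9),
                                   "wt")
  stack <- render_image_stack(pop$traces, dim = c(32, 32), seed = 4)
  path <- tempfile(fileext = ".tif")
  write_image_stack(stack, path)
  back <- read_image_stack(path)
  expect_equal(dim(back$frames), dim(stack$frames))
  # 16-bit quantization: relative error bounded by max/2^16
  expect_lt(max(abs(back$frames - stack$frames)),
            max(stack$frames) / 2^15)
  expect_equal(back$positions, stack$positions, tolerance = 1e-8)
})
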