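test_that("linear-model construction hits the target spectral radii", {
  # diagonal design: eigenvalues of gamma*I are gamma
  m <- make_linear_model(8, 1:3, 0.9, design = "diagonal")
  expect_equal(dnmcrit:::spectral_radius(m$A[1:3, 1:3]), 0.9, tolerance = 1e-12)

  # uniform 8-member block, gamma 0.95: checked against an independent
  # power-iteration estimate on the block
  m2 <- make_linear_model(32, 1:8, 0.95)
  B <- m2$A[1:8, 1:8]
  v <- rep(1 / sqrt(8), 8)
  for (i in 1:200) { v <- B %*% v; v <- v / sqrt(sum(v^2)) }
  expect_equal(as.numeric(t(v) %*% B %*% v), 0.95, tolerance = 1e-6)
  expect_lt(m2$spectral_radius, 1)

  # open-interval precondition on gamma
  expect_error(make_linear_model(8, 1:3, 1.0), "outside")
  expect_error(make_linear_model(8, 1:3, 0), "outside")
  # DNM members must be a strict subset
  expect_error(make_linear_model(4, 1:4, 0.9), "strict subset")
  expect_error(make_linear_model(4, integer(0), 0.9), "strict subset")
})

test_that("difference process is stationary with the AR(1) closed-form SD", {
  # channel 1 is a pure AR(1) with gamma = 0.9 under the diagonal design
  m <- make_linear_model(2, 1, 0.9, design = "diagonal", self_coupling = 0.3,
                         direct_coupling = 0, noise_sd = 1)
  z <- simulate_difference_process(m, 50000, seed = 4)
  expect_equal(sd(z[1, ]), 1 / sqrt(1 - 0.81), tolerance = 0.05)

  # determinism and the noiseless degenerate case
  expect_identical(simulate_difference_process(m, 500, seed = 9),
                   simulate_difference_process(m, 500, seed = 9))
  m0 <- make_linear_model(2, 1, 0.9, noise_sd = 0)
  expect_true(all(simulate_difference_process(m0, 100, seed = 1) == 0))
  expect_error(simulate_difference_process(m, 1), ">= 2")
})

test_that("empirical covariance solves the discrete Lyapunov equation", {
  # includes the delayed direct coupling: oracle iterates the companion form
  m <- make_linear_model(6, 1:2, 0.9, self_coupling = 0.25,
                         direct_coupling = 0.5, coupling_delay = 3,
                         noise_sd = 1)
  Ac <- dnmcrit:::companion_matrix(m$A, m$D, m$delay)
  k <- nrow(Ac)
  Q <- matrix(0, k, k); diag(Q)[1:6] <- 1
  S_theory <- lyapunov_cov(Ac, Q)[1:6, 1:6]
  z <- simulate_difference_process(m, 50000, seed = 8)
  S_emp <- tcrossprod(z) / ncol(z)
  expect_lt(max(abs(S_emp - S_theory)) / max(abs(S_theory)), 0.05)
})

test_that("DNM-member variance grows with gamma; non-members are unaffected", {
  gammas <- c(0.5, 0.7, 0.9, 0.98)
  mean_sd <- function(gamma, seeds = 1:5) {
    sapply(seeds, function(s) {
      m <- make_linear_model(12, 1:4, gamma, direct_coupling = 0.4,
                             noise_sd = 1)
      z <- simulate_difference_process(m, 8000, seed = s)
      c(dnm = mean(apply(z[1:4, ], 1, sd)),
        other = mean(apply(z[5:12, ], 1, sd)))
    })
  }
  res <- vapply(gammas, function(g) rowMeans(mean_sd(g)), numeric(2))
  expect_true(all(diff(res["dnm", ]) > 0))
  expect_lt(max(res["other", ]) / min(res["other", ]) - 1, 0.05)
})

test_that("oddball recordings respect the stimulus design", {
  gs <- default_group_specs(); gs$n <- c(1L, 1L, 1L)
  cfg <- sim_config(n_channels = 8, n_stimuli = 2000, dnm_members = 1:3,
                    groups = gs, seed = 5)
  model <- make_linear_model(8, 1:3, 0.97, noise_sd = 5)
  rec <- simulate_oddball_recording(cfg, model, "S1", "HC", seed = 5)
  expect_equal(nrow(rec$events), 2000)
  k <- rec$events$kind
  n_dev <- sum(k == "deviant")
  # expected 200 deviants; binomial 3-SE band
  expect_lt(abs(n_dev - 200), 3 * sqrt(2000 * 0.1 * 0.9))
  # no two consecutive deviants under the default convention
  expect_false(any(k[-1] == "deviant" & k[-length(k)] == "deviant"))
  expect_true(all(diff(rec$events$onset_sample) == cfg$soa_samples))
  # mismatched channel counts rejected
  expect_error(simulate_oddball_recording(cfg, make_linear_model(6, 1:2, 0.9),
                                          "S1", "HC", 1), "channels")
})

test_that("a planted MMN deflection is recovered from corrected epochs", {
  # dynamics off, sensor noise 5 uV: the corrected-ERP minimum on a DNM
  # channel recovers -3 uV at 170 ms within the SE of the epoch mean
  gs <- data.frame(group = "HC", n = 1L, gamma = 0.5, mmn_amplitude = -3,
                   mmn_latency = 170, direct_coupling = 0)
  cfg <- sim_config(n_channels = 6, n_stimuli = 2000, dnm_members = 1:2,
                    groups = gs, noise_sd = 0, sensor_noise_sd = 5, seed = 2)
  model <- make_linear_model(6, 1:2, 0.5, noise_sd = 0)
  rec <- simulate_oddball_recording(cfg, model, "S1", "HC", seed = 2)
  ce <- correct_epochs(extract_epochs(rec))
  w <- erp_average(ce)
  n_dev <- sum(rec$events$kind == "deviant")
  tol_amp <- 3 * 5 / sqrt(n_dev)
  ch <- 1
  expect_lt(abs(min(w[ch, ]) - (-3)), tol_amp)
  # the Gaussian deflection is nearly flat near its peak, so under sensor
  # noise the argmin wanders a few samples; noiseless recovery is exact
  t_min <- attr(w, "time_axis")[which.min(w[ch, ])]
  expect_lte(abs(t_min - 170), 10)

  cfg0 <- sim_config(n_channels = 6, n_stimuli = 300, dnm_members = 1:2,
                     groups = gs, noise_sd = 0, sensor_noise_sd = 0, seed = 2)
  rec0 <- simulate_oddball_recording(cfg0, model, "S1", "HC", seed = 2)
  w0 <- erp_average(correct_epochs(extract_epochs(rec0)))
  expect_equal(attr(w0, "time_axis")[which.min(w0[ch, ])], 170)
  expect_equal(min(w0[ch, ]), -3, tolerance = 1e-9)
})

test_that("zero injected difference leaves deviant and standard means equal", {
  gs <- data.frame(group = "HC", n = 1L, gamma = 0.5, mmn_amplitude = 0,
                   mmn_latency = 170, direct_coupling = 0)
  cfg <- sim_config(n_channels = 4, n_stimuli = 200, dnm_members = 1:2,
                    groups = gs, noise_sd = 0, sensor_noise_sd = 0, seed = 3)
  model <- make_linear_model(4, 1:2, 0.5, noise_sd = 0)
  rec <- simulate_oddball_recording(cfg, model, "S1", "HC", seed = 3)
  es <- extract_epochs(rec)
  expect_equal(apply(es$deviant, c(2, 3), mean),
               apply(es$standard, c(2, 3), mean), tolerance = 1e-12)
})

test_that("study generation is deterministic and labelled correctly", {
  gs <- default_group_specs(); gs$n <- c(2L, 0L, 2L); gs <- gs[gs$n > 0, ]
  cfg <- sim_config(n_channels = 6, n_stimuli = 30, dnm_members = 1:2,
                    groups = gs, seed = 77)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_length(st1, 4)
  expect_equal(unname(vapply(st1, function(r) r$group, character(1))),
               c("HC", "HC", "PD", "PD"))
  expect_identical(st1[["HC01"]]$signal, st2[["HC01"]]$signal)
  expect_identical(st1[["PD02"]]$events, st2[["PD02"]]$events)
  # per-subject streams differ
  expect_false(identical(st1[["HC01"]]$signal, st1[["HC02"]]$signal))
  gs_bad <- gs; gs_bad$n[1] <- 0L
  expect_error(sim_config(groups = gs_bad), "at least one subject")
})

test_that("streaming simulation matches the two-step generate/preprocess path", {
  gs <- default_group_specs(); gs$n <- c(2L, 1L, 1L)
  cfg <- sim_config(n_channels = 6, n_stimuli = 60, dnm_members = 1:2,
                    groups = gs, seed = 99)
  direct <- simulate_corrected_study(cfg)
  two_step <- preprocess_study(generate_study(cfg))$corrected
  expect_named(direct, names(two_step))
  for (sid in names(direct))
    expect_identical(direct[[sid]]$data, two_step[[sid]]$data)
})
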