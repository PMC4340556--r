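test_that("activity classifier uses a strict excited-count threshold", {
  expect_error(af_activity(integer(0), 10), "empty")
  expect_equal(af_activity(c(0L, 10L, 11L), L = 10, threshold_factor = 1),
               c(FALSE, FALSE, TRUE))
  expect_equal(af_activity(c(0L, 10L, 11L), L = 10, threshold_factor = 1.2),
               c(FALSE, FALSE, FALSE))
  expect_equal(time_in_af(c(0L, 10L, 11L, 30L), L = 10, threshold_factor = 1),
               0.5)
  # default threshold tolerates straggler blips, flags a second front
  expect_equal(af_activity(c(10L, 11L, 21L), L = 10),
               c(FALSE, FALSE, TRUE))
})

test_that("online reentry detection fires within two cycles on the motif", {
  toy <- make_fixture("toy_circuit", ell = 3, tau = 4)
  st <- prepare_wavebreak_state(toy)
  tr <- run_episode(toy, 60, state = st, record_activations = TRUE,
                    detect_reentry = TRUE)
  expect_false(is.null(tr$first_reentry))
  # detection within the first two reentry cycles after the wave break
  period <- 2 * 3 + 4
  expect_lt(tr$first_reentry$t, st$t + 2 * 3 + 2 + 2 * period)
})

test_that("offline reentry detector agrees with the online one on a full run", {
  # a fully recorded run from t = 0, so the offline event log carries the
  # same history the online detector tracks
  fix <- make_fixture("critical_one", seed = 1)
  tr <- run_episode(fix, 7000, record_activations = TRUE,
                    detect_reentry = TRUE)
  expect_false(is.null(tr$first_reentry))
  off <- reentry_detector(tr)
  expect_equal(off, tr$first_reentry)
})

test_that("no reentry is reported for planar rhythm", {
  sub <- generate_substrate(model_config(L = 30, nu = 1, delta = 0.05,
                                         tau = 8, T = 50, seed = 2))
  tr <- run_episode(sub, 250, record_activations = TRUE,
                    detect_reentry = TRUE)
  expect_null(tr$first_reentry)
  expect_null(reentry_detector(tr))
  expect_error(reentry_detector(run_episode(sub, 10)), "activations")
})

test_that("phase sweep rows are complete, deterministic and seeded apart", {
  cfg <- model_config(L = 40, tau = 10, T = 50, seed = 31)
  sw <- phase_sweep(c(0.1, 0.6), n_realizations = 3, n_steps = 500,
                    config = cfg)
  expect_equal(nrow(sw), 6)
  expect_equal(sort(unique(sw$nu)), c(0.1, 0.6))
  expect_equal(length(unique(sw$seed[sw$nu == 0.1])), 3)
  expect_true(all(sw$time_in_af >= 0 & sw$time_in_af <= 1))
  sw2 <- phase_sweep(c(0.1, 0.6), n_realizations = 3, n_steps = 500,
                     config = cfg)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  md <- attr(sw, "metadata")
  expect_equal(md$n_steps, 500L)
  expect_equal(md$base_seed, 31L)
})

test_that("transition locator finds the steepest drop midpoint", {
  fake <- data.frame(
    nu = rep(c(0.1, 0.12, 0.14, 0.16), each = 2),
    realization = rep(1:2, 4), seed = 1:8,
    time_in_af = c(0.9, 0.8, 0.7, 0.8, 0.1, 0.2, 0.05, 0.0),
    n_critical = 0L, reentry_detected = FALSE)
  class(fake) <- c("af_sweep", "data.frame")
  expect_equal(transition_estimate(fake), 0.13)
  s <- summarize_sweep(fake)
  expect_equal(s$mean_time_in_af, c(0.85, 0.75, 0.15, 0.025))
})

test_that("ablation is inconclusive when no reentry forms", {
  sub <- make_fixture("planar", L = 30, tau = 8, T = 60)
  ab <- ablation_experiment(substrate = sub, max_wait = 300)
  expect_equal(ab$outcome, "inconclusive")
  expect_null(ab$detection)
})

test_that("lesioning a scripted rotor terminates it; a remote lesion does not", {
  fix <- make_fixture("critical_one", seed = 1)
  ab <- ablation_experiment(substrate = fix, max_wait = 2e4)
  expect_equal(ab$outcome, "terminated")
  # the lesion covers the critical cell
  motif <- attr(fix, "motif")
  expect_true(ab$lesion$x0 <= motif$xd &&
                motif$xd < ab$lesion$x0 + ab$lesion$w)
  expect_equal(ab$n_post_reentry_events, 0)
  # pacing resumed: pacemaker beats occur in the post-lesion tail
  post_len <- length(ab$post_trace)
  expect_gt(sum(ab$post_trace > 0), 0)

  ctrl <- ablation_experiment(substrate = fix, max_wait = 2e4,
                              lesion_center = c(50, 5))
  # same detection, but the circuit keeps firing after the remote lesion
  expect_false(is.null(ctrl$post_reentry))
  expect_gt(ctrl$n_post_reentry_events, 10)
})
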