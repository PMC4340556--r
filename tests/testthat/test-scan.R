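test_that("ell distances in degenerate substrates", {
  full <- generate_substrate(model_config(L = 12, nu = 1, seed = 1))
  for (xy in list(c(1, 1), c(5, 9), c(12, 12))) {
    expect_equal(ell_distance(full, xy[1], xy[2]), 0L)
  }
  expect_equal(nrow(find_critical_regions(full, tau = 4)), 0)

  none <- generate_substrate(model_config(L = 12, nu = 0, delta = 0.3,
                                          seed = 1))
  expect_true(is.na(ell_distance(none, 3, 3)))
  # no transverse edge anywhere: no circuit can close, so no critical
  # region is emitted even though every ell is undefined
  expect_equal(nrow(find_critical_regions(none, tau = 4)), 0)
  expect_error(ell_distance(full, 13, 1), "x")
})

test_that("ell distance counts cells to the first coupled column", {
  # the toy motif couples columns xd - 1 and xd + ell only (cables 1, 2)
  toy <- make_fixture("toy_circuit", ell = 7, tau = 4, xd = 4)
  expect_equal(ell_distance(toy, 4, 2), 7L)
  expect_equal(ell_distance(toy, 4, 1), 7L)
  expect_equal(ell_distance(toy, 3, 2), 0L)   # sits on the left closure
  expect_equal(ell_distance(toy, 5, 2), 6L)
  expect_true(is.na(ell_distance(toy, 12, 2)))  # right of the last edge
  expect_true(is.na(ell_distance(toy, 4, 5)))   # uncoupled cable
})

test_that("scanner emits exactly the dysfunctional cells with long ell", {
  toy <- make_fixture("toy_circuit", ell = 3, tau = 4)
  regions <- find_critical_regions(toy)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$x, attr(toy, "motif")$xd)
  expect_equal(regions$y, 2)
  expect_equal(regions$ell, 3L)
  # still critical at tau = 6 (ell = tau/2 ties are critical), gone at 8
  expect_equal(nrow(find_critical_regions(toy, tau = 6)), 1)
  expect_equal(nrow(find_critical_regions(toy, tau = 8)), 0)
  # delta = 0: no dysfunctional cells, no regions
  clean <- generate_substrate(model_config(L = 30, nu = 0.1, delta = 0,
                                           tau = 10, seed = 3))
  expect_equal(nrow(find_critical_regions(clean)), 0)
})

test_that("scanner ignores ablated cells", {
  toy <- make_fixture("toy_circuit", ell = 3, tau = 4)
  xd <- attr(toy, "motif")$xd
  les <- apply_lesion(toy, xd, 2, 1, 1)
  expect_equal(nrow(find_critical_regions(les)), 0)
})

test_that("ell distances follow the geometric law of the coupling", {
  # one sample per odd cable (odd cables share no candidate edges), at
  # the left boundary so truncation is negligible within the binned range
  nu <- 0.3
  p <- 1 - (1 - nu)^2
  L <- 40
  K <- 8L
  rows <- seq(3, L - 1, by = 2)
  samples <- integer(0)
  for (i in 1:530) {
    sub <- generate_substrate(model_config(L = L, nu = nu, seed = 5000 + i))
    em <- vapply(rows, function(y) {
      d <- ell_distance(sub, 1, y)
      if (is.na(d)) K else min(d, K)
    }, integer(1))
    samples <- c(samples, em)
  }
  expect_gte(length(samples), 1e4)
  obs <- tabulate(samples + 1L, nbins = K + 1L)
  probs <- c((1 - p)^(0:(K - 1)) * p, (1 - p)^K)  # tail bin: ell >= K or NA
  fit <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(fit$p.value, 0.01)
})

test_that("expected critical-region count matches the exact enumeration", {
  L <- 100L
  tau <- 10L
  delta <- 0.05
  nu <- 0.2
  p <- 1 - (1 - nu)^2
  # exact per-column probability that a dysfunctional cell at column x is
  # critical: no coupled cell within tau/2, but at least one before the
  # boundary
  k <- tau / 2
  xs <- seq_len(L)
  p_crit <- ifelse(xs <= L - k,
                   (1 - p)^k * (1 - (1 - p)^(L - xs + 1 - k)), 0)
  expected <- delta * L * sum(p_crit)
  n_sub <- 500
  counts <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    sub <- generate_substrate(model_config(L = L, nu = nu, delta = delta,
                                           tau = tau, seed = 9000 + i))
    counts[i] <- nrow(find_critical_regions(sub))
  }
  se <- stats::sd(counts) / sqrt(n_sub)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # and the naive delta L^2 (1-nu)^tau formula is close to the exact one
  expect_lt(abs(expected - delta * L^2 * (1 - nu)^tau) / expected, 0.1)
})

test_that("Monte Carlo risk estimate is consistent with the closed form", {
  cfg <- model_config(L = 100, nu = 0.25, delta = 0.05, tau = 20, seed = 77)
  est <- mc_risk_estimate(cfg, 200)
  pa <- p_risk(0.25, 20, 0.05, 100)
  expect_lt(abs(est$fraction - pa), 3 * sqrt(pa * (1 - pa) / 200))
  # degenerate cases
  expect_equal(mc_risk_estimate(model_config(L = 50, nu = 1, tau = 10),
                                20)$fraction, 0)
  expect_equal(mc_risk_estimate(model_config(L = 50, nu = 0, tau = 10),
                                20)$fraction, 0)  # no edge, no circuit
})

test_that("detected reentry implies a scanned critical region", {
  found <- 0L
  for (r in 1:5) {
    cfg <- model_config(L = 100, nu = 0.1, delta = 0.05, tau = 20, T = 110,
                        seed = 400 + r)
    sub <- generate_substrate(cfg)
    tr <- run_episode(sub, 4000, detect_reentry = TRUE)
    if (!is.null(tr$first_reentry)) {
      found <- found + 1L
      expect_gte(nrow(find_critical_regions(sub)), 1)
    }
  }
  expect_gt(found, 0)  # the regime does produce reentry
})
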