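test_that("rescoring a deterministic backend collapses to the exact mean", {
  land <- flat_landscape(mean_binding = -15, noise_sd = 0)
  r <- rescore("AAAA", land, seed = 1)
  expect_equal(r$mean, -15)
  expect_equal(r$sd, 0)
  expect_equal(r$sem, 0)
  expect_identical(nrow(r$samples), 100L)  # 10 runs x last 10 configurations
  expect_identical(sort(unique(r$samples$step)), 91:100)
})

test_that("single-shot mode reduces to plain independent draws", {
  land <- flat_landscape(mean_binding = -9, noise_sd = 1)
  r <- rescore("AAAA", land, n_steps = 1, retain_last = 1, n_runs = 50,
               seed = 12)
  expect_identical(nrow(r$samples), 50L)
  # no Monte Carlo selection: mean is unbiased around the backend mean
  expect_equal(r$mean, -9, tolerance = 4 / sqrt(50))
  expect_error(rescore("AAAA", land, n_steps = 5, retain_last = 6),
               class = "pepremc_bad_config")
})

test_that("Metropolis selection biases retained energies into the low tail", {
  land <- flat_landscape(mean_binding = -15, noise_sd = 1)
  means <- vapply(1:10, function(s) rescore("AAAA", land, seed = s)$mean,
                  numeric(1))
  # stationary mean of the independence sampler is mu - sd^2/kBT = -16.67
  expect_true(all(means <= -15))
  expect_true(mean(means) > -17 && mean(means) < -15)
})

test_that("retained-sample dispersion scales linearly with backend noise", {
  # The chain is scale-equivariant: scores mu + noise*z with kBT proportional
  # to the noise give identical acceptance decisions, so the retained-sample
  # SD is exactly proportional to noise_sd.
  noises <- c(0.5, 1, 2)
  sds <- vapply(noises, function(ns) {
    land <- flat_landscape(mean_binding = -15, noise_sd = ns)
    rescore("AAAA", land, kBT = 0.6 * ns, n_runs = 50, seed = 7)$sd
  }, numeric(1))
  slope <- sum(sds * noises) / sum(noises^2)
  expect_equal(slope, sds[2], tolerance = 0.1)
  expect_equal(sds[1] / 0.5, sds[3] / 2, tolerance = 1e-10)
  # at fixed kBT the selection strength grows with noise, so dispersion
  # still increases with noise but sub-linearly
  fixed <- vapply(noises, function(ns) {
    land <- flat_landscape(mean_binding = -15, noise_sd = ns)
    rescore("AAAA", land, n_runs = 50, seed = 7)$sd
  }, numeric(1))
  expect_true(all(diff(fixed) > 0))
})

test_that("corrected binding energy is the site difference with summed SEMs", {
  # deterministic landscapes pinned to published-scale means
  terms_b <- matrix(-18.7 / 4, 4, 4, dimnames = list(NULL, ab4))
  land <- synthetic_landscape(terms_b, noise_sd = 0, control_offset = 8.2)
  b <- rescore("AAAA", land, site = "binding", seed = 1, name = "MBP-9-like")
  cc <- rescore("AAAA", land, site = "control", seed = 2, name = "MBP-9-like")
  be <- compute_be(b, cc)
  expect_equal(be$be, -8.2, tolerance = 1e-12)   # -18.7 - (-10.5)
  expect_equal(be$mean_binding, -18.7)
  expect_equal(be$mean_control, -10.5)

  # stated sum rule and its quadrature alternative
  f1 <- fake_rescore(-18.7, 0.11)
  f2 <- fake_rescore(-10.5, 0.25, site = "control")
  expect_equal(compute_be(f1, f2)$err, 0.36)
  expect_equal(compute_be(f1, f2, err_method = "quadrature")$err,
               sqrt(0.11^2 + 0.25^2))

  # identical sample sets give BE = 0
  expect_equal(compute_be(f1, f1)$be, 0)

  expect_error(compute_be(f1, fake_rescore(-10, 0.1, sequence = "GGGG")),
               class = "pepremc_peptide_mismatch")
})

test_that("candidate ranking orders by BE and flags unresolved intervals", {
  tab <- tibble::tibble(peptide = c("X", "Y", "Z"),
                        be = c(-8.2, -2.0, -5.0),
                        err = c(0.3, 0.3, 0.3))
  rk <- rank_candidates(tab)
  expect_identical(rk$peptide, c("X", "Z", "Y"))
  expect_identical(rk$rank, 1:3)
  expect_false(any(rk$unresolved))

  one <- rank_candidates(tab[1, ])
  expect_identical(nrow(one), 1L)
  expect_false(one$unresolved)

  two <- rank_candidates(tibble::tibble(peptide = c("A", "B"),
                                        be = c(-5.0, -4.8), err = c(0.2, 0.2)))
  expect_true(all(two$unresolved))

  expect_error(rank_candidates(tab[0, ]), class = "pepremc_empty_input")
})

test_that("rescore_candidates runs the whole BE pipeline reproducibly", {
  land <- generate_landscape(length = 4, alphabet = ab4, noise_sd = 1,
                             control_offset = 4, seed = 6)
  cands <- tibble::tibble(name = c("p1", "p2", "p3"),
                          sequence = c("AAAA", "GGGG", "YRYR"))
  rk1 <- rescore_candidates(cands, land, n_runs = 4, n_steps = 20,
                            retain_last = 5, seed = 11)
  rk2 <- rescore_candidates(cands, land, n_runs = 4, n_steps = 20,
                            retain_last = 5, seed = 11)
  expect_identical(nrow(rk1), 3L)
  expect_identical(as.data.frame(rk1), as.data.frame(rk2))
  expect_true(all(c("mean_binding", "mean_control", "be", "err", "rank",
                    "unresolved") %in% names(rk1)))
  expect_error(rescore_candidates(cands[0, ], land),
               class = "pepremc_empty_input")
})
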