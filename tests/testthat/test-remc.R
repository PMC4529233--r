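test_that("Metropolis rule always accepts improvements and equal scores", {
  withr::local_seed(1)
  expect_true(all(metropolis_accept(rep(-10, 500), rep(-10, 500), 0.6)))
  expect_true(all(metropolis_accept(rep(-10, 500), runif(500, -30, -10), 0.2)))
  expect_error(metropolis_accept(0, Inf, 0.6), class = "pepremc_nonfinite_score")
  expect_error(metropolis_accept(0, 1, 0), class = "pepremc_bad_temperature")
})

test_that("Metropolis acceptance matches the Boltzmann factor and grows with kBT", {
  withr::local_seed(21)
  # closed form at a second operating point than the headline one
  acc <- mean(metropolis_accept(rep(0, 5e4), rep(0.8, 5e4), 0.4))
  p <- exp(-2)
  expect_lt(abs(acc - p), 4 * sqrt(p * (1 - p) / 5e4))
  # monotone in temperature for fixed unfavourable step
  rates <- vapply(c(0.2, 0.4, 0.6, 1.2), function(kt) {
    mean(metropolis_accept(rep(0, 4e4), rep(0.6, 4e4), kt))
  }, numeric(1))
  expect_true(all(diff(rates) > -0.01))
})

test_that("swap criterion follows detailed balance sign analysis", {
  expect_equal(swap_probability(-12, -12, 0.2, 0.6), 1)  # equal scores
  # better (lower) score sits hot: moving it cold is always accepted
  expect_equal(swap_probability(-10, -14, 0.2, 0.6), 1)
  # worked closed form: cold replica better by 0.3 -> exp(-1)
  expect_equal(swap_probability(-14.3, -14, 0.2, 0.6), exp(-1), tolerance = 1e-12)
  expect_error(swap_probability(-1, -2, 0.4, 0.4),
               class = "pepremc_same_temperature")
})

test_that("accepted swaps exchange configurations but keep temperature slots", {
  a <- replica_state("AAAA", -14, 0.2, 1L)
  b <- replica_state("GGGG", -16, 0.6, 3L)
  withr::local_seed(2)
  out <- attempt_swap(a, b)   # favourable direction: always accepted
  expect_true(out$accepted)
  expect_identical(out$a$sequence, "GGGG")
  expect_identical(out$b$sequence, "AAAA")
  expect_identical(out$a$kBT, 0.2)
  expect_identical(out$b$kBT, 0.6)
  expect_identical(out$a$replica_index, 1L)
})

test_that("trajectory bookkeeping matches the three-replica 100-step protocol", {
  land <- generate_landscape(length = 8, noise_sd = 0, seed = 1)
  tr <- run_remc("AAAAAAAA", land, ladder = c(0.2, 0.4, 0.6), n_steps = 100,
                 seed = 5)
  st <- tr$steps
  expect_identical(sum(st$move == "mutation"), 3L * 101L)
  expect_identical(sum(st$move == "swap"), 100L)
  expect_true(all(st$accepted[st$step == 0]))
  expect_true(all(table(st$step[st$move == "swap"]) == 1))   # one swap per step
  expect_setequal(unique(st$kBT[st$move == "mutation"]), c(0.2, 0.4, 0.6))
  # scores in mutation records are post-decision chain states
  for (r in 1:3) {
    s <- st[st$move == "mutation" & st$replica == r, ]
    expect_equal(s$score,
                 landscape_mean(land, s$sequence), tolerance = 1e-12)
  }
})

test_that("identical seeds give identical trajectories", {
  land <- generate_landscape(length = 4, alphabet = ab4, noise_sd = 1, seed = 2)
  t1 <- run_remc("AAAA", land, n_steps = 50, seed = 123)
  t2 <- run_remc("AAAA", land, n_steps = 50, seed = 123)
  expect_identical(t1$steps, t2$steps)
})

test_that("the greedy limit is monotonically non-increasing", {
  land <- generate_landscape(length = 4, alphabet = ab4, noise_sd = 0, seed = 8)
  tr <- run_remc("AAAA", land, ladder = 1e-9, n_steps = 200, seed = 3)
  scores <- tr$steps$score[tr$steps$move == "mutation"]
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("degenerate and invalid engine inputs are handled", {
  land <- flat_landscape()
  tr0 <- run_remc("AAAA", land, n_steps = 0, seed = 1)
  expect_identical(unique(tr0$steps$sequence), "AAAA")
  expect_identical(nrow(final_states(tr0)), 3L)
  expect_error(run_remc("AAAA", land, ladder = c(0.2, 0.2)),
               class = "pepremc_bad_temperature")
  expect_error(run_remc("AAAA", land, ladder = numeric(0)),
               class = "pepremc_bad_temperature")
  expect_error(run_remc("AAXA", land), class = "pepremc_invalid_residue")
})

test_that("campaign selection takes the lowest final score with stated tie-breaks", {
  land <- generate_landscape(length = 4, alphabet = ab4, noise_sd = 0.5, seed = 4)
  camp <- run_campaign("AAAA", land, n_steps = 20, n_runs = 9, seed = 99)
  expect_identical(nrow(camp$selected), 9L)
  expect_identical(camp$selected$run, 1:9)
  for (i in c(1, 5, 9)) {
    fin <- final_states(camp$trajectories[[i]])
    expect_equal(camp$selected$score[i], min(fin$score))
  }
  # identical seed reproduces the whole campaign
  camp2 <- run_campaign("AAAA", land, n_steps = 20, n_runs = 9, seed = 99)
  expect_identical(camp$selected, camp2$selected)

  # tie-breaks on a hand-built trajectory: lower kBT, then lexicographic
  fake <- structure(list(
    steps = tibble::tibble(
      run = 1L, step = 1L, replica = 1:3, partner = NA_integer_,
      kBT = c(0.6, 0.2, 0.4), move = "mutation",
      sequence = c("GAAA", "CAAA", "BAAA"), score = c(-16, -16, -12),
      accepted = TRUE),
    meta = list(run = 1L, n_steps = 1L, ladder = c(0.6, 0.2, 0.4))),
    class = "remc_trajectory")
  expect_identical(select_best(fake)$sequence, "CAAA")  # -16 tie, kBT 0.2 wins
  fake$steps$kBT <- 0.4
  fake$steps$score <- -16
  expect_identical(select_best(fake)$sequence, "BAAA")  # full tie: lexicographic
})

test_that("backend failures are logged and treated as rejected proposals", {
  # scores: 3 starting scores, then proposals; two NAs fail mid-run
  vals <- c(-5, -5, -5, -6, NA, -7, NA, -6.5, -8)
  rb <- replay_backend(vals)
  warns <- testthat::capture_warnings(
    tr <- run_remc("AAA", rb, ladder = c(0.2, 0.4, 0.6), n_steps = 2,
                   seed = 17, alphabet = ab4))
  expect_length(warns, 2)   # one logged warning per failing proposal
  expect_match(warns, "backend failure", all = TRUE)
  st <- tr$steps
  expect_identical(nrow(st), 3L * 3L + 2L)
  # the two failing proposals were rejected: state carried over
  mut <- st[st$move == "mutation" & st$step > 0, ]
  expect_gte(sum(!mut$accepted), 2)
  expect_true(all(is.finite(mut$score)))
  expect_identical(tr$meta$n_backend_failures, 2L)
})

test_that("the engine is indifferent to the backend behind the contract", {
  # a recorded-replay fake drives the full REMC loop end to end
  vals <- -10 - cumsum(runif(200, 0, 0.1))
  rb <- replay_backend(vals)
  tr <- run_remc("AAAA", rb, n_steps = 20, seed = 31, alphabet = ab4)
  st <- tr$steps[tr$steps$move == "mutation", ]
  expect_identical(nrow(st), 63L)
  expect_true(all(st$score %in% vals))
  # every scored proposal was a Hamming-1 neighbour of the previous state
  seqs <- rb$log$sequences
  expect_true(length(seqs) >= 23)
})

test_that("replica exchange escapes a decoy basin better than cold-only search", {
  land <- two_basin_landscape()
  n <- 50
  hits <- function(ladder, n_steps, seed0) {
    sum(vapply(seq_len(n), function(i) {
      tr <- run_remc("GGG", land, ladder = ladder, n_steps = n_steps,
                     seed = seed0 + i)
      select_best(tr)$score <= -5.9   # reached the -6 global optimum
    }, logical(1)))
  }
  remc <- hits(c(0.2, 0.4, 0.6), 100, 2000)     # 300 scoring calls
  cold <- hits(0.2, 300, 6000)                  # equal budget, coldest kBT only
  expect_gte(remc, cold)
  expect_gt(remc, 0)
})
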