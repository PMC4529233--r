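test_that("noise-free synthetic scoring is deterministic and additive", {
  terms <- matrix(-1, 8, 20, dimnames = list(NULL, aa_alphabet()))
  land <- synthetic_landscape(terms, noise_sd = 0)
  s1 <- score_sequence(land, "AAAAAAAA")
  s2 <- score_sequence(land, "AAAAAAAA")
  expect_identical(s1$value, s2$value)
  expect_identical(s1$value, -8)              # sum of 8 unit terms
  expect_false(identical(s1$pose_id, s2$pose_id))  # fresh pose handle per call
  expect_identical(s1$site_label, "binding")
})

test_that("deterministic mean matches a brute-force term sum on the full space", {
  land <- generate_landscape(length = 4, alphabet = ab4, noise_sd = 0, seed = 3)
  seqs <- enumerate_peptides(4, ab4)
  expect_length(seqs, 256)
  # independent oracle: explicit per-position lookup loop
  oracle <- vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    tot <- 0
    for (p in 1:4) tot <- tot + land$terms[p, chars[p]]
    tot
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(landscape_mean(land, seqs), oracle, tolerance = 1e-12)
})

test_that("control site is the binding mean plus the configured offset", {
  land <- flat_landscape(mean_binding = -15, control_offset = 4)
  expect_equal(landscape_mean(land, "AAAA", site = "binding"), -15)
  expect_equal(landscape_mean(land, "AAAA", site = "control"), -11)
  zero <- synthetic_landscape(matrix(0, 4, 4, dimnames = list(NULL, ab4)))
  expect_equal(landscape_mean(zero, enumerate_peptides(4, ab4)), rep(0, 256))
})

test_that("per-call noise has the configured dispersion", {
  land <- flat_landscape(mean_binding = -15, noise_sd = 1)
  withr::local_seed(5)
  vals <- replicate(10000, score_sequence(land, "AAAA")$value)
  expect_equal(mean(vals), -15, tolerance = 0.05)
  expect_gt(sd(vals), 0.97)   # chi-square band for the SD of 1e4 normals
  expect_lt(sd(vals), 1.03)
})

test_that("landscape generation is seed-reproducible and records the true optimum", {
  l1 <- generate_landscape(length = 4, alphabet = ab4, seed = 1)
  l2 <- generate_landscape(length = 4, alphabet = ab4, seed = 1)
  expect_identical(l1$terms, l2$terms)

  land <- generate_landscape(length = 4, alphabet = ab4, noise_sd = 0, seed = 9)
  seqs <- enumerate_peptides(4, ab4)
  mu <- landscape_mean(land, seqs)
  expect_equal(landscape_optimum(land)$score, min(mu), tolerance = 1e-12)
  expect_identical(landscape_optimum(land)$sequence, seqs[which.min(mu)])

  # non-negative terms with no control offset give a non-negative optimum
  withr::local_seed(2)
  pos <- synthetic_landscape(
    matrix(abs(rnorm(16)), 4, 4, dimnames = list(NULL, ab4)),
    control_offset = 0)
  expect_gte(landscape_optimum(pos)$score, 0)
})

test_that("epistasis terms enter the mean only when both residues are present", {
  land <- two_basin_landscape()
  expect_equal(landscape_mean(land, "GGG"), 3 * 0.5 - 2 * 3.5)
  expect_equal(landscape_mean(land, "AGG"), -2 + 0.5 + 0.5 - 3.5)
  expect_equal(landscape_mean(land, "AAA"), -6)
  expect_null(landscape_optimum(land))  # argmin invalid under epistasis
})

test_that("landscape TSV serialisation round-trips every component", {
  land <- generate_landscape(length = 3, alphabet = ab4, noise_sd = c(1, 2),
                             control_offset = 3.5, independent_control = TRUE,
                             seed = 4)
  land$epistasis <- tibble::tibble(pos_i = 1, pos_j = 2, res_i = "A",
                                   res_j = "G", term = -0.7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(land, path)
  back <- read_landscape(path)
  expect_equal(back$terms, land$terms, tolerance = 1e-12)
  expect_equal(back$control_terms, land$control_terms, tolerance = 1e-12)
  expect_equal(back$noise_sd, land$noise_sd)
  expect_equal(back$control_offset, land$control_offset)
  expect_equal(as.data.frame(back$epistasis), as.data.frame(land$epistasis),
               tolerance = 1e-12)
  seqs <- enumerate_peptides(3, ab4)
  expect_equal(landscape_mean(back, seqs, "control"),
               landscape_mean(land, seqs, "control"), tolerance = 1e-12)
})

test_that("replay backend honours the contract including failures", {
  rb <- replay_backend(c(-5, NA, -7))
  expect_identical(score_sequence(rb, "AAAA")$value, -5)
  expect_error(score_sequence(rb, "AAAA"), class = "pepremc_backend_failure")
  expect_identical(score_sequence(rb, "GGGG")$value, -7)
  expect_error(score_sequence(rb, "AAAA"), class = "pepremc_backend_failure")
  expect_identical(rb$log$sequences, c("AAAA", "GGGG"))
})

test_that("docking box metadata is validated", {
  cfg <- docking_config(box_center = c(1, 2, 3), site_label = "control")
  expect_identical(cfg$box_size, c(25, 25, 25))
  expect_identical(cfg$exhaustiveness, 10L)
  expect_identical(cfg$energy_range, 4)
  expect_error(docking_config(box_size = c(25, 0, 25)),
               class = "pepremc_bad_config")
})
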