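# Shared fixtures, all built in code.

ab4 <- c("A", "G", "Y", "R")

# flat landscape: every sequence has the same binding mean
flat_landscape <- function(mean_binding = -15, length = 4, alphabet = ab4,
                           noise_sd = 0, control_offset = 4) {
  terms <- matrix(mean_binding / length, length, base::length(alphabet),
                  dimnames = list(NULL, alphabet))
  synthetic_landscape(terms, noise_sd = noise_sd,
                      control_offset = control_offset)
}

# two-basin landscape: global optimum AAA (-6), decoy GGG (-5.5) behind a
# ~1 kcal/mol-per-move barrier, built from G-G pairwise couplings
two_basin_landscape <- function() {
  terms <- matrix(rep(c(-2, 0.5, 1, 1), each = 3), 3, 4,
                  dimnames = list(NULL, ab4))
  epi <- tibble::tibble(pos_i = c(1, 2), pos_j = c(2, 3),
                        res_i = "G", res_j = "G", term = -3.5)
  synthetic_landscape(terms, epistasis = epi)
}

# exact Boltzmann distribution over an enumerable landscape
exact_boltzmann <- function(landscape, kBT, site = "binding") {
  seqs <- enumerate_peptides(landscape$length, landscape$alphabet)
  mu <- landscape_mean(landscape, seqs, site = site)
  w <- exp(-(mu - min(mu)) / kBT)
  stats::setNames(w / sum(w), seqs)
}

# total-variation distance between empirical sequence frequencies and a
# reference distribution
tv_distance <- function(sequences, ref) {
  emp <- table(factor(sequences, levels = names(ref))) / length(sequences)
  0.5 * sum(abs(as.numeric(emp) - ref))
}

# minimal rescore_result stub for arithmetic-only tests
fake_rescore <- function(mean, sem, sequence = "AAAA", name = sequence,
                         site = "binding") {
  structure(list(name = name, sequence = sequence, site = site,
                 samples = tibble::tibble(run = 1L, step = 1L, score = mean),
                 mean = mean, sd = NA_real_, sem = sem, sem_samples = sem,
                 sd_run_means = NA_real_, kBT = 0.6, n_runs = 1L,
                 n_steps = 1L, retain_last = 1L, seed = NULL),
            class = "rescore_result")
}
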