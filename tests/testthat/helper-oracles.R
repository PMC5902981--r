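# Independent oracles and small fixtures shared across the test files.

# Full tabular (recursive) additive-relationship matrix over a whole
# pedigree, written independently of the package's generation-wise
# propagation kernel. `id` must be topologically sorted (parents before
# offspring); sire/dam 0 = unknown founder parent.
tabular_A <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id, nomatch = 0L)
  di <- match(dam, id, nomatch = 0L)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        a <- 0
        if (si[i] > 0L) a <- a + 0.5 * A[j, si[i]]
        if (di[i] > 0L) a <- a + 0.5 * A[j, di[i]]
        A[i, j] <- A[j, i] <- a
      }
    }
    A[i, i] <- 1 + if (si[i] > 0L && di[i] > 0L) 0.5 * A[si[i], di[i]] else 0
  }
  A
}

# Downscaled breeding design used where the full 20,000-candidate program
# would be wasteful: 5 sires, 20 dams, 6 offspring per mating.
tiny_spec <- function(...) {
  args <- list(n_sires = 5L, n_dams = 20L, n_off_per_mating = 6L,
               founder_allele_freq = 0.2, n_burnin_generations = 2L,
               n_selection_generations = 5L, n_replicates = 5L,
               base_seed = 101L)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_spec, args)
}

# Hand-built cohort rows for module-level tests.
make_cohort <- function(id, sex, ebv, g, tbv = ebv, f = 0,
                        sire_id = 0L, dam_id = 0L, generation = 0L) {
  data.frame(id = id, sire_id = sire_id, dam_id = dam_id,
             generation = generation, sex = sex, tbv = tbv, ebv = ebv,
             g = g, f = f, edited = FALSE, alive = TRUE)
}
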