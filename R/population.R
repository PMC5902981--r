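#' @useDynLib edsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rbinom var
NULL

# A cohort is a data.frame with one row per animal and columns:
#   id        integer, unique, strictly greater than both parent ids
#   sire_id   integer, 0 = unknown (founders)
#   dam_id    integer, 0 = unknown
#   generation integer (founders at -n_burnin_generations)
#   sex       "M" or "F"
#   tbv       true breeding value for the polygenic trait
#   ebv       pseudo-estimated breeding value (NA for dead zygotes)
#   g         count of desired alleles at the monogenic locus, 0/1/2
#   f         pedigree inbreeding coefficient
#   edited    TRUE if the zygote was subjected to an editing procedure
#   alive     FALSE for zygotes that died from the procedure
new_cohort <- function(id, sire_id, dam_id, generation, sex, tbv, ebv, g, f,
                       edited, alive) {
  data.frame(id = id, sire_id = sire_id, dam_id = dam_id,
             generation = generation, sex = sex, tbv = tbv, ebv = ebv,
             g = g, f = f, edited = edited, alive = alive)
}

#' Create the founder cohort
#'
#' Founders are unrelated, non-inbred animals at generation
#' `-n_burnin_generations`. Their true breeding values are drawn from N(0, 1)
#' (the founder genetic variance defines the TBV unit), monogenic genotypes
#' from Hardy-Weinberg proportions at the founder desired-allele frequency,
#' and sexes from a Bernoulli(0.5). Pseudo-EBV are attached with
#' [simulate_ebv()].
#'
#' @param spec A [scenario_spec()].
#' @return A founder cohort data.frame of `n_dams * n_off_per_mating` animals.
#' @export
init_founders <- function(spec) {
  n <- spec$n_dams * spec$n_off_per_mating
  p <- spec$founder_allele_freq
  tbv <- rnorm(n)
  g <- sample.int(3L, n, replace = TRUE,
                  prob = c((1 - p)^2, 2 * p * (1 - p), p^2)) - 1L
  sex <- ifelse(rbinom(n, 1L, 0.5) == 1L, "M", "F")
  ebv <- simulate_ebv(tbv, spec$reliability_r2)
  new_cohort(id = seq_len(n), sire_id = 0L, dam_id = 0L,
             generation = -spec$n_burnin_generations, sex = sex,
             tbv = tbv, ebv = ebv, g = g, f = 0,
             edited = FALSE, alive = TRUE)
}

#' Simulate a pseudo-estimated breeding value
#'
#' Emulates genomic evaluation without simulating markers: a prediction error
#' drawn from N(0, (1 - r2) / r2), on the founder genetic-variance scale, is
#' added to the true breeding value and the sum is scaled by the reliability,
#' `ebv = r2 * (tbv + pe)`. With `r2 = 1` the EBV equals the TBV. On a founder
#' population the correlation between TBV and EBV is `sqrt(r2)`.
#'
#' The prediction-error variance stays on the founder scale (sigma^2 = 1) in
#' every generation; it is not rescaled as genetic variance shrinks under the
#' Bulmer effect, so realized accuracy drifts slightly below `sqrt(r2)` at
#' equilibrium.
#'
#' @param tbv Numeric vector of true breeding values.
#' @param r2 Reliability in (0, 1].
#' @return Numeric vector of EBV, same length as `tbv`.
#' @export
simulate_ebv <- function(tbv, r2) {
  if (length(r2) != 1L || is.na(r2) || r2 <= 0 || r2 > 1)
    stop("reliability r2 must lie in (0, 1]", call. = FALSE)
  if (r2 == 1) return(tbv)
  pe <- rnorm(length(tbv), mean = 0, sd = sqrt((1 - r2) / r2))
  r2 * (tbv + pe)
}

#' Mendelian sampling variance given parental inbreeding
#'
#' Variance of the within-family deviation of offspring breeding values,
#' `0.5 * (1 - 0.5 * (F_sire + F_dam))` on the founder genetic-variance scale:
#' half the base additive variance for non-inbred parents, shrinking to zero
#' as parents approach complete inbreeding.
#'
#' @param f_sire,f_dam Parental inbreeding coefficients in \[0, 1\]
#'   (vectorized).
#' @return Nonnegative variance(s).
#' @examples
#' mendelian_sampling_variance(0, 0)      # 0.5
#' mendelian_sampling_variance(0.25, 0.25) # 0.375
#' @export
mendelian_sampling_variance <- function(f_sire, f_dam) {
  stopifnot(all(f_sire >= 0 & f_sire <= 1), all(f_dam >= 0 & f_dam <= 1))
  0.5 * (1 - 0.5 * (f_sire + f_dam))
}

# One transmitted allele per parent: a parent with g desired alleles passes
# the desired allele never (g=0), with probability 1/2 (g=1), always (g=2).
transmit_allele <- function(g_parent) {
  het <- g_parent == 1L
  out <- as.integer(g_parent == 2L)
  if (any(het)) out[het] <- rbinom(sum(het), 1L, 0.5)
  out
}

#' Produce offspring from mated parents
#'
#' Vectorized over matings (scalar inputs give one offspring). The offspring
#' true breeding value is the midparent average plus a Mendelian sampling
#' deviation with variance [mendelian_sampling_variance()] of the parental
#' inbreeding coefficients; the monogenic genotype is the sum of one allele
#' transmitted by each parent; sex is Bernoulli(0.5). The offspring inbreeding
#' coefficient `f_offspring` (half the additive relationship of the parents)
#' is supplied by the caller, normally from [offspring_inbreeding()].
#'
#' EBV are not attached here: in the zygote lifecycle editing and survival
#' come first, and [simulate_ebv()] is applied to survivors.
#'
#' Random draws per call, in order: Mendelian sampling deviations, sire
#' transmitted alleles, dam transmitted alleles, sexes.
#'
#' @param sire,dam Parent records: cohort rows (data.frames) or named lists
#'   of row-aligned vectors with fields `id`, `tbv`, `g`, `f`.
#' @param f_offspring Offspring inbreeding coefficient(s).
#' @param id Offspring id(s); must exceed all parent ids.
#' @param generation Generation index of the offspring.
#' @return A cohort data.frame of offspring with `ebv = NA`.
#' @export
make_offspring <- function(sire, dam, f_offspring, id, generation) {
  n <- max(length(sire$id), length(dam$id), length(f_offspring))
  msv <- mendelian_sampling_variance(sire$f, dam$f)
  ms <- rnorm(n, mean = 0, sd = sqrt(msv))
  tbv <- 0.5 * sire$tbv + 0.5 * dam$tbv + ms
  g <- transmit_allele(sire$g) + transmit_allele(dam$g)
  sex <- ifelse(rbinom(n, 1L, 0.5) == 1L, "M", "F")
  new_cohort(id = id, sire_id = sire$id, dam_id = dam$id,
             generation = generation, sex = sex, tbv = tbv,
             ebv = NA_real_, g = g, f = f_offspring,
             edited = FALSE, alive = TRUE)
}
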