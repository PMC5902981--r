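test_that("selection index is the stated linear merit", {
  expect_equal(compute_index(1.2, 0, 1, 0.5), 1.2)
  expect_equal(compute_index(1.2, 2, 1, 0.5), 2.2)
  expect_equal(compute_index(c(1, -1), c(0, 2), 1, 1000), c(1, 1999))
  # with b2 = 1000 any carrier outranks any non-carrier for |ebv| < 500
  ebv <- runif(50, -499, 499)
  expect_true(min(compute_index(ebv, 1, 1, 1000)) >
                max(compute_index(ebv, 0, 1, 1000)))
})

test_that("truncation selection matches a brute-force sort oracle", {
  set.seed(52)
  for (case in 1:20) {
    n <- sample(20:60, 1)
    b2 <- sample(c(0, 0.5, 1000), 1)
    # coarse EBV grid creates ties that exercise the id tie-break
    cohort <- make_cohort(id = seq_len(n),
                          sex = sample(c("M", "F"), n, replace = TRUE),
                          ebv = round(rnorm(n), 1),
                          g = sample(0:2, n, replace = TRUE))
    n_m <- sum(cohort$sex == "M")
    n_f <- sum(cohort$sex == "F")
    if (n_m < 2 || n_f < 2) next
    ns <- sample(n_m, 1)
    nd <- sample(n_f, 1)
    sel <- truncation_select(cohort, ns, nd, 1, b2)
    oracle <- function(sex, k) {
      sub <- cohort[cohort$sex == sex, ]
      idx <- 1 * sub$ebv + b2 * sub$g
      sub$id[order(-idx, sub$id)][seq_len(k)]
    }
    expect_identical(sel$sires$id, oracle("M", ns))
    expect_identical(sel$dams$id, oracle("F", nd))
    # truncation property: worst selected >= best non-selected, each sex
    idx <- compute_index(cohort$ebv, cohort$g, 1, b2)
    for (sx in c("M", "F")) {
      sel_ids <- if (sx == "M") sel$sires$id else sel$dams$id
      in_sel <- cohort$id %in% sel_ids
      rest <- idx[!in_sel & cohort$sex == sx]
      if (length(rest))
        expect_gte(min(idx[in_sel & cohort$sex == sx]), max(rest))
    }
  }
})

test_that("all-equal indices select the lowest ids deterministically", {
  cohort <- make_cohort(id = 1:6, sex = rep("M", 6), ebv = rep(1, 6),
                        g = rep(0L, 6))
  cohort <- rbind(cohort,
                  make_cohort(id = 7:8, sex = "F", ebv = 0, g = 0L))
  sel <- truncation_select(cohort, 3, 1)
  expect_identical(sel$sires$id, 1:3)
})

test_that("selection fails loudly when a sex has too few candidates", {
  cohort <- make_cohort(id = 1:10, sex = rep("M", 10), ebv = rnorm(10),
                        g = 0L)
  expect_error(truncation_select(cohort, 2, 1), "female")
  cohort$alive[1:9] <- FALSE
  expect_error(truncation_select(cohort, 2, 0 + 1), "male")
})

test_that("mate assignment is one mating per dam, sires uniform", {
  sires <- make_cohort(id = 1L, sex = "M", ebv = 0, g = 0L)
  dams <- make_cohort(id = 2:4, sex = "F", ebv = 0, g = 0L)
  set.seed(61)
  m <- assign_mates(sires, dams)
  expect_equal(nrow(m), 3L)
  expect_true(all(m$sire_id == 1L))

  # sire usage ~ multinomial(n_dams, uniform): chi-square goodness of fit
  sires <- make_cohort(id = 1:20, sex = "M", ebv = 0, g = 0L)
  dams <- make_cohort(id = 100 + 1:2000, sex = "F", ebv = 0, g = 0L)
  set.seed(62)
  m <- assign_mates(sires, dams)
  expect_equal(nrow(m), 2000L)
  usage <- tabulate(m$sire_row, 20L)
  chisq <- sum((usage - 100)^2 / 100)
  expect_lt(chisq, qchisq(0.999, df = 19))

  # balanced option: every sire gets exactly n_dams / n_sires matings
  set.seed(63)
  mb <- assign_mates(sires, dams, balanced = TRUE)
  expect_true(all(tabulate(mb$sire_row, 20L) == 100L))

  # parental allele counts and parent-average index carried on the mating
  sires <- make_cohort(id = 1L, sex = "M", ebv = 2, g = 1L)
  dams <- make_cohort(id = 2L, sex = "F", ebv = 0, g = 2L)
  m <- assign_mates(sires, dams, b1 = 1, b2 = 0.5)
  expect_equal(m$parental_g, 3L)
  expect_equal(m$parent_avg_index, 0.5 * ((2 + 0.5) + (0 + 1)))
})

test_that("produce_generation yields the designed cohort size and mortality", {
  spec <- tiny_spec()
  set.seed(71)
  founders <- init_founders(spec)
  sel <- truncation_select(founders, spec$n_sires, spec$n_dams)
  cache <- propagate_relationships(NULL, rbind(sel$sires, sel$dams))
  m <- assign_mates(sel$sires, sel$dams)
  f_off <- offspring_inbreeding(m$sire_id, m$dam_id, cache)

  res <- produce_generation(m, sel$sires, sel$dams, spec, 1L,
                            next_id = nrow(founders) + 1L, f_off)
  expect_equal(nrow(res$cohort), spec$n_dams * spec$n_off_per_mating)
  expect_true(all(res$cohort$alive))
  expect_equal(res$edit$n_subjected, 0L)
  expect_false(anyNA(res$cohort$ebv))

  # lethal editing: flagged families contribute no live offspring
  spec0 <- tiny_spec(use_editing = TRUE, edit_survival_s = 0,
                     edit_fraction = 0.5)
  plan <- select_matings_for_editing(m, spec0$edit_fraction)
  set.seed(72)
  res0 <- produce_generation(m, sel$sires, sel$dams, spec0, 1L,
                             next_id = nrow(founders) + 1L, f_off, plan)
  dead_fams <- unique((which(!res0$cohort$alive) - 1L) %/%
                        spec0$n_off_per_mating + 1L)
  expect_setequal(dead_fams, plan$flagged)
  alive_per_flagged <- vapply(plan$flagged, function(i) {
    sum(res0$cohort$alive[(i - 1L) * spec0$n_off_per_mating +
                            seq_len(spec0$n_off_per_mating)])
  }, integer(1))
  expect_true(all(alive_per_flagged == 0L))
  expect_true(all(is.na(res0$cohort$ebv[!res0$cohort$alive])))

  # full survival leaves the cohort size unchanged by editing
  spec1 <- tiny_spec(use_editing = TRUE, edit_survival_s = 1,
                     edit_fraction = 0.5)
  set.seed(73)
  res1 <- produce_generation(m, sel$sires, sel$dams, spec1, 1L,
                             next_id = nrow(founders) + 1L, f_off, plan)
  expect_true(all(res1$cohort$alive))
})
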