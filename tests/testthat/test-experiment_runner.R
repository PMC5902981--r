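test_that("fixation detection scans the frequency trajectory", {
  expect_equal(time_to_fixation(c(0.01, 0.4, 1.0)), 2L)
  expect_true(is.na(time_to_fixation(c(0.01, 0.4, 0.99))))
  expect_equal(time_to_fixation(c(0.5, 1.0, 1.0), generation = 4:6), 5L)
})

test_that("loss metrics reproduce the months/sigma arithmetic", {
  expect_equal(loss_in_months(1, 1, 1.13, 24), 0)
  expect_equal(loss_in_months(-0.560 + 5, 5, 1.13, 24), -11.89381,
               tolerance = 1e-6)
  expect_error(loss_in_months(1, 0, 0), "equilibrium_response")

  expect_equal(loss_in_sd(0, 0.73), 0)
  expect_equal(loss_in_sd(-0.560, 0.73), -0.7671233, tolerance = 1e-6)
  expect_equal(loss_in_sd(-0.419, 0.73), -0.5739726, tolerance = 1e-6)
  expect_error(loss_in_sd(1, 0))
})

test_that("breakeven cost follows the linear cost-benefit identity", {
  expect_equal(breakeven_cost(58.5, 20000, 5, 10, 10000), 58.5)
  # serving a 1M-cow population instead of the nucleus
  expect_equal(breakeven_cost(58.5, 1e6, 5, 10, 10000), 2925)
  expect_equal(breakeven_cost(0, 20000, 5, 10, 10000), 0)
  expect_error(breakeven_cost(58.5, 20000, 5, 10, 0), "positive")
})

test_that("replicates are bit-reproducible given (spec, seed)", {
  spec <- tiny_spec(b2 = 0.5, use_editing = TRUE, edit_survival_s = 0.5)
  r1 <- run_replicate(spec, 7)
  r2 <- run_replicate(spec, 7)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$fixation_generation, r2$fixation_generation)
  r3 <- run_replicate(spec, 8)
  expect_false(identical(r1$stats, r3$stats))
})

test_that("experiment aggregation averages replicate trajectories", {
  spec <- tiny_spec(b2 = 0.5)
  ex <- run_experiment(spec, n_reps = 3, base_seed = 200)
  expect_equal(sort(unique(ex$stats$replicate)), 1:3)
  expect_equal(nrow(ex$summary),
               spec$n_burnin_generations + spec$n_selection_generations + 1L)
  # single replicate: the aggregate equals that replicate's trajectory
  one <- run_experiment(spec, n_reps = 1, base_seed = 200)
  r1 <- run_replicate(spec, 201)
  expect_equal(one$summary$mean_freq, r1$stats$freq)
  expect_equal(one$summary$mean_mean_tbv, r1$stats$mean_tbv)
  # fixation-time averaging excludes allele-lost replicates only
  fix <- ex$fixation_generations
  expect_equal(ex$mean_fixation, mean(fix[!is.na(fix)]))
  expect_equal(ex$lost_fraction, ex$n_lost / 3)
})

test_that("cumulative benefit counts desired phenotypes over the horizon", {
  # fixed founder population: every animal shows the desired phenotype
  ex <- run_experiment(tiny_spec(founder_allele_freq = 1), n_reps = 2,
                       base_seed = 300)
  expect_equal(cumulative_benefit(ex, "dominant", 5), 100)
  expect_equal(cumulative_benefit(ex, "recessive", 5), 100)

  # identity: (100 - benefit%) x animals born = undesired animals
  spec <- tiny_spec(b2 = 0.5)
  ex2 <- run_experiment(spec, n_reps = 2, base_seed = 301)
  st <- ex2$stats[ex2$stats$generation >= 1, ]
  undesired <- tapply(st$n - st$n_dominant, st$replicate, sum)
  born <- tapply(st$n, st$replicate, sum)
  expect_equal((100 - cumulative_benefit(ex2, "dominant", 5)) / 100,
               mean(undesired / born))
})

test_that("scenario summary compares against the baseline at both horizons", {
  spec <- tiny_spec(b2 = 0.5, use_editing = TRUE)
  base <- run_experiment(tiny_spec(b2 = 0), n_reps = 3, base_seed = 400)
  ex <- run_experiment(spec, n_reps = 3, base_seed = 400)
  tab <- scenario_summary(ex, base, horizons = c(2L, 5L))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$horizon, c(2L, 5L))
  expect_equal(tab$months,
               tab$delta_tbv / equilibrium_response(base) * 24)
  expect_equal(tab$sd_loss, tab$delta_tbv / equilibrium_variance(base))
  expect_equal(tab$sd_loss_sqrt,
               tab$delta_tbv / sqrt(equilibrium_variance(base)))
  # a scenario compared with itself shows zero loss
  self <- scenario_summary(base, base, horizons = 5L)
  expect_equal(self$delta_tbv, 0)
  expect_equal(self$months, 0)
})

test_that("reports are written as documented CSV files", {
  out <- file.path(tempdir(), "edsim-report-test")
  unlink(out, recursive = TRUE)
  base <- run_experiment(tiny_spec(b2 = 0), n_reps = 2, base_seed = 500)
  ex <- run_experiment(tiny_spec(b2 = 0.5, use_editing = TRUE,
                                 name = "demo"),
                       n_reps = 2, base_seed = 500)
  paths <- write_report(ex, out, baseline = base, horizons = c(2L, 5L))
  expect_true(all(file.exists(file.path(out, c("demo_generations.csv",
                                               "demo_replicates.csv",
                                               "demo_spec.yml",
                                               "summary.csv")))))
  summ <- read.csv(file.path(out, "summary.csv"))
  expect_equal(nrow(summ), 2L)
  expect_true(all(c("months", "procedures", "benefit_dominant",
                    "mean_fixation", "lost_fraction") %in% names(summ)))
  # deterministic overwrite
  before <- readLines(file.path(out, "summary.csv"))
  write_report(ex, out, baseline = base, horizons = c(2L, 5L))
  expect_identical(readLines(file.path(out, "summary.csv")), before)
  # round-trip of the spec written next to the report
  expect_equal(load_spec(file.path(out, "demo_spec.yml")), ex$spec)
  unlink(out, recursive = TRUE)
})

test_that("command-line wrapper runs a scenario end to end", {
  cli <- system.file("cli", "edsim.R", package = "edsim")
  expect_true(nzchar(cli))
  cfg <- tempfile(fileext = ".yml")
  write_spec(tiny_spec(b2 = 0.5, use_editing = TRUE, name = "cli_demo"), cfg)
  out <- file.path(tempdir(), "edsim-cli-test")
  unlink(out, recursive = TRUE)
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript,
                    c(cli, "run", "--config", shQuote(cfg),
                      "--replicates", "2", "--seed", "600",
                      "--out", shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "cli_demo_generations.csv")))
  unlink(out, recursive = TRUE)
  unlink(cfg)
})
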