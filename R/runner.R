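#' Run one replicate of a breeding-program scenario
#'
#' Simulates the full program: founders at generation
#' `-n_burnin_generations`, a burn-in phase of truncation selection on EBV
#' alone (bringing genetic variance and response to their Bulmer
#' equilibrium at generation 0), then `n_selection_generations` of index
#' selection with optional zygote genome editing. Runs are bit-reproducible
#' for a given `(spec, seed)`.
#'
#' Random draws per generation, in order: sire-to-dam assignment, Mendelian
#' sampling deviations, sire transmitted alleles, dam transmitted alleles,
#' sexes, editing conversions, editing survival, prediction errors of the
#' survivors' EBV.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed for this replicate.
#' @param keep_pedigree Keep the full 3-column pedigree (id, sire, dam) of
#'   every animal ever born, for audit or [export_pedigree()].
#' @return Object of class `replicate_result`: `stats` (one row per
#'   generation, see [generation_stats()]), `fixation_generation` (`NA` if
#'   the desired allele never fixes), `allele_lost` (frequency hit zero at
#'   some generation), `cum_procedures`, `cum_procedures_to_fixation`,
#'   `seed`, and optionally `pedigree`.
#' @export
run_replicate <- function(spec, seed, keep_pedigree = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(as.integer(seed))
  cohort <- init_founders(spec)
  next_id <- nrow(cohort) + 1L
  n_gen <- spec$n_burnin_generations + spec$n_selection_generations
  stats <- vector("list", n_gen + 1L)
  stats[[1L]] <- generation_stats(cohort)
  ped <- if (keep_pedigree)
    list(cohort[, c("id", "sire_id", "dam_id")]) else NULL
  cache <- NULL

  gens <- seq(-spec$n_burnin_generations + 1L, spec$n_selection_generations)
  for (i in seq_along(gens)) {
    gen <- gens[i]
    phase2 <- gen >= 1L
    b2 <- if (phase2) spec$b2 else 0
    sel <- truncation_select(cohort, spec$n_sires, spec$n_dams, spec$b1, b2)
    parents <- rbind(sel$sires, sel$dams)
    cache <- propagate_relationships(cache, parents)
    matings <- assign_mates(sel$sires, sel$dams, spec$b1, b2,
                            balanced = spec$balanced_mating)
    f_off <- offspring_inbreeding(matings$sire_id, matings$dam_id, cache)
    plan <- if (phase2 && spec$use_editing)
      select_matings_for_editing(matings, spec$edit_fraction) else NULL
    res <- produce_generation(matings, sel$sires, sel$dams, spec, gen,
                              next_id, f_off, plan)
    cohort <- res$cohort
    next_id <- next_id + nrow(cohort)
    stats[[i + 1L]] <- generation_stats(cohort, stats[[i]], res$edit)
    if (keep_pedigree)
      ped[[i + 1L]] <- cohort[, c("id", "sire_id", "dam_id")]
  }

  stats <- do.call(rbind, stats)
  fix_gen <- time_to_fixation(stats$freq, stats$generation)
  cum_proc <- sum(stats$n_subjected)
  cum_to_fix <- if (is.na(fix_gen)) cum_proc
                else sum(stats$n_subjected[stats$generation <= fix_gen])
  structure(list(
    spec = spec,
    seed = as.integer(seed),
    stats = stats,
    fixation_generation = fix_gen,
    allele_lost = any(stats$freq == 0),
    cum_procedures = cum_proc,
    cum_procedures_to_fixation = cum_to_fix,
    pedigree = if (keep_pedigree) do.call(rbind, ped) else NULL
  ), class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  cat("<replicate_result> seed", x$seed, "\n")
  cat(sprintf("  fixation: %s; allele lost: %s; procedures: %d\n",
              ifelse(is.na(x$fixation_generation), "never",
                     paste("generation", x$fixation_generation)),
              x$allele_lost, x$cum_procedures))
  invisible(x)
}

#' Run a replicated scenario experiment
#'
#' Runs `n_reps` independent replicates (replicate `i` is seeded with
#' `base_seed + i`) and aggregates their trajectories: per-generation
#' replicate means and standard errors of every statistic, mean time to
#' fixation over the replicates in which the desired allele was not lost to
#' drift, the allele-lost fraction, and mean cumulative editing procedures.
#'
#' @param spec A [scenario_spec()].
#' @param n_reps Number of replicates (default `spec$n_replicates`).
#' @param base_seed Base seed (default `spec$base_seed`).
#' @return Object of class `edsim_experiment`: `spec`, `stats` (long
#'   data.frame, one row per replicate x generation), `summary`
#'   (per-generation means and standard errors), `fixation_generations`,
#'   `mean_fixation`, `n_lost`, `lost_fraction`, `mean_cum_procedures`,
#'   `mean_cum_procedures_to_fixation`.
#' @export
run_experiment <- function(spec, n_reps = spec$n_replicates,
                           base_seed = spec$base_seed) {
  stopifnot(n_reps >= 1L)
  reps <- lapply(seq_len(n_reps), function(i) {
    r <- run_replicate(spec, base_seed + i)
    r$stats$replicate <- i
    r
  })
  stats <- do.call(rbind, lapply(reps, `[[`, "stats"))
  fix <- vapply(reps, `[[`, integer(1), "fixation_generation")
  lost <- vapply(reps, `[[`, logical(1), "allele_lost")
  structure(list(
    spec = spec,
    n_reps = n_reps,
    base_seed = as.integer(base_seed),
    stats = stats,
    summary = summarize_generations(stats),
    fixation_generations = fix,
    mean_fixation = if (all(is.na(fix))) NA_real_
                    else mean(fix[!is.na(fix)]),
    n_lost = sum(lost),
    lost_fraction = mean(lost),
    mean_cum_procedures =
      mean(vapply(reps, `[[`, numeric(1), "cum_procedures")),
    mean_cum_procedures_to_fixation =
      mean(vapply(reps, `[[`, numeric(1), "cum_procedures_to_fixation"))
  ), class = "edsim_experiment")
}

# Replicate means and standard errors of every statistic, by generation.
summarize_generations <- function(stats) {
  fields <- setdiff(names(stats), c("generation", "replicate", "fixed"))
  gens <- sort(unique(stats$generation))
  out <- data.frame(generation = gens)
  for (f in fields) {
    m <- tapply(stats[[f]], stats$generation, mean)
    s <- tapply(stats[[f]], stats$generation, stats_se)
    out[[paste0("mean_", f)]] <- as.numeric(m[as.character(gens)])
    out[[paste0("se_", f)]] <- as.numeric(s[as.character(gens)])
  }
  out
}

stats_se <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' @export
print.edsim_experiment <- function(x, ...) {
  nm <- if (!is.na(x$spec$name)) x$spec$name else "scenario"
  cat("<edsim_experiment>", nm, "-", x$n_reps, "replicates\n")
  cat(sprintf("  mean fixation: %s; allele lost in %d/%d replicates\n",
              ifelse(is.na(x$mean_fixation), "never",
                     sprintf("generation %.1f", x$mean_fixation)),
              x$n_lost, x$n_reps))
  cat(sprintf("  equilibrium (gen 0): response %.3f, genetic variance %.3f\n",
              equilibrium_response(x), equilibrium_variance(x)))
  if (x$mean_cum_procedures > 0)
    cat(sprintf("  mean editing procedures: %.0f (%.0f to fixation)\n",
                x$mean_cum_procedures, x$mean_cum_procedures_to_fixation))
  invisible(x)
}

#' Equilibrium response and genetic variance at generation 0
#'
#' The equilibrium per-generation selection response is the replicate mean of
#' the change in mean TBV from generation -1 to generation 0, at the end of
#' the burn-in phase; the equilibrium genetic variance is the replicate mean
#' of the TBV variance among the generation-0 candidates. Both serve as the
#' denominators of the loss metrics.
#'
#' @param experiment An `edsim_experiment`.
#' @return A scalar.
#' @export
equilibrium_response <- function(experiment) {
  s <- experiment$summary
  s$mean_response[s$generation == 0L]
}

#' @rdname equilibrium_response
#' @export
equilibrium_variance <- function(experiment) {
  s <- experiment$summary
  s$mean_var_tbv[s$generation == 0L]
}

#' First generation at which the desired allele is fixed
#'
#' @param freq Vector of cohort desired-allele frequencies.
#' @param generation Matching generation indices (defaults to
#'   `seq_along(freq) - 1`).
#' @return The first generation with frequency 1, or `NA_integer_`.
#' @examples
#' time_to_fixation(c(0.01, 0.4, 1.0)) # 2
#' @export
time_to_fixation <- function(freq, generation = seq_along(freq) - 1L) {
  hit <- which(freq == 1)
  if (length(hit) == 0L) NA_integer_ else as.integer(generation[hit[1L]])
}

#' Loss in selection response expressed in months
#'
#' Converts a difference in mean TBV between a scenario and the baseline at
#' the same generation into months of genetic progress:
#' `(scenario - baseline) / equilibrium_response * interval_months`.
#' Negative values are losses.
#'
#' @param mean_tbv_scenario,mean_tbv_baseline Mean TBV at the comparison
#'   generation.
#' @param equilibrium_response Baseline per-generation response at
#'   generation 0 (must be positive).
#' @param interval_months Generation interval (default 24).
#' @return Months of progress gained (positive) or lost (negative).
#' @export
loss_in_months <- function(mean_tbv_scenario, mean_tbv_baseline,
                           equilibrium_response, interval_months = 24) {
  stopifnot(equilibrium_response > 0)
  (mean_tbv_scenario - mean_tbv_baseline) / equilibrium_response *
    interval_months
}

#' Loss in selection response in genetic standard deviations
#'
#' Divides a TBV difference by the equilibrium dispersion estimated at
#' generation 0. [scenario_summary()] divides by the equilibrium genetic
#' variance itself (about 0.73 at the defaults), the convention under which
#' its months and sigma columns stay mutually consistent; the square-root
#' convention is available by passing
#' `sqrt(equilibrium_variance(baseline))` as the divisor.
#'
#' @param delta_tbv TBV difference (scenario minus baseline).
#' @param sd_divisor Positive divisor.
#' @return `delta_tbv / sd_divisor`.
#' @export
loss_in_sd <- function(delta_tbv, sd_divisor) {
  stopifnot(sd_divisor > 0)
  delta_tbv / sd_divisor
}

#' Cumulative percentage of animals with the desired phenotype
#'
#' Over all animals born in generations 1 to `horizon`, the percentage
#' showing the desired phenotype: carriers (`g >= 1`) under dominant gene
#' action, homozygotes (`g = 2`) under recessive gene action. Computed per
#' replicate and averaged.
#'
#' @param experiment An `edsim_experiment`.
#' @param gene_action `"dominant"` or `"recessive"`.
#' @param horizon Last generation included.
#' @return Percentage in \[0, 100\].
#' @export
cumulative_benefit <- function(experiment,
                               gene_action = c("dominant", "recessive"),
                               horizon = experiment$spec$n_selection_generations) {
  gene_action <- match.arg(gene_action)
  st <- experiment$stats
  st <- st[st$generation >= 1L & st$generation <= horizon, , drop = FALSE]
  cnt <- if (gene_action == "dominant") st$n_dominant else st$n_recessive
  per_rep <- tapply(cnt, st$replicate, sum) / tapply(st$n, st$replicate, sum)
  100 * mean(per_rep)
}

#' Cumulative editing procedures up to a horizon
#'
#' Replicate-mean total number of zygotes subjected to editing in
#' generations 1 to `horizon`.
#'
#' @inheritParams cumulative_benefit
#' @return Mean number of procedures.
#' @export
cumulative_procedures <- function(experiment,
                                  horizon = experiment$spec$n_selection_generations) {
  st <- experiment$stats
  st <- st[st$generation >= 1L & st$generation <= horizon, , drop = FALSE]
  mean(tapply(st$n_subjected, st$replicate, sum))
}

#' Breakeven editing cost per zygote
#'
#' The editing cost per zygote at which the saved per-animal cost of the
#' undesired phenotype (e.g. dehorning) exactly pays for the editing
#' procedures:
#' `(extra_desired_pct/100 * population_per_generation * horizon * unit_cost)
#'  / total_procedures`.
#'
#' @param extra_desired_pct Extra percentage of desired-phenotype animals of
#'   the editing scenario over the baseline (percentage points).
#' @param population_per_generation Animals born per generation in the served
#'   population.
#' @param horizon Number of generations evaluated.
#' @param unit_cost Cost saved per desired-phenotype animal.
#' @param total_procedures Total zygotes subjected to editing (> 0).
#' @return Currency per zygote.
#' @examples
#' breakeven_cost(58.5, 20000, 5, 10, 10000) # 58.5
#' @export
breakeven_cost <- function(extra_desired_pct, population_per_generation,
                           horizon, unit_cost, total_procedures) {
  if (total_procedures <= 0)
    stop("total_procedures must be positive", call. = FALSE)
  (extra_desired_pct / 100) * population_per_generation * horizon *
    unit_cost / total_procedures
}

#' Scenario summary against a baseline
#'
#' Builds the standard comparison table of a scenario versus the baseline
#' program (genomic selection with zero weight on the monogenic trait), at
#' one or more horizons: TBV difference, its conversion to months
#' ([loss_in_months()]) and to genetic standard deviations ([loss_in_sd()],
#' both divisor conventions), desired-allele frequency, mean inbreeding,
#' cumulative editing procedures, and cumulative desired-phenotype
#' percentages under dominant and recessive gene action. The equilibrium
#' response and variance are estimated from the baseline experiment at
#' generation 0.
#'
#' @param experiment Scenario `edsim_experiment`.
#' @param baseline Baseline `edsim_experiment` (may be the same object).
#' @param horizons Generations at which to compare.
#' @return Data.frame with one row per horizon.
#' @export
scenario_summary <- function(experiment, baseline, horizons = c(5L, 20L)) {
  r_eq <- equilibrium_response(baseline)
  v_eq <- equilibrium_variance(baseline)
  interval <- experiment$spec$generation_interval_months
  nm <- if (!is.na(experiment$spec$name)) experiment$spec$name else "scenario"
  rows <- lapply(horizons, function(h) {
    s <- experiment$summary
    b <- baseline$summary
    tbv_s <- s$mean_mean_tbv[s$generation == h]
    tbv_b <- b$mean_mean_tbv[b$generation == h]
    delta <- tbv_s - tbv_b
    data.frame(
      scenario = nm,
      horizon = h,
      delta_tbv = delta,
      sd_loss = loss_in_sd(delta, v_eq),
      sd_loss_sqrt = loss_in_sd(delta, sqrt(v_eq)),
      months = loss_in_months(tbv_s, tbv_b, r_eq, interval),
      freq = s$mean_freq[s$generation == h],
      mean_f = s$mean_mean_f[s$generation == h],
      procedures = cumulative_procedures(experiment, h),
      benefit_dominant = cumulative_benefit(experiment, "dominant", h),
      benefit_recessive = cumulative_benefit(experiment, "recessive", h)
    )
  })
  do.call(rbind, rows)
}

#' Write experiment reports to CSV
#'
#' Writes, for each experiment, a per-generation summary CSV
#' (`<name>_generations.csv`), a per-replicate long CSV
#' (`<name>_replicates.csv`) and the scenario file (`<name>_spec.yml`);
#' if a baseline is supplied, also a scenario-comparison table
#' (`summary.csv`) built with [scenario_summary()]. Re-running with the same
#' inputs overwrites the same files.
#'
#' @param experiments An `edsim_experiment` or list of them.
#' @param out_dir Output directory (created if missing).
#' @param baseline Optional baseline `edsim_experiment` for `summary.csv`.
#' @param horizons Horizons passed to [scenario_summary()].
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(experiments, out_dir, baseline = NULL,
                         horizons = c(5L, 20L)) {
  if (inherits(experiments, "edsim_experiment"))
    experiments <- list(experiments)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  for (i in seq_along(experiments)) {
    ex <- experiments[[i]]
    nm <- if (!is.na(ex$spec$name)) ex$spec$name else paste0("scenario", i)
    paths <- c(paths,
               wr(ex$summary, paste0(nm, "_generations.csv")),
               wr(ex$stats, paste0(nm, "_replicates.csv")))
    sp <- file.path(out_dir, paste0(nm, "_spec.yml"))
    write_spec(ex$spec, sp)
    paths <- c(paths, sp)
  }
  if (!is.null(baseline)) {
    tab <- do.call(rbind, lapply(experiments, scenario_summary,
                                 baseline = baseline, horizons = horizons))
    extra <- data.frame(
      mean_fixation = vapply(experiments, `[[`, numeric(1), "mean_fixation"),
      lost_fraction = vapply(experiments, `[[`, numeric(1), "lost_fraction")
    )
    tab <- cbind(tab,
                 extra[rep(seq_along(experiments), each = length(horizons)), ,
                       drop = FALSE])
    rownames(tab) <- NULL
    paths <- c(paths, wr(tab, "summary.csv"))
  }
  invisible(paths)
}
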