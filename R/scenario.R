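#' Define a breeding-program scenario
#'
#' A scenario fully parameterizes one simulated breeding program: the mating
#' design (numbers of sires, dams and offspring per mating), the reliability of
#' the pseudo-genomic evaluation, the selection-index weight on the monogenic
#' genotype, and the genome-editing regime (fraction of matings targeted,
#' per-allele editing success `k`, per-zygote survival `s`).
#'
#' The default values reproduce the main design: 100 sires and 2000 dams per
#' discrete generation, 10 offspring per mating (20,000 selection candidates),
#' EBV reliability r-squared of 0.5, a desired-allele starting frequency of
#' 0.01, five burn-in generations of selection on EBV alone followed by 20
#' generations of index selection, and editing (when enabled) of the zygotes of
#' 10\% of the matings with `k = s = 1`.
#'
#' @param n_sires Number of male parents selected per generation.
#' @param n_dams Number of female parents selected per generation; each dam is
#'   mated once.
#' @param n_off_per_mating Zygotes produced per mating.
#' @param reliability_r2 Reliability (squared accuracy) of the pseudo-EBV, in
#'   (0, 1].
#' @param b1 Index weight on the EBV (conventionally fixed at 1).
#' @param b2 Index weight on the count of desired alleles `G`; 0 ignores the
#'   monogenic trait, 0.5 gives it moderate emphasis, 1000 makes it dominate
#'   the index for any realistic EBV.
#' @param use_editing Apply genome editing to zygotes of targeted matings in
#'   the index-selection phase?
#' @param edit_fraction Fraction of matings whose zygotes may be edited per
#'   generation (number of targeted matings = `round(edit_fraction * n_dams)`).
#' @param edit_success_k Per-allele probability that an undesired allele is
#'   converted to the desired allele.
#' @param edit_survival_s Per-zygote probability of surviving the editing
#'   procedure.
#' @param founder_allele_freq Founder frequency of the desired allele; founder
#'   genotypes are drawn from Hardy-Weinberg proportions.
#' @param n_burnin_generations Generations of selection on EBV alone before
#'   generation 0 (founders sit at generation `-n_burnin_generations`).
#' @param n_selection_generations Generations of index selection after
#'   generation 0.
#' @param n_replicates Default number of Monte Carlo replicates.
#' @param base_seed Default base seed; replicate `i` runs with
#'   `base_seed + i`.
#' @param generation_interval_months Generation interval used to express losses
#'   in selection response in months.
#' @param dehorn_cost Cost saved per animal born with the desired phenotype
#'   (cost-benefit analysis only).
#' @param balanced_mating If `TRUE`, dams are divided evenly among sires
#'   instead of drawing a sire per dam uniformly with replacement (sensitivity
#'   switch; the default follows random assignment).
#' @param edit_carriers_only Editing eligibility is decided at the family
#'   level: a mating is eligible when its parents jointly carry at least one
#'   undesired allele. By default every zygote of a targeted mating is then
#'   subjected to (counted as, and put at survival risk by) the editing
#'   procedure, including zygotes already homozygous for the desired allele.
#'   Set to `TRUE` to subject only carrier zygotes (`g < 2`) within targeted
#'   matings (sensitivity switch; lowers late-generation procedure counts).
#' @param name Optional scenario label carried into reports.
#'
#' @return An object of class `scenario_spec` (a validated named list).
#' @seealso [builtin_scenarios()], [load_spec()], [run_experiment()]
#' @examples
#' spec <- scenario_spec(b2 = 0.5, use_editing = TRUE)
#' spec$edit_success_k
#' @export
scenario_spec <- function(n_sires = 100L,
                          n_dams = 2000L,
                          n_off_per_mating = 10L,
                          reliability_r2 = 0.5,
                          b1 = 1,
                          b2 = 0,
                          use_editing = FALSE,
                          edit_fraction = 0.10,
                          edit_success_k = 1.0,
                          edit_survival_s = 1.0,
                          founder_allele_freq = 0.01,
                          n_burnin_generations = 5L,
                          n_selection_generations = 20L,
                          n_replicates = 50L,
                          base_seed = 20180416L,
                          generation_interval_months = 24,
                          dehorn_cost = 10,
                          balanced_mating = FALSE,
                          edit_carriers_only = FALSE,
                          name = NULL) {
  spec <- list(
    n_sires = as.integer(n_sires),
    n_dams = as.integer(n_dams),
    n_off_per_mating = as.integer(n_off_per_mating),
    reliability_r2 = as.numeric(reliability_r2),
    b1 = as.numeric(b1),
    b2 = as.numeric(b2),
    use_editing = isTRUE(use_editing),
    edit_fraction = as.numeric(edit_fraction),
    edit_success_k = as.numeric(edit_success_k),
    edit_survival_s = as.numeric(edit_survival_s),
    founder_allele_freq = as.numeric(founder_allele_freq),
    n_burnin_generations = as.integer(n_burnin_generations),
    n_selection_generations = as.integer(n_selection_generations),
    n_replicates = as.integer(n_replicates),
    base_seed = as.integer(base_seed),
    generation_interval_months = as.numeric(generation_interval_months),
    dehorn_cost = as.numeric(dehorn_cost),
    balanced_mating = isTRUE(balanced_mating),
    edit_carriers_only = isTRUE(edit_carriers_only),
    name = if (is.null(name)) NA_character_ else as.character(name)
  )
  class(spec) <- "scenario_spec"
  validate_spec(spec)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", if (!is.na(x$name)) x$name else "", "\n")
  cat(sprintf("  design: %d sires x %d dams x %d offspring (%d candidates)\n",
              x$n_sires, x$n_dams, x$n_off_per_mating,
              x$n_dams * x$n_off_per_mating))
  cat(sprintf("  index: I = %g EBV + %g G (r2 = %g)\n", x$b1, x$b2,
              x$reliability_r2))
  if (x$use_editing) {
    cat(sprintf("  editing: %g%% of matings, k = %g, s = %g\n",
                100 * x$edit_fraction, x$edit_success_k, x$edit_survival_s))
  } else {
    cat("  editing: none\n")
  }
  cat(sprintf("  generations: %d burn-in + %d selection; p0 = %g\n",
              x$n_burnin_generations, x$n_selection_generations,
              x$founder_allele_freq))
  invisible(x)
}

# Field-by-field range checks; also enforces that selection is feasible in
# expectation (enough candidates to supply both parent sexes).
validate_spec <- function(spec) {
  stop_bad <- function(field, msg) {
    stop(sprintf("invalid scenario field `%s`: %s", field, msg), call. = FALSE)
  }
  chk_count <- function(field, min = 1L) {
    v <- spec[[field]]
    if (length(v) != 1L || is.na(v) || v < min)
      stop_bad(field, sprintf("must be a single integer >= %d", min))
  }
  chk_prob <- function(field) {
    v <- spec[[field]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_bad(field, "must be a probability in [0, 1]")
  }
  for (f in c("n_sires", "n_dams", "n_off_per_mating",
              "n_selection_generations", "n_replicates")) chk_count(f)
  chk_count("n_burnin_generations", min = 0L)
  for (f in c("edit_fraction", "edit_success_k", "edit_survival_s",
              "founder_allele_freq")) chk_prob(f)
  if (is.na(spec$reliability_r2) || spec$reliability_r2 <= 0 ||
      spec$reliability_r2 > 1)
    stop_bad("reliability_r2", "must lie in (0, 1]")
  if (is.na(spec$b2) || spec$b2 < 0)
    stop_bad("b2", "must be a nonnegative index weight")
  if (is.na(spec$b1)) stop_bad("b1", "must be numeric")
  if (spec$n_sires + spec$n_dams > spec$n_dams * spec$n_off_per_mating)
    stop_bad("n_sires",
             "n_sires + n_dams must not exceed n_dams * n_off_per_mating")
  if (spec$generation_interval_months <= 0)
    stop_bad("generation_interval_months", "must be positive")
  spec
}

# Fields settable from a config file or CLI flags.
spec_fields <- function() {
  setdiff(names(formals(scenario_spec)), "name")
}

#' Load a scenario from a flat key-value (YAML) file
#'
#' Reads a flat YAML file whose keys are [scenario_spec()] argument names,
#' fills unstated fields with the main-scenario defaults, and validates the
#' result. Unknown keys are rejected rather than ignored so that typos cannot
#' silently fall back to defaults. `overrides` (e.g. parsed CLI flags) take
#' precedence over file values.
#'
#' @param path Path to a YAML file; `NULL` uses defaults only.
#' @param overrides Named list of field overrides applied after the file.
#' @return A validated [scenario_spec()].
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("b2: 0.5", "use_editing: true"), f)
#' load_spec(f)$b2
#' @export
load_spec <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("scenario file not found: ", path)
    vals <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("cannot parse scenario file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
    if (is.null(vals)) vals <- list()
    if (!is.list(vals) || (length(vals) && is.null(names(vals))))
      stop("scenario file must contain key: value pairs", call. = FALSE)
  }
  if (length(overrides)) vals[names(overrides)] <- overrides
  allowed <- c(spec_fields(), "name")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(scenario_spec, vals)
}

#' Write a scenario to a flat YAML file
#'
#' Inverse of [load_spec()]: `load_spec(write_spec(spec, path))` reproduces
#' `spec` exactly.
#'
#' @param spec A [scenario_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  vals <- unclass(spec)
  if (is.na(vals$name)) vals$name <- NULL
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Built-in scenario grid
#'
#' Returns the named scenarios evaluated in the package: the main design under
#' genomic selection alone (`main_gs_*`) and with genome editing
#' (`main_gs_ge_*`) for index weights b2 of 0, 0.5 and 1000; sweeps of the
#' editing success probability `k` and the survival probability `s` at
#' b2 = 0.5 (`gs_ge_k*`, `gs_ge_s*`); the low-efficiency combination
#' `low_efficiency` (k = 0.2, s = 0.2, about one live fully edited offspring
#' per 25 subjected zygotes); and four species-sized designs (`cattle`,
#' `pig`, `fish`, `small`) that keep every other parameter at the main
#' defaults.
#'
#' @return Named list of [scenario_spec()] objects.
#' @examples
#' names(builtin_scenarios())
#' builtin_scenarios()[["pig"]]$n_off_per_mating
#' @export
builtin_scenarios <- function() {
  mk <- function(name, ...) scenario_spec(name = name, ...)
  out <- list(
    main_gs_b0      = mk("main_gs_b0", b2 = 0),
    main_gs_b05     = mk("main_gs_b05", b2 = 0.5),
    main_gs_b1000   = mk("main_gs_b1000", b2 = 1000),
    main_gs_ge_b0   = mk("main_gs_ge_b0", b2 = 0, use_editing = TRUE),
    main_gs_ge_b05  = mk("main_gs_ge_b05", b2 = 0.5, use_editing = TRUE),
    main_gs_ge_b1000 = mk("main_gs_ge_b1000", b2 = 1000, use_editing = TRUE)
  )
  for (k in c(1.0, 0.8, 0.6, 0.4, 0.2, 0.1)) {
    nm <- sprintf("gs_ge_k%02d", round(100 * k))
    out[[nm]] <- mk(nm, b2 = 0.5, use_editing = TRUE, edit_success_k = k)
  }
  for (s in c(1.0, 0.8, 0.6, 0.4, 0.2, 0.05)) {
    nm <- sprintf("gs_ge_s%02d", round(100 * s))
    out[[nm]] <- mk(nm, b2 = 0.5, use_editing = TRUE, edit_survival_s = s)
  }
  out$low_efficiency <- mk("low_efficiency", b2 = 0.5, use_editing = TRUE,
                           edit_success_k = 0.2, edit_survival_s = 0.2)
  out$cattle <- mk("cattle", n_sires = 200L, n_dams = 600L,
                   n_off_per_mating = 16L)
  out$pig  <- mk("pig", n_sires = 50L, n_dams = 2000L, n_off_per_mating = 20L)
  out$fish <- mk("fish", n_sires = 120L, n_dams = 240L,
                 n_off_per_mating = 40L)
  out$small <- mk("small", n_sires = 20L, n_dams = 240L,
                  n_off_per_mating = 70L)
  out
}
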