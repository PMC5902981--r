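#' Selection index combining polygenic EBV and monogenic genotype
#'
#' `I = b1 * ebv + b2 * g`. With `b2 = 0` this is genomic selection on the
#' polygenic trait alone; with a very large `b2` (1000 in the built-in
#' scenarios) the desired-allele count dominates the ranking for any
#' realistic EBV.
#'
#' @param ebv Numeric vector of (pseudo-)EBV.
#' @param g Desired-allele counts in 0/1/2.
#' @param b1,b2 Index weights.
#' @return Numeric index values.
#' @export
compute_index <- function(ebv, g, b1 = 1, b2 = 0) {
  b1 * ebv + b2 * g
}

#' Truncation selection of sires and dams on the index
#'
#' Ranks the live candidates of each sex by [compute_index()] and returns the
#' top `n_sires` males and `n_dams` females. Ties are broken by lower id so
#' that selection is deterministic for a given cohort.
#'
#' @param cohort Candidate cohort data.frame.
#' @param n_sires,n_dams Numbers of parents to select.
#' @param b1,b2 Index weights.
#' @return List with elements `sires` and `dams`, each a cohort data.frame
#'   ordered from best to worst index.
#' @export
truncation_select <- function(cohort, n_sires, n_dams, b1 = 1, b2 = 0) {
  alive <- cohort[cohort$alive, , drop = FALSE]
  idx <- compute_index(alive$ebv, alive$g, b1, b2)
  pick <- function(sex, n) {
    rows <- which(alive$sex == sex)
    if (length(rows) < n)
      stop(sprintf("only %d live %s candidates for %d slots",
                   length(rows), if (sex == "M") "male" else "female", n),
           call. = FALSE)
    rows[order(-idx[rows], alive$id[rows])][seq_len(n)]
  }
  list(sires = alive[pick("M", n_sires), , drop = FALSE],
       dams = alive[pick("F", n_dams), , drop = FALSE])
}

#' Assign one sire to each dam
#'
#' Each selected dam is mated once. By default the sire for each dam is drawn
#' uniformly at random with replacement, so realized sire usage is
#' multinomial and a sire may go unused. With `balanced = TRUE` the dams are
#' instead divided as evenly as possible over the sires in random order
#' (sensitivity switch).
#'
#' @param sires,dams Parent cohort data.frames from [truncation_select()].
#' @param b1,b2 Index weights used for the mating's parent-average index
#'   (consumed by the editing module's targeting rule).
#' @param balanced Use balanced instead of random sire usage.
#' @return A data.frame of matings with one row per dam: parent row indices
#'   (`sire_row`, `dam_row` into `sires`/`dams`), parent ids and genotypes,
#'   `parental_g` (= `g_sire + g_dam`, 0-4) and `parent_avg_index`.
#' @export
assign_mates <- function(sires, dams, b1 = 1, b2 = 0, balanced = FALSE) {
  n_dams <- nrow(dams)
  n_sires <- nrow(sires)
  stopifnot(n_dams >= 1L, n_sires >= 1L)
  if (balanced) {
    sire_row <- sample(rep_len(seq_len(n_sires), n_dams))
  } else {
    sire_row <- sample.int(n_sires, n_dams, replace = TRUE)
  }
  idx_s <- compute_index(sires$ebv, sires$g, b1, b2)
  idx_d <- compute_index(dams$ebv, dams$g, b1, b2)
  data.frame(
    sire_row = sire_row,
    dam_row = seq_len(n_dams),
    sire_id = sires$id[sire_row],
    dam_id = dams$id,
    g_sire = sires$g[sire_row],
    g_dam = dams$g,
    parental_g = sires$g[sire_row] + dams$g,
    parent_avg_index = 0.5 * (idx_s[sire_row] + idx_d)
  )
}

#' Produce the next candidate cohort from a set of matings
#'
#' Expands every mating into `n_off_per_mating` zygotes via
#' [make_offspring()], applies the editing plan (if any) with
#' [apply_editing()], and attaches EBV to the surviving zygotes. Zygotes that
#' die from the editing procedure remain in the returned cohort with
#' `alive = FALSE` and `ebv = NA` and are excluded from all later selection
#' and statistics.
#'
#' @param matings Mating data.frame from [assign_mates()].
#' @param sires,dams Parent cohorts the mating rows index into.
#' @param spec A [scenario_spec()].
#' @param generation Generation index of the offspring.
#' @param next_id First offspring id to assign.
#' @param f_offspring Per-mating offspring inbreeding coefficients
#'   (from [offspring_inbreeding()]).
#' @param plan Editing plan from [select_matings_for_editing()], or `NULL`.
#' @return List with `cohort` (all zygotes, dead included) and `edit`
#'   (per-generation editing counters, see [apply_editing()]).
#' @export
produce_generation <- function(matings, sires, dams, spec, generation,
                               next_id, f_offspring, plan = NULL) {
  n_off <- spec$n_off_per_mating
  z <- rep(seq_len(nrow(matings)), each = n_off)
  cols <- c("id", "tbv", "g", "f")
  # plain-list parent views (avoids data.frame row-subset overhead at 20k rows)
  sire <- lapply(sires[cols], `[`, matings$sire_row[z])
  dam <- lapply(dams[cols], `[`, matings$dam_row[z])
  ids <- next_id + seq_along(z) - 1L
  cohort <- make_offspring(sire, dam, f_offspring[z], ids, generation)

  edit <- list(n_eligible = 0L, n_flagged = 0L, n_subjected = 0L,
               n_edit_survived = 0L, n_fully_edited = 0L)
  if (!is.null(plan) && length(plan$flagged)) {
    edit$n_eligible <- plan$n_eligible
    edit$n_flagged <- length(plan$flagged)
    in_flagged <- z %in% plan$flagged
    target <- if (spec$edit_carriers_only) in_flagged & cohort$g < 2L
              else in_flagged
    if (any(target)) {
      res <- apply_editing(cohort[target, , drop = FALSE],
                           spec$edit_success_k, spec$edit_survival_s,
                           allow_noncarriers = !spec$edit_carriers_only)
      cohort[target, ] <- res$zygotes
      edit$n_subjected <- res$n_subjected
      edit$n_edit_survived <- res$n_survived
      edit$n_fully_edited <- res$n_fully_edited
    }
  }
  alive <- cohort$alive
  cohort$ebv[alive] <- simulate_ebv(cohort$tbv[alive], spec$reliability_r2)
  list(cohort = cohort, edit = edit)
}
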