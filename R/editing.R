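#' Target matings for genome editing
#'
#' At most `round(edit_fraction * n_matings)` matings are flagged per
#' generation. Only matings whose parents jointly carry at least one undesired
#' allele (`parental_g < 4`) are eligible. Eligible matings are ranked by
#' (1) smallest parental desired-allele count, then (2) best parent-average
#' index, with dam id as the final deterministic tie-break, and flagged from
#' the top until the quota is filled (fewer if fewer are eligible).
#'
#' @param matings Mating data.frame from [assign_mates()].
#' @param edit_fraction Fraction of matings that may be edited.
#' @return List of class `editing_plan`: `flagged` (row indices into
#'   `matings`), `n_eligible`, and `quota`.
#' @export
select_matings_for_editing <- function(matings, edit_fraction) {
  n_matings <- nrow(matings)
  quota <- round_half_up(edit_fraction * n_matings)
  eligible <- which(matings$parental_g < 4L)
  ord <- eligible[order(matings$parental_g[eligible],
                        -matings$parent_avg_index[eligible],
                        matings$dam_id[eligible])]
  flagged <- ord[seq_len(min(quota, length(ord)))]
  structure(list(flagged = flagged, n_eligible = length(eligible),
                 quota = quota),
            class = "editing_plan")
}

# Deterministic commercial rounding (round() in R rounds half to even).
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Apply genome editing to zygotes
#'
#' Each undesired allele of a subjected zygote is independently converted to
#' the desired allele with probability `k`; the zygote then survives the
#' procedure with probability `s`, regardless of whether any conversion
#' succeeded (the mortality attaches to the procedure, not its success; it
#' aggregates mosaicism and off-target losses). Every subjected zygote counts
#' as one editing procedure. Parental genotypes are never altered.
#'
#' Random draws, in order: per-zygote conversion counts (binomial in the
#' number of undesired alleles), then survival Bernoullis.
#'
#' @param zygotes Cohort data.frame of zygotes to subject. By contract these
#'   carry at least one undesired allele (`g < 2`); passing a `g = 2` zygote
#'   is an error unless `allow_noncarriers = TRUE` (the switch that subjects
#'   every zygote of a flagged mating).
#' @param k Per-allele editing success probability.
#' @param s Per-zygote survival probability.
#' @param allow_noncarriers Permit already-homozygous zygotes (counted and at
#'   risk, nothing to convert).
#' @return List: `zygotes` (updated rows: `g`, `edited`, `alive`, and
#'   `ebv = NA` for the dead), `n_subjected`, `n_survived`, `n_fully_edited`
#'   (live and `g = 2` after editing).
#' @export
apply_editing <- function(zygotes, k, s, allow_noncarriers = FALSE) {
  n <- nrow(zygotes)
  if (!allow_noncarriers && any(zygotes$g == 2L))
    stop("apply_editing() called on zygote(s) without an undesired allele",
         call. = FALSE)
  undesired <- 2L - zygotes$g
  converted <- rbinom(n, undesired, k)
  zygotes$g <- zygotes$g + converted
  zygotes$edited <- TRUE
  survive <- if (s >= 1) rep(TRUE, n) else rbinom(n, 1L, s) == 1L
  zygotes$alive <- survive
  zygotes$ebv[!survive] <- NA_real_
  list(zygotes = zygotes,
       n_subjected = n,
       n_survived = sum(survive),
       n_fully_edited = sum(survive & zygotes$g == 2L))
}
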