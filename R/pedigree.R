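# A relationship cache holds the additive (numerator) relationship matrix
# among one generation's selected parents plus the id -> row map. Because
# generations are discrete and parents always come from the immediately
# preceding generation's parents, propagating the cache generation by
# generation is exactly the classic tabular method restricted to those
# animals, at ~(n_sires + n_dams)^2 cost instead of the full pedigree.
new_relationship_cache <- function(A, ids) {
  structure(list(A = A, ids = as.integer(ids)), class = "relationship_cache")
}

#' Propagate the additive relationship matrix to a new parent set
#'
#' Given the relationship cache among the previous generation's selected
#' parents, computes the relationship matrix among a newly selected parent
#' set whose sires and dams are all rows of the previous cache. For animals
#' x and y with parents (sx, dx) and (sy, dy):
#' `a(x, y) = 0.25 * (a(sx,sy) + a(sx,dy) + a(dx,sy) + a(dx,dy))` for
#' x != y, and `a(x, x) = 1 + 0.5 * a(sx, dx)`. Founders (unknown parents,
#' `prev_cache = NULL`) get an identity matrix: unrelated and non-inbred.
#'
#' @param prev_cache A `relationship_cache` for the parents' generation, or
#'   `NULL` when the new parents are founders.
#' @param selected Cohort data.frame of the newly selected parents (sires
#'   first, then dams, by convention).
#' @return A `relationship_cache` among `selected`.
#' @export
propagate_relationships <- function(prev_cache, selected) {
  n <- nrow(selected)
  if (is.null(prev_cache)) {
    if (any(selected$sire_id != 0L | selected$dam_id != 0L))
      stop("no relationship cache supplied but parents are known",
           call. = FALSE)
    return(new_relationship_cache(diag(n), selected$id))
  }
  s <- match(selected$sire_id, prev_cache$ids)
  d <- match(selected$dam_id, prev_cache$ids)
  if (anyNA(s) || anyNA(d))
    stop("selected animal has a parent outside the relationship cache",
         call. = FALSE)
  A <- propagate_A_cpp(prev_cache$A, s - 1L, d - 1L)
  new_relationship_cache(A, selected$id)
}

#' Offspring inbreeding coefficient from the parental relationship cache
#'
#' `F = 0.5 * a(sire, dam)`; animals with unknown parents are non-inbred.
#' Vectorized over parent pairs.
#'
#' @param sire_id,dam_id Parent ids (0 = unknown).
#' @param cache `relationship_cache` containing both parents.
#' @return Inbreeding coefficient(s) in \[0, 1).
#' @export
offspring_inbreeding <- function(sire_id, dam_id, cache) {
  n <- max(length(sire_id), length(dam_id))
  out <- numeric(n)
  known <- sire_id != 0L & dam_id != 0L
  if (any(known)) {
    s <- match(sire_id[known], cache$ids)
    d <- match(dam_id[known], cache$ids)
    if (anyNA(s) || anyNA(d))
      stop("parent id not present in the relationship cache", call. = FALSE)
    out[known] <- 0.5 * cache$A[cbind(s, d)]
  }
  out
}

#' Per-generation population statistics
#'
#' Summarizes the live animals of one candidate cohort: desired-allele
#' frequency, mean and variance of TBV, mean inbreeding, selection response
#' and inbreeding rate against the previous generation, counts of animals
#' showing the desired phenotype under dominant (`g >= 1`) or recessive
#' (`g = 2`) gene action, and the generation's editing counters.
#'
#' @param cohort Cohort data.frame (dead zygotes are excluded internally).
#' @param prev_stats The previous generation's one-row stats data.frame, or
#'   `NULL` (responses are then `NA`).
#' @param edit Editing counters as returned by [produce_generation()], or
#'   `NULL` for an unedited generation.
#' @return One-row data.frame (fields above plus `generation`, `n`, `fixed`).
#' @export
generation_stats <- function(cohort, prev_stats = NULL, edit = NULL) {
  alive <- cohort[cohort$alive, , drop = FALSE]
  n <- nrow(alive)
  if (n == 0L) stop("cannot summarize an empty cohort", call. = FALSE)
  if (is.null(edit))
    edit <- list(n_eligible = 0L, n_flagged = 0L, n_subjected = 0L,
                 n_edit_survived = 0L, n_fully_edited = 0L)
  freq <- sum(alive$g) / (2 * n)
  mean_tbv <- mean(alive$tbv)
  data.frame(
    generation = cohort$generation[1L],
    n = n,
    freq = freq,
    fixed = freq == 1,
    mean_tbv = mean_tbv,
    var_tbv = var(alive$tbv),
    mean_f = mean(alive$f),
    response = if (is.null(prev_stats)) NA_real_
               else mean_tbv - prev_stats$mean_tbv,
    delta_f = if (is.null(prev_stats)) NA_real_
              else mean(alive$f) - prev_stats$mean_f,
    n_dominant = sum(alive$g >= 1L),
    n_recessive = sum(alive$g == 2L),
    n_eligible_matings = edit$n_eligible,
    n_flagged_matings = edit$n_flagged,
    n_subjected = edit$n_subjected,
    n_edit_survived = edit$n_edit_survived,
    n_fully_edited = edit$n_fully_edited
  )
}

#' Export a pedigree in 3-column format
#'
#' Writes `id sire_id dam_id` (whitespace-delimited, 0 = unknown parent),
#' topologically sorted by id, as consumed by standard pedigree software.
#'
#' @param pedigree Data.frame with columns `id`, `sire_id`, `dam_id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_pedigree <- function(pedigree, path) {
  stopifnot(all(c("id", "sire_id", "dam_id") %in% names(pedigree)))
  ped <- pedigree[order(pedigree$id), c("id", "sire_id", "dam_id")]
  utils::write.table(ped, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
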