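#' Assign a bioactivity class from an IC50 value
#'
#' Compounds at or below `active_max` are active, at or above `inactive_min`
#' inactive, strictly between the cutoffs intermediate. Boundaries are
#' inclusive on the class side (<= active_max, >= inactive_min), so 5000 nM
#' is active and 20000 nM is inactive under the defaults.
#'
#' @param ic50_nM positive IC50 value(s) in nM (vectorized).
#' @param active_max,inactive_min class cutoffs in nM.
#' @return character vector in `c("active", "intermediate", "inactive")`.
#' @export
assign_class <- function(ic50_nM, active_max = 5000, inactive_min = 20000) {
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0))
    stop("value error: ic50_nM must be positive and finite")
  if (active_max >= inactive_min)
    stop("value error: active_max must be below inactive_min")
  ifelse(ic50_nM <= active_max, "active",
         ifelse(ic50_nM >= inactive_min, "inactive", "intermediate"))
}

#' Every-fifth-compound train/test split
#'
#' Compounds are ordered by activity class (active, intermediate, inactive),
#' shuffled within each class under the given seed, and every fifth compound
#' of the concatenated ordering (positions `start`, `start + 5`, ...) is
#' assigned to the testing set together with all of its docked poses. The
#' split is therefore class-stratified: every class contributes
#' floor(n/5) or ceiling(n/5) testing compounds, and an approximately
#' 80:20 training-to-testing ratio is maintained.
#'
#' @param compounds data.frame with `compound_id` and `activity_class`
#'   columns (one row per compound).
#' @param seed integer seed for the within-class shuffle (required, logged).
#' @param start 1-based position of the first testing compound.
#' @return A `split_assignment`: list with `training_compounds` and
#'   `testing_compounds` character vectors.
#' @export
split_every_fifth <- function(compounds, seed, start = 5L) {
  if (anyDuplicated(compounds$compound_id))
    stop("split_every_fifth: duplicate compound ids")
  n <- nrow(compounds)
  if (n < 5L) stop("split_every_fifth: need at least 5 compounds")
  rank <- match(compounds$activity_class,
                c("active", "intermediate", "inactive"))
  if (any(is.na(rank))) stop("split_every_fifth: unknown activity class")
  ord <- with_seed(seed, {
    jitter <- runif(n)
    order(rank, jitter)
  })
  ids <- compounds$compound_id[ord]
  test_pos <- seq(from = start, to = n, by = 5L)
  res <- list(training_compounds = ids[-test_pos],
              testing_compounds = ids[test_pos],
              seed = seed, start = start)
  class(res) <- "split_assignment"
  res
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %d training / %d testing compounds (seed %s)\n",
              length(x$training_compounds), length(x$testing_compounds),
              x$seed))
  invisible(x)
}
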