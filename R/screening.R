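#' Percent of a compound's poses predicted active
#'
#' 100 * n_active / (n_active + n_inactive), reported to one decimal with
#' half-up rounding (the convention used when pose-count tables are printed).
#'
#' @param n_active,n_inactive predicted pose counts (vectorized).
#' @return percentage(s) in `[0, 100]`, rounded to 1 decimal.
#' @export
percent_active <- function(n_active, n_inactive) {
  total <- n_active + n_inactive
  if (any(total <= 0)) stop("percent_active: zero total pose count")
  round_half_up(100 * n_active / total, 1)
}

#' Pose-ratio records from per-pose predictions
#'
#' @param pred_labels named vector pose_id -> predicted class
#'   (`"active"`/`"inactive"`).
#' @param compound_of named vector pose_id -> compound_id.
#' @return data.frame: compound_id, n_active_poses, n_inactive_poses,
#'   percent_active.
#' @export
pose_ratio_records <- function(pred_labels, compound_of) {
  cmp <- compound_of[names(pred_labels)]
  df <- data.frame(compound_id = cmp, active = pred_labels == "active")
  agg <- stats::aggregate(active ~ compound_id, df,
                          FUN = function(v) c(sum(v), sum(!v)))
  out <- data.frame(compound_id = agg$compound_id,
                    n_active_poses = agg$active[, 1],
                    n_inactive_poses = agg$active[, 2],
                    stringsAsFactors = FALSE)
  out$percent_active <- percent_active(out$n_active_poses,
                                       out$n_inactive_poses)
  out[order(out$compound_id), , drop = FALSE]
}

#' Derive the active-pose-ratio threshold from documented actives
#'
#' Compounds with fewer than `min_poses` predicted poses are excluded (a
#' single docked pose is not a usable augmentation signal); the threshold is
#' the minimum percent-active among the remaining documented actives, and
#' the compound attaining it is recorded as the defining compound.
#'
#' @param records data.frame from [pose_ratio_records()] for the documented
#'   active compounds of the testing set.
#' @param min_poses minimum total pose count for eligibility.
#' @return A `threshold_decision`: list with `threshold_percent`,
#'   `defining_compound`, `excluded_compounds` (data.frame with reasons).
#' @export
derive_threshold <- function(records, min_poses = 2L) {
  total <- records$n_active_poses + records$n_inactive_poses
  excluded <- records$compound_id[total < min_poses]
  elig <- records[total >= min_poses, , drop = FALSE]
  if (!nrow(elig)) stop("derive_threshold: no eligible records")
  i <- which.min(elig$percent_active)
  structure(list(threshold_percent = elig$percent_active[i],
                 defining_compound = elig$compound_id[i],
                 excluded_compounds = data.frame(
                   compound_id = excluded,
                   reason = if (length(excluded))
                     sprintf("fewer than %d predicted poses", min_poses)
                   else character(0),
                   stringsAsFactors = FALSE)),
            class = "threshold_decision")
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat(sprintf("<threshold_decision> %.1f%% (defined by %s; %d excluded)\n",
              x$threshold_percent, x$defining_compound,
              nrow(x$excluded_compounds)))
  invisible(x)
}

#' Triage screened compounds by the active-pose-ratio threshold
#'
#' A compound is promising when its percent-active is at or above the
#' threshold (inclusive, so the threshold-defining compound passes its own
#' threshold). Results are sorted by decreasing percent-active.
#'
#' @param records data.frame from [pose_ratio_records()] for the screened
#'   compounds.
#' @param threshold a [derive_threshold()] decision or a bare percentage.
#' @return `records` with a `promising` flag, sorted by percent-active.
#' @export
triage_hits <- function(records, threshold) {
  thr <- if (inherits(threshold, "threshold_decision"))
    threshold$threshold_percent else threshold
  records$promising <- records$percent_active >= thr
  records[order(-records$percent_active, records$compound_id), ,
          drop = FALSE]
}
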