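#' Consensus votes from the top-20% rule
#'
#' For every scoring column, poses are ranked in the column's direction and
#' the best `ceiling(N * top_fraction)` poses receive that function's vote;
#' a pose's consensus score is the sum of its votes. Poses tying with the
#' cutoff value are all included (inclusive boundary), so vote counts can
#' exceed the nominal 20% under ties; a column with all-identical values
#' votes for every pose. By default all poses in the table are pooled into
#' one ranking population per column; set `by_compound` together with
#' `compound_of` to rank within each compound instead.
#'
#' @param table a [score_table()].
#' @param top_fraction fraction of poses receiving a vote per column.
#' @param by_compound rank within compounds rather than globally.
#' @param compound_of named character vector pose_id -> compound_id
#'   (required when `by_compound = TRUE`).
#' @return data.frame (`consensus_score`) with `pose_id`, `votes`, and one
#'   0/1 column per scoring function named `vote_<score>`.
#' @export
consensus_votes <- function(table, top_fraction = 0.20, by_compound = FALSE,
                            compound_of = NULL) {
  if (!inherits(table, "score_table")) stop("consensus_votes: need a score_table")
  if (nrow(table) == 0L) stop("consensus_votes: empty score table")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("consensus_votes: top_fraction must be in (0, 1)")
  dirs <- attr(table, "directions")
  score_cols <- names(dirs)
  vote_one <- function(values) {
    # orient so larger is better, then vote for values >= the m-th best
    m <- ceiling(length(values) * top_fraction)
    cut <- sort(values, decreasing = TRUE)[m]
    as.integer(values >= cut)
  }
  votes <- matrix(0L, nrow(table), length(score_cols),
                  dimnames = list(NULL, paste0("vote_", score_cols)))
  for (j in seq_along(score_cols)) {
    v <- table[[score_cols[j]]]
    if (dirs[[score_cols[j]]] == "lower_better") v <- -v
    if (by_compound) {
      if (is.null(compound_of))
        stop("consensus_votes: by_compound needs compound_of")
      grp <- compound_of[table$pose_id]
      votes[, j] <- stats::ave(v, grp, FUN = vote_one)
    } else {
      votes[, j] <- vote_one(v)
    }
  }
  out <- data.frame(pose_id = table$pose_id,
                    votes = as.integer(rowSums(votes)), votes,
                    check.names = FALSE)
  class(out) <- c("consensus_score", "data.frame")
  out
}

#' Heavy-atom RMSD between two poses of the same compound
#'
#' Root-mean-square deviation over paired atoms in the docking frame (no
#' superposition). Pairing is by identical atom order, which docked poses of
#' one molecule share; hydrogens are excluded by default.
#'
#' @param pose_a,pose_b poses of the same compound with identical atom order.
#' @param heavy_only drop hydrogens before pairing.
#' @return RMSD in angstrom.
#' @export
pose_rmsd <- function(pose_a, pose_b, heavy_only = TRUE) {
  if (!identical(pose_a$compound_id, pose_b$compound_id))
    stop("pose_rmsd: poses belong to different compounds")
  a <- pose_a$coords
  b <- pose_b$coords
  if (heavy_only) {
    a <- a[!pose_a$is_hydrogen, , drop = FALSE]
    b <- b[!pose_b$is_hydrogen, , drop = FALSE]
  }
  if (nrow(a) != nrow(b)) stop("pose_rmsd: atom-count mismatch")
  cpp_rmsd(a, b)
}

#' Deduplicate one compound's poses by RMSD, keeping top-consensus poses
#'
#' Greedy clustering: poses are visited by decreasing consensus votes (ties
#' broken by pose id); a pose is kept iff its heavy-atom RMSD to every
#' already-kept pose is at or above the threshold (duplicates are strictly
#' closer than `rmsd_threshold`), otherwise it is recorded as removed under
#' its nearest kept pose. Poses missing from the consensus table count as
#' zero votes.
#'
#' @param poses list of poses, all of one compound.
#' @param consensus a [consensus_votes()] result (or data.frame with
#'   `pose_id` and `votes`).
#' @param rmsd_threshold duplicate threshold in angstrom.
#' @return A `dedup_result`: list with `kept` (pose ids) and `removed`
#'   (named character vector removed_pose_id -> representative pose id).
#' @export
dedup_poses <- function(poses, consensus, rmsd_threshold = 2.0) {
  if (!length(poses)) return(structure(list(kept = character(0),
                                            removed = character(0)),
                                       class = "dedup_result"))
  cids <- unique(vapply(poses, `[[`, "", "compound_id"))
  if (length(cids) > 1L) stop("dedup_poses: poses from multiple compounds")
  ids <- vapply(poses, `[[`, "", "pose_id")
  votes <- consensus$votes[match(ids, consensus$pose_id)]
  votes[is.na(votes)] <- 0L
  ord <- order(-votes, ids)
  kept_idx <- integer(0)
  removed <- character(0)
  for (i in ord) {
    if (!length(kept_idx)) { kept_idx <- i; next }
    d <- vapply(kept_idx, function(k) pose_rmsd(poses[[i]], poses[[k]]),
                numeric(1))
    if (all(d >= rmsd_threshold)) {
      kept_idx <- c(kept_idx, i)
    } else {
      removed[ids[i]] <- ids[kept_idx[which.min(d)]]
    }
  }
  structure(list(kept = ids[sort(kept_idx)], removed = removed),
            class = "dedup_result")
}

#' Keep poses reaching a consensus level
#'
#' @param poses list of poses (any compounds).
#' @param consensus a [consensus_votes()] result.
#' @param min_votes minimal consensus score; poses absent from the table
#'   count as zero votes.
#' @return the surviving subset of `poses`.
#' @export
filter_by_consensus <- function(poses, consensus, min_votes) {
  if (min_votes < 0) stop("filter_by_consensus: min_votes must be >= 0")
  ids <- vapply(poses, `[[`, "", "pose_id")
  votes <- consensus$votes[match(ids, consensus$pose_id)]
  votes[is.na(votes)] <- 0L
  poses[votes >= min_votes]
}
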