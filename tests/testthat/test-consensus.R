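mk_scores <- function(mat, ids = NULL, dirs = NULL) {
  ids <- ids %||% sprintf("p%02d", seq_len(nrow(mat)))
  cols <- sprintf("S%d", seq_len(ncol(mat)))
  colnames(mat) <- cols
  dirs <- dirs %||% setNames(rep("higher_better", ncol(mat)), cols)
  score_table(data.frame(pose_id = ids, mat, check.names = FALSE), dirs)
}

test_that("top-20% voting: extremes, derived counts, direction handling", {
  posevote:::with_seed(21, {
    m <- matrix(rnorm(90), 10, 9)
    best <- which.max(rowSums(m))  # make one pose best everywhere
    m[best, ] <- 10
    worst <- which.min(rowSums(m[-best, , drop = FALSE]))
    m[-best, ][worst, ] <- -10
    tab <- mk_scores(m)
    cv <- consensus_votes(tab)
    expect_equal(cv$votes[best], 9)
    expect_equal(min(cv$votes), 0)
    # oracle equivalence on random tables with mixed directions
    for (rep in 1:20) {
      mm <- matrix(rnorm(12 * 5), 12, 5)
      dd <- setNames(sample(c("higher_better", "lower_better"), 5, TRUE),
                     sprintf("S%d", 1:5))
      tt <- mk_scores(mm, dirs = dd)
      expect_equal(setNames(consensus_votes(tt)$votes, tt$pose_id),
                   bf_votes(tt, dd))
    }
  })
})

test_that("vote boundary is tie-inclusive; constant columns vote for all", {
  m <- cbind(c(5, 5, 3, 2, 1, 0, 0, 0, 0, 0))  # tie at the 20% cutoff
  cv <- consensus_votes(mk_scores(m))
  expect_equal(cv$votes[1:2], c(1L, 1L))
  cvc <- consensus_votes(mk_scores(cbind(rep(7, 10))))
  expect_true(all(cvc$votes == 1L))
  expect_error(consensus_votes(mk_scores(m), top_fraction = 1), "top_fraction")
})

test_that("per-column vote counts sum to ceiling(N * fraction) up to ties", {
  posevote:::with_seed(4, {
    m <- matrix(rnorm(200 * 4), 200, 4)  # continuous: no ties
    cv <- consensus_votes(mk_scores(m))
    for (j in 1:4)
      expect_equal(sum(cv[[paste0("vote_S", j)]]), ceiling(200 * 0.2))
  })
})

test_that("rmsd: identity, uniform shift, hand-computed, hydrogens", {
  co <- rbind(c(0, 0, 0), c(1, 1, 1))
  a <- toy_pose(co)
  expect_equal(pose_rmsd(a, a), 0)
  b <- toy_pose(co + rep(c(3, 0, 0), each = 2))
  expect_equal(pose_rmsd(a, b), 3)
  # 2-atom toy with displacements 1 and 3: sqrt((1 + 9) / 2)
  d <- toy_pose(rbind(c(1, 0, 0), c(1 + 3, 1, 1)))
  expect_equal(pose_rmsd(a, d), sqrt(5))
  # hydrogens excluded under heavy_only
  ah <- toy_pose(rbind(co, c(9, 9, 9)), element = c("C", "C", "H"))
  bh <- toy_pose(rbind(co, c(0, 0, 0)), element = c("C", "C", "H"))
  expect_equal(pose_rmsd(ah, bh), 0)
  expect_gt(pose_rmsd(ah, bh, heavy_only = FALSE), 0)
  expect_error(pose_rmsd(a, toy_pose(rbind(c(0, 0, 0)))), "mismatch")
  expect_error(pose_rmsd(a, toy_pose(co, compound_id = "C9")), "different")
})

test_that("dedup keeps the top-vote representative and traces the greedy rule", {
  co <- rbind(c(0, 0, 0), c(4, 0, 0))
  mk <- function(id, shift) toy_pose(co + rep(shift, each = 2),
                                     pose_id = id)
  votes <- function(...) {
    v <- c(...)
    data.frame(pose_id = names(v), votes = unname(v))
  }
  # identical poses: vote-5 pose kept
  r <- dedup_poses(list(mk("x#1", c(0, 0, 0)), mk("x#2", c(0, 0, 0))),
                   votes(`x#1` = 3, `x#2` = 5))
  expect_equal(r$kept, "x#2")
  expect_equal(unname(r$removed["x#1"]), "x#2")
  # pairwise far poses: all kept
  r2 <- dedup_poses(list(mk("x#1", c(0, 0, 0)), mk("x#2", c(0, 3, 0)),
                         mk("x#3", c(0, 0, 3))),
                    votes(`x#1` = 1, `x#2` = 1, `x#3` = 1))
  expect_length(r2$kept, 3)
  # chain A-B 1.5, B-C 1.5, A-C 3.0, votes A>B>C -> kept {A, C}
  A <- mk("A", c(0, 0, 0)); B <- mk("B", c(1.5, 0, 0)); C <- mk("C", c(3, 0, 0))
  r3 <- dedup_poses(list(A, B, C), votes(A = 5, B = 4, C = 3))
  expect_equal(r3$kept, c("A", "C"))
  expect_equal(unname(r3$removed["B"]), "A")
  # boundary: RMSD exactly 2.0 is NOT a duplicate (strict <)
  r4 <- dedup_poses(list(mk("y#1", c(0, 0, 0)), mk("y#2", c(2, 0, 0))),
                    votes(`y#1` = 1, `y#2` = 1))
  expect_length(r4$kept, 2)
})

test_that("dedup is idempotent and missing votes count as zero", {
  posevote:::with_seed(8, {
    poses <- lapply(1:10, function(i)
      toy_pose(matrix(runif(9, 0, 6), 3, 3), pose_id = sprintf("z#%d", i)))
    cs <- data.frame(pose_id = sprintf("z#%d", 1:5), votes = 5:1)
    r1 <- dedup_poses(poses, cs)
    kept_poses <- poses[vapply(poses, `[[`, "", "pose_id") %in% r1$kept]
    r2 <- dedup_poses(kept_poses, cs)
    expect_identical(sort(r2$kept), sort(r1$kept))
    expect_length(r2$removed, 0)
  })
})

test_that("consensus filtering is monotone and respects bounds", {
  posevote:::with_seed(13, {
    m <- matrix(rnorm(30 * 9), 30, 9)
    tab <- mk_scores(m)
    cv <- consensus_votes(tab)
    poses <- lapply(tab$pose_id, function(id)
      toy_pose(rbind(c(0, 0, 0)), pose_id = id))
    expect_length(filter_by_consensus(poses, cv, 0), 30)
    expect_length(filter_by_consensus(poses, cv, 10), 0)
    prev <- 31
    for (lv in 0:9) {
      n <- length(filter_by_consensus(poses, cv, lv))
      expect_lte(n, prev)
      prev <- n
    }
    mixed <- data.frame(pose_id = c("a", "b", "c"), votes = c(0, 1, 3))
    ps <- lapply(c("a", "b", "c"), function(id)
      toy_pose(rbind(c(0, 0, 0)), pose_id = id))
    expect_length(filter_by_consensus(ps, mixed, 1), 2)
    expect_error(filter_by_consensus(ps, mixed, -1), "min_votes")
  })
})
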