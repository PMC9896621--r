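# Small in-code fixtures and independent oracles shared across test files.

toy_site <- function(coords, resnames = NULL, atom_names = NULL,
                     elements = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  binding_site(data.frame(
    atom_name = atom_names %||% paste0("CA", seq_len(n)),
    residue_name = resnames %||% rep("ALA", n),
    residue_number = seq_len(n),
    chain_id = "A",
    element = elements %||% rep("C", n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

toy_pose <- function(coords, compound_id = "C1", pose_id = "C1#1",
                     element = NULL) {
  coords <- as.matrix(coords)
  pose(compound_id, pose_id, coords,
       element %||% rep("C", nrow(coords)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n*m) double-loop contact oracle, independent of the compiled path
bf_contact_bits <- function(lig, site, cutoff) {
  bits <- integer(nrow(site))
  for (j in seq_len(nrow(site))) {
    for (i in seq_len(nrow(lig))) {
      if (sqrt(sum((lig[i, ] - site[j, ])^2)) <= cutoff) {
        bits[j] <- 1L
        break
      }
    }
  }
  bits
}

# brute-force per-column top-fraction voting oracle
bf_votes <- function(df, directions, top_fraction = 0.2) {
  score_cols <- names(directions)
  votes <- setNames(integer(nrow(df)), df$pose_id)
  for (cl in score_cols) {
    v <- df[[cl]]
    if (directions[[cl]] == "lower_better") v <- -v
    m <- ceiling(length(v) * top_fraction)
    cutv <- sort(v, decreasing = TRUE)[m]
    votes <- votes + as.integer(v >= cutv)
  }
  votes
}

# Exact Shapley oracle by enumerating all orderings of the features and
# averaging marginal contributions (formulation independent of the
# subset-weight implementation in the package).
bf_shapley <- function(value_fn, M) {
  perms <- .permutations(M)
  phi <- numeric(M)
  for (p in seq_len(nrow(perms))) {
    have <- logical(M)
    v_prev <- value_fn(have)
    for (k in seq_len(M)) {
      j <- perms[p, k]
      have[j] <- TRUE
      v_now <- value_fn(have)
      phi[j] <- phi[j] + (v_now - v_prev)
      v_prev <- v_now
    }
  }
  phi / nrow(perms)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# tiny labeled descriptor world with planted binary signal, for ML tests
toy_signal_matrix <- function(n_cmp = 60, poses_per = 6, p_noise = 20,
                              signal = 0.9, seed = 1) {
  posevote:::with_seed(seed, {
    cls <- rep(c("active", "inactive"), length.out = n_cmp)
    rows <- n_cmp * poses_per
    cid <- rep(sprintf("C%03d", seq_len(n_cmp)), each = poses_per)
    pid <- paste0(cid, "#", rep(seq_len(poses_per), n_cmp))
    lab <- rep(cls, each = poses_per)
    X <- matrix(rbinom(rows * p_noise, 1, 0.3), rows, p_noise)
    sig <- matrix(rbinom(rows * 3, 1,
                         ifelse(rep(lab == "active", 3), signal, 1 - signal)),
                  rows, 3)
    X <- cbind(sig, X)
    colnames(X) <- c(paste0("SIG", 1:3), paste0("N", seq_len(p_noise)))
    rownames(X) <- pid
    names(lab) <- pid
    co <- cid
    names(co) <- pid
    structure(list(X = X, labels = lab, compound_of = co),
              class = "feature_matrix")
  })
}

toy_split <- function(fm, seed = 5) {
  first <- !duplicated(fm$compound_of)
  cmp <- data.frame(compound_id = unname(fm$compound_of[first]),
                    activity_class = unname(fm$labels[names(fm$compound_of)[first]]),
                    stringsAsFactors = FALSE)
  split_every_fifth(cmp, seed = seed)
}
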