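# Synthetic-fixture generator: a self-contained world (binding site, docked
# poses, scores, activities, annotations) with a planted contact-activity
# association. Pose geometry is synthesized directly in the site frame (no
# physics): realism is limited to the statistical structure the downstream
# method consumes — contact bits, correlated scores, pose multiplicity.

#' Fixture configuration
#'
#' Defaults emulate the reference data shape at desk scale: a few hundred
#' compounds augmented to thousands of poses, a ~100-atom contact axis plus
#' 9 scoring columns, class proportions matching the curated 116/92/106
#' inhibitor set, and a 5-atom planted contact signal touched by active
#' poses with probability `signal_strength` (inactives: 1 - signal_strength;
#' 0.5 = no signal, the null world).
#'
#' @param n_compounds number of compounds.
#' @param poses_per_compound inclusive range of poses per compound.
#' @param n_site_atoms binding-site atoms (fingerprint axis length).
#' @param planted_contact_ids site-atom indices carrying the signal.
#' @param signal_strength probability an active pose touches a planted atom.
#' @param background_rate contact probability of non-planted slots.
#' @param score_noise_sd noise SD of the scoring columns.
#' @param class_proportions named proportions for active/intermediate/inactive.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n_compounds = 200L, poses_per_compound = c(5L, 20L),
                           n_site_atoms = 100L, planted_contact_ids = 1:5,
                           signal_strength = 0.9, background_rate = 0.3,
                           score_noise_sd = 1,
                           class_proportions = c(active = 116, intermediate = 92,
                                                 inactive = 106) / 314,
                           seed = 1L) {
  if (any(planted_contact_ids < 1 | planted_contact_ids > n_site_atoms))
    stop("config error: planted ids outside the site")
  if (signal_strength < 0.5 || signal_strength > 1)
    stop("config error: signal_strength must lie in [0.5, 1]")
  if (abs(sum(class_proportions) - 1) > 1e-6)
    stop("config error: class_proportions must sum to 1")
  structure(list(n_compounds = as.integer(n_compounds),
                 poses_per_compound = as.integer(poses_per_compound),
                 n_site_atoms = as.integer(n_site_atoms),
                 planted_contact_ids = as.integer(planted_contact_ids),
                 signal_strength = signal_strength,
                 background_rate = background_rate,
                 score_noise_sd = score_noise_sd,
                 class_proportions = class_proportions,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# lattice site: 6-angstrom spacing so a 2.5-angstrom contact sphere around
# one atom cannot graze a neighbouring atom
.fixture_site <- function(n) {
  m <- ceiling(n^(1 / 3))
  g <- expand.grid(ix = 0:(m - 1), iy = 0:(m - 1), iz = 0:(m - 1))
  g <- g[seq_len(n), ]
  resnames <- c("SER", "GLU", "TYR", "LYS", "MET", "VAL", "GLN")
  anames <- c("N", "CA", "CB", "O", "HN", "HA")
  is_water <- seq_len(n) %% 7L == 0L
  atom_name <- ifelse(is_water, "OH2",
                      anames[(seq_len(n) - 1L) %% length(anames) + 1L])
  element <- toupper(substr(atom_name, 1, 1))
  binding_site(data.frame(
    atom_name = atom_name,
    residue_name = ifelse(is_water, "HOH",
                          resnames[(seq_len(n) - 1L) %% length(resnames) + 1L]),
    residue_number = seq_len(n) + 100L,
    chain_id = "A",
    element = element,
    x = g$ix * 6, y = g$iy * 6, z = g$iz * 6,
    stringsAsFactors = FALSE))
}

.jitter_ball <- function(r) {
  v <- rnorm(3)
  v / sqrt(sum(v^2)) * r * runif(1)^(1 / 3)
}

# a point guaranteed > 2.5 angstrom from every lattice atom: cell centers
# sit at least sqrt(27) ~ 5.2 angstrom from every lattice point
.far_point <- function(site_xyz, m) {
  cell <- sample.int(m, 3, replace = TRUE) - 1L
  cell * 6 + 3 + .jitter_ball(0.5)
}

#' Generate a synthetic fixture world
#'
#' Active compounds' poses touch each planted site atom with probability
#' `signal_strength`, inactive poses with `1 - signal_strength`
#' (intermediates: 0.5); non-planted contacts are background noise. One
#' scoring column (`SF1`) carries an activity signal scaled by
#' `signal_strength - 0.5` (so the null world has none); the other eight are
#' noise, two of them ranked lower-better. Poses of one compound share slot
#' layout and atom order, so heavy-atom RMSD pairing is well defined.
#'
#' @param config a [fixture_config()].
#' @param out_dir optional directory; when given, receptor PDB, poses SDF,
#'   scores CSV, activities CSV and annotations CSV are written (byte-stable
#'   per seed).
#' @return list: `site`, `poses`, `scores`, `activities`, `annotations`,
#'   `intended_bits` (pose x site 0/1 matrix), `config`.
#' @export
generate_fixtures <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    n_site <- config$n_site_atoms
    site <- .fixture_site(n_site)
    sxyz <- site_coords(site)
    m <- ceiling(n_site^(1 / 3))
    planted <- config$planted_contact_ids
    n_planted <- length(planted)
    n_bg <- 6L
    n_slots <- n_planted + n_bg + 2L + 2L  # + far anchors + hydrogens
    elements <- c(rep("C", n_planted + n_bg + 2L), "H", "H")

    props <- config$class_proportions
    counts <- floor(props * config$n_compounds)
    while (sum(counts) < config$n_compounds)
      counts[which.max(props * config$n_compounds - counts)] <-
        counts[which.max(props * config$n_compounds - counts)] + 1L
    classes <- rep(names(props), counts)
    n_cmp <- config$n_compounds
    cids <- sprintf("C%04d", seq_len(n_cmp))
    ic50 <- numeric(n_cmp)
    for (i in seq_len(n_cmp)) {
      ic50[i] <- switch(classes[i],
        active = 10^runif(1, 1, log10(5000)),
        intermediate = 10^runif(1, log10(5050), log10(19900)),
        inactive = 10^runif(1, log10(20000), 6))
    }
    activities <- data.frame(compound_id = cids,
                             smiles = strrep("C", 5L + seq_len(n_cmp) %% 11L),
                             ic50_nM = round(ic50, 1),
                             activity_class = classes,
                             stringsAsFactors = FALSE)

    touch_prob <- c(active = config$signal_strength, intermediate = 0.5,
                    inactive = 1 - config$signal_strength)
    poses <- list()
    intended <- list()
    pose_count_pool <- config$poses_per_compound[1]:config$poses_per_compound[2]
    for (i in seq_len(n_cmp)) {
      np <- pose_count_pool[sample.int(length(pose_count_pool), 1L)]
      pt <- touch_prob[[classes[i]]]
      for (j in seq_len(np)) {
        bits <- integer(n_site)
        xyz <- matrix(0, n_slots, 3)
        for (s in seq_len(n_planted)) {
          if (runif(1) < pt) {
            bits[planted[s]] <- 1L
            xyz[s, ] <- sxyz[planted[s], ] + .jitter_ball(1.0)
          } else xyz[s, ] <- .far_point(sxyz, m)
        }
        for (b in seq_len(n_bg)) {
          slot <- n_planted + b
          if (runif(1) < config$background_rate) {
            target <- sample(setdiff(seq_len(n_site), planted), 1L)
            bits[target] <- 1L
            xyz[slot, ] <- sxyz[target, ] + .jitter_ball(1.0)
          } else xyz[slot, ] <- .far_point(sxyz, m)
        }
        a1 <- .far_point(sxyz, m)
        a2 <- .far_point(sxyz, m)
        xyz[n_planted + n_bg + 1L, ] <- a1
        xyz[n_planted + n_bg + 2L, ] <- a2
        xyz[n_planted + n_bg + 3L, ] <- a1 + c(0.9, 0, 0)
        xyz[n_planted + n_bg + 4L, ] <- a2 + c(0, 0.9, 0)
        # hydrogens near far anchors can still graze a cell-center sphere;
        # they are > 2.5 A from lattice points by construction (5.2 - 1.4)
        pid <- sprintf("%s#%d", cids[i], j)
        poses[[length(poses) + 1L]] <- pose(cids[i], pid, xyz, elements)
        intended[[pid]] <- bits
      }
    }
    intended_bits <- do.call(rbind, intended)
    colnames(intended_bits) <- site_atom_ids(site)

    n_pose <- length(poses)
    pids <- vapply(poses, `[[`, "", "pose_id")
    cls_of_pose <- classes[match(sub("#.*", "", pids), cids)]
    effect <- 6 * (config$signal_strength - 0.5)
    sf <- matrix(rnorm(n_pose * 9L, sd = config$score_noise_sd), n_pose, 9L)
    colnames(sf) <- paste0("SF", 1:9)
    sf[, 1] <- sf[, 1] + effect * (cls_of_pose == "active") +
      0.5 * effect * (cls_of_pose == "intermediate")
    directions <- c(rep("higher_better", 7L), rep("lower_better", 2L))
    names(directions) <- colnames(sf)
    scores <- score_table(data.frame(pose_id = pids, sf,
                                     stringsAsFactors = FALSE), directions)

    lig_roles <- c("hb_donor", "hb_acceptor", "neg_charged", "hydrophobic",
                   "hb_acceptor")[seq_len(min(5L, n_planted))]
    rec_roles <- c("hb_acceptor", "hb_donor", "pos_charged", "hydrophobic",
                   "hb_donor")[seq_len(min(5L, n_planted))]
    annotations <- atom_annotations(
      side = c(rep("ligand", length(lig_roles)),
               rep("receptor", length(rec_roles))),
      ref = c(as.character(seq_along(lig_roles)),
              site_atom_ids(site)[planted[seq_along(rec_roles)]]),
      role = c(lig_roles, rec_roles))

    out <- list(site = site, poses = poses, scores = scores,
                activities = activities, annotations = annotations,
                intended_bits = intended_bits, config = config)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_receptor_pdb(site, file.path(out_dir, "receptor.pdb"))
      write_poses_sdf(poses, file.path(out_dir, "poses.sdf"))
      sdf <- data.frame(pose_id = pids, round(sf, 6),
                        stringsAsFactors = FALSE)
      write.csv(sdf, file.path(out_dir, "scores.csv"), row.names = FALSE,
                quote = FALSE)
      write.csv(activities, file.path(out_dir, "activities.csv"),
                row.names = FALSE, quote = FALSE)
      write.csv(as.data.frame(annotations),
                file.path(out_dir, "annotations.csv"), row.names = FALSE,
                quote = FALSE)
    }
    out
  })
}
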