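# Rule-based structure pharmacophore extraction from one annotated
# receptor-ligand pose. Atom role typing (donor/acceptor/charges/
# hydrophobic) is an input: annotations are supplied per atom for both
# sides, which keeps the geometric engine free of chemistry perception.

.kind_priority <- c(NegIon = 1, PosIon = 1, HBD = 2, HBA = 2, Hbic = 3)

#' Annotation table constructor
#'
#' @param side `"ligand"` or `"receptor"` per row.
#' @param ref ligand atom index (as character) or receptor atom id.
#' @param role one of `hb_donor`, `hb_acceptor`, `pos_charged`,
#'   `neg_charged`, `hydrophobic`.
#' @return data.frame of class `atom_annotations`.
#' @export
atom_annotations <- function(side, ref, role) {
  ok <- role %in% c("hb_donor", "hb_acceptor", "pos_charged", "neg_charged",
                    "hydrophobic")
  if (!all(ok)) stopf("unknown role: %s", paste(unique(role[!ok]), collapse = ", "))
  if (!all(side %in% c("ligand", "receptor")))
    stop("atom_annotations: side must be ligand/receptor")
  out <- data.frame(side = side, ref = as.character(ref), role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("atom_annotations", "data.frame")
  out
}

#' Read an annotation CSV (columns side, ref, role)
#' @param path CSV file
#' @return [atom_annotations()]
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(ref = "character"))
  atom_annotations(df$side, df$ref, df$role)
}

.annot_positions <- function(annotations, pose, site, side, role) {
  a <- annotations[annotations$side == side & annotations$role == role, ]
  if (!nrow(a)) return(matrix(numeric(0), 0, 3))
  if (side == "ligand") {
    idx <- as.integer(a$ref)
    if (any(is.na(idx)) || any(idx < 1 | idx > nrow(pose$coords)))
      stop("annotation refers to a missing ligand atom")
    pose$coords[idx, , drop = FALSE]
  } else {
    m <- match(a$ref, site_atom_ids(site))
    if (anyNA(m)) {
      warnf("ignoring annotation(s) for unknown receptor atom(s): %s",
            paste(a$ref[is.na(m)], collapse = ", "))
      m <- m[!is.na(m)]
    }
    site_coords(site)[m, , drop = FALSE]
  }
}

# candidate rows: kind, x, y, z, direction (unit vector to the receptor
# partner for H-bond kinds), interaction distance
.candidate <- function(kind, posn, dirn, dist) {
  data.frame(kind = kind, x = posn[1], y = posn[2], z = posn[3],
             dx = dirn[1], dy = dirn[2], dz = dirn[3], distance = dist,
             stringsAsFactors = FALSE)
}

#' Detect candidate pharmacophore features of a pose
#'
#' Distance rules (all inclusive): hydrogen-bond pairs between annotated
#' heavy atoms at <= 4.0 angstrom (the ligand-side role names the feature:
#' ligand donor -> HBD, ligand acceptor -> HBA, with a direction vector
#' toward the nearest receptor partner); opposite-charge pairs at <= 8.0
#' angstrom (ligand negative -> NegIon, positive -> PosIon); and a
#' hydrophobic feature at the centroid of the ligand's hydrophobic atoms
#' when a receptor hydrophobic atom lies within 5.5 angstrom. Annotated
#' water atoms on the receptor side act as ordinary partners, which covers
#' bridging-water hydrogen bonds.
#'
#' @param pose the template [pose()].
#' @param site the [binding_site()].
#' @param annotations an [atom_annotations()] table covering both sides.
#' @param cutoffs named distances in angstrom.
#' @return data.frame of candidate features (possibly 0 rows).
#' @export
detect_interactions <- function(pose, site, annotations,
                                cutoffs = c(hbond = 4.0, charge = 8.0,
                                            hydrophobic = 5.5)) {
  out <- list()
  pair_rule <- function(lig_role, rec_role, kind, cutoff, vectored) {
    L <- .annot_positions(annotations, pose, site, "ligand", lig_role)
    R <- .annot_positions(annotations, pose, site, "receptor", rec_role)
    if (!nrow(L) || !nrow(R)) return()
    D <- .cross_dist(L, R)
    for (i in seq_len(nrow(L))) {
      j <- which.min(D[i, ])
      if (D[i, j] <= cutoff) {
        dirn <- if (vectored) {
          v <- R[j, ] - L[i, ]
          v / max(sqrt(sum(v^2)), 1e-9)
        } else c(NA_real_, NA_real_, NA_real_)
        out[[length(out) + 1L]] <<- .candidate(kind, L[i, ], dirn, D[i, j])
      }
    }
  }
  pair_rule("hb_donor", "hb_acceptor", "HBD", cutoffs[["hbond"]], TRUE)
  pair_rule("hb_acceptor", "hb_donor", "HBA", cutoffs[["hbond"]], TRUE)
  pair_rule("neg_charged", "pos_charged", "NegIon", cutoffs[["charge"]], FALSE)
  pair_rule("pos_charged", "neg_charged", "PosIon", cutoffs[["charge"]], FALSE)
  Lh <- .annot_positions(annotations, pose, site, "ligand", "hydrophobic")
  Rh <- .annot_positions(annotations, pose, site, "receptor", "hydrophobic")
  if (nrow(Lh) && nrow(Rh)) {
    centroid <- colMeans(Lh)
    d <- min(.cross_dist(matrix(centroid, 1), Rh))
    if (d <= cutoffs[["hydrophobic"]])
      out[[length(out) + 1L]] <- .candidate("Hbic", centroid,
                                            c(NA_real_, NA_real_, NA_real_), d)
  }
  if (!length(out))
    return(data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), dx = numeric(0), dy = numeric(0),
                      dz = numeric(0), distance = numeric(0)))
  do.call(rbind, out)
}

#' Build a pharmacophore model from candidate features
#'
#' Candidates closer than `min_interfeature` are merged (centroid position,
#' the higher-priority kind, the shorter interaction distance). If more than
#' `n_range[2]` remain, the top candidates by priority (ionic > H-bond >
#' hydrophobic, ties by shorter interaction distance) are kept; fewer than
#' `n_range[1]` is an error carrying the candidate dump.
#'
#' @param candidates data.frame from [detect_interactions()].
#' @param n_range allowed feature-count range.
#' @param min_interfeature minimum distance between features in angstrom.
#' @param source_pose_id pose id recorded in the model.
#' @param tolerance_radius feature tolerance sphere in angstrom.
#' @return A `pharmacophore_model`: list of `features` (data.frame),
#'   `source_pose_id`, `generation_params`.
#' @export
build_model <- function(candidates, n_range = c(4L, 6L),
                        min_interfeature = 1.0, source_pose_id = NA_character_,
                        tolerance_radius = 1.5) {
  feats <- candidates
  # iterative closest-pair merging below the interfeature minimum
  repeat {
    if (nrow(feats) < 2L) break
    P <- as.matrix(feats[, c("x", "y", "z")])
    D <- .cross_dist(P, P)
    diag(D) <- Inf
    mn <- which(D == min(D), arr.ind = TRUE)[1, ]
    if (D[mn[1], mn[2]] >= min_interfeature) break
    i <- mn[1]; j <- mn[2]
    pick <- if (.kind_priority[feats$kind[i]] <= .kind_priority[feats$kind[j]])
      i else j
    merged <- feats[pick, ]
    merged[, c("x", "y", "z")] <- (P[i, ] + P[j, ]) / 2
    merged$distance <- min(feats$distance[c(i, j)])
    feats <- rbind(feats[-c(i, j), ], merged)
  }
  if (nrow(feats) < n_range[1]) {
    cond <- structure(class = c("posevote_model_too_small", "error",
                                "condition"),
                      list(message = sprintf(
                        "model-too-small error: %d candidate feature(s) after merging (need >= %d)",
                        nrow(feats), n_range[1]),
                        call = sys.call(-1), candidates = feats))
    stop(cond)
  }
  ord <- order(.kind_priority[feats$kind], feats$distance)
  feats <- feats[ord, , drop = FALSE]
  if (nrow(feats) > n_range[2]) feats <- feats[seq_len(n_range[2]), ,
                                               drop = FALSE]
  feats$tolerance_radius <- tolerance_radius
  rownames(feats) <- NULL
  structure(list(features = feats, source_pose_id = source_pose_id,
                 generation_params = list(n_range = n_range,
                                          min_interfeature = min_interfeature,
                                          tolerance_radius = tolerance_radius)),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat(sprintf("<pharmacophore_model> %d features (%s) from pose %s\n",
              nrow(x$features), paste(x$features$kind, collapse = ", "),
              x$source_pose_id))
  invisible(x)
}

#' Serialize a pharmacophore model to JSON
#' @param model pharmacophore_model
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(model, path) {
  payload <- list(source_pose_id = model$source_pose_id,
                  generation_params = model$generation_params,
                  features = model$features)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE)
  invisible(path)
}

.role_for_kind <- c(HBD = "hb_donor", HBA = "hb_acceptor",
                    NegIon = "neg_charged", PosIon = "pos_charged",
                    Hbic = "hydrophobic")

#' Map a conformer onto a pharmacophore model (rigid)
#'
#' Greedy one-to-one assignment, in feature-priority order, of the
#' conformer's annotated atoms (plus its hydrophobic centroid for Hbic
#' features) to features of a compatible kind within `match_tolerance`.
#' A matched feature at distance d contributes `1 - d / (2 * tolerance)`,
#' so the score lies in `[0, n_features]` and the source pose attains the
#' maximum on its own model.
#'
#' @param model a [build_model()] result.
#' @param coords conformer coordinate matrix (n x 3).
#' @param annotations ligand-side [atom_annotations()] for the conformer
#'   (refs are row indices into `coords`).
#' @param match_tolerance matching radius in angstrom.
#' @return list with `score`, `n_matched`, `matches` data.frame.
#' @export
map_compound <- function(model, coords, annotations, match_tolerance = 1.5) {
  feats <- model$features
  lig <- annotations[annotations$side == "ligand", , drop = FALSE]
  points <- list()
  for (r in seq_len(nrow(lig))) {
    idx <- as.integer(lig$ref[r])
    if (is.na(idx) || idx < 1 || idx > nrow(coords)) next
    points[[length(points) + 1L]] <- list(role = lig$role[r],
                                          pos = coords[idx, ])
  }
  hyd <- which(vapply(points, function(p) p$role == "hydrophobic", TRUE))
  if (length(hyd))
    points[[length(points) + 1L]] <- list(
      role = "hydrophobic_centroid",
      pos = colMeans(do.call(rbind, lapply(points[hyd], `[[`, "pos"))))
  if (!length(points))
    return(list(score = 0, n_matched = 0L,
                matches = data.frame(feature = integer(0),
                                     distance = numeric(0))))
  used <- logical(length(points))
  ord <- order(.kind_priority[feats$kind], feats$distance)
  score <- 0
  matches <- list()
  for (fi in ord) {
    want <- .role_for_kind[[feats$kind[fi]]]
    ok_role <- vapply(points, function(p)
      p$role == want ||
        (feats$kind[fi] == "Hbic" && p$role == "hydrophobic_centroid"),
      TRUE)
    cand <- which(ok_role & !used)
    if (!length(cand)) next
    d <- vapply(cand, function(ci)
      sqrt(sum((points[[ci]]$pos -
                  as.numeric(feats[fi, c("x", "y", "z")]))^2)), numeric(1))
    best <- which.min(d)
    if (d[best] <= match_tolerance) {
      used[cand[best]] <- TRUE
      score <- score + (1 - d[best] / (2 * match_tolerance))
      matches[[length(matches) + 1L]] <- data.frame(feature = fi,
                                                    distance = d[best])
    }
  }
  list(score = score, n_matched = length(matches),
       matches = if (length(matches)) do.call(rbind, matches)
                 else data.frame(feature = integer(0), distance = numeric(0)))
}
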