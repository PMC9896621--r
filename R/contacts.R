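#' Compute the ligand-receptor contact fingerprint of one pose
#'
#' Bit j is 1 iff the minimum Euclidean distance between any ligand atom and
#' binding-site atom j is at most `cutoff` (boundary inclusive: a distance of
#' exactly 2.5 angstrom is a contact). All atoms participate on both sides,
#' including hydrogens; distances are measured in the shared docking frame
#' with no superposition.
#'
#' @param pose a [pose()].
#' @param site a [binding_site()], the project's fingerprint axis.
#' @param cutoff contact distance in angstrom.
#' @param axis_ids optional project axis to check `site` against.
#' @return A `contact_fingerprint`: named integer 0/1 vector over the site's
#'   atom ids, with attributes `pose_id` and `axis_ids`.
#' @export
compute_lrcf <- function(pose, site, cutoff = 2.5, axis_ids = NULL) {
  if (cutoff <= 0) stop("compute_lrcf: cutoff must be positive")
  ids <- site_atom_ids(site)
  if (!is.null(axis_ids) && !identical(ids, axis_ids))
    stop("axis error: binding site does not match the project fingerprint axis")
  bits <- cpp_contact_bits(pose$coords, site_coords(site), cutoff)
  names(bits) <- ids
  structure(bits, pose_id = pose$pose_id, axis_ids = ids,
            class = "contact_fingerprint")
}

#' Build the pose-by-site-atom fingerprint matrix
#'
#' Row i is the contact fingerprint of pose i; column order equals the
#' binding-site atom ids. The matrix (0/1, poses in rows) is the
#' descriptor block fed to the machine-learning stage.
#'
#' @param poses list of [pose()] objects sharing the project axis.
#' @param site the [binding_site()].
#' @param cutoff contact distance in angstrom.
#' @return integer matrix with pose ids as rownames, atom ids as colnames.
#' @export
build_fingerprint_matrix <- function(poses, site, cutoff = 2.5) {
  ids <- site_atom_ids(site)
  n <- length(poses)
  mat <- matrix(0L, nrow = n, ncol = length(ids),
                dimnames = list(vapply(poses, `[[`, "", "pose_id"), ids))
  sc <- site_coords(site)
  for (i in seq_len(n))
    mat[i, ] <- cpp_contact_bits(poses[[i]]$coords, sc, cutoff)
  if (anyDuplicated(rownames(mat)))
    stopf("duplicate pose_id in fingerprint matrix: %s",
          rownames(mat)[duplicated(rownames(mat))][1])
  mat
}

#' Write a fingerprint matrix as a dense 0/1 CSV
#' @param mat matrix from [build_fingerprint_matrix()]
#' @param path output CSV
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(mat, path) {
  df <- data.frame(pose_id = rownames(mat), mat, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
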