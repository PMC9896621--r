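#' Binding-site constructor
#'
#' A binding site is the ordered list of receptor atoms that defines the
#' contact-fingerprint axis. Atom identities follow the convention
#' `"RESNAME RESNUM ATOMNAME"` with PDB atom names verbatim (hydrogen names
#' as they appear in the file); the chain id is appended only when the same
#' residue number occurs in more than one chain.
#'
#' @param atoms data.frame with columns `atom_name`, `residue_name`,
#'   `residue_number`, `chain_id`, `element`, `x`, `y`, `z`.
#' @return A `binding_site` object (data.frame plus `atom_ids` attribute).
#' @export
binding_site <- function(atoms) {
  req <- c("atom_name", "residue_name", "residue_number", "chain_id",
           "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stopf("binding_site: missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty-site error: selection matched no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("binding_site: non-finite coordinates")
  atoms$element <- toupper(trimws(atoms$element))
  if (any(!nzchar(atoms$element))) stop("binding_site: empty element")
  atoms$is_hydrogen <- atoms$element == "H"

  ids <- paste(atoms$residue_name, atoms$residue_number, atoms$atom_name)
  res_key <- paste(atoms$residue_name, atoms$residue_number)
  # residue numbering collision across chains -> disambiguate with chain id
  chain_per_res <- tapply(atoms$chain_id, res_key, function(ch)
    length(unique(ch)))
  clash <- names(chain_per_res)[chain_per_res > 1]
  if (length(clash)) {
    hit <- res_key %in% clash
    ids[hit] <- paste(ids[hit], atoms$chain_id[hit])
  }
  if (anyDuplicated(ids))
    stopf("binding_site: duplicate atom ids (e.g. %s)", ids[duplicated(ids)][1])
  rownames(atoms) <- NULL
  attr(atoms, "atom_ids") <- ids
  class(atoms) <- c("binding_site", "data.frame")
  atoms
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("<binding_site> %d atoms (%d hydrogens, %d water atoms)\n",
              nrow(x), sum(x$is_hydrogen), sum(x$residue_name == "HOH")))
  invisible(x)
}

#' Atom identifiers of a binding site
#' @param site binding_site
#' @return character vector, the fingerprint axis
#' @export
site_atom_ids <- function(site) attr(site, "atom_ids")

site_coords <- function(site) as.matrix(site[, c("x", "y", "z")])

.parse_pdb_atoms <- function(lines) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  ln <- lines[sel]
  if (!length(ln)) return(NULL)
  num <- function(s) suppressWarnings(as.numeric(s))
  atom_name <- trimws(substr(ln, 13, 16))
  residue_name <- trimws(substr(ln, 18, 20))
  chain_id <- trimws(substr(ln, 22, 22))
  residue_number <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
  x <- num(substr(ln, 31, 38))
  y <- num(substr(ln, 39, 46))
  z <- num(substr(ln, 47, 54))
  element <- toupper(trimws(substr(ln, 77, 78)))
  guess <- toupper(substr(gsub("^[0-9']+", "", atom_name), 1, 1))
  element <- ifelse(nzchar(element), element, guess)
  if (any(is.na(x) | is.na(y) | is.na(z)))
    stop("format error: unparsable PDB coordinate field")
  data.frame(atom_name = atom_name, residue_name = residue_name,
             residue_number = residue_number, chain_id = chain_id,
             element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

#' Read a receptor PDB file into a binding site
#'
#' Atom order equals file order restricted to the selection; waters
#' (residue name HOH) are retained, hydrogens are read as-is (never added).
#'
#' @param path PDB file.
#' @param site_definition `NULL`/`"all"` for all atoms; a list
#'   `list(residues = c("SER 613", "HOH 32"))` for an explicit residue list;
#'   or `list(center = c(x, y, z), radius = r)` for an inclusive sphere.
#' @return A [binding_site()].
#' @export
read_receptor <- function(path, site_definition = NULL) {
  lines <- readLines(path, warn = FALSE)
  atoms <- .parse_pdb_atoms(lines)
  if (is.null(atoms)) stop("format error: no ATOM/HETATM records found")
  keep <- .select_atoms(atoms, site_definition)
  if (!any(keep)) stop("empty-site error: selection matched no atoms")
  binding_site(atoms[keep, , drop = FALSE])
}

.select_atoms <- function(atoms, spec) {
  if (is.null(spec) || identical(spec, "all")) return(rep(TRUE, nrow(atoms)))
  if (!is.null(spec$residues)) {
    key <- paste(atoms$residue_name, atoms$residue_number)
    return(key %in% spec$residues)
  }
  if (!is.null(spec$center)) {
    if (is.null(spec$radius)) stop("site_definition: sphere needs a radius")
    d2 <- (atoms$x - spec$center[1])^2 + (atoms$y - spec$center[2])^2 +
      (atoms$z - spec$center[3])^2
    return(d2 <= spec$radius^2)
  }
  stop("site_definition: expected 'all', $residues or $center/$radius")
}

#' Docked-pose constructor
#'
#' @param compound_id compound identifier shared by all poses of a molecule.
#' @param pose_id unique pose identifier.
#' @param coords n x 3 numeric matrix of coordinates (angstrom), docking frame.
#' @param element character vector of element symbols.
#' @param source_engine optional docking-engine label.
#' @return A `pose` object.
#' @export
pose <- function(compound_id, pose_id, coords, element,
                 source_engine = NA_character_) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (nrow(coords) < 1L) stop("pose: needs at least one atom")
  if (!all(is.finite(coords))) stop("pose: non-finite coordinates")
  if (length(element) != nrow(coords))
    stop("pose: element/coords length mismatch")
  element <- toupper(trimws(element))
  structure(list(compound_id = as.character(compound_id),
                 pose_id = as.character(pose_id),
                 coords = coords, element = element,
                 is_hydrogen = element == "H",
                 source_engine = source_engine),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> %s (%s): %d atoms\n", x$pose_id, x$compound_id,
              nrow(x$coords)))
  invisible(x)
}

.parse_sdf <- function(lines, id_field) {
  recs <- split(lines, cumsum(c(0L, head(lines, -1) == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    title <- trimws(rec[1])
    counts <- rec[4]
    v3000 <- grepl("V3000", counts)
    if (v3000) {
      al <- grep("^M  V30 [0-9]+ ", rec, value = TRUE)
      flds <- strsplit(trimws(sub("^M  V30 ", "", al)), "\\s+")
      natoms <- length(flds)
      if (natoms) {
        element <- vapply(flds, `[`, "", 2L)
        coords <- t(vapply(flds, function(f) as.numeric(f[3:5]), numeric(3)))
      } else coords <- matrix(0, 0, 3)
    } else {
      natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
      if (is.na(natoms)) stop("format error: bad SDF counts line")
      if (natoms > 0) {
        al <- rec[5:(4 + natoms)]
        x <- as.numeric(substr(al, 1, 10))
        y <- as.numeric(substr(al, 11, 20))
        z <- as.numeric(substr(al, 21, 30))
        element <- trimws(substr(al, 32, 34))
        coords <- cbind(x, y, z)
      } else coords <- matrix(0, 0, 3)
    }
    props <- .sdf_properties(rec)
    out[[length(out) + 1L]] <- list(
      title = title, natoms = natoms, coords = coords,
      element = if (natoms) element else character(0), props = props)
  }
  out
}

.sdf_properties <- function(rec) {
  tag_idx <- grep("^> *<.+>", rec)
  props <- list()
  for (i in tag_idx) {
    tag <- sub("^> *<([^>]+)>.*$", "\\1", rec[i])
    val <- if (i + 1 <= length(rec)) trimws(rec[i + 1]) else ""
    props[[tag]] <- val
  }
  props
}

#' Read docked poses from an SD file or a multi-model PDB
#'
#' One pose per SDF record or PDB MODEL block. The compound id is taken from
#' the SDF tag named by `id_field` (falling back to the record title) or, for
#' PDB input, from the COMPND record / file name. Missing pose ids are
#' assigned as `"<compound_id>#<ordinal>"`.
#'
#' @param path SD file (V2000/V3000) or multi-model PDB.
#' @param id_field SDF property tag holding the compound id.
#' @param pose_id_field optional SDF property tag holding an explicit pose id.
#' @return list of [pose()] objects.
#' @export
read_poses <- function(path, id_field = "COMPOUND_ID",
                       pose_id_field = "POSE_ID") {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(list())
  is_pdb <- any(grepl("^(ATOM  |HETATM|MODEL)", lines))
  is_sdf <- any(lines == "$$$$") || any(grepl("V2000|V3000", lines))
  poses <- list()
  counter <- new.env(parent = emptyenv())
  next_ordinal <- function(cid) {
    n <- (get0(cid, envir = counter) %||% 0L) + 1L
    assign(cid, n, envir = counter)
    n
  }
  if (is_sdf) {
    for (rec in .parse_sdf(lines, id_field)) {
      cid <- rec$props[[id_field]] %||%
        (if (nzchar(rec$title)) rec$title else NA_character_)
      if (is.na(cid)) stop("format error: SDF record without compound id")
      if (rec$natoms == 0L) {
        warnf("skipping zero-atom record for compound %s", cid)
        next
      }
      pid <- rec$props[[pose_id_field]] %||%
        sprintf("%s#%d", cid, next_ordinal(cid))
      poses[[length(poses) + 1L]] <- pose(cid, pid, rec$coords, rec$element)
    }
  } else if (is_pdb) {
    cid <- {
      comp <- grep("^COMPND", lines, value = TRUE)
      if (length(comp)) trimws(substr(comp[1], 11, 80))
      else sub("\\.[^.]*$", "", basename(path))
    }
    starts <- grep("^MODEL", lines)
    if (!length(starts)) {
      blocks <- list(lines)
    } else {
      ends <- grep("^ENDMDL", lines)
      blocks <- mapply(function(s, e) lines[s:e], starts, ends,
                       SIMPLIFY = FALSE)
    }
    for (blk in blocks) {
      at <- .parse_pdb_atoms(blk)
      if (is.null(at)) {
        warnf("skipping zero-atom model for compound %s", cid)
        next
      }
      pid <- sprintf("%s#%d", cid, next_ordinal(cid))
      poses[[length(poses) + 1L]] <- pose(cid, pid,
                                          as.matrix(at[, c("x", "y", "z")]),
                                          at$element)
    }
  } else stop("format error: not an SD file or PDB")
  ids <- vapply(poses, `[[`, "", "pose_id")
  if (anyDuplicated(ids))
    stopf("duplicate pose_id: %s", ids[duplicated(ids)][1])
  poses
}

#' Score-table constructor
#'
#' @param df data.frame with a `pose_id` column plus one numeric column per
#'   scoring function.
#' @param directions named character vector mapping every score column to
#'   `"higher_better"` or `"lower_better"`.
#' @return A `score_table` object.
#' @export
score_table <- function(df, directions) {
  if (!"pose_id" %in% names(df)) stop("score_table: missing pose_id column")
  score_cols <- setdiff(names(df), "pose_id")
  if (!length(score_cols)) stop("score_table: no score columns")
  miss <- setdiff(score_cols, names(directions))
  if (length(miss))
    stopf("config error: no ranking direction for column(s): %s",
          paste(miss, collapse = ", "))
  bad <- !directions[score_cols] %in% c("higher_better", "lower_better")
  if (any(bad))
    stopf("config error: direction must be higher_better/lower_better")
  df$pose_id <- as.character(df$pose_id)
  for (cl in score_cols) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  drop <- !stats::complete.cases(df[, score_cols, drop = FALSE])
  if (any(drop)) {
    warnf("dropping %d pose(s) with missing/non-numeric scores: %s",
          sum(drop), paste(head(df$pose_id[drop], 5), collapse = ", "))
    df <- df[!drop, , drop = FALSE]
  }
  if (anyDuplicated(df$pose_id))
    stopf("score_table: duplicate pose_id %s",
          df$pose_id[duplicated(df$pose_id)][1])
  rownames(df) <- NULL
  attr(df, "directions") <- directions[score_cols]
  class(df) <- c("score_table", "data.frame")
  df
}

#' Read a per-pose score CSV into a score table
#'
#' Poses with blank or non-numeric cells are dropped with a warning; a pose
#' absent from the score table later collects zero consensus votes.
#'
#' @param path CSV with header `pose_id,<score>,...`.
#' @param directions named vector, see [score_table()].
#' @return A [score_table()].
#' @export
read_scores <- function(path, directions) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  score_table(df, directions)
}

#' Read a compound activity CSV
#'
#' @param path CSV with columns `compound_id`, `smiles`, `ic50_nM` (blank
#'   ic50 allowed for screening hits).
#' @param active_max,inactive_min class cutoffs in nM, see [assign_class()].
#' @return data.frame with an added `activity_class` column.
#' @export
read_activities <- function(path, active_max = 5000, inactive_min = 20000) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "ic50_nM") %in% names(df)))
    stop("format error: activities CSV needs compound_id and ic50_nM")
  df$compound_id <- as.character(df$compound_id)
  df$ic50_nM <- suppressWarnings(as.numeric(df$ic50_nM))
  df$activity_class <- "unknown"
  known <- !is.na(df$ic50_nM)
  if (any(known))
    df$activity_class[known] <- assign_class(df$ic50_nM[known], active_max,
                                             inactive_min)
  df
}

# ---- writers (also used by the fixture generator) ----

#' Write a binding site as a PDB file
#' @param site binding_site
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_receptor_pdb <- function(site, path) {
  rec <- ifelse(site$residue_name == "HOH", "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(site$atom_name) < 4,
                  sprintf(" %-3s", site$atom_name),
                  sprintf("%-4s", site$atom_name))
  lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(site)), name4, site$residue_name,
                   site$chain_id, site$residue_number, site$x, site$y,
                   site$z, 1, 0, site$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write poses as an SD file (V2000)
#' @param poses list of pose objects
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_poses_sdf <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    n <- nrow(p$coords)
    writeLines(c(p$pose_id, "  posevote", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L)),
               con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       p$coords[, 1], p$coords[, 2], p$coords[, 3],
                       p$element), con)
    writeLines(c("M  END",
                 "> <COMPOUND_ID>", p$compound_id, "",
                 "> <POSE_ID>", p$pose_id, "",
                 "$$$$"), con)
  }
  invisible(path)
}
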