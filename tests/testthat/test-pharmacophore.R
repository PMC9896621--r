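# Hand-placed geometries: a site atom at the origin and ligand atoms moved
# along x to probe each distance rule.

ph_site <- function() {
  toy_site(rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0), c(60, 0, 0)),
           resnames = c("SER", "ARG", "VAL", "GLU"),
           atom_names = c("OG", "NH1", "CG1", "OE1"),
           elements = c("O", "N", "C", "O"))
}

ph_ann <- function(lig_roles, rec = TRUE) {
  ann <- atom_annotations(rep("ligand", length(lig_roles)),
                          as.character(seq_along(lig_roles)), lig_roles)
  if (rec)
    ann <- rbind(ann, atom_annotations(
      rep("receptor", 4),
      c("SER 1 OG", "ARG 2 NH1", "VAL 3 CG1", "GLU 4 OE1"),
      c("hb_acceptor", "pos_charged", "hydrophobic", "neg_charged")))
  ann
}

test_that("distance rules: hydrogen bond 4.0, charge 8.0, hydrophobic 5.5", {
  site <- ph_site()
  ann <- ph_ann(c("hb_donor", "neg_charged", "hydrophobic"))
  mk <- function(d_hb, d_chg, d_hyd)
    toy_pose(rbind(c(d_hb, 0, 0), c(20 - d_chg, 0, 0), c(40 - d_hyd, 0, 0)))
  cand <- detect_interactions(mk(3.5, 7.9, 5.0), site, ann)
  expect_setequal(cand$kind, c("HBD", "NegIon", "Hbic"))
  expect_equal(cand$x[cand$kind == "HBD"], 3.5)  # ligand-side anchor
  # beyond each cutoff the candidate disappears
  expect_false("HBD" %in% detect_interactions(mk(4.5, 7.9, 5.0), site,
                                              ann)$kind)
  expect_false("NegIon" %in% detect_interactions(mk(3.5, 8.1, 5.0), site,
                                                 ann)$kind)
  expect_false("Hbic" %in% detect_interactions(mk(3.5, 7.9, 5.6), site,
                                               ann)$kind)
  # boundaries inclusive
  b <- detect_interactions(mk(4.0, 8.0, 5.5), site, ann)
  expect_setequal(b$kind, c("HBD", "NegIon", "Hbic"))
  # H-bond direction points at the receptor partner
  expect_equal(cand[cand$kind == "HBD", c("dx", "dy", "dz")],
               data.frame(dx = -1, dy = 0, dz = 0),
               ignore_attr = TRUE)
})

test_that("ligand-side role names the feature kind", {
  site <- ph_site()
  p <- toy_pose(rbind(c(3.5, 0, 0)))
  hba <- detect_interactions(p, site, rbind(
    atom_annotations("ligand", "1", "hb_acceptor"),
    atom_annotations("receptor", "SER 1 OG", "hb_donor")))
  expect_equal(hba$kind, "HBA")
  # GLU 4 OE1 sits at x = 60: 45 is out of the 8.0 range, 53 is inside
  pos <- detect_interactions(toy_pose(rbind(c(45, 0, 0))), site, rbind(
    atom_annotations("ligand", "1", "pos_charged"),
    atom_annotations("receptor", "GLU 4 OE1", "neg_charged")))
  expect_equal(nrow(pos), 0L)
  pos2 <- detect_interactions(toy_pose(rbind(c(53, 0, 0))), site, rbind(
    atom_annotations("ligand", "1", "pos_charged"),
    atom_annotations("receptor", "GLU 4 OE1", "neg_charged")))
  expect_equal(pos2$kind, "PosIon")
})

test_that("model building: counts, merging, priority truncation, errors", {
  cand5 <- data.frame(kind = c("HBD", "HBA", "NegIon", "Hbic", "HBA"),
                      x = c(0, 3, 6, 9, 12), y = 0, z = 0,
                      dx = NA_real_, dy = NA_real_, dz = NA_real_,
                      distance = c(2, 3, 5, 4, 3.5))
  m5 <- build_model(cand5, source_pose_id = "p#1")
  expect_equal(nrow(m5$features), 5)
  # two candidates 0.5 apart merge into one (centroid, higher priority kind)
  cand_merge <- cand5
  cand_merge$x[2] <- 0.5
  cand_merge$kind[2] <- "Hbic"
  mm <- build_model(cand_merge, source_pose_id = "p#1")
  expect_equal(nrow(mm$features), 4)
  expect_true("HBD" %in% mm$features$kind)
  expect_false("Hbic" %in% mm$features$kind[mm$features$x < 1])
  expect_equal(min(mm$features$x), 0.25)
  # 8 candidates -> 6 kept, ionic before hydrophobic
  cand8 <- data.frame(kind = c("NegIon", "PosIon", "HBD", "HBA", "Hbic",
                               "Hbic", "HBD", "HBA"),
                      x = seq(0, 35, 5), y = 0, z = 0,
                      dx = NA_real_, dy = NA_real_, dz = NA_real_,
                      distance = c(5, 6, 2, 3, 4, 4.5, 2.5, 3.5))
  m8 <- build_model(cand8)
  expect_equal(nrow(m8$features), 6)
  expect_equal(sum(m8$features$kind == "Hbic"), 0)  # lowest priority dropped
  expect_equal(m8$features$kind[1:2], c("NegIon", "PosIon"))
  err <- tryCatch(build_model(cand5[1:3, ]), error = function(e) e)
  expect_s3_class(err, "posevote_model_too_small")
  expect_equal(nrow(err$candidates), 3)
})

test_that("pairwise feature distances respect the interfeature minimum", {
  posevote:::with_seed(14, {
    for (rep in 1:10) {
      n <- 8
      cand <- data.frame(kind = sample(c("HBD", "HBA", "NegIon", "Hbic"), n,
                                       TRUE),
                         x = runif(n, 0, 6), y = runif(n, 0, 6),
                         z = runif(n, 0, 6),
                         dx = NA_real_, dy = NA_real_, dz = NA_real_,
                         distance = runif(n, 1, 5))
      m <- tryCatch(build_model(cand), error = function(e) NULL)
      if (is.null(m)) next
      P <- as.matrix(m$features[, c("x", "y", "z")])
      D <- as.matrix(dist(P))
      expect_true(all(D[upper.tri(D)] >= 1.0 - 1e-9))
      expect_true(nrow(m$features) >= 4 && nrow(m$features) <= 6)
    }
  })
})

test_that("self-match attains the maximum score; empty conformers score 0", {
  site <- ph_site()
  ann <- ph_ann(c("hb_donor", "neg_charged", "hydrophobic", "hb_donor"))
  p <- toy_pose(rbind(c(3.5, 0, 0), c(13, 0, 0), c(36, 0, 0), c(1, 2, 0)))
  cand <- detect_interactions(p, site, ann)
  m <- build_model(cand, source_pose_id = p$pose_id)
  self <- map_compound(m, p$coords, ann)
  expect_equal(self$score, nrow(m$features))
  expect_equal(self$n_matched, nrow(m$features))
  none <- map_compound(m, p$coords,
                       atom_annotations(character(0), character(0),
                                        character(0)))
  expect_equal(none$score, 0)
  # a conformer matching exactly one feature
  one <- map_compound(m, rbind(c(3.5, 0, 0), c(90, 0, 0), c(95, 0, 0),
                               c(99, 0, 0)), ann)
  expect_equal(one$n_matched, 1L)
  expect_true(one$score > 0 && one$score <= 1)
})

test_that("rigid motion leaves the model congruent", {
  site <- ph_site()
  ann <- ph_ann(c("hb_donor", "neg_charged", "hydrophobic", "hb_donor"))
  p <- toy_pose(rbind(c(3.5, 0, 0), c(13, 0, 0), c(36, 0, 0), c(1, 2, 0)))
  m1 <- build_model(detect_interactions(p, site, ann))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(5, -3, 2)
  rot <- function(M) sweep(M %*% t(R), 2, -tr)
  site2 <- toy_site(rot(posevote:::site_coords(site)),
                    resnames = site$residue_name,
                    atom_names = site$atom_name, elements = site$element)
  p2 <- toy_pose(rot(p$coords))
  m2 <- build_model(detect_interactions(p2, site2, ann))
  d1 <- dist(as.matrix(m1$features[, c("x", "y", "z")]))
  d2 <- dist(as.matrix(m2$features[, c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-6)
  expect_equal(m1$features$kind, m2$features$kind)
})

test_that("pharmacophore JSON serialization is deterministic", {
  cand <- data.frame(kind = c("HBD", "HBA", "NegIon", "Hbic"),
                     x = c(0, 3, 6, 9), y = 0.25, z = -1,
                     dx = c(1, NA, NA, NA), dy = c(0, NA, NA, NA),
                     dz = c(0, NA, NA, NA), distance = c(2, 3, 5, 4))
  m <- build_model(cand, source_pose_id = "p#9")
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_pharmacophore(m, f1)
  write_pharmacophore(m, f2)
  expect_identical(readLines(f1), readLines(f2))
  js <- jsonlite::read_json(f1)
  expect_equal(js$source_pose_id, "p#9")
  expect_length(js$features, 4)
})
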