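#' Run the full pipeline on a fixture world and report signal recovery
#'
#' Chains contacts -> consensus voting -> RMSD deduplication -> every-fifth
#' split -> genetic descriptor selection -> final model -> SHAP consistency
#' filter -> active-pose-ratio threshold, and reports whether the planted
#' contact descriptors were recovered in the SHAP-consistent set. When
#' `build_pharmacophore` is set, the template pose of the most potent active
#' testing compound is translated into a pharmacophore model as well.
#'
#' @param config a [fixture_config()] (or a pre-generated fixture list).
#' @param min_votes consensus level a pose must reach to enter modeling.
#' @param learner `"xgb"` or `"rf"` for selection fitness and final model.
#' @param preset GA phase-2 schedule, `"desk"` or `"full"`.
#' @param shap_k k-means background size.
#' @param n_perm SHAP sampling permutations.
#' @param do_shap compute the SHAP consistency stage (skippable for
#'   null-calibration runs that only need the test kappa).
#' @param build_pharmacophore attempt pharmacophore extraction.
#' @return list of class `recovery_report`; see fields in the source.
#' @export
end_to_end_recovery <- function(config, min_votes = 1L, learner = "xgb",
                                preset = "desk", shap_k = 100L,
                                n_perm = 20L, do_shap = TRUE,
                                build_pharmacophore = FALSE) {
  fx <- if (inherits(config, "fixture_config")) generate_fixtures(config)
        else config
  cfg <- fx$config
  seed <- cfg$seed

  fp <- build_fingerprint_matrix(fx$poses, fx$site)
  votes <- consensus_votes(fx$scores)
  kept1 <- filter_by_consensus(fx$poses, votes, min_votes)

  by_cmp <- split(kept1, vapply(kept1, `[[`, "", "compound_id"))
  kept_ids <- unlist(lapply(by_cmp, function(pl)
    dedup_poses(pl, votes)$kept), use.names = FALSE)
  kept2 <- kept1[vapply(kept1, `[[`, "", "pose_id") %in% kept_ids]

  compound_of <- vapply(kept2, `[[`, "", "compound_id")
  names(compound_of) <- vapply(kept2, `[[`, "", "pose_id")
  fm <- feature_matrix(fp[names(compound_of), , drop = FALSE], fx$scores,
                       fx$activities, compound_of)

  cmp_present <- unique(fm$compound_of)
  cmp_df <- fx$activities[fx$activities$compound_id %in% cmp_present,
                          c("compound_id", "activity_class")]
  split_a <- split_every_fifth(cmp_df, seed = child_seed(seed, 5L))

  train <- fm_subset(fm, split_a$training_compounds, drop_intermediates = TRUE)
  test <- fm_subset(fm, split_a$testing_compounds, drop_intermediates = TRUE)

  sel <- two_phase_select(train, learner = learner,
                          seed = child_seed(seed, 9L), preset = preset)
  model <- lrn_fit(learner, train$X[, sel$descriptors, drop = FALSE],
                   train$labels, seed = child_seed(seed, 13L))
  pred_test <- lrn_predict_class(model, test$X[, sel$descriptors,
                                               drop = FALSE])
  names(pred_test) <- rownames(test$X)
  cm <- confusion_counts(test$labels, pred_test,
                         c("active", "inactive"))
  kappa_test <- cohens_kappa(cm)

  planted_ids <- site_atom_ids(fx$site)[cfg$planted_contact_ids]
  report <- list(descriptors = sel$descriptors,
                 fitness = sel$fitness,
                 kappa_test = kappa_test,
                 accuracy_test = accuracy(cm),
                 n_train_poses = nrow(train$X), n_test_poses = nrow(test$X),
                 planted_ids = planted_ids,
                 planted_selected = intersect(sel$descriptors, planted_ids))

  if (do_shap) {
    Xte <- test$X[, sel$descriptors, drop = FALSE]
    bg <- shap_background(Xte, k = shap_k, seed = child_seed(seed, 17L))
    contrib <- shap_values(model, Xte, bg, n_perm = n_perm,
                           seed = child_seed(seed, 19L))
    summ <- summarize_by_class(contrib, test$labels)
    consistent <- filter_consistent(summ)
    report$shap_summary <- summ
    report$consistent <- consistent
    report$planted_recovered <- intersect(consistent, planted_ids)

    # active-pose-ratio threshold from the documented actives of the test set
    rec <- pose_ratio_records(pred_test, test$compound_of)
    doc_active <- fx$activities$compound_id[
      fx$activities$activity_class == "active"]
    rec_act <- rec[rec$compound_id %in% doc_active, , drop = FALSE]
    report$threshold <- tryCatch(derive_threshold(rec_act),
                                 error = function(e) NULL)

    if (build_pharmacophore) {
      te_act <- fx$activities[fx$activities$compound_id %in%
                                test$compound_of &
                                fx$activities$activity_class == "active", ]
      te_act <- te_act[order(te_act$ic50_nM), ]
      report$pharmacophore <- NULL
      for (cid in te_act$compound_id) {
        tp <- select_template_pose(cid, contrib, test$compound_of, consistent)
        ppose <- fx$poses[[match(tp, vapply(fx$poses, `[[`, "", "pose_id"))]]
        cand <- detect_interactions(ppose, fx$site, fx$annotations)
        mdl <- tryCatch(build_model(cand, source_pose_id = tp),
                        error = function(e) NULL)
        if (!is.null(mdl)) {
          report$template_pose <- tp
          report$template_compound <- cid
          report$pharmacophore <- mdl
          break
        }
      }
    }
  }
  class(report) <- "recovery_report"
  report
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> kappa_test = %.3f; %d descriptors selected\n",
              x$kappa_test, length(x$descriptors)))
  if (!is.null(x$consistent))
    cat(sprintf("  SHAP-consistent: %d (planted recovered: %d/%d)\n",
                length(x$consistent), length(x$planted_recovered),
                length(x$planted_ids)))
  invisible(x)
}
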