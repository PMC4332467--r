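test_that("confusion metrics match direct arithmetic and flag undefineds", {
  m <- metrics_from_confusion(tp = 9, fp = 2, tn = 8, fn = 1)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)

  perfect <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(unlist(perfect[1:3]), c(accuracy = 1, sensitivity = 1,
                                       specificity = 1))

  none_pos <- metrics_from_confusion(0, 3, 7, 0)
  expect_true(is.na(none_pos$sensitivity))
  expect_false(none_pos$sensitivity_defined)

  expect_error(metrics_from_confusion(0, 0, 0, 0),
               class = "gaitsym_empty_evaluation_error")
  expect_error(metrics_from_confusion(-1, 0, 1, 0),
               class = "gaitsym_domain_error")
})

test_that("balanced folds stratify by side and keep subject pairs intact", {
  pat <- toy_pattern_cohort(60, seed = 1)
  folds <- make_balanced_folds(pat, k = 6, seed = 2)
  tab <- table(folds, as.character(pat$side))
  expect_true(all(tab == 10)) # six folds of 10 right + 10 left

  by_subject <- tapply(folds, pat$subject_id, function(f) length(unique(f)))
  expect_true(all(by_subject == 1))

  expect_identical(folds, make_balanced_folds(pat, k = 6, seed = 2))
  expect_false(identical(folds, make_balanced_folds(pat, k = 6, seed = 3)))

  # leave-pair-out: k equal to the number of subjects
  small <- toy_pattern_cohort(4, seed = 5)
  lpo <- make_balanced_folds(small, k = 4, seed = 1)
  expect_equal(sort(unique(lpo)), 1:4)
  expect_true(all(table(lpo) == 2))

  # pattern-level mode stratifies by side only
  plevel <- make_balanced_folds(pat, k = 6, pairing = "pattern_level",
                                seed = 4)
  expect_true(all(table(plevel, as.character(pat$side)) == 10))

  expect_error(make_balanced_folds(pat[-1, ], k = 6),
               class = "gaitsym_fold_error")
  expect_error(make_balanced_folds(toy_pattern_cohort(7, seed = 1), k = 6),
               class = "gaitsym_fold_error")
})

test_that("huge injected asymmetry is classified perfectly in every mode", {
  cfg <- cohort_config(n_subjects = 60, trials_per_side = 2,
                       within_cv = rep(1, 6), between_cv = rep(1, 6),
                       asymmetry = c(fz1 = 0.3), seed = 44)
  pat <- preprocess_trials(sample_cohort(cfg)$trials)
  for (mode in c("all_101", "six_params", "pca")) {
    for (kern in list(linear_kernel(), rbf_kernel(), poly_kernel(2))) {
      cv <- cross_validate(pat, mode, kernel = kern, cost = 10,
                           repeats = 1, seed = 7)
      expect_equal(cv$accuracy, 1.0)
    }
  }
})

test_that("fold transforms and models never see held-out patterns", {
  pat <- toy_pattern_cohort(12, delta = c(fz1 = 0.05), seed = 9)
  cv1 <- cross_validate(pat, "pca", kernel = linear_kernel(),
                        repeats = 1, seed = 11)

  # corrupt one pattern; with the same seed, decision values of all
  # patterns in OTHER folds must be bit-identical (no leakage through
  # standardizer, PCA basis or SVM)
  corrupted <- pat
  vcols <- sprintf("v%03d", 0:100)
  corrupted[3, vcols] <- as.list(5 * unlist(corrupted[3, vcols]) + 40)
  cv2 <- cross_validate(corrupted, "pca", kernel = linear_kernel(),
                        repeats = 1, seed = 11)

  bad_subject <- pat$subject_id[3]
  bad_fold <- cv1$predictions$fold[cv1$predictions$subject_id == bad_subject][1]
  same_order <- order(paste(cv1$predictions$subject_id, cv1$predictions$side))
  p1 <- cv1$predictions[same_order, ]; p2 <- cv2$predictions[same_order, ]
  # the corrupted pattern sits in the held-out set of its own fold, so the
  # model and transforms for that fold were fitted without it: every other
  # pattern of that fold must score bit-identically
  peers <- p1$fold == bad_fold & p1$subject_id != bad_subject
  expect_identical(p1$decision_value[peers], p2$decision_value[peers])
  expect_true(any(peers))
})

test_that("accuracy is invariant to trial-id relabeling", {
  pat <- toy_pattern_cohort(12, delta = c(fz1 = 0.04), seed = 14)
  cv1 <- cross_validate(pat, "all_101", kernel = linear_kernel(),
                        repeats = 2, seed = 5)
  relabeled <- dplyr::mutate(pat, trial_id = paste0("X", trial_id))
  cv2 <- cross_validate(relabeled, "all_101", kernel = linear_kernel(),
                        repeats = 2, seed = 5)
  expect_equal(cv1$accuracy, cv2$accuracy)
})

test_that("accuracy responds monotonically to the asymmetry magnitude", {
  acc <- vapply(c(0, 0.3), function(delta) {
    cfg <- cohort_config(n_subjects = 12, trials_per_side = 2,
                         asymmetry = c(fz1 = delta, fz3 = delta), seed = 77)
    pat <- preprocess_trials(sample_cohort(cfg)$trials)
    cross_validate(pat, "all_101", kernel = linear_kernel(),
                   repeats = 1, seed = 3)$accuracy
  }, numeric(1))
  expect_lt(acc[1], 0.8) # no signal: near chance
  expect_gt(acc[2], 0.9) # strong signal: near perfect
})

test_that("grid search ranks by accuracy with the documented tie-breaks", {
  cfg <- cohort_config(n_subjects = 6, trials_per_side = 2,
                       within_cv = rep(1, 6), between_cv = rep(1, 6),
                       asymmetry = c(fz1 = 0.3), seed = 20)
  pat <- preprocess_trials(sample_cohort(cfg)$trials)

  single <- grid_search(pat, kernels = list(linear_kernel()), costs = 2,
                        feature_modes = "six_params", k = 3, repeats = 1,
                        seed = 2)
  direct <- cross_validate(pat, "six_params", kernel = linear_kernel(),
                           cost = 2, k = 3, repeats = 1, seed = 2)
  expect_equal(nrow(single), 1)
  expect_equal(single$accuracy, direct$accuracy)

  # separable data: every row at accuracy 1, ranking falls to smaller C
  grid <- grid_search(pat, kernels = list(linear_kernel()),
                      costs = c(10, 0.5), feature_modes = "six_params",
                      k = 3, repeats = 1, seed = 2)
  expect_true(all(grid$accuracy == 1))
  expect_equal(grid$cost, c(0.5, 10))
  expect_error(grid_search(pat, kernels = list()),
               class = "gaitsym_parameter_error")
})

test_that("symmetry score maps accuracy to [0,1] with a permutation p", {
  cfg <- cohort_config(n_subjects = 8, trials_per_side = 2,
                       within_cv = rep(1, 6), between_cv = rep(1, 6),
                       asymmetry = c(fz1 = 0.3), seed = 25)
  pat <- preprocess_trials(sample_cohort(cfg)$trials)
  sc <- symmetry_score(pat, feature_mode = "six_params",
                       kernel = linear_kernel(), k = 4,
                       n_permutations = 19, seed = 6)
  expect_equal(sc$mean_accuracy, 1.0)
  expect_equal(sc$score, 0.0) # perfect separation = maximal asymmetry
  expect_lte(sc$permutation_p, 0.10)
  expect_equal(sc$score, 1 - 2 * max(sc$mean_accuracy - 0.5, 0))
  expect_warning(
    symmetry_score(pat, feature_mode = "six_params", k = 4,
                   kernel = linear_kernel(), n_permutations = 5, seed = 1),
    "19")
})
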