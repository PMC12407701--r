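test_that("a perfectly separable label is learned exactly", {
  fm <- family_feature_matrix()
  labels <- fm$nhr40_autoregulated == 1
  clf <- train_acceptability_classifier(fm, labels, max_depth = 2, seed = 1)
  expect_equal(clf$cv_accuracy, 1.0)
  expect_true(all(predict(clf, fm) == labels))
})

test_that("single-class labels give a majority rule without splitting", {
  fm <- family_feature_matrix()[1:100, ]
  clf <- train_acceptability_classifier(fm, rep(FALSE, 100), seed = 1)
  expect_null(clf$tree)
  expect_equal(clf$cv_accuracy, 1.0)
  expect_false(any(predict(clf, fm)))
})

test_that("depth sweep reports accuracy per depth", {
  fm <- family_feature_matrix()[seq(1, 13824, by = 16), ]
  labels <- fm$eud1_regulated_by_N == 1 & fm$sult1_cooperative == 1
  sw <- sweep_tree_depth(fm, labels, depths = 1:3, seed = 2)
  expect_equal(nrow(sw), 3)
  expect_true(all(sw$cv_accuracy >= 0.5))
  expect_equal(max(sw$cv_accuracy), 1.0) # depth 2+ separates a 2-conjunction
})

test_that("upsampling the minority class is available", {
  fm <- family_feature_matrix()[seq(1, 13824, by = 32), ]
  labels <- fm$eud1_regulated_by_N == 1 & fm$nhr40_any_repression == 1
  clf <- train_acceptability_classifier(fm, labels, upsample_minority = TRUE,
                                        seed = 3)
  expect_s3_class(clf, "grn_classifier")
  expect_gt(clf$cv_accuracy, clf$null_accuracy - 0.05)
})

test_that("extract_model_set equals brute-force filtering", {
  fam <- build_family()
  set <- extract_model_set(function(f) f$nhr40_autoregulated == 1, fam)
  # brute force on a random subset via featurize directly
  set.seed(23)
  idx <- sample(0:13823, 400)
  brute <- idx[vapply(idx, function(i) {
    featurize(model_from_index(fam, i))[["nhr40_autoregulated"]] == 1
  }, logical(1))]
  expect_setequal(intersect(set$indices, idx), brute)
  # trivial predicates
  everything <- extract_model_set(function(f) rep(TRUE, nrow(f)), fam)
  expect_length(everything$indices, 13824)
  # disjoint leaf predicates give disjoint sets
  a <- extract_model_set(function(f) f$eud1_cooperative == 1, fam)
  b <- extract_model_set(function(f) f$eud1_cooperative == 0, fam)
  expect_length(intersect(a$indices, b$indices), 0)
})

test_that("model sets intersect with knock-out projection", {
  fam <- build_family()
  unified <- named_models()$unified
  other <- named_models()$model_11574
  red_e <- reduce_for_knockout(unified, "eud-1")
  red_s <- reduce_for_knockout(unified, "sult-1")
  wt <- grn_model_set(c(unified$model_index, other$model_index),
                      experiment = "WT")
  ko_e <- grn_model_set(red_e$model_index, experiment = "eud1_KO",
                        knockout = "eud-1")
  ko_s <- grn_model_set(red_s$model_index, experiment = "sult1_KO",
                        knockout = "sult-1")
  inter <- intersect_model_sets(list(wt, ko_e, ko_s))
  expect_equal(inter$indices, unified$model_index)
  # intersection with itself is identity
  self <- intersect_model_sets(list(wt, wt))
  expect_equal(self$indices, sort(wt$indices))
  # disjoint sets are empty
  empty <- intersect_model_sets(list(
    grn_model_set(1:3, "WT"), grn_model_set(7:9, "WT")))
  expect_length(empty$indices, 0)
  # same-gene knock-out sets intersect directly
  kk <- intersect_model_sets(list(ko_e, grn_model_set(c(red_e$model_index, 3),
                                                      knockout = "eud-1")))
  expect_equal(kk$indices, red_e$model_index)
  expect_error(intersect_model_sets(list(ko_e, ko_s)), "project")
})

test_that("model sets serialize to JSON and back", {
  s <- grn_model_set(c(5, 1, 9), experiment = "WT", description = "toy")
  path <- withr::local_tempfile(fileext = ".json")
  model_set_to_json(s, path)
  s2 <- model_set_from_json(path)
  expect_equal(s2$indices, c(1, 5, 9))
  expect_equal(s2$experiment, "WT")
})
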