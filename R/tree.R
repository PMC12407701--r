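# Decision-tree classification of acceptability from structural features,
# and model sets with their cross-experiment intersection.

#' Train a decision tree predicting fit acceptability from structure
#'
#' Fits a CART tree (default depth 5) mapping the 21 binary structural
#' features to the acceptable/unacceptable label obtained from the cost
#' curve, and reports mean stratified K-fold cross-validation accuracy. A
#' tree that beats the trivial all-unacceptable baseline (92.8% when 1000 of
#' 13824 structures are acceptable) has found structural signal.
#'
#' @param features tibble of binary features (a `model_index` column, if
#'   present, is ignored by the tree).
#' @param labels logical (or 2-level factor) acceptability labels, one per
#'   row.
#' @param max_depth maximum tree depth.
#' @param criterion split criterion, `"gini"` or `"entropy"`.
#' @param k_folds number of cross-validation folds.
#' @param upsample_minority replicate minority-class rows to balance the
#'   training folds (off by default; tends to overfit).
#' @param seed seed for fold assignment.
#' @return An object of class `grn_classifier`: list with `tree` (an rpart
#'   object, or `NULL` for a single-class majority rule), `cv_accuracy`,
#'   `fold_accuracies`, `majority_class`, `null_accuracy`.
#' @export
train_acceptability_classifier <- function(features, labels, max_depth = 5,
                                           criterion = c("gini", "entropy"),
                                           k_folds = 5,
                                           upsample_minority = FALSE,
                                           seed = 1) {
  criterion <- match.arg(criterion)
  X <- dplyr::select(tibble::as_tibble(features),
                     -dplyr::any_of("model_index"))
  y <- factor(as.logical(labels), levels = c(FALSE, TRUE),
              labels = c("unacceptable", "acceptable"))
  if (length(y) != nrow(X)) abort("one label per feature row is required.")
  majority <- names(which.max(table(y)))
  null_acc <- max(table(y)) / length(y)
  if (length(unique(y)) == 1) {
    out <- list(tree = NULL, cv_accuracy = 1.0, fold_accuracies = 1.0,
                majority_class = majority, null_accuracy = 1.0)
    class(out) <- "grn_classifier"
    return(out)
  }
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 2,
                               minbucket = 1, xval = 0)
  split <- if (criterion == "gini") "gini" else "information"
  df <- X
  df$.label <- y
  fit_one <- function(train_df) {
    if (upsample_minority) {
      tab <- table(train_df$.label)
      minority <- names(which.min(tab))
      extra <- train_df[train_df$.label == minority, ][
        sample.int(min(tab), max(tab) - min(tab), replace = TRUE), ]
      train_df <- rbind(train_df, extra)
    }
    rpart::rpart(.label ~ ., data = train_df, method = "class",
                 parms = list(split = split), control = ctrl)
  }
  # stratified folds
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in levels(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k_folds), length(i)))
  }
  fold_acc <- vapply(seq_len(k_folds), function(f) {
    train <- df[fold != f, ]
    test <- df[fold == f, ]
    tree_f <- fit_one(train)
    pred <- predict(tree_f, test, type = "class")
    mean(pred == test$.label)
  }, numeric(1))
  out <- list(
    tree = fit_one(df), cv_accuracy = mean(fold_acc),
    fold_accuracies = fold_acc, majority_class = majority,
    null_accuracy = as.numeric(null_acc)
  )
  class(out) <- "grn_classifier"
  out
}

#' @export
print.grn_classifier <- function(x, ...) {
  cat("<grn_classifier> CV accuracy ", sprintf("%.3f", x$cv_accuracy),
      " (null ", sprintf("%.3f", x$null_accuracy), ")\n", sep = "")
  invisible(x)
}

#' Predicted acceptability for new feature rows
#' @param object a `grn_classifier`.
#' @param newdata tibble of features.
#' @param ... unused.
#' @return Logical vector, `TRUE` for predicted-acceptable.
#' @export
predict.grn_classifier <- function(object, newdata, ...) {
  newdata <- dplyr::select(tibble::as_tibble(newdata),
                           -dplyr::any_of("model_index"))
  if (is.null(object$tree)) {
    return(rep(object$majority_class == "acceptable", nrow(newdata)))
  }
  predict(object$tree, newdata, type = "class") == "acceptable"
}

#' Sweep the maximum tree depth
#'
#' @inheritParams train_acceptability_classifier
#' @param depths depths to evaluate.
#' @return A tibble with `max_depth` and `cv_accuracy`.
#' @export
sweep_tree_depth <- function(features, labels, depths = 1:10,
                             criterion = "gini", k_folds = 5, seed = 1) {
  purrr::map_dfr(depths, function(d) {
    clf <- train_acceptability_classifier(features, labels, max_depth = d,
                                          criterion = criterion,
                                          k_folds = k_folds, seed = seed)
    tibble::tibble(max_depth = d, cv_accuracy = clf$cv_accuracy)
  })
}

# Model sets -----------------------------------------------------------------

#' Construct a model set
#'
#' A model set is the collection of structures (family indices) that fit an
#' experiment acceptably, typically sharing regulatory features.
#'
#' @param indices 0-based model indices.
#' @param experiment experiment label.
#' @param description free-text description of the defining features.
#' @param knockout the family's knocked-out gene, or `NULL` for wild type.
#' @return An object of class `grn_model_set`.
#' @export
grn_model_set <- function(indices, experiment = "WT", description = "",
                          knockout = NULL) {
  structure(
    list(indices = sort(unique(as.numeric(indices))), experiment = experiment,
         description = description, knockout = knockout),
    class = "grn_model_set"
  )
}

#' @export
print.grn_model_set <- function(x, ...) {
  cat("<grn_model_set> ", x$experiment, ": ", length(x$indices), " models",
      if (nzchar(x$description)) paste0(" (", x$description, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Extract the model set predicted acceptable by a classifier or predicate
#'
#' Enumerates the family's feature matrix and returns every structure whose
#' features are predicted acceptable. Equivalent to brute-force filtering of
#' the full enumeration.
#'
#' @param predictor a `grn_classifier`, an `rpart` tree, or a predicate
#'   function mapping the feature tibble to a logical vector.
#' @param family the wild-type family.
#' @param experiment,description passed to [grn_model_set()].
#' @return A [grn_model_set()].
#' @export
#' @examples
#' fam <- build_family()
#' s <- extract_model_set(function(f) f$nhr40_autoregulated == 1, fam)
#' length(s$indices)  # 6912
extract_model_set <- function(predictor, family = build_family(),
                              experiment = "WT", description = "") {
  feats <- family_feature_matrix(family)
  accept <- if (inherits(predictor, "grn_classifier")) {
    predict(predictor, feats)
  } else if (inherits(predictor, "rpart")) {
    predict(predictor, dplyr::select(feats, -"model_index"),
            type = "class") == "acceptable"
  } else if (is.function(predictor)) {
    as.logical(predictor(feats))
  } else {
    abort("`predictor` must be a classifier, rpart tree, or predicate function.")
  }
  grn_model_set(feats$model_index[accept], experiment = experiment,
                description = description, knockout = family$knockout)
}

#' Intersect model sets across experiments
#'
#' Same-family sets intersect directly. Across experiments, a wild-type
#' structure belongs to the intersection when it lies in every wild-type set
#' and its knock-out reduction lies in the corresponding knock-out
#' experiment's set (a wild-type structure whose reduction is not
#' representable in the knock-out family — e.g. a term collapsing to no
#' regulated production — cannot match).
#'
#' @param sets a list of [grn_model_set()]s including at least one wild-type
#'   set; knock-out sets are projected through [reduce_for_knockout()].
#' @return A wild-type [grn_model_set()].
#' @export
intersect_model_sets <- function(sets) {
  if (!all(vapply(sets, inherits, logical(1), "grn_model_set"))) {
    abort("`sets` must be a list of grn_model_set objects.")
  }
  wt_sets <- purrr::keep(sets, function(s) is.null(s$knockout))
  ko_sets <- purrr::keep(sets, function(s) !is.null(s$knockout))
  if (length(wt_sets) == 0) {
    kos <- unique(vapply(ko_sets, function(s) s$knockout, character(1)))
    if (length(kos) > 1) {
      abort("knock-out sets from different families need a wild-type set to project through.")
    }
    idx <- Reduce(intersect, lapply(ko_sets, function(s) s$indices))
    return(grn_model_set(idx, experiment = "intersection",
                         knockout = kos[[1]]))
  }
  idx <- Reduce(intersect, lapply(wt_sets, function(s) s$indices))
  if (length(ko_sets) > 0) {
    fam <- build_family()
    for (ko in ko_sets) {
      keep <- vapply(idx, function(i) {
        red <- reduce_for_knockout(model_from_index(fam, i), ko$knockout)
        !is.na(red$model_index) && red$model_index %in% ko$indices
      }, logical(1))
      idx <- idx[keep]
    }
  }
  grn_model_set(idx, experiment = "intersection",
                description = paste(vapply(sets, function(s) s$experiment,
                                           character(1)), collapse = " & "))
}

#' Serialize a model set to/from JSON
#' @param set a [grn_model_set()].
#' @param path file path.
#' @return `model_set_to_json` returns `path` invisibly; `model_set_from_json`
#'   the model set.
#' @export
model_set_to_json <- function(set, path) {
  jsonlite::write_json(
    list(experiment = set$experiment, knockout = set$knockout,
         description = set$description, indices = set$indices),
    path, auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' @rdname model_set_to_json
#' @export
model_set_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  grn_model_set(doc$indices, experiment = doc$experiment,
                description = doc$description %||% "",
                knockout = doc$knockout)
}
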