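# Larval-habitat risk classification: a gradient-boosted decision-tree
# binary classifier over the six categorical waterbody features, with a
# fixed probability threshold, stratified cross-validation and normalized
# relative feature importance (RFI).
#
# Backend: xgboost with one-hot encoding of the categorical levels. The
# contract is the algorithm family (boosted trees) plus the config surface,
# not a particular serialization.

RISK_FEATURES <- c("waterbody_type", "origin", "area_size_class",
                   "vegetation_inside", "vegetation_around",
                   "visual_turbidity")

#' Risk-classifier configuration
#'
#' @param max_iterations Maximum boosting iterations (default 1000).
#' @param max_tree_depth Maximum tree depth (default 10).
#' @param early_stopping Stop when the internal 10% validation split has not
#'   improved for `patience` rounds (default TRUE).
#' @param patience Early-stopping patience in iterations (default 50).
#' @param decision_threshold Probability cut-off for a high-risk call,
#'   strictly between 0 and 1 (default 0.5).
#' @param cv_folds Number of stratified cross-validation folds (default 5).
#' @param random_seed Integer seed controlling the validation split, fold
#'   assignment and booster (default 42).
#' @param learning_rate Boosting shrinkage (default 0.1).
#' @return A list of class `lsm_classifier_config`.
#' @export
classifier_config <- function(max_iterations = 1000, max_tree_depth = 10,
                              early_stopping = TRUE, patience = 50,
                              decision_threshold = 0.5, cv_folds = 5,
                              random_seed = 42, learning_rate = 0.1) {
  stopifnot(max_iterations >= 1, max_tree_depth >= 1, cv_folds >= 2,
            decision_threshold > 0, decision_threshold < 1,
            learning_rate > 0)
  structure(list(max_iterations = max_iterations,
                 max_tree_depth = max_tree_depth,
                 early_stopping = early_stopping, patience = patience,
                 decision_threshold = decision_threshold,
                 cv_folds = cv_folds, random_seed = random_seed,
                 learning_rate = learning_rate),
            class = "lsm_classifier_config")
}

# One-hot encode the six categorical features against a stored vocabulary.
# Unseen levels at prediction time are an error: field-data hygiene over
# silent mapping.
encode_features <- function(features, vocab = NULL) {
  missing <- setdiff(RISK_FEATURES, names(features))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(vocab)) {
    vocab <- lapply(RISK_FEATURES, function(f) {
      sort(unique(as.character(features[[f]])))
    })
    names(vocab) <- RISK_FEATURES
  }
  cols <- list()
  for (f in RISK_FEATURES) {
    v <- as.character(features[[f]])
    unseen <- setdiff(unique(v), vocab[[f]])
    if (length(unseen)) {
      stop(sprintf("unseen level(s) for %s: %s", f,
                   paste(unseen, collapse = ", ")), call. = FALSE)
    }
    for (lev in vocab[[f]]) {
      cols[[paste0(f, "=", lev)]] <- as.numeric(v == lev)
    }
  }
  list(matrix = do.call(cbind, cols), vocab = vocab)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  code
}

#' Train the larval-risk classifier
#'
#' Fits a gradient-boosted tree ensemble to binary larval-presence labels
#' (1 = at least one larva observed, high risk; 0 = none, low risk) over
#' the six categorical waterbody features. With `early_stopping`, 10% of
#' the rows (stratified by label) are held out internally and boosting
#' stops once log-loss there has not improved for `patience` rounds.
#' Deterministic given the data and `config$random_seed`.
#'
#' @param features Data.frame containing the six feature columns.
#' @param labels Integer vector of 0/1 labels, both classes present.
#' @param config A [classifier_config()].
#' @return An object of class `lsm_risk_model`.
#' @export
train_risk_model <- function(features, labels, config = classifier_config()) {
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels differ in length", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("both classes must be present in the training labels",
         call. = FALSE)
  }
  enc <- encode_features(features)
  x <- enc$matrix
  params <- list(objective = "binary:logistic",
                 max_depth = config$max_tree_depth,
                 eta = config$learning_rate,
                 nthread = 1, seed = config$random_seed)
  booster <- with_seed(config$random_seed, {
    if (isTRUE(config$early_stopping) && nrow(x) >= 20) {
      val_idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
        sample(ix, max(1, round(0.1 * length(ix))))
      }))
      dtrain <- xgboost::xgb.DMatrix(x[-val_idx, , drop = FALSE],
                                     label = labels[-val_idx])
      dval <- xgboost::xgb.DMatrix(x[val_idx, , drop = FALSE],
                                   label = labels[val_idx])
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = config$max_iterations,
                         evals = list(val = dval),
                         early_stopping_rounds = config$patience,
                         verbose = 0)
    } else {
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(x, label = labels),
                         nrounds = config$max_iterations, verbose = 0)
    }
  })
  structure(list(booster = booster, vocab = enc$vocab, config = config,
                 feature_names = colnames(x)),
            class = "lsm_risk_model")
}

#' Predict larval risk for new waterbodies
#'
#' Returns the model probability and the high/low call at the configured
#' decision threshold (high iff probability >= threshold). Category levels
#' not seen at training raise an error naming the level.
#'
#' @param model An `lsm_risk_model` from [train_risk_model()].
#' @param features Data.frame with the six feature columns.
#' @param threshold Optional override of the config decision threshold;
#'   may be 0 (everything high) or 1 (high only at probability 1) for
#'   boundary sweeps.
#' @return Data.frame with columns `probability`, `label` (1 = high risk),
#'   and a `threshold` attribute.
#' @export
predict_risk <- function(model, features, threshold = NULL) {
  stopifnot(inherits(model, "lsm_risk_model"))
  thr <- threshold %||% model$config$decision_threshold
  enc <- encode_features(features, vocab = model$vocab)
  p <- predict(model$booster, xgboost::xgb.DMatrix(enc$matrix))
  out <- data.frame(probability = p, label = as.integer(p >= thr))
  attr(out, "threshold") <- thr
  out
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  sizes <- numeric(k)
  with_seed(seed, {
    for (cls in unique(labels)) {
      ix <- sample(which(labels == cls))
      if (length(ix) < k) {
        stop(sprintf("class %s has %d members, fewer than %d folds",
                     cls, length(ix), k), call. = FALSE)
      }
      counts <- rep(length(ix) %/% k, k)
      r <- length(ix) %% k
      if (r > 0) {
        # spread each class's remainder onto the least-loaded folds so the
        # overall fold sizes never differ by more than one
        extra <- order(sizes, stats::runif(k))[seq_len(r)]
        counts[extra] <- counts[extra] + 1
      }
      fold[ix] <- rep(seq_len(k), counts)
      sizes <- sizes + counts
    }
  })
  fold
}

#' Stratified cross-validation of the risk classifier
#'
#' Splits the data into `config$cv_folds` folds preserving the class
#' balance, trains on the complement of each fold and scores the held-out
#' fold with [confusion_metrics()]. Reported means are the plain averages
#' of the per-fold metrics.
#'
#' @inheritParams train_risk_model
#' @return A list: `accuracy`, `precision`, `recall` (fold means),
#'   `per_fold` (data.frame), `n_samples`.
#' @export
cross_validate_risk <- function(features, labels,
                                config = classifier_config()) {
  labels <- as.integer(labels)
  fold <- stratified_folds(labels, config$cv_folds, config$random_seed)
  rows <- lapply(seq_len(config$cv_folds), function(k) {
    tr <- fold != k
    m <- train_risk_model(features[tr, , drop = FALSE], labels[tr], config)
    pred <- predict_risk(m, features[!tr, , drop = FALSE])
    y <- labels[!tr]
    cm <- confusion_metrics(tp = sum(pred$label == 1 & y == 1),
                            fp = sum(pred$label == 1 & y == 0),
                            fn = sum(pred$label == 0 & y == 1),
                            tn = sum(pred$label == 0 & y == 0))
    data.frame(fold = k, accuracy = cm$accuracy, precision = cm$precision,
               recall = cm$recall)
  })
  per_fold <- do.call(rbind, rows)
  list(accuracy = mean(per_fold$accuracy),
       precision = mean(per_fold$precision),
       recall = mean(per_fold$recall),
       per_fold = per_fold,
       n_samples = length(labels))
}

#' Normalized relative feature importance (RFI)
#'
#' Aggregates the booster's split gain over the one-hot columns back to the
#' six original features and normalizes to percentages summing to 100.
#' Features never split on report 0.
#'
#' @param model An `lsm_risk_model`.
#' @return Named numeric vector of percentages over the six features.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "lsm_risk_model"))
  imp <- xgboost::xgb.importance(model = model$booster)
  rfi <- stats::setNames(numeric(length(RISK_FEATURES)), RISK_FEATURES)
  if (!is.null(imp) && nrow(imp)) {
    base <- sub("=.*$", "", imp$Feature)
    gain <- tapply(imp$Gain, base, sum)
    rfi[names(gain)] <- gain
  }
  if (sum(rfi) <= 0) stop("model has no splits", call. = FALSE)
  100 * rfi / sum(rfi)
}

#' Field validation of risk predictions against observed larvae
#'
#' Compares high/low calls with ground-truth larval presence from a field
#' survey: positive = larvae observed, a high call on a positive site is a
#' true positive.
#'
#' @param predicted_labels Integer 0/1 vector of high-risk calls.
#' @param larvae_observed Integer 0/1 vector of the same length.
#' @return [confusion_metrics()] output (counts plus accuracy, precision,
#'   recall).
#' @export
field_validation <- function(predicted_labels, larvae_observed) {
  if (length(predicted_labels) != length(larvae_observed)) {
    stop("prediction and observation vectors differ in length",
         call. = FALSE)
  }
  p <- as.integer(predicted_labels)
  y <- as.integer(larvae_observed)
  confusion_metrics(tp = sum(p == 1 & y == 1), fp = sum(p == 1 & y == 0),
                    fn = sum(p == 0 & y == 1), tn = sum(p == 0 & y == 0))
}
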