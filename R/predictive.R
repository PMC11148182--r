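# Predictive-power protocol: a boosted-tree classifier limited to a single
# boosting round on the three functionality scores, evaluated by 3-fold
# cross-validated AUC, repeated over bootstrap-resampled cohorts of sizes
# 15..29.

.feature_cols <- c("pd1_score", "pdl1_score", "pdl2_score")

#' Train the single-round boosted-tree classifier
#'
#' A gradient-boosted decision-tree ensemble restricted to exactly one
#' boosting round (one tree) with logistic loss; at one round the learning
#' rate only rescales the risk score and is irrelevant for ranking.
#'
#' @param features numeric matrix (patients x features).
#' @param labels logical/0-1 responder flags; both classes must be present.
#' @param max_depth tree depth, default 3.
#' @param nrounds boosting rounds; default (and protocol) 1.
#' @return fitted `xgb.Booster`.
#' @export
train_single_round_model <- function(features, labels, max_depth = 3,
                                     nrounds = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("degenerate_labels")
  features <- as.matrix(features)
  if (anyNA(features)) stop("missing feature values in training rows")
  dtrain <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = 1, nthread = 1,
                  # logistic hessians are ~0.25/sample, so the default
                  # min_child_weight = 1 forbids any split with a child under
                  # ~4 samples and the tree degenerates to a constant at the
                  # protocol's fold sizes; disable the floor
                  # lambda = 0 keeps leaf values a pure function of class
                  # proportions (invariant to duplicating rows)
                  min_child_weight = 0, lambda = 0),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

#' Predict risk scores from a fitted model
#' @param model an `xgb.Booster`.
#' @param features numeric matrix with the training columns.
#' @return numeric risk score per row (monotone in predicted response odds).
#' @export
predict_risk <- function(model, features) {
  features <- as.matrix(features)
  stats::predict(model, xgboost::xgb.DMatrix(features, nthread = 1))
}

#' ROC AUC (Mann-Whitney form)
#'
#' Probability that a random positive outranks a random negative, ties
#' counting one half; computed from rank sums.
#'
#' @param scores numeric risk scores.
#' @param labels logical/0-1 class labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(as.integer(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("degenerate_labels")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stratified k-fold assignment: splits each class across folds as evenly as
# possible so every training set keeps both classes whenever feasible.
.stratified_folds <- function(labels, k, rng_permute = sample) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[rng_permute(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated AUC
#'
#' Stratified 3-fold cross-validation (2/3 training, 1/3 testing); the
#' out-of-fold risk scores are pooled across folds and a single AUC is
#' computed on the pooled predictions. If a random fold assignment leaves a
#' training fold with one class, folds are redrawn up to 10 times.
#'
#' @param features numeric matrix (patients x features).
#' @param labels responder flags.
#' @param seed integer seed controlling the fold assignment.
#' @param k number of folds, default 3.
#' @param max_depth tree depth for the single-round model.
#' @return pooled out-of-fold AUC.
#' @export
cv_auc <- function(features, labels, seed, k = 3, max_depth = 3) {
  labels <- as.integer(labels)
  features <- as.matrix(features)
  n <- length(labels)
  if (n < 2 * k || length(unique(labels)) < 2) stop("unsplittable_cohort")
  rng <- .new_rng(seed)
  fold <- NULL
  for (attempt in 1:10) {
    cand <- .stratified_folds(labels, k, rng_permute = function(m) rng$permute(m))
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[cand != f])) == 2
    }, logical(1)))
    if (ok) { fold <- cand; break }
  }
  if (is.null(fold)) stop("unsplittable_cohort")
  oof <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- train_single_round_model(features[!test, , drop = FALSE],
                                      labels[!test], max_depth = max_depth)
    oof[test] <- predict_risk(model, features[test, , drop = FALSE])
  }
  roc_auc(oof, labels)
}

#' Cohort-size sampling curve of cross-validated AUC
#'
#' For each cohort size, draws `repeats` simulated cohorts from the source
#' cohort by stratified bootstrap (sampling responders and non-responders
#' with replacement in the source proportions), runs [cv_auc()] on each,
#' and summarises the minimum and mean test AUC per size. Fully
#' reproducible from `seed`.
#'
#' @param cohort data.frame with the three score columns and a `responder`
#'   logical column (or `best_response` codes).
#' @param sizes integer vector of cohort sizes, default 15:29.
#' @param repeats simulated cohorts per size, default 100.
#' @param seed master seed.
#' @param feature_cols feature columns, default the three ligand scores.
#' @return list: `per_repeat` data.frame (size, repeat, auc) and `summary`
#'   data.frame (size, min_auc, mean_auc).
#' @export
cohort_sampling_curve <- function(cohort, sizes = 15:29, repeats = 100, seed,
                                  feature_cols = .feature_cols) {
  if (any(sizes < 15)) stop("size_out_of_protocol: sizes below 15")
  labels <- if ("responder" %in% names(cohort)) {
    as.integer(cohort$responder)
  } else {
    as.integer(classify_response(cohort$best_response) == "responder")
  }
  features <- as.matrix(cohort[, feature_cols])
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0 || length(neg) == 0) stop("degenerate_labels")
  p_pos <- length(pos) / length(labels)

  rows <- vector("list", length(sizes) * repeats)
  i <- 0
  for (size in sizes) {
    n_pos <- round(size * p_pos)
    n_pos <- min(max(n_pos, 3L), size - 3L)  # every fold needs both classes
    for (rep_i in seq_len(repeats)) {
      sub_seed <- (seed + 100003L * match(size, sizes) + rep_i) %% .Machine$integer.max
      rng <- .new_rng(sub_seed)
      draw <- c(pos[rng$sample_int(length(pos), n_pos, replace = TRUE)],
                neg[rng$sample_int(length(neg), size - n_pos, replace = TRUE)])
      auc <- cv_auc(features[draw, , drop = FALSE], labels[draw],
                    seed = sub_seed + 7L)
      i <- i + 1
      rows[[i]] <- data.frame(size = size, rep = rep_i, auc = auc)
    }
  }
  per_repeat <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_repeat, per_repeat$size),
    function(d) data.frame(size = d$size[1], min_auc = min(d$auc),
                           mean_auc = mean(d$auc))))
  rownames(summary) <- NULL
  list(per_repeat = per_repeat, summary = summary)
}

# Small self-contained RNG wrapper: isolates all protocol randomness from
# the global .Random.seed so runs are reproducible regardless of caller
# state.
.new_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    s
  })
  with_state <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    fn()
  }
  list(
    permute = function(n) with_state(function() sample.int(n)),
    sample_int = function(n, size, replace = FALSE)
      with_state(function() sample.int(n, size, replace = replace))
  )
}
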