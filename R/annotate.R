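# Cluster annotation by marker-profile rules and transfer of population
# labels across developmental branches with regularized logistic regression.

#' Annotation rule
#'
#' A population name plus per-marker level constraints on the scaled
#' (min-max, `[0,1]`) cluster profile: `hi` (scaled value >= threshold),
#' `lo` (<= threshold), or `mid` (between two thresholds).
#'
#' @param population population name.
#' @param ... named constraints; each is `c("hi", thr)`, `c("lo", thr)` or
#'   `c("mid", lo_thr, hi_thr)` (numbers may be given as strings or via
#'   `list()`).
#' @return class `annotation_rule`.
#' @export
annotation_rule <- function(population, ...) {
  cs <- list(...)
  parsed <- lapply(cs, function(cc) {
    lvl <- as.character(cc[[1]])
    thr <- as.numeric(unlist(cc[-1]))
    if (!lvl %in% c("hi", "lo", "mid")) stopf("annotation_rule: level '%s'", lvl)
    if (lvl == "mid" && length(thr) != 2) stopf("annotation_rule: mid needs two thresholds")
    if (any(thr < 0 | thr > 1)) stopf("annotation_rule: thresholds must lie in [0,1]")
    list(level = lvl, thr = thr)
  })
  structure(list(population = population, constraints = parsed),
            class = "annotation_rule")
}

#' @noRd
rule_matches <- function(rule, profile_row) {
  for (m in names(rule$constraints)) {
    if (!m %in% names(profile_row)) stopf("annotation rule '%s': unknown marker '%s'",
                                          rule$population, m)
    v <- profile_row[[m]]
    con <- rule$constraints[[m]]
    ok <- switch(con$level,
                 hi = v >= con$thr,
                 lo = v <= con$thr,
                 mid = v >= con$thr[1] && v <= con$thr[2])
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Annotate clusters from scaled MFI profiles
#'
#' Maps each cluster to the unique rule whose constraints its scaled profile
#' satisfies; clusters matching no rule become `"unassigned"`, clusters
#' matching several rules raise an error naming the ambiguity.
#'
#' @param profile a `cluster_profile`.
#' @param rules list of [annotation_rule()]s.
#' @return named character vector: cluster id -> population name.
#' @export
annotate_clusters <- function(profile, rules) {
  sc <- profile$scaled
  out <- stats::setNames(rep("unassigned", nrow(sc)), rownames(sc))
  for (ci in seq_len(nrow(sc))) {
    row <- as.list(sc[ci, ])
    hits <- vapply(rules, function(r) rule_matches(r, row), logical(1))
    if (sum(hits) > 1) {
      stopf("annotate_clusters: cluster %s matches several rules: %s",
            rownames(sc)[ci],
            paste(vapply(rules[hits], `[[`, "", "population"), collapse = ", "))
    }
    if (sum(hits) == 1) out[ci] <- rules[[which(hits)]]$population
  }
  out
}

#' Read annotation rules from JSON
#'
#' @param path JSON array of objects `{population, constraints: {marker:
#'   [level, thr...]}}`.
#' @return list of [annotation_rule()]s.
#' @export
rules_from_json <- function(path) {
  spec <- jsonlite::read_json(path)
  lapply(spec, function(r) {
    do.call(annotation_rule, c(list(population = r$population), r$constraints))
  })
}

#' Fit a label-transfer model
#'
#' L2-regularized multinomial logistic regression (ridge): the inverse
#' regularization strength `C` maximising mean stratified k-fold
#' cross-validated accuracy over `C_grid` is selected (ties resolved toward
#' the smaller, i.e. more regularized, `C`), then the model is refit on all
#' training data. Deterministic given the seed.
#'
#' @param x training events x features matrix.
#' @param labels class label per event (>= 2 classes, each with >= `n_folds`
#'   members).
#' @param C_grid inverse-regularization grid; default
#'   `c(0.01, 0.1, 1, 10, 100)`.
#' @param n_folds stratified CV folds; default 5.
#' @param seed integer seed for the fold split.
#' @return class `transfer_model`: `classes`, `C`, `cv_accuracy`, `fit`
#'   (glmnet), `features`, `n_folds`, `seed`.
#' @export
fit_transfer <- function(x, labels, C_grid = c(0.01, 0.1, 1, 10, 100),
                         n_folds = 5, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stopf("fit_transfer: need >= 2 classes")
  if (any(tab < n_folds)) {
    stopf("fit_transfer: class(es) with < %d members: %s", n_folds,
          paste(names(tab)[tab < n_folds], collapse = ", "))
  }
  n <- nrow(x)
  lambda_of <- function(C) 1 / (n * C)

  folds <- with_seed(seed, {
    f <- integer(n)
    for (cl in names(tab)) {
      ix <- which(labels == cl)
      f[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
    }
    f
  })

  cv_acc <- vapply(C_grid, function(C) {
    correct <- 0
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], labels[tr],
                            family = "multinomial", alpha = 0,
                            lambda = lambda_of(C), standardize = FALSE)
      pr <- predict(fit, x[!tr, , drop = FALSE], type = "class")
      correct <- correct + sum(pr == labels[!tr])
    }
    correct / n
  }, numeric(1))

  best <- which(cv_acc == max(cv_acc))
  best <- best[which.min(C_grid[best])]
  C <- C_grid[best]
  fit <- glmnet::glmnet(x, labels, family = "multinomial", alpha = 0,
                        lambda = lambda_of(C), standardize = FALSE)
  structure(list(classes = sort(names(tab)), C = C,
                 cv_accuracy = stats::setNames(cv_acc, C_grid),
                 fit = fit, features = colnames(x),
                 n_folds = n_folds, seed = as.integer(seed)),
            class = "transfer_model")
}

#' Predict population labels and score against truth
#'
#' Argmax-probability class per event; when true labels are supplied,
#' per-class one-vs-rest confusion counts and the derived accuracy
#' `(TP+TN)/(TP+TN+FN+FP)`, sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)` are returned. Per-event class probabilities sum to 1.
#'
#' @param model a `transfer_model`.
#' @param x events x features matrix (feature names must match the model).
#' @param truth optional true labels.
#' @return list with `labels`, `probabilities`, and (given truth) `metrics`
#'   (data frame from [transfer_metrics()]).
#' @export
predict_and_score <- function(model, x, truth = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$features)) {
    stopf("predict_and_score: %d features supplied, model has %d",
          ncol(x), length(model$features))
  }
  pr <- predict(model$fit, x, type = "response")[, , 1]
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                     dimnames = list(NULL, model$classes))
  labels <- colnames(pr)[max.col(pr, ties.method = "first")]
  out <- list(labels = labels, probabilities = pr)
  if (!is.null(truth)) out$metrics <- transfer_metrics(labels, as.character(truth))
  out
}

#' One-vs-rest transfer metrics
#'
#' @param predicted,truth label vectors of equal length.
#' @param skip_undefined drop classes whose sensitivity or specificity has a
#'   0/0 denominator instead of raising.
#' @return data frame: class, TP, TN, FP, FN, accuracy, sensitivity,
#'   specificity.
#' @export
transfer_metrics <- function(predicted, truth, skip_undefined = FALSE) {
  classes <- sort(union(predicted, truth))
  rows <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    tn <- sum(predicted != cl & truth != cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    metrics_from_counts(tp, tn, fp, fn, class = cl,
                        skip_undefined = skip_undefined)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FN+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`. Undefined 0/0 ratios raise an error unless
#' `skip_undefined`, in which case `NULL` is returned.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @param class optional class label carried into the output.
#' @param skip_undefined return `NULL` instead of raising on 0/0.
#' @return one-row data frame, or `NULL`.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn, class = NA_character_,
                                skip_undefined = FALSE) {
  if (tp + tn + fp + fn == 0 || tp + fn == 0 || tn + fp == 0) {
    if (skip_undefined) return(NULL)
    stopf("metrics_from_counts: undefined 0/0 metric for class '%s' (TP=%d TN=%d FP=%d FN=%d)",
          class, tp, tn, fp, fn)
  }
  data.frame(class = class, TP = tp, TN = tn, FP = fp, FN = fn,
             accuracy = (tp + tn) / (tp + tn + fn + fp),
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp))
}

#' Serialize a transfer model to JSON
#'
#' @param model a `transfer_model`.
#' @param path output path.
#' @export
write_transfer_model <- function(model, path) {
  co <- stats::coef(model$fit)
  weights <- lapply(co, function(m) as.numeric(m))
  jsonlite::write_json(
    list(classes = model$classes, C = model$C, seed = model$seed,
         features = model$features,
         weights = weights, cv_accuracy = as.list(model$cv_accuracy)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
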