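# Training loop, cross-validation schemes, and classification metrics.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

#' Train a classifier on feature tensors
#'
#' Minibatch training with the Adam optimizer and cross-entropy loss. The
#' reference protocol is batch size 128, learning rate 0.001 and 100 epochs;
#' desk-scale runs use far fewer epochs.
#'
#' @param x Feature batch: `N x 9 x 9 x 4` array or a `de_tensors` object.
#' @param labels Integer class labels (0-based), length N.
#' @param cfg A [model_config()].
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size (default 128).
#' @param lr Adam learning rate (default 0.001).
#' @param seed Seed controlling initialization and batch shuffling; defaults
#'   to `cfg$seed`.
#' @param verbose Print per-epoch mean loss.
#' @return The trained `eegemo_model` with an added `loss_log` (mean loss per
#'   epoch).
#' @export
train_model <- function(x, labels, cfg, epochs = 10L, batch_size = 128L,
                        lr = 1e-3, seed = NULL, verbose = FALSE) {
  if (inherits(x, "de_tensors")) x <- x$grid
  labels <- as.integer(labels)
  n <- dim(x)[1]
  stopifnot(length(labels) == n)
  if (any(labels < 0L | labels >= cfg$n_classes))
    stop("labels must be 0-based class ids below n_classes")
  seed <- seed %||% cfg$seed
  cfg$seed <- derive_seed(seed, 0L)
  model <- build_model(cfg)
  opt <- adam_init(model$params)
  loss_log <- numeric(epochs)
  with_seed(derive_seed(seed, 1L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batch norm needs > 1 sample
        xb <- x[idx, , , , drop = FALSE]
        fw <- model_forward(model, xb, train = TRUE, grad = TRUE)
        model$state <- fw$state
        sc <- softmax_ce(fw$logits, labels[idx])
        grads <- model_backward(model, fw$cache, sc$dlogits)
        upd <- adam_step(model$params, grads, opt, lr = lr)
        model$params <- upd$params
        opt <- upd$st
        losses <- c(losses, sc$loss)
      }
      loss_log[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.4f", ep, epochs, loss_log[ep]))
    }
  })
  model$loss_log <- loss_log
  model
}

#' Predict class probabilities / labels
#'
#' @param model A trained `eegemo_model`.
#' @param x Feature batch or `de_tensors`.
#' @param batch_size Evaluation batch size.
#' @return `predict_proba`: N x n_classes probability matrix.
#'   `predict_labels`: integer vector of 0-based class ids.
#' @export
predict_proba <- function(model, x, batch_size = 256L) {
  if (inherits(x, "de_tensors")) x <- x$grid
  n <- dim(x)[1]
  out <- matrix(0, n, model$cfg$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- model_forward(model, x[idx, , , , drop = FALSE], train = FALSE)
    out[idx, ] <- fw$probs
  }
  out
}

#' @rdname predict_proba
#' @export
predict_labels <- function(model, x, batch_size = 256L) {
  max.col(predict_proba(model, x, batch_size)) - 1L
}

#' Binarize continuous 1-9 ratings at the midpoint
#'
#' Scores above 5 become class 1 ("high"), scores at or below 5 become class
#' 0 ("low"). The tie at exactly 5 goes to "low" for determinism.
#'
#' @param ratings Numeric vector of scores in `[1, 9]`.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_ratings <- function(ratings) {
  if (any(!is.finite(ratings)) || any(ratings < 1 | ratings > 9))
    stop("ratings must lie in [1, 9]")
  as.integer(ratings > 5)
}

#' Build a cross-validation fold plan
#'
#' `kfold`: samples are split into K folds of near-equal size (difference at
#' most 1), stratified by class label when labels are given. `loso`
#' (leave-one-subject-out): one fold per subject.
#'
#' @param n Number of samples (ignored for `loso` when `subjects` given).
#' @param scheme `"kfold"` or `"loso"`.
#' @param k Number of folds for `kfold` (default 5).
#' @param labels Optional class labels used for stratification.
#' @param subjects Subject id per sample (required for `loso`).
#' @param seed Seed; the plan is deterministic given it.
#' @return Object of class `fold_plan`: list with `scheme`, `assignments`
#'   (fold id per sample), `n_folds`, `seed`.
#' @export
make_folds <- function(n, scheme = c("kfold", "loso"), k = 5L,
                       labels = NULL, subjects = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "loso") {
    if (is.null(subjects)) stop("'subjects' is required for loso")
    n <- length(subjects)
    subj <- unique(subjects)
    assignments <- match(subjects, subj)
    plan <- list(scheme = "loso", assignments = assignments,
                 n_folds = length(subj), subjects = subj, seed = seed)
  } else {
    k <- check_count(k, "k", 2L)
    n <- check_count(n, "n")
    if (k > n) stop(sprintf("k = %d exceeds the number of samples (%d)", k, n))
    assignments <- integer(n)
    with_seed(seed, {
      if (is.null(labels)) {
        assignments <- sample(rep_len(seq_len(k), n))
      } else {
        stopifnot(length(labels) == n)
        for (cl in unique(labels)) {
          idx <- which(labels == cl)
          assignments[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
      }
    })
    plan <- list(scheme = "kfold", assignments = assignments,
                 n_folds = k, seed = seed)
  }
  class(plan) <- "fold_plan"
  validate_fold_plan(plan)
}

validate_fold_plan <- function(plan) {
  a <- plan$assignments
  if (any(is.na(a)) || any(a < 1L | a > plan$n_folds))
    stop("fold assignments must cover 1..n_folds")
  if (any(tabulate(a, plan$n_folds) == 0L))
    stop("every fold must receive at least one sample")
  plan
}

#' Confusion counts for a set of predictions
#'
#' One-vs-rest counts per class: TP, TN, FP, FN, always summing to the number
#' of evaluated samples.
#'
#' @param y_true,y_pred Integer 0-based class labels.
#' @param n_classes Number of classes.
#' @return Matrix `n_classes x 4` with columns TP, TN, FP, FN.
#' @export
confusion_counts <- function(y_true, y_pred, n_classes = max(y_true, y_pred) + 1L) {
  stopifnot(length(y_true) == length(y_pred))
  out <- matrix(0L, n_classes, 4,
                dimnames = list(paste0("class", seq_len(n_classes) - 1L),
                                c("TP", "TN", "FP", "FN")))
  for (cl in seq_len(n_classes) - 1L) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- length(y_true) - tp - fp - fn
    out[cl + 1L, ] <- c(tp, tn, fp, fn)
  }
  out
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FN+FP+TN) x 100, precision = TP/(TP+FP) x 100,
#' recall = TP/(TP+FN) x 100 and the F-score as the harmonic mean of
#' precision and recall, all in percent. For more than two classes the
#' per-class one-vs-rest values are macro-averaged (and accuracy is the
#' plain multiclass accuracy). Ratios with zero denominators are reported as
#' `NA` with a warning rather than as 0.
#'
#' @param counts Either a vector with named entries TP, TN, FP, FN (binary)
#'   or a matrix as returned by [confusion_counts()].
#' @return Object of class `metric_report`: list with `accuracy`,
#'   `precision`, `recall`, `f_score` (percent) and `per_class`.
#' @export
compute_metrics <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, 1,
                                             dimnames = list(NULL, names(counts)))
  counts <- counts[, c("TP", "TN", "FP", "FN"), drop = FALSE]
  if (any(counts < 0)) stop("negative confusion counts")
  total <- sum(counts[1, ])
  if (total == 0) stop("no evaluated samples")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA", what),
              call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  per_class <- data.frame(t(apply(counts, 1, function(cnt) {
    pr <- if (cnt["TP"] + cnt["FP"] == 0) NA_real_
          else 100 * cnt["TP"] / (cnt["TP"] + cnt["FP"])
    rc <- if (cnt["TP"] + cnt["FN"] == 0) NA_real_
          else 100 * cnt["TP"] / (cnt["TP"] + cnt["FN"])
    f <- if (is.na(pr) || is.na(rc) || pr + rc == 0) NA_real_
         else 2 * pr * rc / (pr + rc)
    c(precision = pr, recall = rc, f_score = f)
  })))
  if (nrow(counts) <= 2L) {
    # binary: class 1 ("high") is the positive class
    row <- min(nrow(counts), 2L)
    cnt <- counts[row, ]
    acc <- ratio(cnt["TP"] + cnt["TN"], sum(cnt), "accuracy")
    pr <- ratio(cnt["TP"], cnt["TP"] + cnt["FP"], "precision")
    rc <- ratio(cnt["TP"], cnt["TP"] + cnt["FN"], "recall")
  } else {
    acc <- 100 * sum(counts[, "TP"]) / total
    pr <- mean(per_class$precision)
    rc <- mean(per_class$recall)
    if (anyNA(per_class$precision) || anyNA(per_class$recall))
      warning("some per-class ratios undefined; macro averages contain NA",
              call. = FALSE)
  }
  f <- if (is.na(pr) || is.na(rc) || pr + rc == 0) {
    if (!is.na(pr) && !is.na(rc))
      warning("F-score undefined (precision + recall = 0)", call. = FALSE)
    NA_real_
  } else 2 * pr * rc / (pr + rc)
  structure(list(accuracy = unname(acc), precision = unname(pr),
                 recall = unname(rc), f_score = unname(f),
                 per_class = per_class, n = total),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F-score %.2f%%  (n = %d)\n",
              x$accuracy, x$precision, x$recall, x$f_score, x$n))
  invisible(x)
}

#' Cross-validated training and evaluation
#'
#' Trains one model per fold (fresh initialization from a seed derived from
#' the master seed and the fold id), evaluates on the held-out fold, and
#' aggregates the metrics as mean and standard deviation across folds.
#'
#' @param x Feature tensors (`de_tensors` or `N x 9 x 9 x 4` array).
#' @param labels Integer 0-based labels, length N.
#' @param cfg A [model_config()].
#' @param plan A [make_folds()] plan covering all N samples.
#' @param epochs,batch_size,lr Training-loop parameters.
#' @param seed Master seed (defaults to the plan's seed).
#' @param verbose Print per-fold progress.
#' @return Object of class `cv_result`: list with `folds` (per-fold
#'   `metric_report`s), `mean`, `sd`, `predictions` (per-sample predicted
#'   labels) and `plan`.
#' @export
train_and_evaluate <- function(x, labels, cfg, plan, epochs = 10L,
                               batch_size = 128L, lr = 1e-3, seed = NULL,
                               verbose = FALSE) {
  if (inherits(x, "de_tensors")) x <- x$grid
  labels <- as.integer(labels)
  n <- dim(x)[1]
  stopifnot(inherits(plan, "fold_plan"), length(plan$assignments) == n,
            length(labels) == n)
  seed <- seed %||% plan$seed
  reports <- vector("list", plan$n_folds)
  preds <- integer(n)
  for (fold in seq_len(plan$n_folds)) {
    test_idx <- which(plan$assignments == fold)
    train_idx <- which(plan$assignments != fold)
    if (!length(test_idx)) stop(sprintf("fold %d has an empty test set", fold))
    if (length(unique(labels[train_idx])) < 2L)
      warning(sprintf("fold %d: training data contains a single class", fold))
    model <- train_model(x[train_idx, , , , drop = FALSE], labels[train_idx],
                         cfg, epochs = epochs, batch_size = batch_size,
                         lr = lr, seed = derive_seed(seed, fold))
    yp <- predict_labels(model, x[test_idx, , , , drop = FALSE])
    preds[test_idx] <- yp
    reports[[fold]] <- compute_metrics(
      confusion_counts(labels[test_idx], yp, cfg$n_classes))
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.2f%%", fold, plan$n_folds,
                      reports[[fold]]$accuracy))
  }
  fields <- c("accuracy", "precision", "recall", "f_score")
  vals <- lapply(fields, function(f) vapply(reports, function(r) r[[f]], 1))
  names(vals) <- fields
  structure(list(
    folds = reports,
    mean = vapply(vals, mean, 1, na.rm = TRUE),
    sd = vapply(vals, stats::sd, 1),
    predictions = preds, plan = plan, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s):\n", x$plan$n_folds, x$plan$scheme))
  cat(sprintf("  accuracy %.2f +/- %.2f %%\n", x$mean["accuracy"],
              x$sd["accuracy"]))
  invisible(x)
}

#' Nearest-centroid baseline on flattened feature tensors
#'
#' A deliberately simple reference classifier: class centroids in the
#' flattened differential-entropy feature space, prediction by smallest
#' Euclidean distance. Used to verify that a synthetic task is actually easy
#' before asking the network to solve it.
#'
#' @param x_train,x_test Feature arrays (`N x ...`), flattened per sample.
#' @param y_train Integer 0-based training labels.
#' @return Integer vector of predicted 0-based labels for `x_test`.
#' @export
nearest_centroid <- function(x_train, y_train, x_test) {
  if (inherits(x_train, "de_tensors")) x_train <- x_train$grid
  if (inherits(x_test, "de_tensors")) x_test <- x_test$grid
  xtr <- matrix(x_train, nrow = dim(x_train)[1])
  xte <- matrix(x_test, nrow = dim(x_test)[1])
  classes <- sort(unique(y_train))
  cents <- t(vapply(classes, function(cl)
    colMeans(xtr[y_train == cl, , drop = FALSE]), numeric(ncol(xtr))))
  d2 <- outer(rowSums(xte^2), rowSums(cents^2), "+") - 2 * xte %*% t(cents)
  classes[max.col(-d2)]
}
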