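#' Fit the MFCC -> LDA -> SVM reference classifier
#'
#' The evaluation classifier used throughout: each one-second segment is
#' represented by `mfcc_n` (default 20) MFCC coefficients, z-scored with
#' training-set statistics, projected by linear discriminant analysis onto
#' `C - 1` components (2 for the three hive-event classes), and classified
#' by a linear-kernel support vector machine on the projected features.
#'
#' @param train a [segment_set] with at least two classes.
#' @param feature_cfg a [feature_config].
#' @param cost SVM regularization constant (default 1).
#' @return An object of class `lda_svm` with fields `center`, `scale`
#'   (standardization), `lda` (the [MASS::lda] fit), `svm`, `classes`.
#' @export
lda_svm <- function(train, feature_cfg = feature_config(), cost = 1) {
  stopifnot(inherits(train, "segment_set"))
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L)
    stopf("lda_svm needs at least two classes, got %d", length(classes))
  if (length(train) < length(classes))
    stopf("need at least one sample per class")
  M <- feature_matrix(train, feature_cfg, type = "mfcc")
  center <- colMeans(M)
  scl <- pmax(apply(M, 2, stats::sd), 1e-8)
  Z <- sweep(sweep(M, 2, center), 2, scl, "/")
  fit <- MASS::lda(Z, grouping = factor(train$labels, levels = classes))
  proj <- Z %*% fit$scaling
  sv <- e1071::svm(x = proj, y = factor(train$labels, levels = classes),
                   kernel = "linear", cost = cost, scale = FALSE)
  structure(list(center = center, scale = scl, lda = fit, svm = sv,
                 classes = classes, feature_cfg = feature_cfg, cost = cost),
            class = "lda_svm")
}

#' @export
print.lda_svm <- function(x, ...) {
  cat(sprintf("<lda_svm> %d classes (%s); %d MFCCs -> %d LDA components -> linear SVM (cost %g)\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$center), ncol(x$lda$scaling), x$cost))
  invisible(x)
}

#' Classify segments with a fitted LDA-SVM model
#'
#' @param object an [lda_svm] model.
#' @param newdata a [segment_set], or a precomputed MFCC matrix (one row
#'   per segment).
#' @param ... unused.
#' @return Character vector of predicted labels (empty input gives an
#'   empty vector).
#' @export
predict.lda_svm <- function(object, newdata, ...) {
  M <- if (inherits(newdata, "segment_set")) {
    if (length(newdata) == 0L) return(character(0))
    feature_matrix(newdata, object$feature_cfg, type = "mfcc")
  } else as.matrix(newdata)
  if (nrow(M) == 0L) return(character(0))
  Z <- sweep(sweep(M, 2, object$center), 2, object$scale, "/")
  proj <- Z %*% object$lda$scaling
  as.character(predict(object$svm, proj))
}

#' Project segments onto the LDA plane
#'
#' Maps segments through the model's standardization and LDA projection
#' (without the SVM), giving the `C - 1` dimensional coordinates used for
#' the class-separation plots.
#'
#' @param model an [lda_svm] model.
#' @param x a [segment_set] or MFCC matrix.
#' @return Numeric matrix, one row per segment, `C - 1` columns.
#' @export
lda_project <- function(model, x) {
  stopifnot(inherits(model, "lda_svm"))
  M <- if (inherits(x, "segment_set"))
    feature_matrix(x, model$feature_cfg, type = "mfcc") else as.matrix(x)
  Z <- sweep(sweep(M, 2, model$center), 2, model$scale, "/")
  Z %*% model$lda$scaling
}

#' Class distribution of predictions
#'
#' Counts and percentages per class over a fixed alphabet; counts sum to
#' the number of predictions.
#'
#' @param predictions character vector of predicted labels.
#' @param alphabet class alphabet (default: the three event labels).
#' @return data.frame with columns `class`, `count`, `percent`.
#' @export
class_distribution <- function(predictions, alphabet = EVENT_LABELS) {
  counts <- vapply(alphabet, function(cl) sum(predictions == cl), 0L)
  n <- length(predictions)
  data.frame(class = alphabet, count = as.integer(counts),
             percent = if (n) 100 * counts / n else rep(0, length(alphabet)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classification metrics report
#'
#' Confusion matrix (rows true, columns predicted), overall accuracy, and
#' one-vs-rest precision/recall/F1 per class plus their macro averages.
#' Zero-denominator cases (no predicted or no true positives) give 0 by
#' convention.
#'
#' @param predictions,truths equal-length label vectors.
#' @param positive_class optional class whose one-vs-rest metrics are
#'   surfaced as `$precision`, `$recall`, `$f1`.
#' @return An object of class `metrics_report`.
#' @export
classification_metrics <- function(predictions, truths, positive_class = NULL) {
  if (length(predictions) != length(truths))
    stopf("predictions and truths must have equal length")
  alphabet <- sort(unique(c(predictions, truths)))
  conf <- table(factor(truths, levels = alphabet),
                factor(predictions, levels = alphabet))
  per_class <- do.call(rbind, lapply(alphabet, function(cl) {
    tp <- sum(predictions == cl & truths == cl)
    fp <- sum(predictions == cl & truths != cl)
    fn <- sum(predictions != cl & truths == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  out <- list(confusion = conf,
              accuracy = mean(predictions == truths),
              per_class = per_class,
              macro_precision = mean(per_class$precision),
              macro_recall = mean(per_class$recall),
              macro_f1 = mean(per_class$f1))
  if (!is.null(positive_class)) {
    row <- per_class[per_class$class == positive_class, ]
    if (nrow(row) == 0L) row <- data.frame(precision = 0, recall = 0, f1 = 0)
    out$positive_class <- positive_class
    out$precision <- row$precision
    out$recall <- row$recall
    out$f1 <- row$f1
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.3f (n = %d)\n",
              x$accuracy, sum(x$confusion)))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Stratified train/test split of a segment set
#'
#' @param x a [segment_set].
#' @param train_frac training fraction (default 0.8).
#' @param seed split seed.
#' @return List with `train` and `test` [segment_set]s and the index
#'   vectors used.
#' @export
stratified_split <- function(x, train_frac = 0.8, seed = 1L) {
  stopifnot(inherits(x, "segment_set"))
  idx_train <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(unique(x$labels), function(cl) {
      ii <- which(x$labels == cl)
      sample(ii, round(train_frac * length(ii)))
    }))
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(length(x)), idx_train)
  list(train = x[idx_train], test = x[idx_test],
       train_idx = idx_train, test_idx = idx_test)
}

#' Class-imbalance augmentation experiment
#'
#' Emulates the minority-class augmentation protocol: the real data are
#' split 80/20 (stratified, test split frozen before any augmentation);
#' the training set keeps the majority classes fixed while the minority
#' class starts at the first requested proportion (real samples only) and
#' is stepped up by adding synthetic minority samples until each requested
#' proportion of the training set is reached (e.g. 20% -> 26% -> 30% ->
#' 33.3%, the last being fully balanced for three classes). Each row
#' refits the classifier and evaluates on the same held-out real test set.
#'
#' @param real a [segment_set] of real (or fixture) data, all classes.
#' @param synthetic a [segment_set] of synthetic samples, all labeled
#'   `minority_class` (or relabeled to it).
#' @param minority_class the scarce event class.
#' @param steps minority proportions of the training set; values above 1
#'   are read as percentages.
#' @param feature_cfg a [feature_config].
#' @param seed split seed.
#' @return List: `table` (one row per step: `minority_prop`, training
#'   class counts, minority-class precision/recall/f1, macro f1,
#'   accuracy), `test` (the frozen test [segment_set]).
#' @export
run_augmentation_experiment <- function(real, synthetic, minority_class,
                                        steps = c(20, 26, 30, 33.3),
                                        feature_cfg = feature_config(),
                                        seed = 1L) {
  stopifnot(inherits(real, "segment_set"), inherits(synthetic, "segment_set"))
  steps <- ifelse(steps > 1, steps / 100, steps)
  if (is.unsorted(steps)) stopf("steps must be non-decreasing proportions")
  if (!minority_class %in% real$labels)
    stopf("minority class '%s' absent from real data", minority_class)
  synthetic$labels <- rep_len(minority_class, length(synthetic))

  sp <- stratified_split(real, 0.8, seed)
  maj <- sp$train[sp$train$labels != minority_class]
  min_real <- sp$train[sp$train$labels == minority_class]
  M <- length(maj)

  rows <- vector("list", length(steps))
  for (k in seq_along(steps)) {
    p <- steps[k]
    m_needed <- round(p / (1 - p) * M)
    m_base <- round(steps[1] / (1 - steps[1]) * M)
    m_base <- min(m_base, length(min_real))
    n_synth <- max(0L, m_needed - m_base)
    if (n_synth > length(synthetic))
      stopf("step %.3f needs %d synthetic minority samples but only %d are available",
            p, n_synth, length(synthetic))
    train_k <- c(maj, min_real[seq_len(m_base)])
    if (n_synth > 0L) train_k <- c(train_k, synthetic[seq_len(n_synth)])
    model <- lda_svm(train_k, feature_cfg)
    pred <- predict(model, sp$test)
    met <- classification_metrics(pred, sp$test$labels, minority_class)
    cc <- table(factor(train_k$labels, levels = sort(unique(real$labels))))
    rows[[k]] <- data.frame(minority_prop = p, t(as.integer(cc)),
                            precision = met$precision, recall = met$recall,
                            f1 = met$f1, macro_f1 = met$macro_f1,
                            accuracy = met$accuracy)
    names(rows[[k]])[2:(1 + length(cc))] <- paste0("n_", names(cc))
  }
  list(table = do.call(rbind, rows), test = sp$test)
}
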