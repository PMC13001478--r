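# Balanced one-vs-rest random-forest classification of single cells on the
# 10 OMI variables, with ROC/AUC, confusion-matrix and feature-importance
# reporting.

#' Undersample all classes to the minority-class size
#'
#' Class balancing by random undersampling without replacement, so every
#' class ends with exactly the minority-class count.
#'
#' @param table Feature table.
#' @param label_col Class label column.
#' @param rng_seed Integer seed.
#' @return The balanced table (row order: class blocks in label order).
#' @export
balance_classes <- function(table, label_col, rng_seed = NULL) {
  stopifnot(label_col %in% names(table))
  counts <- table(table[[label_col]])
  if (length(counts) < 2) stop("balancing needs >= 2 classes", call. = FALSE)
  if (any(counts == 0)) stop("empty class in '", label_col, "'", call. = FALSE)
  m <- min(counts)
  .with_seed(rng_seed, {
    keep <- unlist(lapply(names(counts), function(cl) {
      idx <- which(table[[label_col]] == cl)
      if (length(idx) == m) idx else sample(idx, m)
    }))
    table[keep, , drop = FALSE]
  })
}

#' Random train/test split
#'
#' Disjoint, exhaustive random partition of the rows; `floor(n * fraction)`
#' rows go to training.
#'
#' @param table Feature table (>= 2 rows).
#' @param train_fraction Fraction of cells used for training (default 0.7).
#' @param rng_seed Integer seed.
#' @return List with `train` and `test` data.frames.
#' @export
split_train_test <- function(table, train_fraction = 0.7, rng_seed = NULL) {
  n <- nrow(table)
  if (is.null(n) || n < 2) stop("need >= 2 rows to split", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- floor(n * train_fraction)
  if (n_train < 1 || n_train >= n) stop("degenerate split for n = ", n, call. = FALSE)
  .with_seed(rng_seed, {
    idx <- sample.int(n, n_train)
    list(train = table[idx, , drop = FALSE],
         test = table[-idx, , drop = FALSE])
  })
}

#' Classifier configuration
#'
#' @param variables Ordered feature names (default the 10 OMI variables).
#' @param train_fraction Training fraction (0.7).
#' @param n_trees Trees per forest (500).
#' @param rng_seed Integer seed.
#' @param balance Undersample to the minority class before splitting.
#' @param mode "multiclass" (one forest, per-class probability outputs) or
#'   "per_class" (a literal binary forest per class).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(variables = omi_variables(),
                              train_fraction = 0.7, n_trees = 500L,
                              rng_seed = 1L, balance = TRUE,
                              mode = c("multiclass", "per_class")) {
  stopifnot(length(variables) >= 1, train_fraction > 0, train_fraction < 1,
            n_trees >= 1)
  structure(list(variables = variables, train_fraction = train_fraction,
                 n_trees = as.integer(n_trees), rng_seed = rng_seed,
                 balance = isTRUE(balance), mode = match.arg(mode)),
            class = "classifier_config")
}

#' Train a one-vs-rest random-forest classifier
#'
#' Default mode fits a single multi-class random forest whose per-class vote
#' fractions serve as the one-vs-rest scores; `mode = "per_class"` fits a
#' literal binary (class vs rest) forest per class. Feature importances
#' (mean decrease in Gini impurity) are normalised to sum to 1.
#'
#' @param train Training table (balanced beforehand if desired).
#' @param label_col Class label column.
#' @param config A [classifier_config()].
#' @return An `ovr_model` list: `forests`, `classes`, `importances`
#'   (overall, sums to 1), `per_class_importances` (in `"per_class"` mode),
#'   `config`, `label_col`.
#' @export
train_one_vs_rest <- function(train, label_col, config = classifier_config()) {
  stopifnot(all(config$variables %in% names(train)),
            label_col %in% names(train))
  y <- factor(train[[label_col]])
  if (nlevels(y) < 2) stop("training set contains a single class", call. = FALSE)
  if (any(table(y) == 0)) stop("class absent from training split", call. = FALSE)
  x <- as.matrix(train[, config$variables, drop = FALSE])
  norm1 <- function(v) if (sum(v) > 0) v / sum(v) else rep(1 / length(v), length(v))
  .with_seed(config$rng_seed, {
    if (config$mode == "multiclass") {
      rf <- randomForest::randomForest(x, y, ntree = config$n_trees)
      imp <- norm1(rf$importance[, "MeanDecreaseGini"])
      forests <- list(multiclass = rf)
      pci <- NULL
    } else {
      forests <- list()
      pci <- list()
      for (cl in levels(y)) {
        yb <- factor(ifelse(y == cl, cl, "rest"), levels = c(cl, "rest"))
        rf <- randomForest::randomForest(x, yb, ntree = config$n_trees)
        forests[[cl]] <- rf
        pci[[cl]] <- norm1(rf$importance[, "MeanDecreaseGini"])
      }
      imp <- norm1(Reduce(`+`, pci) / length(pci))
    }
    structure(list(forests = forests, classes = levels(y),
                   importances = imp, per_class_importances = pci,
                   config = config, label_col = label_col),
              class = "ovr_model")
  })
}

# Per-class score matrix in [0,1] for new data.
.ovr_scores <- function(model, newdata) {
  x <- as.matrix(newdata[, model$config$variables, drop = FALSE])
  if (model$config$mode == "multiclass") {
    p <- stats::predict(model$forests$multiclass, x, type = "prob")
    p[, model$classes, drop = FALSE]
  } else {
    sapply(model$classes, function(cl) {
      stats::predict(model$forests[[cl]], x, type = "prob")[, cl]
    })
  }
}

#' ROC curve by threshold sweep
#'
#' Sweeps the unique score values as thresholds (prediction positive when
#' score >= threshold) and returns the stepwise false/true positive rates;
#' tied scores collapse onto single ROC vertices, so the trapezoidal area
#' handles ties by linear interpolation. A degenerate all-tied score vector
#' yields the chance diagonal (AUC 0.5).
#'
#' @param scores Continuous classifier scores.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive.
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`, beginning at
#'   (0, 0) and ending at (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("ROC needs both positive and negative examples", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(scores >= th & labels) / np, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & !labels) / nn, numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve (trapezoidal rule)
#' @inheritParams roc_curve
#' @return Scalar AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Evaluate a one-vs-rest model on held-out cells
#'
#' Hard labels are the argmax of the per-class scores. Reports per-class ROC
#' curves and AUC, the confusion matrix in counts and row percentages (rows =
#' true class, so row sums equal per-class test counts), overall accuracy,
#' per-class and macro precision/recall, and the model's feature importances.
#'
#' @param model An [train_one_vs_rest()] model.
#' @param test Held-out table (disjoint from training).
#' @return A `classification_report` list.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "ovr_model"))
  truth <- factor(test[[model$label_col]], levels = model$classes)
  scores <- .ovr_scores(model, test)
  pred <- factor(model$classes[max.col(scores, ties.method = "first")],
                 levels = model$classes)
  cm <- table(truth = truth, predicted = pred)
  cm_counts <- matrix(as.integer(cm), nrow(cm), ncol(cm),
                      dimnames = dimnames(cm))
  row_tot <- rowSums(cm_counts)
  cm_pct <- sweep(cm_counts, 1, pmax(row_tot, 1), "/") * 100

  per_class <- lapply(model$classes, function(cl) {
    pos <- truth == cl
    if (!any(pos) || all(pos)) {
      return(list(auc = NA_real_, roc = NULL, precision = NA_real_,
                  recall = NA_real_, n_test = sum(pos)))
    }
    roc <- roc_curve(scores[, cl], pos)
    tp <- sum(pred == cl & pos); fp <- sum(pred == cl & !pos)
    fn <- sum(pred != cl & pos)
    list(auc = auc_score(scores[, cl], pos), roc = roc,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = tp / (tp + fn), n_test = sum(pos))
  })
  names(per_class) <- model$classes
  aucs <- vapply(per_class, `[[`, numeric(1), "auc")
  prec <- vapply(per_class, `[[`, numeric(1), "precision")
  rec <- vapply(per_class, `[[`, numeric(1), "recall")
  structure(list(
    accuracy = mean(pred == truth),
    auc = aucs, precision = prec, recall = rec,
    macro_precision = mean(prec, na.rm = TRUE),
    macro_recall = mean(rec, na.rm = TRUE),
    confusion_counts = cm_counts, confusion_row_pct = cm_pct,
    roc = lapply(per_class, `[[`, "roc"),
    n_test = vapply(per_class, `[[`, numeric(1), "n_test"),
    importances = model$importances,
    classes = model$classes,
    rng_seed = model$config$rng_seed
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> accuracy %.1f%% over %d test cells\n",
              100 * x$accuracy, sum(x$n_test)))
  for (cl in x$classes) {
    cat(sprintf("  %-14s AUC %.3f  precision %.3f  recall %.3f (n=%d)\n",
                cl, x$auc[[cl]], x$precision[[cl]], x$recall[[cl]],
                x$n_test[[cl]]))
  }
  invisible(x)
}

#' Balanced classification pipeline
#'
#' The full protocol: optional minority-class undersampling, 70/30 random
#' split, one-vs-rest random-forest training on the OMI variables, and
#' evaluation on the held-out cells. `reruns > 1` repeats the whole protocol
#' with derived seeds and reports per-run metrics plus their mean and SD.
#'
#' @param table Feature table (use QC-passed rows).
#' @param label_col Class label column (e.g. `"cell_type"` or
#'   `"condition"`).
#' @param config A [classifier_config()].
#' @param reruns Number of repeated random splits.
#' @return For `reruns = 1`, a `classification_report` with
#'   `class_sizes_before` / `class_sizes_after` attached; otherwise a list
#'   with `runs` (reports), `metrics` (per-run data.frame) and `summary`
#'   (mean and SD per metric).
#' @export
run_classification <- function(table, label_col, config = classifier_config(),
                               reruns = 1L) {
  one <- function(seed) {
    before <- table(table[[label_col]])
    tab <- table
    if (config$balance) tab <- balance_classes(tab, label_col, rng_seed = seed)
    after <- table(tab[[label_col]])
    sp <- split_train_test(tab, config$train_fraction,
                           rng_seed = .sub_seed(seed, 3L, 1L))
    cfg <- config
    cfg$rng_seed <- .sub_seed(seed, 3L, 2L)
    model <- train_one_vs_rest(sp$train, label_col, cfg)
    rep <- evaluate_classifier(model, sp$test)
    rep$class_sizes_before <- before
    rep$class_sizes_after <- after
    rep
  }
  if (reruns <= 1L) return(one(config$rng_seed))
  seeds <- vapply(seq_len(reruns), function(i) .sub_seed(config$rng_seed, 9L, i),
                  numeric(1))
  runs <- lapply(seeds, one)
  metrics <- do.call(rbind, lapply(seq_along(runs), function(i) {
    data.frame(run = i, seed = seeds[i], accuracy = runs[[i]]$accuracy,
               macro_auc = mean(runs[[i]]$auc, na.rm = TRUE),
               macro_precision = runs[[i]]$macro_precision,
               macro_recall = runs[[i]]$macro_recall)
  }))
  list(runs = runs, metrics = metrics,
       summary = data.frame(
         metric = c("accuracy", "macro_auc", "macro_precision", "macro_recall"),
         mean = c(mean(metrics$accuracy), mean(metrics$macro_auc),
                  mean(metrics$macro_precision), mean(metrics$macro_recall)),
         sd = c(stats::sd(metrics$accuracy), stats::sd(metrics$macro_auc),
                stats::sd(metrics$macro_precision), stats::sd(metrics$macro_recall))))
}
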