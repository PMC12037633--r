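#' Stratified five-fold split of all lncRNA-disease pairs
#'
#' Known associations (positives) and unknown pairs (negatives) are each
#' shuffled and dealt into five near-equal subsets; fold f's test set is
#' positive subset f together with negative subset f, so the folds
#' partition the full pair set and every fold preserves the class ratio.
#'
#' @param dataset An `lnclink_dataset`.
#' @param seed Integer seed; the same seed always yields the same split.
#' @param n_folds Number of folds (default 5).
#' @return An nl x nd integer matrix of fold indices in `1:n_folds`.
#' @export
five_fold_split <- function(dataset, seed = 1L, n_folds = 5L) {
  LD <- dataset$LD
  pos <- which(LD == 1)
  neg <- which(LD == 0)
  if (length(pos) < n_folds) {
    stop("need at least ", n_folds, " positive pairs, have ", length(pos),
         call. = FALSE)
  }
  set.seed(seed)
  assign_folds <- function(idx) {
    f <- rep_len(seq_len(n_folds), length(idx))
    setNames(f, sample(idx))
  }
  folds <- matrix(NA_integer_, nrow(LD), ncol(LD), dimnames = dimnames(LD))
  fp <- assign_folds(pos)
  fn <- assign_folds(neg)
  folds[as.integer(names(fp))] <- fp
  folds[as.integer(names(fn))] <- fn
  folds
}

# trapezoidal ROC AUC with tie groups; identical to the Mann-Whitney
# statistic with half credit for ties
roc_auc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- unname(tapply(y, grp, sum))
  fp <- unname(tapply(1 - y, grp, sum))
  ctp <- c(0, cumsum(tp)); cfp <- c(0, cumsum(fp))
  P <- sum(labels); N <- length(labels) - P
  tpr <- ctp / P; fpr <- cfp / N
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# precision-recall area by step integration over tie-grouped thresholds:
# sum over recall increments of the precision attained at that threshold
pr_auc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- unname(tapply(y, grp, sum))
  n_at <- unname(tapply(y, grp, length))
  ctp <- cumsum(tp); cn <- cumsum(n_at)
  P <- sum(labels)
  recall <- ctp / P
  precision <- ctp / cn
  sum(diff(c(0, recall)) * precision)
}

confusion_stats <- function(tp, fp, fn, tn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  c(f1 = f1, mcc = mcc, precision = prec, recall = rec)
}

#' Ranking and classification metrics for pooled predictions
#'
#' AUC is the area under the ROC curve by trapezoidal integration over
#' tie-grouped thresholds (exactly the Mann-Whitney concordance statistic
#' with half credit for ties). AUPR integrates precision over recall
#' increments. F1 and MCC are computed at a binarization threshold chosen
#' by `threshold_rule`: `"max_f1"` scans all distinct scores for the
#' F1-maximizing threshold, `"fixed"` uses the supplied value.
#'
#' @param scores Numeric prediction vector.
#' @param labels Binary label vector (same length).
#' @param threshold_rule `"max_f1"` or `"fixed"`.
#' @param threshold Fixed threshold when `threshold_rule = "fixed"`;
#'   predictions with `score >= threshold` are called positive.
#' @return A tibble with columns `auc`, `aupr`, `f1`, `mcc`, `threshold`.
#' @examples
#' compute_metrics(c(0.9, 0.4, 0.35, 0.1), c(1, 0, 1, 0))
#' @export
compute_metrics <- function(scores, labels, threshold_rule = "max_f1",
                            threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  P <- sum(labels); N <- length(labels) - P
  if (P == 0 || N == 0) {
    stop("compute_metrics needs both classes present", call. = FALSE)
  }
  auc <- roc_auc(scores, labels)
  aupr <- pr_auc(scores, labels)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  ctp <- cumsum(y)[keep]
  cn <- seq_along(y)[keep]
  tp <- ctp; fp <- cn - ctp; fn <- P - tp; tn <- N - fp
  prec <- ifelse(cn > 0, tp / cn, 0)
  rec <- tp / P
  f1s <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  if (threshold_rule == "max_f1") {
    best <- which.max(f1s)
    thr <- s[keep][best]
    st <- confusion_stats(tp[best], fp[best], fn[best], tn[best])
  } else {
    pred <- as.numeric(scores >= threshold)
    st <- confusion_stats(sum(pred * labels), sum(pred * (1 - labels)),
                          sum((1 - pred) * labels),
                          sum((1 - pred) * (1 - labels)))
    thr <- threshold
  }
  tibble::tibble(auc = auc, aupr = aupr, f1 = unname(st["f1"]),
                 mcc = unname(st["mcc"]), threshold = thr)
}

#' Per-disease top-k recall
#'
#' For each disease, its candidate lncRNAs (all lncRNAs except excluded
#' ones, e.g. training positives) are ranked by score, descending, ties
#' broken by lncRNA index ascending; the top k are called positive. The
#' recall is the fraction of all test positives captured this way,
#' aggregated over diseases.
#'
#' @param score_matrix nl x nd score matrix.
#' @param test_positives nl x nd binary/logical matrix of held-out true
#'   associations.
#' @param k Number of top-ranked lncRNAs called per disease; values above
#'   nl are clamped with a warning.
#' @param exclude Optional nl x nd logical matrix of pairs that are not
#'   candidates (e.g. training positives); they are never called.
#' @return Scalar recall in \[0, 1\].
#' @export
topk_recall <- function(score_matrix, test_positives, k, exclude = NULL) {
  stopifnot(k >= 1)
  nl <- nrow(score_matrix)
  if (k > nl) {
    warning("k = ", k, " exceeds the number of lncRNAs (", nl,
            "); clamped", call. = FALSE)
    k <- nl
  }
  test_positives <- test_positives != 0
  total <- sum(test_positives)
  if (total == 0) return(NA_real_)
  hit <- 0
  for (j in seq_len(ncol(score_matrix))) {
    cand <- if (is.null(exclude)) seq_len(nl) else which(!exclude[, j])
    if (!length(cand)) next
    ord <- cand[order(-score_matrix[cand, j], cand)]
    top <- ord[seq_len(min(k, length(ord)))]
    hit <- hit + sum(test_positives[top, j])
  }
  hit / total
}

#' Five-fold cross-validated evaluation of the full pipeline
#'
#' For each fold: the test-fold positives are removed from the association
#' matrix *everywhere it is consumed* (similarities, both view adjacencies
#' and the loss), the model is trained on the remaining data, and the
#' held-out pairs are scored. Test-pair scores are pooled over the five
#' folds (every pair is scored exactly once) and all metrics are computed
#' on the pooled set.
#'
#' @param dataset An `lnclink_dataset`.
#' @param config An `lnclink_config`.
#' @param view `"both"` for the multiview model, `"net1"`/`"net2"` for the
#'   single-view ablations.
#' @param semantic_DS Optional precomputed disease semantic similarity.
#' @param progress Emit per-fold progress messages.
#' @return An object of class `lnclink_cv`: `predictions` (tibble with
#'   lncrna, disease, score, label, fold), `metrics` (tibble), `topk`
#'   (tibble: k, recall), `folds` (matrix), `pooled_scores` (matrix),
#'   `traces` (list of per-fold loss traces), `view`, `config`.
#' @export
run_cross_validation <- function(dataset, config = lnclink_config(),
                                 view = c("both", "net1", "net2"),
                                 semantic_DS = NULL, progress = FALSE) {
  view <- match.arg(view)
  folds <- five_fold_split(dataset, config$seed)
  n_folds <- max(folds)
  LD <- dataset$LD
  pooled <- matrix(NA_real_, nrow(LD), ncol(LD), dimnames = dimnames(LD))
  traces <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_mask <- folds == f
    LD_train <- LD
    LD_train[test_mask] <- 0  # hide held-out positives everywhere
    ds_train <- assemble_dataset(LD_train, dataset$LM,
                                 dataset$lncrna_ids, dataset$disease_ids,
                                 dataset$mirna_ids)
    views <- build_views(ds_train, config, semantic_DS, view)
    masks <- make_mask_pair(LD, test_mask)
    # overwrite positives that fell into the test fold: the trainer must
    # never see them as labels either
    fit <- train_model(views, LD_train, masks, config,
                       seed = config$seed + 101L * f)
    pooled[test_mask] <- fit$scores[test_mask]
    traces[[f]] <- fit$trace
    if (progress) {
      message(sprintf("fold %d/%d: final loss %.4g", f, n_folds,
                      fit$trace$loss[nrow(fit$trace)]))
    }
  }
  stopifnot(!anyNA(pooled))
  metrics <- compute_metrics(as.vector(pooled), as.vector(LD),
                             config$threshold_rule,
                             config$classification_threshold)
  ks <- config$topk[config$topk <= nrow(LD)]
  if (length(ks) < length(config$topk)) {
    ks <- unique(c(ks, nrow(LD)))  # clamp oversized k to nl
  }
  topk <- tibble::tibble(
    k = as.integer(ks),
    recall = vapply(ks, function(k) topk_recall(pooled, LD, k), numeric(1))
  )
  predictions <- tibble::tibble(
    lncrna = rep(dataset$lncrna_ids, times = ncol(LD)),
    disease = rep(dataset$disease_ids, each = nrow(LD)),
    score = as.vector(pooled),
    label = as.integer(as.vector(LD)),
    fold = as.integer(as.vector(folds))
  )
  structure(
    list(predictions = predictions, metrics = metrics, topk = topk,
         folds = folds, pooled_scores = pooled, traces = traces,
         view = view, config = config),
    class = "lnclink_cv"
  )
}

#' @export
print.lnclink_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<lnclink_cv> view = %s, 5-fold pooled metrics:\n", x$view))
  cat(sprintf("  AUC %.4f | AUPR %.4f | F1 %.4f | MCC %.4f (threshold %.3g)\n",
              m$auc, m$aupr, m$f1, m$mcc, m$threshold))
  if (nrow(x$topk)) {
    cat("  top-k recall:",
        paste(sprintf("k=%d: %.3f", x$topk$k, x$topk$recall),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy lnclink_cv
#' @export
tidy.lnclink_cv <- function(x, ...) x$predictions

#' @method glance lnclink_cv
#' @export
glance.lnclink_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(view = x$view), x$metrics)
}

#' ROC and precision-recall curves of a cross-validation result
#'
#' @param object An `lnclink_cv`.
#' @param ... Unused.
#' @return A ggplot object with ROC and PR panels.
#' @method autoplot lnclink_cv
#' @export
autoplot.lnclink_cv <- function(object, ...) {
  cd <- curve_data(object$predictions$score, object$predictions$label)
  df <- dplyr::bind_rows(
    tibble::tibble(panel = "ROC", x = cd$fpr, y = cd$tpr),
    tibble::tibble(panel = "Precision-Recall", x = cd$recall,
                   y = cd$precision)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Pooled CV curves (view = %s)",
                                  object$view)) +
    ggplot2::theme_minimal()
}

#' ROC / precision-recall coordinates for plotting or export
#'
#' @param scores,labels Pooled predictions and binary labels.
#' @return A tibble with `threshold`, `fpr`, `tpr`, `recall`, `precision`.
#' @export
curve_data <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- as.numeric(labels)[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  ctp <- cumsum(y)[keep]; cn <- seq_along(y)[keep]
  P <- sum(y); N <- length(y) - P
  tibble::tibble(
    threshold = s[keep],
    fpr = (cn - ctp) / N,
    tpr = ctp / P,
    recall = ctp / P,
    precision = ctp / cn
  )
}
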