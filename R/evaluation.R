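#' Leave-one-out cross-validation with fold-nested feature selection
#'
#' For each sample in turn: the association scan, variant ranking and top-k
#' selection are recomputed on the remaining samples only; missing dosages
#' are mean-imputed from the training fold; a Cauchy-prior logistic risk
#' model is fitted on the training fold; and the held-out sample's risk is
#' predicted out-of-fold. The held-out sample therefore never influences its
#' own fold's feature selection, imputation or training. Fold-selected
#' variant lists are pooled as a de-duplicated union ordered by selection
#' frequency (then best within-fold rank).
#'
#' @param genotypes samples x variants dosage matrix with dimnames.
#' @param annotations annotation data frame aligned to the matrix columns.
#' @param phenotypes phenotype data frame as from [read_phenotypes()], rows
#'   aligned to the genotype rows; the `severity` column is the target.
#' @param k number of top-ranked variants selected inside each fold.
#' @param threshold risk threshold for the severe call (ties to severe).
#' @param prior_scale,prior_scale_intercept passed to [fit_risk_model()].
#' @return an object of class `loocv_result`: list with `k`, `per_sample`
#'   (data frame: `sample_id`, `true`, `risk`, `predicted`), `fold_variants`
#'   (named list of per-fold selections), `confusion` (`tp`, `fp`, `fn`,
#'   `tn`; severe = positive), `metrics` (accuracy, sensitivity,
#'   specificity, mcc, auc), and `pooled_variants` (data frame:
#'   `variant_id`, `n_folds`, `best_rank`).
#' @export
run_loocv <- function(genotypes, annotations, phenotypes, k,
                      threshold = 0.5, prior_scale = 2.5,
                      prior_scale_intercept = 10) {
  n <- nrow(genotypes)
  severity <- phenotypes$severity
  if (length(severity) != n)
    stop_validation("phenotypes must have one row per genotype sample")
  if (sum(severity == "severe") < 2L || sum(severity == "mild") < 2L)
    stop_validation("need at least 2 samples per class for LOOCV")
  if (!is_count(k, 1L) || k > ncol(genotypes))
    stop_validation("k must satisfy 1 <= k <= number of variants")

  sample_ids <- rownames(genotypes) %||% as.character(seq_len(n))
  risks <- numeric(n)
  fold_variants <- vector("list", n)
  names(fold_variants) <- sample_ids
  fold_rank <- list()

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    scan <- assoc_scan(genotypes[tr, , drop = FALSE], annotations, severity[tr])
    ranked <- rank_variants(scan)
    sel <- select_top_k(ranked, k)
    fold_variants[[i]] <- sel

    xtr <- genotypes[tr, sel, drop = FALSE]
    ctr <- colMeans(xtr, na.rm = TRUE)
    for (j in seq_along(sel)) {
      nas <- is.na(xtr[, j])
      if (any(nas)) xtr[nas, j] <- ctr[j]
    }
    fit <- fit_risk_model(xtr, severity[tr], prior_scale = prior_scale,
                          prior_scale_intercept = prior_scale_intercept)
    xte <- genotypes[i, sel, drop = FALSE]
    nas <- is.na(xte[1L, ])
    if (any(nas)) xte[1L, nas] <- ctr[nas]
    risks[i] <- predict(fit, xte, type = "response")
  }

  predicted <- ifelse(risks >= threshold, "severe", "mild")
  tp <- sum(predicted == "severe" & severity == "severe")
  fp <- sum(predicted == "severe" & severity == "mild")
  fn <- sum(predicted == "mild" & severity == "severe")
  tn <- sum(predicted == "mild" & severity == "mild")
  metrics <- confusion_metrics(tp, fp, fn, tn)
  metrics$auc <- roc_auc(risks, severity)

  tab <- table(unlist(fold_variants))
  best_rank <- vapply(names(tab), function(vid) {
    min(vapply(fold_variants, function(sel) {
      m <- match(vid, sel)
      if (is.na(m)) length(sel) + 1L else m
    }, integer(1)))
  }, integer(1))
  ord <- order(-as.integer(tab), best_rank, names(tab), method = "radix")
  pooled <- data.frame(variant_id = names(tab)[ord],
                       n_folds = as.integer(tab)[ord],
                       best_rank = unname(best_rank[ord]),
                       stringsAsFactors = FALSE)

  structure(
    list(k = k,
         per_sample = data.frame(sample_id = sample_ids, true = severity,
                                 risk = risks, predicted = predicted,
                                 stringsAsFactors = FALSE),
         fold_variants = fold_variants,
         confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
         metrics = metrics,
         pooled_variants = pooled),
    class = "loocv_result")
}

#' @exportS3Method base::print
print.loocv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("LOOCV (k = %d, %d folds)\n", x$k, nrow(x$per_sample)))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * m$accuracy, 100 * m$sensitivity, 100 * m$specificity))
  cat(sprintf("  MCC %.3f  AUC %.3f  pooled variants %d\n",
              m$mcc, m$auc, nrow(x$pooled_variants)))
  invisible(x)
}

#' @export
summary.loocv_result <- function(object, ...) {
  print(object)
  cat("Confusion (severe = positive):\n")
  print(object$confusion)
  invisible(object)
}

#' Scan the number of selected variants until accuracy saturates
#'
#' Runs [run_loocv()] over an increasing grid of k (top variants per fold),
#' starting at `k_start` and stepping by `k_step`, and stops once `patience`
#' consecutive evaluations fall strictly below the running maximum accuracy
#' (evaluations tying the maximum do not count against patience), or when
#' `k_max` is reached. The chosen k is the smallest grid point attaining the
#' maximum accuracy.
#'
#' @inheritParams run_loocv
#' @param k_start first grid value.
#' @param k_step grid increment.
#' @param patience consecutive below-maximum evaluations tolerated before
#'   stopping.
#' @param k_max largest k considered.
#' @param evaluator optional function `k -> accuracy`, used instead of the
#'   full LOOCV (exposed for testing and custom pipelines).
#' @param ... passed on to [run_loocv()].
#' @return object of class `saturation_scan`: list with `grid`,
#'   `accuracy_by_k` (named numeric), `chosen_k`.
#' @export
saturation_scan <- function(genotypes = NULL, annotations = NULL,
                            phenotypes = NULL, k_start = 6L, k_step = 2L,
                            patience = 3L, k_max = NULL, evaluator = NULL, ...) {
  if (!is_count(k_start, 1L)) stop_validation("k_start must be >= 1")
  if (!is_count(k_step, 1L)) stop_validation("k_step must be >= 1")
  if (is.null(k_max))
    k_max <- if (!is.null(genotypes)) min(50L, ncol(genotypes)) else
      stop_validation("k_max is required when no genotypes are supplied")
  if (k_max < k_start) stop_validation("k_max must be >= k_start")
  if (is.null(evaluator)) {
    evaluator <- function(k)
      run_loocv(genotypes, annotations, phenotypes, k, ...)$metrics$accuracy
  }
  grid <- integer(0)
  acc <- numeric(0)
  best <- -Inf
  below <- 0L
  k <- k_start
  while (k <= k_max) {
    a <- evaluator(k)
    grid <- c(grid, k)
    acc <- c(acc, a)
    if (a > best) {
      best <- a
      below <- 0L
    } else if (a < best) {
      below <- below + 1L
      if (below >= patience) break
    }
    k <- k + k_step
  }
  names(acc) <- grid
  chosen_k <- grid[which(acc == max(acc))[1L]]
  structure(list(grid = grid, accuracy_by_k = acc, chosen_k = chosen_k),
            class = "saturation_scan")
}

#' @exportS3Method base::print
print.saturation_scan <- function(x, ...) {
  cat("Saturation scan over top-k selected variants\n")
  print(round(x$accuracy_by_k, 4))
  cat(sprintf("chosen k = %d (accuracy %.4f)\n", x$chosen_k,
              max(x$accuracy_by_k)))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Severe is the positive class. Sensitivity or specificity with a zero
#' denominator is reported as `NA`; the Matthews correlation coefficient is
#' defined as 0 whenever any factor of its denominator vanishes (e.g. all
#' predictions in one class).
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `mcc`
#'   (proportions, not percentages).
#' @examples
#' confusion_metrics(tp = 11, fp = 2, fn = 4, tn = 16)
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  cells <- c(tp, fp, fn, tn)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop_validation("confusion cells must be non-negative integers")
  total <- sum(cells)
  if (total == 0) stop_validation("empty confusion matrix")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  list(accuracy = (tp + tn) / total, sensitivity = sens,
       specificity = spec, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a severe sample's risk
#' exceeds a mild sample's risk, with ties counting one half — equivalent to
#' trapezoidal integration of the empirical ROC curve.
#'
#' @param risks numeric risk scores.
#' @param truths `"severe"`/`"mild"` labels (or 0/1, 1 = severe).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(risks, truths) {
  y <- encode_severity(truths)
  if (length(risks) != length(y)) stop_validation("risks and truths differ in length")
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    stop_validation("both classes must be present to compute AUC")
  r <- rank(risks)  # midranks handle ties
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve coordinates
#'
#' Empirical ROC coordinates (false positive rate, true positive rate) over
#' all distinct thresholds, for external plotting.
#'
#' @inheritParams roc_auc
#' @return data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(risks, truths) {
  y <- encode_severity(truths)
  thr <- c(Inf, sort(unique(risks), decreasing = TRUE))
  data.frame(threshold = thr,
             fpr = vapply(thr, function(t) mean(risks[y == 0] >= t), numeric(1)),
             tpr = vapply(thr, function(t) mean(risks[y == 1] >= t), numeric(1)))
}

#' Reclassification comparison of two risk models
#'
#' Categorizes old and new risks into the half-open intervals defined by
#' `cutpoints` (the last interval is closed) and computes the net
#' reclassification improvement and the integrated discrimination
#' improvement, with severe samples as events:
#' `NRI = [P(up|severe) - P(down|severe)] - [P(up|mild) - P(down|mild)]`,
#' `IDI = [mean(new) - mean(old)]_severe - [mean(new) - mean(old)]_mild`.
#'
#' @param risks_old,risks_new risk vectors from the old and new model.
#' @param truths `"severe"`/`"mild"` labels.
#' @param cutpoints strictly increasing category boundaries spanning `[0,1]`.
#' @return object of class `reclassification`: list with `categories`,
#'   `table_events`, `table_nonevents`, `nri`, `idi`.
#' @export
reclassification <- function(risks_old, risks_new, truths,
                             cutpoints = c(0, 0.5, 1)) {
  if (length(risks_old) != length(risks_new) ||
      length(risks_old) != length(truths))
    stop_validation("risks_old, risks_new and truths must have equal length")
  if (length(cutpoints) < 2L || any(diff(cutpoints) <= 0) ||
      cutpoints[1L] != 0 || cutpoints[length(cutpoints)] != 1)
    stop_validation("cutpoints must be strictly increasing and span [0,1]")
  y <- encode_severity(truths)
  ncat <- length(cutpoints) - 1L
  categorize <- function(r) pmin(findInterval(r, cutpoints), ncat)
  co <- categorize(risks_old)
  cn <- categorize(risks_new)
  lev <- seq_len(ncat)
  tab <- function(sel) table(factor(co[sel], levels = lev),
                             factor(cn[sel], levels = lev))
  ev <- y == 1
  up <- cn > co
  down <- cn < co
  nri <- (mean(up[ev]) - mean(down[ev])) - (mean(up[!ev]) - mean(down[!ev]))
  idi <- (mean(risks_new[ev]) - mean(risks_old[ev])) -
    (mean(risks_new[!ev]) - mean(risks_old[!ev]))
  structure(list(categories = cutpoints,
                 table_events = tab(ev),
                 table_nonevents = tab(!ev),
                 nri = nri, idi = idi),
            class = "reclassification")
}

#' @exportS3Method base::print
print.reclassification <- function(x, ...) {
  cat(sprintf("Reclassification: NRI = %.4f, IDI = %.4f\n", x$nri, x$idi))
  invisible(x)
}

#' Cluster out-of-fold risk scores into molecular subtypes
#'
#' Agglomerative clustering of the scalar risk scores with Euclidean
#' distance and average (UPGMA) linkage, cut to `n_clusters`. With two
#' clusters, the cluster with the higher mean risk is labeled
#' `"high-risk"` and the other `"low-risk"`; samples whose cluster label
#' disagrees with their clinical severity are flagged discordant. Output
#' rows are sorted by descending risk.
#'
#' @param predictions data frame with columns `sample_id`, `risk` and `true`
#'   (clinical severity), e.g. the `per_sample` table of a `loocv_result`.
#' @param n_clusters number of clusters to cut the tree into.
#' @return object of class `risk_clusters`: list with `hclust` (the tree),
#'   `assignments` (data frame: `sample_id`, `risk`, `true`, `cluster`,
#'   `discordant`), and `discordant` (character vector of sample IDs).
#' @export
cluster_risk_scores <- function(predictions, n_clusters = 2L) {
  need <- c("sample_id", "risk", "true")
  if (!all(need %in% names(predictions)))
    stop_validation("predictions needs columns sample_id, risk, true")
  n <- nrow(predictions)
  if (n < n_clusters) stop_validation("fewer samples than clusters")
  hc <- stats::hclust(stats::dist(predictions$risk), method = "average")
  raw <- stats::cutree(hc, k = n_clusters)
  means <- tapply(predictions$risk, raw, mean)
  rank_by_risk <- rank(-means, ties.method = "first")
  if (n_clusters == 2L) {
    cluster <- ifelse(rank_by_risk[as.character(raw)] == 1L, "high-risk", "low-risk")
    discordant_flag <- (cluster == "high-risk") != (predictions$true == "severe")
  } else {
    cluster <- paste0("C", rank_by_risk[as.character(raw)])
    discordant_flag <- rep(NA, n)
  }
  assignments <- data.frame(sample_id = predictions$sample_id,
                            risk = predictions$risk,
                            true = predictions$true,
                            cluster = cluster,
                            discordant = discordant_flag,
                            stringsAsFactors = FALSE)
  assignments <- assignments[order(-assignments$risk, assignments$sample_id), ]
  rownames(assignments) <- NULL
  structure(list(hclust = hc, assignments = assignments,
                 discordant = assignments$sample_id[!is.na(assignments$discordant) &
                                                      assignments$discordant]),
            class = "risk_clusters")
}

#' @exportS3Method base::print
print.risk_clusters <- function(x, ...) {
  cat(sprintf("Risk-score clustering: %d samples, %d discordant with clinical grading\n",
              nrow(x$assignments), length(x$discordant)))
  if (length(x$discordant) > 0L)
    cat("  discordant:", paste(x$discordant, collapse = ", "), "\n")
  invisible(x)
}
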