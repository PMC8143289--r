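# ROC/AUC, Youden cutoff, confusion-derived metrics, bootstrap CIs and
# report artifacts (waterfall / boxplot data).

#' Empirical ROC curve and AUC
#'
#' ROC points over all distinct thresholds with the convention "predict
#' positive when score >= threshold". The AUC is the trapezoidal area,
#' computed through the rank (Mann-Whitney) identity so that tied scores
#' count one half.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary 0/1 labels (both classes present).
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    abort("both classes must be present", "evaluation_error")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / n0, numeric(1))
  list(points = data.frame(threshold = th, fpr = fpr, tpr = tpr), auc = auc)
}

#' Youden-index cutoff
#'
#' The threshold maximizing informedness (sensitivity + specificity - 1).
#' Ties are broken toward the higher specificity (fewer false positives),
#' then toward the larger threshold.
#'
#' @param roc The `points` data frame from [roc_auc()] (or the whole
#'   list).
#' @return The selected finite threshold.
#' @export
youden_cutoff <- function(roc) {
  pts <- if (is.data.frame(roc)) roc else roc$points
  pts <- pts[is.finite(pts$threshold), , drop = FALSE]
  if (nrow(pts) == 0L) abort("empty ROC", "evaluation_error")
  J <- pts$tpr - pts$fpr
  key <- order(-J, pts$fpr, -pts$threshold)
  pts$threshold[key[1]]
}

#' Confusion-matrix derived metrics
#'
#' Sensitivity, specificity, informedness, PPV, FDR and the F2-score
#' (`5 * PPV * SE / (4 * PPV + SE)`, recall weighted four times
#' precision). Metrics whose denominator is zero are returned as `NA` and
#' named in the `undefined` element rather than silently zeroed.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @return List with the counts, `sensitivity`, `specificity`,
#'   `informedness`, `ppv`, `fdr`, `f2` and `undefined`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("confusion counts must be non-negative integers", "validation_error")
  undefined <- character(0)
  se <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  sp <- if (tn + fp > 0) tn / (tn + fp) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  ppv <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "ppv", "fdr", "f2"); NA_real_
  }
  f2 <- if (is.na(ppv) || is.na(se)) NA_real_
        else if (ppv + se == 0) 0
        else 5 * ppv * se / (4 * ppv + se)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = se, specificity = sp,
       informedness = se + sp - 1,
       ppv = ppv, fdr = 1 - ppv, f2 = f2,
       undefined = undefined)
}

confusion_from_scores <- function(scores, labels, cutoff) {
  pred <- as.integer(scores >= cutoff)
  confusion_metrics(tp = sum(pred == 1 & labels == 1),
                    fp = sum(pred == 1 & labels == 0),
                    fn = sum(pred == 0 & labels == 1),
                    tn = sum(pred == 0 & labels == 0))
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples each class with replacement separately (so both classes are
#' always present), recomputes the AUC `n_boot` times, and returns the
#' percentile interval.
#'
#' @param scores,labels As in [roc_auc()].
#' @param n_boot Number of resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric pair `(lo, hi)`.
#' @export
auc_bootstrap_ci <- function(scores, labels, n_boot = 2000, level = 0.95, seed = 1) {
  if (length(unique(labels)) < 2L)
    abort("both classes must be present", "evaluation_error")
  set.seed(seed)
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  reps <- vapply(seq_len(n_boot), function(b) {
    j <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    roc_auc(scores[j], labels[j])$auc
  }, numeric(1))
  a <- (1 - level) / 2
  stats::setNames(as.numeric(stats::quantile(reps, c(a, 1 - a))), c("lo", "hi"))
}

#' Group medians and separation p-value of the radiomic score
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels.
#' @return List with `median_ncs`, `median_cs` and the two-sided Wilcoxon
#'   rank-sum `p`.
#' @export
group_separation <- function(scores, labels) {
  list(median_ncs = stats::median(scores[labels == 0]),
       median_cs = stats::median(scores[labels == 1]),
       p = wilcoxon_rank_sum(scores[labels == 1], scores[labels == 0]))
}

#' Evaluate radiomic scores against labels
#'
#' Full evaluation of a score vector: ROC/AUC with a stratified bootstrap
#' 95% CI, the Youden cutoff, confusion counts and derived metrics at
#' that cutoff, per-patient waterfall data and group separation.
#'
#' @param scores Radiomic probability scores.
#' @param labels Binary 0/1 labels.
#' @param patient_id Optional ids for the waterfall data.
#' @param n_boot,seed Bootstrap parameters (see [auc_bootstrap_ci()]).
#' @param cutoff Optional fixed cutoff; default is the Youden cutoff of
#'   these scores.
#' @return List of class `locrad_report`.
#' @export
evaluate_scores <- function(scores, labels, patient_id = NULL,
                            n_boot = 2000, seed = 1, cutoff = NULL) {
  roc <- roc_auc(scores, labels)
  ci <- auc_bootstrap_ci(scores, labels, n_boot = n_boot, seed = seed)
  if (is.null(cutoff)) cutoff <- youden_cutoff(roc)
  cm <- confusion_from_scores(scores, labels, cutoff)
  sep <- group_separation(scores, labels)
  if (is.null(patient_id)) patient_id <- sprintf("P%03d", seq_along(scores))
  wf <- data.frame(patient_id = patient_id, label = labels, score = scores,
                   stringsAsFactors = FALSE)
  wf <- wf[order(wf$score, decreasing = TRUE), ]
  structure(list(
    roc = roc$points, auc = roc$auc, auc_ci = as.list(ci),
    youden_cutoff = cutoff,
    confusion = cm[c("tp", "fp", "fn", "tn")],
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    informedness = cm$informedness, ppv = cm$ppv, fdr = cm$fdr, f2 = cm$f2,
    waterfall = wf,
    group_medians = sep[c("median_ncs", "median_cs")],
    separation_p = sep$p,
    n = length(scores)),
    class = "locrad_report")
}

#' @export
print.locrad_report <- function(x, ...) {
  cat(sprintf("locrad_report: n = %d, AUC = %.2f (95%% CI %.2f-%.2f)\n",
              x$n, x$auc, x$auc_ci$lo, x$auc_ci$hi))
  cat(sprintf("  at Youden cutoff %.3f: SE %.2f, SP %.2f, I %.2f, PPV %.2f, FDR %.2f, F2 %.2f\n",
              x$youden_cutoff, x$sensitivity, x$specificity, x$informedness,
              x$ppv, x$fdr, x$f2))
  cat(sprintf("  score medians: ncs %.2f, cs %.2f (separation p = %.2g)\n",
              x$group_medians$median_ncs, x$group_medians$median_cs,
              x$separation_p))
  invisible(x)
}

#' Serialize an evaluation report (and optional plots)
#'
#' Writes the report as JSON (numbers exactly as held in memory) and,
#' when `plots_dir` is given, renders ROC, waterfall and score-boxplot
#' figures as PNG files.
#'
#' @param report A `locrad_report` from [evaluate_scores()].
#' @param path JSON output path.
#' @param plots_dir Optional directory for the figures.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, plots_dir = NULL) {
  write_report_json(report, path)
  if (!is.null(plots_dir)) {
    dir.create(plots_dir, showWarnings = FALSE, recursive = TRUE)
    grDevices::png(file.path(plots_dir, "roc.png"), 600, 600)
    graphics::plot(report$roc$fpr, report$roc$tpr, type = "s",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("ROC (AUC = %.2f)", report$auc))
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
    wf <- report$waterfall
    grDevices::png(file.path(plots_dir, "waterfall.png"), 800, 500)
    graphics::barplot(wf$score, col = ifelse(wf$label == 1, "darkblue", "green3"),
                      border = NA, ylab = "radiomic score",
                      main = "Radiomic score per patient")
    graphics::abline(h = report$youden_cutoff, lty = 2)
    grDevices::dev.off()
    grDevices::png(file.path(plots_dir, "boxplot.png"), 500, 600)
    graphics::boxplot(score ~ label, data = wf,
                      names = c("ncsPCa", "csPCa"),
                      col = c("green3", "darkblue"),
                      ylab = "radiomic score",
                      main = sprintf("Group separation (p = %.2g)",
                                     report$separation_p))
    grDevices::dev.off()
  }
  invisible(path)
}
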