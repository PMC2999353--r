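# Detection-to-truth matching and ROC / precision-recall benchmarking.

#' Match detections to ground-truth peptides
#'
#' A detection hits a truth peptide when its mass lies within `dmz` ppm of
#' the truth mass and the elution windows share at least one scan. Each truth
#' entry can be claimed by at most one detection: detections are visited in
#' decreasing order of the ranking criterion (ties broken by smaller mass
#' error) and a detection matching only already-claimed truth entries is
#' labelled a `duplicate` (typically another charge hypothesis of the same
#' feature) and excluded from the false-positive universe.
#'
#' @param outlist Data frame of detections (e.g. `fit$outlist`).
#' @param truth A `ground_truth` data frame.
#' @param dmz ppm mass tolerance (the detector's own tolerance is reused).
#' @param criterion Ranking column used for best-wins assignment (default
#'   `"score"`).
#' @return `outlist` with added columns `label` (`"hit"`, `"duplicate"`,
#'   `"nonhit"`) and `truth_row` (claimed truth row or `NA`); the per-truth
#'   hit flags are in `attr(, "truth_hit")`.
#' @export
match_detections <- function(outlist, truth, dmz = 10, criterion = "score") {
  if (!criterion %in% names(outlist))
    icpd_stop("unknown ranking criterion: ", criterion)
  n <- nrow(outlist)
  label <- rep("nonhit", n)
  truth_row <- rep(NA_integer_, n)
  claimed <- rep(FALSE, nrow(truth))
  if (n > 0 && nrow(truth) > 0) {
    ord <- order(-outlist[[criterion]])
    to <- order(truth$mass)
    tm <- truth$mass[to]
    for (i in ord) {
      m <- outlist$mass[i]
      tol <- dmz * 1e-6 * m
      lo <- findInterval(m - tol, tm, left.open = TRUE) + 1L
      hi <- findInterval(m + tol, tm)
      if (lo > hi) next
      cand <- to[lo:hi]
      cand <- cand[abs(truth$mass[cand] - m) <= dmz * 1e-6 * truth$mass[cand] &
                   pmax(truth$rt_start[cand], outlist$rt_start[i]) <=
                   pmin(truth$rt_end[cand], outlist$rt_end[i])]
      if (length(cand) == 0) next
      free <- cand[!claimed[cand]]
      if (length(free) > 0) {
        best <- free[which.min(abs(truth$mass[free] - m))]
        claimed[best] <- TRUE
        label[i] <- "hit"
        truth_row[i] <- best
      } else label[i] <- "duplicate"
    }
  }
  out <- outlist
  out$label <- label
  out$truth_row <- truth_row
  attr(out, "truth_hit") <- claimed
  out
}

#' ROC and precision-recall curves by threshold sweep
#'
#' Sweeps a threshold over all distinct values of the ranking criterion.
#' Candidates at or above the threshold are detected; true/false positives
#' come from [match_detections()] (duplicates are dropped from the candidate
#' universe), true-positive rate is `TP / (TP + FN)` with `TP + FN` the
#' number of truth peptides, and the false-positive rate uses the non-hit
#' candidates of the output list as the negative universe (the protocol is
#' list-based: there is no pixel-level negative universe). Precision is
#' `TP / (TP + FP)` and recall equals the true-positive rate. ROC AUC is
#' trapezoidal; PR AUC uses step interpolation.
#'
#' @inheritParams match_detections
#' @param tier Optional tier label: restrict the positives to truth entries
#'   with this `tier` value; detections claimed by other tiers are excluded
#'   from the universe rather than counted as false positives.
#' @return Object of class `icpd_curves`: list with `curve` (data frame
#'   `threshold tp fp tpr fpr precision recall`), `auc_roc`, `auc_pr`,
#'   `n_truth`, `n_neg`, `criterion`. Empty `outlist` gives empty curves and
#'   `NA` AUCs.
#' @export
sweep_curves <- function(outlist, truth, dmz = 10, criterion = "score",
                         tier = NULL) {
  md <- match_detections(outlist, truth, dmz, criterion)
  if (!is.null(tier)) {
    if (!"tier" %in% names(truth)) icpd_stop("truth has no tier column")
    in_tier <- !is.na(md$truth_row) & truth$tier[md$truth_row] == tier
    drop <- (md$label %in% c("hit", "duplicate")) & !in_tier
    md <- md[!drop, , drop = FALSE]
    n_truth <- sum(truth$tier == tier)
  } else n_truth <- nrow(truth)
  md <- md[md$label != "duplicate", , drop = FALSE]
  n <- nrow(md)
  empty <- list(curve = data.frame(threshold = numeric(0), tp = integer(0),
                                   fp = integer(0), tpr = numeric(0),
                                   fpr = numeric(0), precision = numeric(0),
                                   recall = numeric(0)),
                auc_roc = NA_real_, auc_pr = NA_real_, n_truth = n_truth,
                n_neg = 0L, criterion = criterion)
  class(empty) <- "icpd_curves"
  if (n == 0 || n_truth == 0) return(empty)
  v <- md[[criterion]]
  o <- order(-v)
  is_hit <- md$label[o] == "hit"
  vv <- v[o]
  n_neg <- sum(!is_hit)
  cum_tp <- cumsum(is_hit)
  cum_fp <- cumsum(!is_hit)
  last <- !duplicated(vv, fromLast = TRUE)   # one point per distinct threshold
  tp <- cum_tp[last]; fp <- cum_fp[last]; thr <- vv[last]
  tpr <- tp / n_truth
  fpr <- if (n_neg > 0) fp / n_neg else rep(0, length(fp))
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  curve <- data.frame(threshold = thr, tp = tp, fp = fp, tpr = tpr, fpr = fpr,
                      precision = prec, recall = tpr)
  auc_roc <- .trapezoid(c(0, fpr, 1), c(0, tpr, tpr[length(tpr)]))
  auc_pr <- sum(diff(c(0, tpr)) * prec)      # step interpolation
  structure(list(curve = curve, auc_roc = auc_roc, auc_pr = auc_pr,
                 n_truth = n_truth, n_neg = n_neg, criterion = criterion),
            class = "icpd_curves")
}

.trapezoid <- function(x, y) {
  o <- order(x, y)
  sum(diff(x[o]) * (utils::head(y[o], -1) + utils::tail(y[o], -1)) / 2)
}

#' Threshold sweep under an alternative peak-picking criterion
#'
#' Identical protocol to [sweep_curves()] but ranking (and truth assignment)
#' by another column of the output list, e.g. `"volume"` (total peak volume),
#' `"max_intensity"`, or `"single_scan_score"` -- the classical alternatives
#' the matching score is compared against.
#'
#' @inheritParams sweep_curves
#' @param criterion Ranking column; must exist in `outlist`.
#' @return An `icpd_curves` object.
#' @export
baseline_criteria_curves <- function(outlist, truth, dmz = 10,
                                     criterion = c("volume", "max_intensity",
                                                   "score", "single_scan_score"),
                                     tier = NULL) {
  criterion <- tryCatch(match.arg(criterion),
                        error = function(e) icpd_stop("unknown criterion: ",
                                                      criterion[1]))
  sweep_curves(outlist, truth, dmz, criterion = criterion, tier = tier)
}

#' Precision at a target recall
#'
#' @param curves An `icpd_curves` object.
#' @param recall Target recall level (default 0.5).
#' @return Precision at the first threshold whose recall reaches the target;
#'   `NA` if the target recall is never reached.
#' @export
precision_at_recall <- function(curves, recall = 0.5) {
  cv <- curves$curve
  i <- which(cv$recall >= recall)
  if (length(i) == 0) return(NA_real_)
  cv$precision[min(i)]
}

#' @export
print.icpd_curves <- function(x, ...) {
  cat(sprintf("<icpd_curves> criterion '%s': %d truth, %d negatives\n",
              x$criterion, x$n_truth, x$n_neg))
  cat(sprintf("  ROC AUC %.4f, PR AUC %.4f\n", x$auc_roc, x$auc_pr))
  invisible(x)
}

#' Plot ROC and precision-recall curves
#'
#' @param x An `icpd_curves` object.
#' @param which `"roc"`, `"pr"` or `"both"` (default: both, side by side).
#' @param add Add to an existing plot (single panel only).
#' @param col Line colour.
#' @param ... Passed to [graphics::plot()] / [graphics::lines()].
#' @export
plot.icpd_curves <- function(x, which = c("both", "roc", "pr"), add = FALSE,
                             col = 1, ...) {
  which <- match.arg(which)
  cv <- x$curve
  draw_roc <- function() {
    if (add) graphics::lines(cv$fpr, cv$tpr, col = col, ...)
    else {
      graphics::plot(c(0, cv$fpr, 1), c(0, cv$tpr, max(cv$tpr)), type = "l",
                     xlab = "false positive rate", ylab = "true positive rate",
                     xlim = c(0, 1), ylim = c(0, 1), col = col, ...)
      graphics::abline(0, 1, lty = 3, col = "grey")
    }
  }
  draw_pr <- function() {
    if (add) graphics::lines(cv$recall, cv$precision, col = col, ...)
    else graphics::plot(cv$recall, cv$precision, type = "l",
                        xlab = "recall", ylab = "precision",
                        xlim = c(0, 1), ylim = c(0, 1), col = col, ...)
  }
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    draw_roc(); draw_pr()
  } else if (which == "roc") draw_roc() else draw_pr()
  invisible(x)
}

#' Export curve points to tsv
#'
#' Columns `threshold tpr fpr precision recall`.
#'
#' @param curves An `icpd_curves` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  utils::write.table(
    curves$curve[, c("threshold", "tpr", "fpr", "precision", "recall")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
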