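#' Cross-validation result container
#'
#' @param auc area under the ROC curve, in \[0,1\].
#' @param curve data.frame with columns `fpr`, `tpr`; starts at (0,0),
#'   ends at (1,1), both coordinates non-decreasing, and `auc` equals its
#'   trapezoidal area.
#' @param n_repeats number of CV repetitions pooled into the result.
#' @param auc_sd standard deviation of the per-repeat AUCs (NA for a
#'   single repeat).
#' @param per_repeat optional vector of per-repeat AUCs.
#' @return object of class `cv_result`.
#' @export
cv_result <- function(auc, curve, n_repeats = 1L, auc_sd = NA_real_,
                      per_repeat = NULL) {
  stopifnot(is.data.frame(curve), all(c("fpr", "tpr") %in% names(curve)))
  structure(list(auc = auc, curve = curve, n_repeats = n_repeats,
                 auc_sd = auc_sd, per_repeat = per_repeat),
            class = "cv_result")
}

trapezoid_area <- function(curve) {
  x <- curve$fpr
  y <- curve$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Midrank percentile of each test score within the candidate pool:
# u = (#{c < t} + 0.5 #{c = t}) / n_candidates.
rank_percentiles <- function(test_scores, candidate_scores) {
  sc <- sort(candidate_scores)
  le <- findInterval(test_scores, sc)                   # {c <= t}
  lt <- findInterval(test_scores, sc, left.open = TRUE) # {c <  t}
  (lt + 0.5 * (le - lt)) / length(sc)
}

# Exact-area ROC staircase for a pooled set of test percentiles u:
# each test contributes a vertical jump of height 1/n at fpr = 1 - u, so
# the trapezoidal area equals mean(u) exactly.
staircase_from_percentiles <- function(u) {
  n <- length(u)
  x <- sort(1 - u)
  jumps <- table(x)
  xs <- as.numeric(names(jumps))
  tpr_after <- cumsum(as.numeric(jumps)) / n
  tpr_before <- c(0, utils::head(tpr_after, -1))
  curve <- data.frame(fpr = rep(xs, each = 2L),
                      tpr = as.vector(rbind(tpr_before, tpr_after)))
  if (curve$fpr[1L] > 0 || curve$tpr[1L] > 0) {
    curve <- rbind(data.frame(fpr = 0, tpr = 0), curve)
  }
  if (curve$fpr[nrow(curve)] < 1) {
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
  }
  curve
}

#' Rank-based AUC of test scores against a candidate pool
#'
#' The AUC is the Mann-Whitney statistic with midrank tie handling:
#' (#\{(t,c): t > c\} + 0.5 #\{t = c\}) / (|tests| * |candidates|). The ROC
#' curve is built by sweeping the decision threshold over the pooled
#' unique scores; ties produce diagonal segments and the trapezoidal area
#' under the curve equals the statistic.
#'
#' @param test_scores scores of held-out positives (non-empty).
#' @param candidate_scores scores of the unlabeled candidate pairs
#'   (non-empty).
#' @return a [cv_result()].
#' @export
auc_from_scores <- function(test_scores, candidate_scores) {
  if (!length(test_scores)) stopf("empty test score list")
  if (!length(candidate_scores)) stopf("empty candidate score list")
  # exact half-integer arithmetic: a single division keeps the statistic
  # identical to exhaustive pair counting
  sc <- sort(candidate_scores)
  le <- findInterval(test_scores, sc)
  lt <- findInterval(test_scores, sc, left.open = TRUE)
  auc <- (sum(lt) + 0.5 * sum(le - lt)) /
    (length(test_scores) * length(candidate_scores))
  thresholds <- sort(unique(c(test_scores, candidate_scores)),
                     decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(test_scores >= t), 0)
  fpr <- vapply(thresholds, function(t) mean(candidate_scores >= t), 0)
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  cv_result(auc = auc, curve = curve, n_repeats = 1L)
}

# Effective scores used for ranking: reliable negatives are demoted
# strictly below every unmasked pair.
effective_scores <- function(sm) {
  if (is.matrix(sm)) return(sm)
  stopifnot(inherits(sm, "score_matrix"))
  s <- sm$scores
  if (!is.null(sm$negative_mask)) s[sm$negative_mask] <- -Inf
  s
}

candidate_pool <- function(A) {
  idx <- which(A$entries == 0)
  if (!length(idx)) stopf("degenerate candidate pool: no unlabeled pairs")
  idx
}

#' Leave-one-out cross validation
#'
#' Each known positive in turn is hidden (set to 0), all matrix-dependent
#' quantities are rebuilt by the scoring pipeline, and the held-out pair
#' is ranked against every unlabeled candidate pair. The pooled midrank
#' percentiles give the AUC.
#'
#' @param pipeline function taking a masked [association_matrix()] and
#'   returning a [score_matrix()] (or plain score matrix).
#' @param A an [association_matrix()] with at least 2 positives.
#' @return a [cv_result()].
#' @export
loocv <- function(pipeline, A) {
  stopifnot(inherits(A, "association_matrix"))
  pos <- which(A$entries == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stopf("need at least 2 positives for LOOCV")
  cand <- candidate_pool(A)
  u <- numeric(nrow(pos))
  for (t in seq_len(nrow(pos))) {
    a2 <- A$entries
    a2[pos[t, , drop = FALSE]] <- 0
    sm <- pipeline(association_matrix(a2, A$disease_ids, A$metabolite_ids))
    s <- effective_scores(sm)
    cs <- s[cand]
    if (all(is.infinite(cs))) {
      stopf("candidate pool is fully masked as reliable negatives")
    }
    u[t] <- rank_percentiles(s[pos[t, 1L], pos[t, 2L]], cs)
  }
  cv_result(auc = mean(u), curve = staircase_from_percentiles(u),
            n_repeats = 1L)
}

#' Random fold assignment of the known positives
#'
#' @param A an [association_matrix()].
#' @param k number of folds.
#' @param seed integer seed.
#' @return object of class `fold_split`: `assignments` (fold label per
#'   positive, positives indexed as rows of `which(A == 1, arr.ind)`),
#'   `k`, `seed`. Fold sizes differ by at most one.
#' @export
make_fold_split <- function(A, k, seed) {
  pos <- which(A$entries == 1, arr.ind = TRUE)
  if (nrow(pos) < k) stopf("fewer positives than folds")
  labels <- rep_len(seq_len(k), nrow(pos))
  assignments <- with_seed(seed, sample(labels))
  structure(list(assignments = assignments, positives = pos, k = k,
                 seed = seed),
            class = "fold_split")
}

#' Repeated k-fold cross validation
#'
#' Per repeat, the positives are split into k near-equal folds; each fold
#' is hidden in turn, the pipeline rescores the masked network, and the
#' fold's positives are ranked against the unlabeled candidate pairs.
#' The reported AUC is the mean over repeats (each repeat pools its folds'
#' percentiles), with the per-repeat standard deviation attached.
#'
#' @inheritParams loocv
#' @param k folds (5 by default).
#' @param n_repeats number of random re-splits (the original protocol uses
#'   100).
#' @param seed integer; repeat r uses `seed + r - 1` for its split.
#' @return a [cv_result()] with `n_repeats`, `auc_sd`, `per_repeat`.
#' @export
kfold_cv <- function(pipeline, A, k = 5L, n_repeats = 100L, seed = 1L) {
  stopifnot(inherits(A, "association_matrix"), k >= 2L, n_repeats >= 1L)
  cand <- candidate_pool(A)
  all_u <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    split <- make_fold_split(A, k, seed = seed + r - 1L)
    pos <- split$positives
    u <- numeric(nrow(pos))
    for (f in seq_len(k)) {
      in_fold <- split$assignments == f
      if (!any(in_fold)) next
      a2 <- A$entries
      a2[pos[in_fold, , drop = FALSE]] <- 0
      sm <- pipeline(association_matrix(a2, A$disease_ids,
                                        A$metabolite_ids))
      s <- effective_scores(sm)
      cs <- s[cand]
      if (all(is.infinite(cs))) {
        stopf("candidate pool is fully masked as reliable negatives")
      }
      u[in_fold] <- rank_percentiles(
        s[pos[in_fold, , drop = FALSE]], cs)
    }
    all_u[[r]] <- u
  }
  per_repeat <- vapply(all_u, mean, 0)
  pooled <- unlist(all_u)
  cv_result(auc = mean(per_repeat),
            curve = staircase_from_percentiles(pooled),
            n_repeats = n_repeats,
            auc_sd = if (n_repeats > 1L) stats::sd(per_repeat) else NA_real_,
            per_repeat = per_repeat)
}

#' Write a CV result as a TSV curve plus summary line
#' @param res a [cv_result()].
#' @param path output path.
#' @export
write_cv_result <- function(res, path) {
  stopifnot(inherits(res, "cv_result"))
  lines <- c(sprintf("# auc=%.17g n_repeats=%d auc_sd=%.17g",
                     res$auc, res$n_repeats, res$auc_sd),
             "fpr\ttpr",
             sprintf("%.17g\t%.17g", res$curve$fpr, res$curve$tpr))
  writeLines(lines, path)
  invisible(res)
}

#' Base-graphics ROC plot of a CV result
#' @param x a [cv_result()].
#' @param ... passed to [plot()].
#' @export
plot.cv_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l", xlab = "FPR", ylab = "TPR",
       main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
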