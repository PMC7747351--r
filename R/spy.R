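#' One spy run: mask spies, rescore, threshold
#'
#' Positive-unlabeled device for mining negatives: a fraction of the known
#' positives ("spies") is hidden (set to 0), the remaining network is
#' rescored with NCP over GIP-only similarities recomputed from the masked
#' matrix, and the lowest spy score becomes the threshold. Unlabeled pairs
#' scoring strictly below it are this run's negative candidates; a spy can
#' never enter the set because the threshold is the minimum over spies.
#'
#' @param A an [association_matrix()] with at least 2 positives.
#' @param spy_fraction fraction of positives to hide, in (0,1); 0.1 by
#'   default.
#' @param seed integer seed controlling the spy sample.
#' @return object of class `spy_run`: `spy_pairs` (2-column index matrix),
#'   `threshold`, `negative_set` (2-column index matrix over unlabeled
#'   pairs), `seed`.
#' @export
spy_run <- function(A, spy_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(A, "association_matrix"))
  if (!(spy_fraction > 0 && spy_fraction < 1)) {
    stopf("`spy_fraction` must lie in (0,1)")
  }
  pos <- which(A$entries == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stopf("need at least 2 positives for a spy run")
  n_spy <- round(spy_fraction * nrow(pos))
  if (n_spy < 1L) stopf("spy sample is empty: increase spy_fraction")

  spy_idx <- with_seed(seed, sample.int(nrow(pos), n_spy))
  spies <- pos[spy_idx, , drop = FALSE]
  dimnames(spies) <- list(NULL, c("row", "col"))

  a2 <- A$entries
  a2[spies] <- 0
  A2 <- association_matrix(a2, A$disease_ids, A$metabolite_ids)

  kd <- gip_kernel(A2, "diseases")
  km <- gip_kernel(A2, "metabolites")
  sc <- ncp_score_matrix(A2, kd, km)$scores

  threshold <- min(sc[spies])
  unlabeled <- which(A$entries == 0 & sc < threshold, arr.ind = TRUE)
  dimnames(unlabeled) <- list(NULL, c("row", "col"))
  structure(list(spy_pairs = spies, threshold = threshold,
                 negative_set = unlabeled, seed = seed),
            class = "spy_run")
}

pair_keys <- function(idx, nrow) {
  (idx[, 2L] - 1L) * nrow + idx[, 1L]
}

#' Reliable negatives: intersection over repeated spy runs
#'
#' Repeats [spy_run()] with consecutive seeds and intersects the negative
#' sets, so only pairs that score below the spy threshold in every run
#' survive. Deterministic given `base_seed`.
#'
#' @param A an [association_matrix()].
#' @param n_runs number of repetitions (100 by default).
#' @param spy_fraction passed to [spy_run()].
#' @param base_seed first seed; run r uses `base_seed + r - 1`.
#' @return object of class `reliable_negative_set`: `pairs` (2-column
#'   index matrix), `n_runs`.
#' @export
reliable_negatives <- function(A, n_runs = 100L, spy_fraction = 0.1,
                               base_seed = 1L) {
  stopifnot(n_runs >= 1L)
  nd <- nrow(A$entries)
  keys <- NULL
  for (r in seq_len(n_runs)) {
    run <- spy_run(A, spy_fraction, seed = base_seed + r - 1L)
    k <- pair_keys(run$negative_set, nd)
    keys <- if (r == 1L) k else intersect(keys, k)
    if (!length(keys)) break
  }
  keys <- sort(keys)
  pairs <- cbind(row = (keys - 1L) %% nd + 1L,
                 col = (keys - 1L) %/% nd + 1L)
  structure(list(pairs = pairs, n_runs = n_runs),
            class = "reliable_negative_set")
}

#' Mark reliable negatives on a score matrix
#'
#' Sets the `negative_mask` of a [score_matrix()] so that evaluators rank
#' masked pairs strictly below all unmasked pairs. The raw scores and the
#' underlying association entries are left untouched: a literal -1 inside
#' the adjacency matrix would corrupt the projection norms.
#'
#' @param scores a [score_matrix()].
#' @param neg a `reliable_negative_set` from [reliable_negatives()].
#' @return the score matrix with `negative_mask` set; errors if a negative
#'   collides with a known positive.
#' @export
apply_negative_labels <- function(scores, neg) {
  stopifnot(inherits(scores, "score_matrix"),
            inherits(neg, "reliable_negative_set"))
  mask <- matrix(FALSE, nrow(scores$scores), ncol(scores$scores))
  if (nrow(neg$pairs)) mask[neg$pairs] <- TRUE
  if (any(mask & scores$known)) {
    stopf("reliable negative collides with a known positive pair")
  }
  score_matrix(scores$scores, scores$disease_ids, scores$metabolite_ids,
               known = scores$known, negative_mask = mask)
}
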