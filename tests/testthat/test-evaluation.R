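test_that("auc_from_scores matches hand examples and pair counting", {
  expect_equal(auc_from_scores(0.9, c(0.1, 0.2))$auc, 1)
  expect_equal(auc_from_scores(0.5, 0.5)$auc, 0.5)
  expect_equal(auc_from_scores(c(0.8, 0.3), c(0.5, 0.1))$auc, 0.75)
  expect_error(auc_from_scores(numeric(), 1), "empty")
  expect_error(auc_from_scores(1, numeric()), "empty")

  for (seed in 1:10) {
    s <- ncplink:::with_seed(seed, {
      nt <- sample(1:80, 1)
      nc <- sample(1:120, 1)
      # coarse grid forces plenty of ties
      list(t = sample(seq(0, 1, 0.1), nt, replace = TRUE),
           c = sample(seq(0, 1, 0.1), nc, replace = TRUE))
    })
    expect_identical(auc_from_scores(s$t, s$c)$auc, oracle_auc(s$t, s$c))
  }
})

test_that("the ROC curve is well-formed and integrates to the AUC", {
  for (seed in 1:5) {
    s <- ncplink:::with_seed(seed, {
      list(t = round(stats::runif(40), 2), c = round(stats::runif(60), 2))
    })
    res <- auc_from_scores(s$t, s$c)
    expect_equal(res$curve$fpr[1], 0)
    expect_equal(res$curve$tpr[1], 0)
    expect_equal(res$curve$fpr[nrow(res$curve)], 1)
    expect_equal(res$curve$tpr[nrow(res$curve)], 1)
    expect_true(all(diff(res$curve$fpr) >= 0))
    expect_true(all(diff(res$curve$tpr) >= 0))
    expect_equal(ncplink:::trapezoid_area(res$curve), res$auc,
                 tolerance = 1e-12)
  }
})

test_that("loocv reports 1 / 0.5 / 0 for oracle, constant, anti-oracle", {
  A <- random_assoc(5, 6, density = 0.3, seed = 2)
  oracle <- function(Am) Am  # closes over nothing; scores = truth below
  truth <- A$entries
  expect_equal(loocv(function(Am) truth, A)$auc, 1)
  expect_equal(loocv(function(Am) matrix(0.7, 5, 6), A)$auc, 0.5)
  # anti-oracle ranks every held-out positive below all candidates
  expect_equal(loocv(function(Am) -truth, A)$auc, 0)
  # curve integrates to the AUC
  res <- loocv(function(Am) truth + 0, A)
  expect_equal(ncplink:::trapezoid_area(res$curve), res$auc,
               tolerance = 1e-12)
})

test_that("kfold_cv is deterministic per seed and fold-label invariant", {
  fx <- generate_fixture(fixture_spec(n_diseases = 12, n_metabolites = 20,
                                      n_blocks = 2, seed = 3))
  pipe <- make_pipeline(NULL)  # GIP-only pipeline
  r1 <- kfold_cv(pipe, fx$A, k = 4, n_repeats = 2, seed = 9)
  r2 <- kfold_cv(pipe, fx$A, k = 4, n_repeats = 2, seed = 9)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$per_repeat, r2$per_repeat)
  r3 <- kfold_cv(pipe, fx$A, k = 4, n_repeats = 2, seed = 10)
  expect_false(identical(r1$auc, r3$auc))
  expect_equal(r1$n_repeats, 2)
  expect_true(is.finite(r1$auc_sd))
  # oracle scorer gives AUC 1 for any k and seed
  truth <- fx$A$entries
  expect_equal(kfold_cv(function(Am) truth, fx$A, k = 3, n_repeats = 2,
                        seed = 4)$auc, 1)
})

test_that("fold splits are near-equal and cover every positive", {
  A <- random_assoc(8, 9, density = 0.4, seed = 5)
  split <- make_fold_split(A, k = 5, seed = 2)
  expect_equal(length(split$assignments), sum(A$entries))
  sizes <- tabulate(split$assignments, 5)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(make_fold_split(random_assoc(2, 2, 0.3, 1), k = 10,
                               seed = 1), "fewer positives")
})

test_that("reliable-negative masking can only help a clean candidate pool", {
  fx <- generate_fixture(fixture_spec(n_diseases = 10, n_metabolites = 16,
                                      n_blocks = 2, p_within = 0.5,
                                      p_between = 0.02, seed = 8))
  base <- make_pipeline(NULL)
  # mask the k lowest-scoring unlabeled pairs (true negatives by and
  # large): AUC must not decrease
  masked_pipe <- function(Am) {
    sc <- base(Am)
    unl <- which(fx$A$entries == 0)
    worst <- unl[order(sc$scores[unl])][1:20]
    mask <- matrix(FALSE, nrow(sc$scores), ncol(sc$scores))
    mask[worst] <- TRUE
    score_matrix(sc$scores, sc$disease_ids, sc$metabolite_ids,
                 known = sc$known, negative_mask = mask)
  }
  a1 <- kfold_cv(base, fx$A, k = 4, n_repeats = 2, seed = 1)$auc
  a2 <- kfold_cv(masked_pipe, fx$A, k = 4, n_repeats = 2, seed = 1)$auc
  expect_gte(a2, a1)
})

test_that("a fully masked candidate pool raises the documented error", {
  A <- random_assoc(4, 5, density = 0.4, seed = 6)
  all_mask_pipe <- function(Am) {
    s <- matrix(stats::runif(20), 4, 5)
    mask <- A$entries == 0
    score_matrix(s, A$disease_ids, A$metabolite_ids,
                 known = A$entries == 1, negative_mask = mask)
  }
  expect_error(loocv(all_mask_pipe, A), "fully masked")
})

test_that("write_cv_result emits the curve with a summary header", {
  res <- auc_from_scores(c(0.9, 0.4), c(0.5, 0.2, 0.1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cv_result(res, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# auc=")
  expect_equal(lines[2], "fpr\ttpr")
  expect_equal(length(lines), 2 + nrow(res$curve))
})
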