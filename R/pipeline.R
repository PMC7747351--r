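#' Annotation-based (topology-free) similarities
#'
#' Computes the three functional similarity matrices that do not depend
#' on the association matrix: gene-set Jaccard over diseases (DFS1),
#' symptom TF-IDF cosine over diseases (DFS2), and enzyme TF-IDF cosine
#' over metabolites (MFS). Computing them once and reusing them across CV
#' folds is safe because no association information leaks through them.
#'
#' @param genes,symptoms disease [annotation_table()]s.
#' @param enzymes metabolite [annotation_table()].
#' @param disease_ids,metabolite_ids entity universes (row/column order
#'   of the association matrix).
#' @return list with `dfs1`, `dfs2`, `mfs`.
#' @export
functional_similarities <- function(genes, symptoms, enzymes,
                                    disease_ids, metabolite_ids) {
  list(
    dfs1 = jaccard_similarity(genes, disease_ids),
    dfs2 = cosine_similarity(tfidf_profiles(symptoms, disease_ids),
                             kind = "DFS2"),
    mfs = cosine_similarity(tfidf_profiles(enzymes, metabolite_ids),
                            kind = "MFS"))
}

#' Spy-strategy settings
#'
#' @param enabled run the spy negative-mining step.
#' @param spy_fraction fraction of positives hidden per run (0.1).
#' @param n_runs number of intersected spy runs (100).
#' @param base_seed first spy seed.
#' @return a named list of class `spy_options`.
#' @export
spy_options <- function(enabled = TRUE, spy_fraction = 0.1,
                        n_runs = 100L, base_seed = 1L) {
  structure(list(enabled = enabled, spy_fraction = spy_fraction,
                 n_runs = n_runs, base_seed = base_seed),
            class = "spy_options")
}

#' Full scoring pipeline factory
#'
#' Returns a scoring function suitable for [loocv()] / [kfold_cv()] and
#' direct prediction: given a (possibly masked) association matrix it
#' recomputes the GIP kernels from that matrix, fuses them with the
#' precomputed functional similarities under the (alpha, beta, gamma)
#' weights, scores every pair by network consistency projection, and
#' optionally re-runs spy negative mining on the masked matrix.
#' Recomputing kernels and spy labels inside every fold prevents held-out
#' positives from leaking through the topology.
#'
#' @param fsim list from [functional_similarities()], or `NULL` for a
#'   GIP-only pipeline.
#' @param params a [parameter_set()].
#' @param spy a [spy_options()] (disabled by default).
#' @param pure_kernel_fallback passed to the integration rules.
#' @param norm projection norm, `"euclidean"` or `"l1"`.
#' @return function(association_matrix) -> [score_matrix()].
#' @export
make_pipeline <- function(fsim = NULL, params = parameter_set(),
                          spy = spy_options(enabled = FALSE),
                          pure_kernel_fallback = FALSE,
                          norm = "euclidean") {
  stopifnot(inherits(params, "parameter_set"),
            inherits(spy, "spy_options"))
  function(A) {
    stopifnot(inherits(A, "association_matrix"))
    kd <- gip_kernel(A, "diseases")
    km <- gip_kernel(A, "metabolites")
    if (is.null(fsim)) {
      sd_m <- kd
      sm_m <- km
    } else {
      db <- integrate_disease_biological(fsim$dfs1, fsim$dfs2,
                                         params$alpha)
      sd_m <- integrate_disease(db, kd, params$beta,
                                pure_kernel_fallback)
      sm_m <- integrate_metabolite(fsim$mfs, km, params$gamma,
                                   pure_kernel_fallback)
    }
    sc <- ncp_score_matrix(A, sd_m, sm_m, norm = norm)
    if (spy$enabled) {
      neg <- reliable_negatives(A, n_runs = spy$n_runs,
                                spy_fraction = spy$spy_fraction,
                                base_seed = spy$base_seed)
      sc <- apply_negative_labels(sc, neg)
    }
    sc
  }
}

#' Cross-validated AUC evaluator for the bee colony search
#'
#' Builds the fitness evaluator the parameter search minimises over:
#' a frozen repeated k-fold division (created once from `seed`, then
#' reused for every candidate parameter set, so differences in AUC
#' reflect the parameters and not the split).
#'
#' @param A an [association_matrix()].
#' @param fsim list from [functional_similarities()].
#' @param k,n_repeats CV shape; small values keep each fitness call cheap.
#' @param seed split seed, fixed for the evaluator's lifetime.
#' @param spy a [spy_options()].
#' @return function(parameter_set) -> AUC, deterministic per call.
#' @export
cv_evaluator <- function(A, fsim, k = 5L, n_repeats = 1L, seed = 1L,
                         spy = spy_options(enabled = FALSE)) {
  force(A); force(fsim); force(k); force(n_repeats); force(seed)
  function(params) {
    if (!inherits(params, "parameter_set")) {
      params <- parameter_set(params$alpha, params$beta, params$gamma)
    }
    pipe <- make_pipeline(fsim, params, spy = spy)
    kfold_cv(pipe, A, k = k, n_repeats = n_repeats, seed = seed)$auc
  }
}
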