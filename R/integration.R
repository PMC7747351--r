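check_weight <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("`%s` must be a single number in [0,1]", name)
  }
}

check_same_entities <- function(a, b) {
  stopifnot(inherits(a, "similarity_matrix"),
            inherits(b, "similarity_matrix"))
  if (!identical(a$entity_ids, b$entity_ids)) {
    stopf("similarity matrices must share the same entity ordering")
  }
}

#' Integrate the two disease biological similarities
#'
#' Piecewise fusion of the gene-based Jaccard similarity (DFS1) and the
#' symptom-based TF-IDF cosine similarity (DFS2): where DFS2 is zero the
#' value falls back to DFS1; elsewhere the two are mixed as
#' (1 - alpha) * DFS2 + alpha * DFS1. Zero-testing is exact (tolerance 0):
#' the base similarities produce exact zeros for disjoint or empty
#' profiles.
#'
#' @param dfs1,dfs2 `similarity_matrix` objects over the same diseases.
#' @param alpha mixing weight in \[0,1\].
#' @return a `similarity_matrix` of kind `"DB"`.
#' @export
integrate_disease_biological <- function(dfs1, dfs2, alpha) {
  check_same_entities(dfs1, dfs2)
  check_weight(alpha, "alpha")
  v <- ifelse(dfs2$values == 0,
              dfs1$values,
              (1 - alpha) * dfs2$values + alpha * dfs1$values)
  similarity_matrix(v, dfs1$entity_ids, kind = "DB")
}

#' Integrate biological and topological disease similarity
#'
#' Where the biological similarity DB is nonzero it is kept as is;
#' where it is zero the literal mixing rule
#' (1 - beta) * DB + beta * KD applies, which reduces to beta * KD.
#' `pure_kernel_fallback = TRUE` substitutes the unscaled kernel in the
#' zero branch for sensitivity analysis.
#'
#' @param db biological disease similarity (`"DB"`).
#' @param kd GIP kernel over diseases (`"KD"`).
#' @param beta mixing weight in \[0,1\].
#' @param pure_kernel_fallback logical, see Details.
#' @return a `similarity_matrix` of kind `"SD"`.
#' @export
integrate_disease <- function(db, kd, beta, pure_kernel_fallback = FALSE) {
  check_same_entities(db, kd)
  check_weight(beta, "beta")
  fac <- if (pure_kernel_fallback) 1 else beta
  v <- ifelse(db$values != 0, db$values, fac * kd$values)
  similarity_matrix(v, db$entity_ids, kind = "SD")
}

#' Integrate functional and topological metabolite similarity
#'
#' Where the enzyme-based functional similarity MFS is nonzero it is kept;
#' where it is zero the literal rule (1 - gamma) * MFS + gamma * KM
#' applies, i.e. gamma * KM. `pure_kernel_fallback` as in
#' [integrate_disease()].
#'
#' @param mfs functional metabolite similarity (`"MFS"`).
#' @param km GIP kernel over metabolites (`"KM"`).
#' @param gamma mixing weight in \[0,1\].
#' @param pure_kernel_fallback logical.
#' @return a `similarity_matrix` of kind `"SM"`.
#' @export
integrate_metabolite <- function(mfs, km, gamma,
                                 pure_kernel_fallback = FALSE) {
  check_same_entities(mfs, km)
  check_weight(gamma, "gamma")
  fac <- if (pure_kernel_fallback) 1 else gamma
  v <- ifelse(mfs$values != 0, mfs$values, fac * km$values)
  similarity_matrix(v, mfs$entity_ids, kind = "SM")
}

#' The (alpha, beta, gamma) similarity mixing weights
#'
#' alpha mixes the two disease biological similarities, beta scales the
#' disease GIP fallback, gamma scales the metabolite GIP fallback. The
#' shipped defaults are the values tuned on the original curated dataset;
#' for new data run the bee colony search ([abc_optimize()]).
#'
#' @param alpha,beta,gamma reals in \[0,1\].
#' @return object of class `parameter_set` (a named list).
#' @export
parameter_set <- function(alpha = 0.56, beta = 0.89, gamma = 0.6) {
  check_weight(alpha, "alpha")
  check_weight(beta, "beta")
  check_weight(gamma, "gamma")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "parameter_set")
}
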