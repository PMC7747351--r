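#' Square similarity matrix container
#'
#' Symmetric matrix with entries in \[0,1\] over one entity set. `kind`
#' labels which similarity it holds: DFS1 (gene-set Jaccard), DFS2
#' (symptom TF-IDF cosine), MFS (enzyme TF-IDF cosine), KD/KM (GIP
#' kernels), DB/SD/SM (integrated).
#'
#' @param values square numeric matrix.
#' @param entity_ids identifiers for rows/columns.
#' @param kind label.
#' @return object of class `similarity_matrix` with fields `values`,
#'   `entity_ids`, `kind`.
#' @export
similarity_matrix <- function(values, entity_ids, kind = "custom") {
  values <- as.matrix(values)
  entity_ids <- as.character(entity_ids)
  stopifnot(nrow(values) == ncol(values),
            nrow(values) == length(entity_ids))
  if (max(abs(values - t(values))) > 1e-12) {
    stopf("similarity matrix must be symmetric")
  }
  if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stopf("similarity values must lie in [0,1]")
  }
  values <- pmin(pmax(values, 0), 1)
  dimnames(values) <- list(entity_ids, entity_ids)
  structure(list(values = values, entity_ids = entity_ids, kind = kind),
            class = "similarity_matrix")
}

#' Jaccard similarity over binary annotation profiles
#'
#' For entities i, j with binary feature profiles, the similarity is
#' p / (p + q + r) where p counts features shared by both, q features of i
#' only, and r features of j only. Weights are binarised (weight > 0 means
#' annotated). Pairs of two unannotated entities get 0.
#'
#' @param table an [annotation_table()] (e.g. disease-gene).
#' @param entities ordered entity universe.
#' @return a `similarity_matrix` of kind `"DFS1"`.
#' @export
jaccard_similarity <- function(table, entities) {
  b <- annotation_matrix(table, entities) > 0
  storage.mode(b) <- "double"
  inter <- tcrossprod(b)
  sizes <- rowSums(b)
  union <- outer(sizes, sizes, `+`) - inter
  v <- ifelse(union > 0, inter / union, 0)
  similarity_matrix(v, entities, kind = "DFS1")
}

#' TF-IDF weighted annotation profiles
#'
#' Weights each annotation count W(i,f) by the inverse document frequency
#' log(n / n_f), where n is the number of entities in the universe and n_f
#' the number of entities annotated with feature f (natural logarithm;
#' another base only rescales columns). Features annotated to every entity
#' vanish; features annotated to none contribute 0.
#'
#' @param table an [annotation_table()] with count weights.
#' @param entities ordered entity universe (defines n).
#' @param log_base logarithm base, `exp(1)` by default.
#' @return numeric matrix of weighted profiles, entities x features.
#' @export
tfidf_profiles <- function(table, entities, log_base = exp(1)) {
  entities <- as.character(entities)
  if (length(entities) < 2L) stopf("need at least 2 entities for TF-IDF")
  w <- annotation_matrix(table, entities)
  n_f <- colSums(w > 0)
  idf <- ifelse(n_f > 0, log(length(entities) / n_f, base = log_base), 0)
  sweep(w, 2L, idf, `*`)
}

#' Cosine similarity of weighted profiles
#'
#' Standard cosine of non-negative weight vectors; any pair involving an
#' all-zero profile scores 0, and the self-similarity of a nonzero profile
#' is exactly 1.
#'
#' @param profiles numeric matrix, one row per entity (e.g. from
#'   [tfidf_profiles()]).
#' @param kind label for the result (`"DFS2"` or `"MFS"`).
#' @return a `similarity_matrix`.
#' @export
cosine_similarity <- function(profiles, kind = "DFS2") {
  profiles <- as.matrix(profiles)
  g <- tcrossprod(profiles)
  nrm <- sqrt(diag(g))
  denom <- outer(nrm, nrm)
  v <- ifelse(denom > 0, g / denom, 0)
  nz <- nrm > 0
  diag(v)[nz] <- 1
  v <- (v + t(v)) / 2
  similarity_matrix(v, rownames(profiles) %||% seq_len(nrow(profiles)),
                    kind = kind)
}

#' Gaussian interaction profile kernel bandwidth
#'
#' The kernel bandwidth is the raw bandwidth omega' divided by the mean
#' squared Euclidean norm of the interaction profiles: rows of A for the
#' disease axis, columns for the metabolite axis.
#'
#' @param A an [association_matrix()].
#' @param axis `"diseases"` or `"metabolites"`.
#' @param omega_prime raw bandwidth, 1 by default.
#' @return object of class `kernel_bandwidth` with fields `omega`,
#'   `omega_prime`, `axis`.
#' @export
gip_bandwidth <- function(A, axis = c("diseases", "metabolites"),
                          omega_prime = 1) {
  stopifnot(inherits(A, "association_matrix"), omega_prime > 0)
  axis <- match.arg(axis)
  p <- if (axis == "diseases") A$entries else t(A$entries)
  msn <- mean(rowSums(p^2))
  if (msn == 0) stopf("empty association network: cannot set GIP bandwidth")
  structure(list(omega = omega_prime / msn, omega_prime = omega_prime,
                 axis = axis),
            class = "kernel_bandwidth")
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' K(i,j) = exp(-omega * ||profile_i - profile_j||^2) over the rows
#' (diseases) or columns (metabolites) of the association matrix. The
#' diagonal is exactly 1, and identical profiles score 1 regardless of
#' their content.
#'
#' @param A an [association_matrix()].
#' @param axis `"diseases"` or `"metabolites"`.
#' @param bw a `kernel_bandwidth` from [gip_bandwidth()] computed on the
#'   same matrix and axis; computed on the fly if omitted.
#' @return a `similarity_matrix` of kind `"KD"` or `"KM"`.
#' @export
gip_kernel <- function(A, axis = c("diseases", "metabolites"), bw = NULL) {
  stopifnot(inherits(A, "association_matrix"))
  axis <- match.arg(axis)
  if (is.null(bw)) bw <- gip_bandwidth(A, axis)
  stopifnot(inherits(bw, "kernel_bandwidth"))
  if (bw$axis != axis) stopf("bandwidth was computed for axis '%s'", bw$axis)
  p <- if (axis == "diseases") A$entries else t(A$entries)
  sq <- rowSums(p^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(p)
  d2[d2 < 0] <- 0
  k <- exp(-bw$omega * d2)
  diag(k) <- 1
  ids <- if (axis == "diseases") A$disease_ids else A$metabolite_ids
  similarity_matrix(k, ids, kind = if (axis == "diseases") "KD" else "KM")
}
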