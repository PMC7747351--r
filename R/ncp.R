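#' Metabolite-space projection score of one pair
#'
#' Projects the metabolite similarity column SM_j onto the disease's
#' association row A_i: msp(i,j) = (A_i . SM_j) / ||A_i||. A disease with
#' no known associations (all-zero row) scores 0, which keeps LOOCV
#' defined when an entity's only association is held out.
#'
#' @param A an [association_matrix()].
#' @param SM metabolite `similarity_matrix`.
#' @param i disease row index.
#' @param j metabolite column index.
#' @param norm `"euclidean"` (default) or `"l1"` for ablation.
#' @return scalar projection score.
#' @export
metabolite_space_projection <- function(A, SM, i, j, norm = "euclidean") {
  ai <- A$entries[i, ]
  n <- if (norm == "euclidean") sqrt(sum(ai^2)) else sum(abs(ai))
  if (n == 0) return(0)
  sum(ai * SM$values[, j]) / n
}

#' Disease-space projection score of one pair
#'
#' Projects the disease similarity row SD_i onto the metabolite's
#' association column A_j: dsp(i,j) = (SD_i . A_j) / ||A_j||; an all-zero
#' column scores 0.
#'
#' @inheritParams metabolite_space_projection
#' @param SD disease `similarity_matrix`.
#' @return scalar projection score.
#' @export
disease_space_projection <- function(A, SD, i, j, norm = "euclidean") {
  aj <- A$entries[, j]
  n <- if (norm == "euclidean") sqrt(sum(aj^2)) else sum(abs(aj))
  if (n == 0) return(0)
  sum(SD$values[i, ] * aj) / n
}

#' Network consistency projection score matrix
#'
#' Scores every disease-metabolite pair by summing the disease- and
#' metabolite-space projections and normalising by the similarity vector
#' lengths: ncp(i,j) = (dsp(i,j) + msp(i,j)) / (||SD_i|| + ||SM_j||).
#' The denominator is positive whenever similarity diagonals are (as GIP
#' kernels guarantee); a zero denominator signals an invalid similarity
#' matrix and raises an error. Known pairs are scored like any other pair;
#' masking them is the evaluator's job.
#'
#' @param A an [association_matrix()].
#' @param SD disease `similarity_matrix` (nd x nd).
#' @param SM metabolite `similarity_matrix` (nm x nm).
#' @param norm vector length: `"euclidean"` (standard) or `"l1"`.
#' @return a [score_matrix()] with `known` taken from A.
#' @export
ncp_score_matrix <- function(A, SD, SM, norm = c("euclidean", "l1")) {
  stopifnot(inherits(A, "association_matrix"),
            inherits(SD, "similarity_matrix"),
            inherits(SM, "similarity_matrix"))
  norm <- match.arg(norm)
  a <- A$entries
  stopifnot(nrow(SD$values) == nrow(a), nrow(SM$values) == ncol(a))

  ra <- row_norms(a, norm)                       # ||A_i||
  msp <- (a %*% SM$values) / ifelse(ra > 0, ra, 1)
  msp[ra == 0, ] <- 0

  ca <- col_norms(a, norm)                       # ||A_j||
  dsp <- sweep(SD$values %*% a, 2L, ifelse(ca > 0, ca, 1), `/`)
  dsp[, ca == 0] <- 0

  denom <- outer(row_norms(SD$values, norm), col_norms(SM$values, norm), `+`)
  if (any(denom == 0)) {
    stopf("zero NCP denominator: similarity matrix has an all-zero row")
  }
  score_matrix((dsp + msp) / denom, A$disease_ids, A$metabolite_ids,
               known = a == 1)
}
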