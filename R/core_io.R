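#' Annotation tables: weighted entity-feature incidence
#'
#' An annotation table records which features (genes, symptoms, enzymes)
#' are attached to which entities (diseases or metabolites), with an
#' optional non-negative co-occurrence weight. Absent pairs have weight 0.
#'
#' @param pairs data.frame with columns `entity_id`, `feature_id`, `weight`.
#' @param entity_ids,feature_ids optional character vectors fixing the
#'   entity / feature universes; default is the lexicographically sorted
#'   set observed in `pairs`. Entities absent from `pairs` are legal and
#'   carry an all-zero profile.
#' @return An object of class `annotation_table` with fields `pairs`,
#'   `entity_ids`, `feature_ids`.
#' @export
annotation_table <- function(pairs, entity_ids = NULL, feature_ids = NULL) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("entity_id", "feature_id", "weight") %in% names(pairs))) {
    stopf("`pairs` needs columns entity_id, feature_id, weight")
  }
  pairs$entity_id <- as.character(pairs$entity_id)
  pairs$feature_id <- as.character(pairs$feature_id)
  pairs$weight <- as.numeric(pairs$weight)
  if (anyNA(pairs$weight) || any(pairs$weight < 0)) {
    stopf("annotation weights must be non-negative numbers")
  }
  key <- paste(pairs$entity_id, pairs$feature_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- pairs[duplicated(key), , drop = FALSE][1L, ]
    stopf("duplicate annotation pair (%s, %s)", d$entity_id, d$feature_id)
  }
  entity_ids <- entity_ids %||% sort(unique(pairs$entity_id))
  feature_ids <- feature_ids %||% sort(unique(pairs$feature_id))
  missing_e <- setdiff(pairs$entity_id, entity_ids)
  if (length(missing_e)) stopf("unknown entity id '%s'", missing_e[1L])
  missing_f <- setdiff(pairs$feature_id, feature_ids)
  if (length(missing_f)) stopf("unknown feature id '%s'", missing_f[1L])
  structure(
    list(pairs = pairs[order(pairs$entity_id, pairs$feature_id), ,
                       drop = FALSE],
         entity_ids = as.character(entity_ids),
         feature_ids = as.character(feature_ids)),
    class = "annotation_table")
}

#' Read a delimited entity-feature (or disease-metabolite) table
#'
#' Parses a 2- or 3-column delimited text file into an
#' [annotation_table()]. Two-column files get unit weights. Entity and
#' feature universes are the lexicographically sorted observed ids, so
#' identical input bytes always yield identical orderings.
#'
#' @param path file path.
#' @param has_weight logical; `TRUE` expects a third numeric weight column.
#' @param delim field delimiter, tab by default.
#' @param header logical; skip a header line.
#' @return an [annotation_table()].
#' @export
read_association_table <- function(path, has_weight = FALSE, delim = "\t",
                                   header = FALSE) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("no records in %s", path)
  want <- if (has_weight) 3L else 2L
  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != want)
  if (length(bad)) {
    stopf("parse error at line %d of %s: expected %d fields, found %d",
          bad[1L] + as.integer(header), path, want, nf[bad[1L]])
  }
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  w <- if (has_weight) suppressWarnings(as.numeric(m[, 3L])) else
    rep(1, nrow(m))
  if (anyNA(w)) {
    stopf("parse error at line %d of %s: non-numeric weight",
          which(is.na(w))[1L] + as.integer(header), path)
  }
  annotation_table(data.frame(entity_id = trimws(m[, 1L]),
                              feature_id = trimws(m[, 2L]),
                              weight = w,
                              stringsAsFactors = FALSE))
}

#' Dense weight matrix of an annotation table
#'
#' @param table an [annotation_table()].
#' @param entities entity universe (rows); defaults to the table's own.
#' @return numeric matrix, `length(entities)` x `length(table$feature_ids)`.
#' @export
annotation_matrix <- function(table, entities = NULL) {
  stopifnot(inherits(table, "annotation_table"))
  entities <- as.character(entities %||% table$entity_ids)
  m <- matrix(0, nrow = length(entities), ncol = length(table$feature_ids),
              dimnames = list(entities, table$feature_ids))
  keep <- table$pairs$entity_id %in% entities
  p <- table$pairs[keep, , drop = FALSE]
  m[cbind(match(p$entity_id, entities),
          match(p$feature_id, table$feature_ids))] <- p$weight
  m
}

#' Binary disease x metabolite association matrix
#'
#' @param entries integer/numeric matrix of 0/1 entries.
#' @param disease_ids,metabolite_ids row / column identifiers.
#' @return object of class `association_matrix` with fields `entries`
#'   (dimnamed 0/1 matrix), `disease_ids`, `metabolite_ids`.
#' @export
association_matrix <- function(entries, disease_ids, metabolite_ids) {
  entries <- as.matrix(entries)
  if (!all(entries %in% c(0, 1))) stopf("association entries must be 0 or 1")
  if (nrow(entries) != length(disease_ids) ||
      ncol(entries) != length(metabolite_ids)) {
    stopf("matrix dimensions do not match identifier lists")
  }
  if (nrow(entries) < 2L || ncol(entries) < 2L) {
    stopf("need at least 2 diseases and 2 metabolites")
  }
  storage.mode(entries) <- "double"
  dimnames(entries) <- list(as.character(disease_ids),
                            as.character(metabolite_ids))
  structure(list(entries = entries,
                 disease_ids = as.character(disease_ids),
                 metabolite_ids = as.character(metabolite_ids)),
            class = "association_matrix")
}

#' Build the adjacency matrix from a pair list
#'
#' Sets A(i,j) = 1 for every (disease, metabolite) pair in `pairs` and 0
#' elsewhere, with rows ordered by `diseases` and columns by `metabolites`.
#'
#' @param pairs an [annotation_table()] whose entities are diseases and
#'   features are metabolites (weights ignored beyond presence).
#' @param diseases,metabolites ordered identifier vectors; every pair must
#'   reference listed ids.
#' @return an [association_matrix()].
#' @export
build_adjacency <- function(pairs, diseases, metabolites) {
  stopifnot(inherits(pairs, "annotation_table"))
  diseases <- as.character(diseases)
  metabolites <- as.character(metabolites)
  p <- pairs$pairs
  bad_d <- setdiff(p$entity_id, diseases)
  if (length(bad_d)) stopf("unknown disease id '%s'", bad_d[1L])
  bad_m <- setdiff(p$feature_id, metabolites)
  if (length(bad_m)) stopf("unknown metabolite id '%s'", bad_m[1L])
  a <- matrix(0, length(diseases), length(metabolites))
  a[cbind(match(p$entity_id, diseases),
          match(p$feature_id, metabolites))] <- 1
  if (sum(a) == 0) warning("association matrix has no positive entries")
  association_matrix(a, diseases, metabolites)
}

#' Prediction score container
#'
#' @param scores real nd x nm matrix of pairwise prediction scores.
#' @param disease_ids,metabolite_ids identifiers.
#' @param known logical matrix marking pairs that were 1 in the source
#'   association matrix.
#' @param negative_mask optional logical matrix of reliable negatives; may
#'   never overlap `known`.
#' @return object of class `score_matrix`.
#' @export
score_matrix <- function(scores, disease_ids, metabolite_ids,
                         known = NULL, negative_mask = NULL) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stopf("scores must all be finite")
  disease_ids <- as.character(disease_ids)
  metabolite_ids <- as.character(metabolite_ids)
  stopifnot(nrow(scores) == length(disease_ids),
            ncol(scores) == length(metabolite_ids))
  dimnames(scores) <- list(disease_ids, metabolite_ids)
  if (is.null(known)) known <- matrix(FALSE, nrow(scores), ncol(scores))
  known <- matrix(as.logical(known), nrow(scores), ncol(scores))
  if (!is.null(negative_mask)) {
    negative_mask <- matrix(as.logical(negative_mask),
                            nrow(scores), ncol(scores))
    if (any(negative_mask & known)) {
      stopf("negative_mask marks a known positive pair")
    }
  }
  structure(list(scores = scores, disease_ids = disease_ids,
                 metabolite_ids = metabolite_ids, known = known,
                 negative_mask = negative_mask),
            class = "score_matrix")
}

#' Write ranked prediction scores to a delimited file
#'
#' Long format `(disease_id, metabolite_id, score, is_known,
#' is_reliable_negative)`, sorted within each disease by score descending
#' with metabolite id as the deterministic tie-break. Scores are printed
#' with 17 significant digits so a read-back reproduces them exactly.
#'
#' @param sm a [score_matrix()].
#' @param path output path.
#' @param delim field delimiter.
#' @param top optional integer: keep only the `top` highest-scoring
#'   metabolites per disease.
#' @export
write_scores <- function(sm, path, delim = "\t", top = NULL) {
  stopifnot(inherits(sm, "score_matrix"))
  neg <- sm$negative_mask %||% matrix(FALSE, nrow(sm$scores), ncol(sm$scores))
  df <- data.frame(
    disease_id = rep(sm$disease_ids, times = length(sm$metabolite_ids)),
    metabolite_id = rep(sm$metabolite_ids, each = length(sm$disease_ids)),
    score = as.vector(sm$scores),
    is_known = as.integer(as.vector(sm$known)),
    is_reliable_negative = as.integer(as.vector(neg)),
    stringsAsFactors = FALSE)
  df <- df[order(df$disease_id, -df$score, df$metabolite_id), , drop = FALSE]
  if (!is.null(top)) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$disease_id),
                          utils::head, n = top), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
  }
  lines <- c(paste(c("disease_id", "metabolite_id", "score", "is_known",
                     "is_reliable_negative"), collapse = delim),
             paste(df$disease_id, df$metabolite_id,
                   sprintf("%.17g", df$score), df$is_known,
                   df$is_reliable_negative, sep = delim))
  writeLines(lines, path)
  invisible(df)
}

#' Read back a score table written by [write_scores()]
#' @param path file path.
#' @param delim field delimiter.
#' @return data.frame in the written row order.
#' @export
read_scores <- function(path, delim = "\t") {
  utils::read.delim(path, sep = delim, header = TRUE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "integer"))
}
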