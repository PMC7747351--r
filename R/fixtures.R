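#' Specification for the block-structured synthetic dataset
#'
#' The generator emulates the statistical structure the predictor
#' assumes: diseases and metabolites fall into latent blocks (disease
#' groups sharing metabolic aetiology), associations are denser inside
#' matched blocks than across, and each block owns disjoint pools of
#' typical genes, symptoms and enzymes so the annotation-based
#' similarities carry the same block signal as the topology.
#'
#' Defaults give a 30 x 80 network with 3 blocks, within-block association
#' probability 0.3 versus 0.01 across, and moderately dense annotations
#' with light uniform noise - small enough to cross-validate in seconds
#' yet structured enough that similarity-based ranking is non-vacuous.
#'
#' @param n_diseases,n_metabolites entity counts (>= n_blocks).
#' @param n_blocks number of latent blocks.
#' @param p_within,p_between association probabilities inside / outside
#'   matched blocks; must satisfy 0 <= p_between <= p_within <= 1 with
#'   strict inequality unless deliberately generating a null dataset.
#' @param n_genes,n_symptoms,n_enzymes feature universe sizes.
#' @param annotation_density probability an entity carries each of its
#'   block's typical features.
#' @param noise_density probability of each off-block feature.
#' @param seed integer seed; the fixture is a pure function of the spec.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_diseases = 30L, n_metabolites = 80L,
                         n_blocks = 3L, p_within = 0.3, p_between = 0.01,
                         n_genes = 200L, n_symptoms = 50L,
                         n_enzymes = 100L, annotation_density = 0.4,
                         noise_density = 0.02, seed = 1L) {
  stopifnot(n_diseases >= 1L, n_metabolites >= 1L, n_blocks >= 1L,
            n_blocks <= min(n_diseases, n_metabolites),
            n_genes >= 1L, n_symptoms >= 1L, n_enzymes >= 1L)
  if (!(p_between <= p_within && p_between >= 0 && p_within <= 1)) {
    stopf("need 0 <= p_between <= p_within <= 1")
  }
  structure(as.list(environment()), class = "fixture_spec")
}

# Deterministic near-equal partition of n items into b blocks.
block_partition <- function(n, b) sort(rep_len(seq_len(b), n))

# Sample one entity-feature annotation table with block-typical pools.
sample_annotations <- function(entity_ids, entity_block, n_features,
                               n_blocks, density, noise, prefix,
                               weighted) {
  feat_block <- block_partition(n_features, n_blocks)
  feat_ids <- sprintf("%s%03d", prefix, seq_len(n_features))
  rows <- vector("list", length(entity_ids))
  for (e in seq_along(entity_ids)) {
    p <- ifelse(feat_block == entity_block[e], density, noise)
    on <- which(stats::runif(n_features) < p)
    if (!length(on)) next
    w <- if (weighted) 1 + stats::rpois(length(on), 1) else
      rep(1, length(on))
    rows[[e]] <- data.frame(entity_id = entity_ids[e],
                            feature_id = feat_ids[on], weight = w,
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) {
    pairs <- data.frame(entity_id = character(), feature_id = character(),
                        weight = numeric())
  }
  annotation_table(pairs, entity_ids = entity_ids, feature_ids = feat_ids)
}

#' Generate a synthetic disease-metabolite dataset
#'
#' Draws the association matrix and the three annotation tables described
#' by a [fixture_spec()], deterministically for a given seed. The returned
#' ground-truth block map supports tests that planted structure is
#' recovered (e.g. within-block unlabeled pairs outscoring cross-block
#' ones).
#'
#' @param spec a [fixture_spec()].
#' @return list with `A` ([association_matrix()]), `genes`, `symptoms`
#'   (disease annotations), `enzymes` (metabolite annotations), and
#'   `blocks` (list `disease`, `metabolite` of integer block labels).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    d_ids <- sprintf("D%03d", seq_len(spec$n_diseases))
    m_ids <- sprintf("M%04d", seq_len(spec$n_metabolites))
    d_block <- block_partition(spec$n_diseases, spec$n_blocks)
    m_block <- block_partition(spec$n_metabolites, spec$n_blocks)

    p <- ifelse(outer(d_block, m_block, `==`), spec$p_within,
                spec$p_between)
    a <- matrix(as.numeric(stats::runif(length(p)) < p), nrow(p), ncol(p))
    A <- association_matrix(a, d_ids, m_ids)

    genes <- sample_annotations(d_ids, d_block, spec$n_genes,
                                spec$n_blocks, spec$annotation_density,
                                spec$noise_density, "G", weighted = FALSE)
    symptoms <- sample_annotations(d_ids, d_block, spec$n_symptoms,
                                   spec$n_blocks,
                                   spec$annotation_density,
                                   spec$noise_density, "S",
                                   weighted = TRUE)
    enzymes <- sample_annotations(m_ids, m_block, spec$n_enzymes,
                                  spec$n_blocks, spec$annotation_density,
                                  spec$noise_density, "E", weighted = TRUE)
    list(A = A, genes = genes, symptoms = symptoms, enzymes = enzymes,
         blocks = list(disease = d_block, metabolite = m_block))
  })
}

#' Write a fixture to the delimited formats the parsers read
#'
#' Emits `associations.tsv`, `disease_gene.tsv`, `disease_symptom.tsv`,
#' `metabolite_enzyme.tsv`, `diseases.tsv`, `metabolites.tsv` under `dir`,
#' so synthetic data exercises the same I/O path as real exports.
#'
#' @param fixture result of [generate_fixture()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pairs <- function(tab, path, weighted) {
    p <- tab$pairs
    lines <- if (weighted) {
      paste(p$entity_id, p$feature_id, sprintf("%.17g", p$weight),
            sep = "\t")
    } else {
      paste(p$entity_id, p$feature_id, sep = "\t")
    }
    writeLines(lines, path)
  }
  pos <- which(fixture$A$entries == 1, arr.ind = TRUE)
  assoc <- file.path(dir, "associations.tsv")
  writeLines(paste(fixture$A$disease_ids[pos[, 1L]],
                   fixture$A$metabolite_ids[pos[, 2L]], sep = "\t"),
             assoc)
  paths <- c(associations = assoc,
             disease_gene = file.path(dir, "disease_gene.tsv"),
             disease_symptom = file.path(dir, "disease_symptom.tsv"),
             metabolite_enzyme = file.path(dir, "metabolite_enzyme.tsv"),
             diseases = file.path(dir, "diseases.tsv"),
             metabolites = file.path(dir, "metabolites.tsv"))
  write_pairs(fixture$genes, paths[["disease_gene"]], weighted = FALSE)
  write_pairs(fixture$symptoms, paths[["disease_symptom"]],
              weighted = TRUE)
  write_pairs(fixture$enzymes, paths[["metabolite_enzyme"]],
              weighted = TRUE)
  writeLines(fixture$A$disease_ids, paths[["diseases"]])
  writeLines(fixture$A$metabolite_ids, paths[["metabolites"]])
  invisible(paths)
}
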