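# Small constructors shared across test files.

tiny_table <- function(df) {
  annotation_table(data.frame(entity_id = df[[1]], feature_id = df[[2]],
                              weight = if (ncol(df) > 2) df[[3]] else 1,
                              stringsAsFactors = FALSE))
}

random_assoc <- function(nd, nm, density = 0.3, seed = 1) {
  a <- ncplink:::with_seed(seed, {
    m <- matrix(as.numeric(stats::runif(nd * nm) < density), nd, nm)
    if (sum(m) == 0) m[1, 1] <- 1  # keep the network non-empty
    m
  })
  association_matrix(a, sprintf("d%d", seq_len(nd)),
                     sprintf("m%d", seq_len(nm)))
}

random_similarity <- function(n, seed = 1) {
  v <- ncplink:::with_seed(seed, {
    m <- matrix(stats::runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  })
  similarity_matrix(v, sprintf("e%d", seq_len(n)))
}

random_annotation <- function(n_entities, n_features, density = 0.3,
                              seed = 1, weighted = FALSE) {
  ids <- sprintf("e%d", seq_len(n_entities))
  feats <- sprintf("f%d", seq_len(n_features))
  ncplink:::with_seed(seed, {
    on <- which(matrix(stats::runif(n_entities * n_features) < density,
                       n_entities, n_features), arr.ind = TRUE)
    w <- if (weighted) 1 + stats::rpois(nrow(on), 2) else rep(1, nrow(on))
    pairs <- data.frame(entity_id = ids[on[, 1]],
                        feature_id = feats[on[, 2]], weight = w,
                        stringsAsFactors = FALSE)
    annotation_table(pairs, entity_ids = ids, feature_ids = feats)
  })
}
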