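test_that("jaccard_similarity matches hand-computed and oracle values", {
  tab <- tiny_table(data.frame(
    e = c("i", "i", "i", "j", "j", "j", "k"),
    f = c("g1", "g2", "g3", "g2", "g3", "g4", "g9")))
  s <- jaccard_similarity(tab, c("i", "j", "k", "z"))
  expect_equal(s$values["i", "j"], 2 / 4)   # shared {g2,g3}, union 4
  expect_equal(s$values["i", "i"], 1)       # identical nonempty sets
  expect_equal(s$values["i", "k"], 0)       # disjoint nonempty sets
  expect_equal(s$values["z", "z"], 0)       # both unannotated -> 0
  expect_equal(s$values["i", "z"], 0)

  for (seed in 1:5) {
    tab <- random_annotation(8, 12, density = 0.35, seed = seed)
    s <- jaccard_similarity(tab, tab$entity_ids)
    b <- annotation_matrix(tab)
    expect_lt(max(abs(s$values - oracle_jaccard(b))), 1e-12)
  }
})

test_that("tfidf_profiles weights counts by log inverse frequency", {
  # 4 entities; f_rare annotated to 1 entity with count 2; f_all to all
  tab <- tiny_table(data.frame(
    e = c("a", "a", "b", "c", "d"),
    f = c("f_rare", "f_all", "f_all", "f_all", "f_all"),
    w = c(2, 1, 1, 1, 1)))
  p <- tfidf_profiles(tab, c("a", "b", "c", "d"))
  expect_equal(p["a", "f_rare"], 2 * log(4))
  expect_equal(unname(p[, "f_all"]), rep(0, 4))  # idf of universal feature
  # entity with no annotations has an all-zero profile
  p2 <- tfidf_profiles(tab, c("a", "b", "c", "d", "e"))
  expect_equal(unname(p2["e", ]), rep(0, ncol(p2)))
  # configurable base only rescales columns
  p10 <- tfidf_profiles(tab, c("a", "b", "c", "d"), log_base = 10)
  expect_equal(p10["a", "f_rare"], 2 * log10(4))
})

test_that("cosine_similarity matches hand values and the oracle", {
  p <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(0, 0, 0))
  s <- cosine_similarity(p)
  expect_equal(s$values["a", "b"], 1 / 2)
  expect_equal(s$values["a", "a"], 1)
  expect_equal(s$values["c", "c"], 0)  # zero profile
  expect_equal(s$values["a", "c"], 0)
  # orthogonal profiles
  expect_equal(cosine_similarity(rbind(c(1, 0), c(0, 3)))$values[1, 2], 0)

  for (seed in 1:5) {
    tab <- random_annotation(8, 10, density = 0.3, seed = seed,
                             weighted = TRUE)
    p <- tfidf_profiles(tab, tab$entity_ids)
    s <- cosine_similarity(p)
    expect_lt(max(abs(s$values - oracle_cosine(p))), 1e-12)
  }
})

test_that("gip_bandwidth normalises by the mean squared profile norm", {
  A <- association_matrix(diag(2), c("d1", "d2"), c("m1", "m2"))
  expect_equal(gip_bandwidth(A, "metabolites")$omega, 1)
  expect_equal(gip_bandwidth(A, "metabolites", omega_prime = 2)$omega, 2)

  ones <- association_matrix(matrix(1, 2, 5), c("d1", "d2"),
                             paste0("m", 1:5))
  expect_equal(gip_bandwidth(ones, "diseases")$omega, 1 / 5)

  A0 <- suppressWarnings(build_adjacency(
    annotation_table(data.frame(entity_id = character(),
                                feature_id = character(),
                                weight = numeric())),
    c("d1", "d2"), c("m1", "m2")))
  expect_error(gip_bandwidth(A0, "diseases"), "empty association")
})

test_that("gip_kernel matches the oracle and its stated examples", {
  A <- association_matrix(diag(2), c("d1", "d2"), c("m1", "m2"))
  km <- gip_kernel(A, "metabolites")
  expect_equal(km$values[1, 2], exp(-2))
  expect_equal(diag(km$values), c(m1 = 1, m2 = 1))

  # identical profiles score 1 even off-diagonal
  a <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0))
  kd <- gip_kernel(association_matrix(a, paste0("d", 1:3),
                                      paste0("m", 1:3)), "diseases")
  expect_equal(kd$values[1, 2], 1)

  for (seed in 1:5) {
    A <- random_assoc(8, 11, density = 0.3, seed = seed)
    bw <- gip_bandwidth(A, "diseases")
    kd <- gip_kernel(A, "diseases", bw)
    expect_lt(max(abs(kd$values - oracle_gip(A$entries, bw$omega))),
              1e-12)
  }
})

test_that("gip kernel on one axis ignores permutations of the other", {
  A <- random_assoc(7, 9, seed = 3)
  kd <- gip_kernel(A, "diseases")
  perm <- ncplink:::with_seed(4, sample(ncol(A$entries)))
  Ap <- association_matrix(A$entries[, perm], A$disease_ids,
                           A$metabolite_ids[perm])
  expect_equal(gip_kernel(Ap, "diseases")$values, kd$values)
})

test_that("all base similarities satisfy the shared invariants", {
  for (seed in 1:3) {
    A <- random_assoc(8, 10, seed = seed)
    tab <- random_annotation(8, 15, seed = seed, weighted = TRUE)
    mats <- list(
      jaccard_similarity(tab, tab$entity_ids)$values,
      cosine_similarity(tfidf_profiles(tab, tab$entity_ids))$values,
      gip_kernel(A, "diseases")$values,
      gip_kernel(A, "metabolites")$values)
    for (v in mats) {
      expect_lt(max(abs(v - t(v))), 1e-12)
      expect_true(all(v >= 0 & v <= 1))
    }
    # unit diagonal for annotated entities
    ann <- rowSums(annotation_matrix(tab)) > 0
    expect_equal(unname(diag(mats[[1]])[ann]), rep(1, sum(ann)))
  }
})
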