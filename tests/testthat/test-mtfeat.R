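make_desc <- function(ids, values) {
  X <- matrix(values, nrow = length(ids),
              dimnames = list(ids, paste0("d", seq_len(length(values) / length(ids)))))
  X
}

pair_tab <- function(drug_id, ec_family, label) {
  structure(data.frame(drug_id = drug_id, smiles = "CCO", ec_family = ec_family,
                       label = as.integer(label), stringsAsFactors = FALSE),
            class = c("pair_table", "data.frame"))
}

test_that("class profiles are arithmetic means over contributing records", {
  desc <- make_desc(c("a", "b", "c"), c(2, 4, 10, 1, 3, 5))
  pairs <- pair_tab(c("a", "b", "c"), c("1.1", "1.1", "2.7"), c(1, 0, 1))
  prof <- build_class_profiles(pairs, desc)
  expect_equal(prof["1.1", "d1"], 3)        # mean of 2 and 4
  expect_equal(prof["1.1", "n_pairs"], 2L)
  expect_equal(prof["2.7", "d1"], 10)       # singleton class
  expect_equal(prof["2.7", "n_pairs"], 1L)
  expect_error(build_class_profiles(pairs, desc, classes = c("1.1", "9.9")),
               class = "empty_class_error")
  # actives-only variant restricts the contributing records
  prof_act <- build_class_profiles(pairs, desc, actives_only = TRUE)
  expect_equal(prof_act["1.1", "d1"], 2)
})

test_that("featurize_pair emits exact (MD, <MD>, DMD) triples", {
  desc <- make_desc("a", c(3, 5))
  pairs <- pair_tab("a", "1.1", 1)
  prof <- build_class_profiles(pairs, desc)
  fv <- featurize_pair(desc["a", ], prof["1.1", , drop = FALSE], c("d1", "d2"))
  expect_equal(length(fv), 6L)
  expect_equal(unname(fv[c("d1_md", "d1_mean", "d1_dmd")]), c(3, 3, 0))

  # MD = 5, mean = 3 -> DMD = 2
  desc2 <- make_desc(c("a", "b"), c(5, 1, 0, 0))
  prof2 <- build_class_profiles(pair_tab(c("a", "b"), "1.1", c(1, 0)), desc2)
  fv2 <- featurize_pair(desc2["a", ], prof2["1.1", , drop = FALSE], "d1")
  expect_equal(unname(fv2), c(5, 3, 2))

  expect_error(featurize_pair(desc2["a", ], prof2["1.1", , drop = FALSE], "zz"),
               class = "unknown_descriptor_error")
})

test_that("13 selected base descriptors produce a 39-long feature vector", {
  ids <- paste0("m", 1:4)
  desc <- matrix(rnorm(4 * 17), 4, dimnames = list(ids, paste0("d", 1:17)))
  pairs <- pair_tab(ids, rep("1.1", 4), c(1, 0, 1, 0))
  prof <- build_class_profiles(pairs, desc)
  sel13 <- paste0("d", 1:13)
  fv <- featurize_pair(desc[1, ], prof["1.1", , drop = FALSE], sel13)
  expect_equal(length(fv), 39L)
  X <- featurize_table(pairs, desc, prof, sel13)
  expect_equal(dim(X), c(4L, 39L))
  # reconstruction is lossless to machine precision: MD = <MD> + DMD
  md <- X[, seq(1, 39, 3)]; mn <- X[, seq(2, 39, 3)]; dm <- X[, seq(3, 39, 3)]
  expect_equal(unname(md), unname(mn + dm), tolerance = 1e-14)
})

test_that("DMD centers to zero over the records that built the profile", {
  set.seed(11)
  ids <- paste0("m", 1:30)
  desc <- matrix(rnorm(30 * 5), 30, dimnames = list(ids, paste0("d", 1:5)))
  pairs <- pair_tab(ids, rep(c("1.1", "3.2", "2.7"), each = 10), rbinom(30, 1, .5))
  prof <- build_class_profiles(pairs, desc)
  X <- featurize_table(pairs, desc, prof, paste0("d", 1:5))
  for (cl in c("1.1", "3.2", "2.7")) {
    dmd <- X[pairs$ec_family == cl, seq(3, 15, 3), drop = FALSE]
    expect_equal(unname(colMeans(dmd)), rep(0, 5), tolerance = 1e-12)
  }
})

test_that("stepwise selection finds the planted feature first", {
  ft <- generate_feature_table(n = 300, k_informative = 1, m_noise = 9,
                               d = 2, seed = 21)
  # independent oracle: exhaustive single-feature deviance scan
  dev1 <- vapply(colnames(ft$X), function(nm) {
    glm(ft$y ~ ft$X[, nm], family = binomial())$deviance
  }, numeric(1))
  expect_equal(names(which.min(dev1)), "inf01")

  sel <- forward_stepwise_select(ft$X, ft$y)
  expect_equal(sel$log$name[1], "inf01")
  expect_equal(sel$log$action[1], "enter")
  expect_true("inf01" %in% sel$selected)
})

test_that("stepwise selection edge cases and determinism", {
  ft <- generate_feature_table(n = 200, k_informative = 2, m_noise = 6,
                               d = 2, seed = 3)
  expect_length(forward_stepwise_select(ft$X, ft$y, max_features = 0)$selected, 0L)

  Xconst <- matrix(1, 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(forward_stepwise_select(Xconst, rbinom(50, 1, .5)),
               class = "degenerate_input_error")

  s1 <- forward_stepwise_select(ft$X, ft$y, max_features = 4)
  s2 <- forward_stepwise_select(ft$X, ft$y, max_features = 4)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$log, s2$log)
  expect_lte(length(s1$selected), 4L)
  # every removal follows a prior entry of the same name
  if (any(s1$log$action == "remove")) {
    for (i in which(s1$log$action == "remove")) {
      expect_true(s1$log$name[i] %in% s1$log$name[seq_len(i - 1)][s1$log$action[seq_len(i - 1)] == "enter"])
    }
  }
})

test_that("first k picks contain the informative features in most seeds", {
  hits <- 0L
  for (sd in 1:50) {
    ft <- generate_feature_table(n = 200, k_informative = 2, m_noise = 8,
                                 d = 2, seed = 1000L + sd)
    sel <- forward_stepwise_select(ft$X, ft$y, max_features = 2)
    if (all(ft$informative %in% sel$selected)) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
})

test_that("grouped candidates enter and leave together", {
  ft <- generate_feature_table(n = 250, k_informative = 2, m_noise = 4,
                               d = 2, seed = 8)
  groups <- rep(c("g1", "g2", "g3"), each = 2)   # pair up the 6 columns
  sel <- forward_stepwise_select(ft$X, ft$y, groups = groups)
  expect_true(all(sel$selected %in% c("g1", "g2", "g3")))
  expect_true("g1" %in% sel$selected)   # both informative columns live in g1
})

test_that("standardization round-trips and freezes training statistics", {
  set.seed(2)
  X <- matrix(rnorm(60, 5, 3), 20, 3)
  std <- standardize_fit(X)
  expect_equal(unname(colMeans(std$X)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(std$X, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(standardize_apply(X, std), std$X)
})
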