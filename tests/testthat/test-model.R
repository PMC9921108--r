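test_that("split_dataset is exact, disjoint and seed-deterministic", {
  tags <- split_dataset(100L, 0.70, seed = 4L)
  expect_equal(sum(tags == "training"), 70L)
  expect_equal(sum(tags == "validation"), 30L)
  expect_setequal(unique(tags), c("training", "validation"))
  expect_identical(tags, split_dataset(100L, 0.70, seed = 4L))
  expect_false(identical(tags, split_dataset(100L, 0.70, seed = 5L)))
  # within one record of the requested fraction for awkward sizes
  t97 <- split_dataset(97L, 0.70, seed = 1L)
  expect_lte(abs(sum(t97 == "training") - 0.7 * 97), 1)
})

test_that("train_mlp separates separable classes and is seed-deterministic", {
  ft <- generate_feature_table(n = 500, k_informative = 3, m_noise = 0,
                               d = 3, seed = 77)
  # brute-force linear scan first: a single-feature threshold must already
  # separate well, establishing that the problem is separable
  scan_acc <- max(vapply(seq_len(ncol(ft$X)), function(j) {
    thr <- sort(ft$X[, j])
    max(vapply(thr, function(t) mean((ft$X[, j] > t) == (ft$y == 1)), numeric(1)))
  }, numeric(1)))
  expect_gte(scan_acc, 0.90)

  m <- train_mlp(ft$X, ft$y, n_hidden = 5L, seed = 9L)
  acc <- mean((predict(m, ft$X)[, "interacting"] > 0.5) == (ft$y == 1))
  expect_gte(acc, 0.95)

  m2 <- train_mlp(ft$X, ft$y, n_hidden = 5L, seed = 9L)
  expect_identical(m$wts, m2$wts)
  m3 <- train_mlp(ft$X, ft$y, n_hidden = 5L, seed = 10L)
  expect_false(identical(m$wts, m3$wts))

  expect_error(train_mlp(ft$X, ft$y, n_hidden = 0L, seed = 1L),
               class = "degenerate_input_error")
})

test_that("predicted probability pairs sum to one", {
  ft <- generate_feature_table(n = 120, k_informative = 1, m_noise = 2,
                               d = 1, seed = 15)
  m <- train_mlp(ft$X, ft$y, n_hidden = 3L, seed = 2L)
  P <- predict(m, ft$X)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  expect_true(all(P >= 0 & P <= 1))
})

test_that("confusion statistics reproduce the published worked example", {
  st <- confusion_from_counts(tp = 25938, tn = 34247, fp = 1191, fn = 1148)
  expect_equal(round(st$mcc, 2), 0.92)
  expect_equal(round(100 * st$accuracy, 2), 96.26)
  expect_equal(round(100 * st$specificity, 2), 96.64)
  expect_equal(round(100 * st$sensitivity, 2), 95.76)
  expect_equal(st$total, 62524)
})

test_that("confusion stats handle perfect, degenerate and mismatched input", {
  perfect <- confusion_stats(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$accuracy, 1)

  onesided <- confusion_stats(rep(1, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(onesided$mcc, 0)
  expect_true(onesided$degenerate)

  expect_error(confusion_stats(c(1, 0), c(1, 0, 1)),
               class = "length_mismatch_error")
})

test_that("MCC is invariant under class swap and negates under inversion", {
  set.seed(31)
  for (rep in 1:20) {
    cnt <- sample(1:50, 4)
    a <- confusion_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    swapped <- confusion_from_counts(cnt[2], cnt[1], cnt[4], cnt[3])
    inverted <- confusion_from_counts(cnt[4], cnt[3], cnt[2], cnt[1])
    expect_equal(a$mcc, swapped$mcc, tolerance = 1e-12)
    expect_equal(a$mcc, -inverted$mcc, tolerance = 1e-12)
  }
})

test_that("ROC/AUC behaves on perfect, inverted and random scores", {
  y <- c(rep(1, 5), rep(0, 5))
  s <- c(seq(0.9, 0.6, length.out = 5), seq(0.4, 0.1, length.out = 5))
  expect_equal(roc_auc(s, y)$auc, 1)
  expect_equal(roc_auc(s, 1 - y)$auc, 0)

  set.seed(5)
  y2 <- rbinom(10000, 1, 0.5); s2 <- runif(10000)
  expect_equal(roc_auc(s2, y2)$auc, 0.5, tolerance = 0.02)

  expect_error(roc_auc(runif(5), rep(1, 5)), class = "degenerate_labels_error")
})

test_that("trapezoid AUC equals the Mann-Whitney normalization", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)      # ties on purpose
    auc <- roc_auc(s, y)$auc
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on a shared instance", {
  set.seed(17)
  y <- rbinom(150, 1, 0.4); s <- runif(150) + 0.5 * y
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("per-class report splits accuracy by true label", {
  pred  <- c(1, 0, 1, 1, 0, 0)
  truth <- c(1, 0, 0, 1, 1, 0)
  ec    <- c("1.1", "1.1", "1.1", "3.2", "3.2", "3.2")
  rep_ <- per_class_report(pred, truth, ec)
  expect_equal(rep_$ec_family, c("1.1", "3.2"))
  expect_equal(rep_$total, c(3L, 3L))
  expect_equal(rep_$acc_interacting, c(1, 0.5))
  expect_equal(rep_$acc_non_interacting, c(0.5, 1))
  expect_error(per_class_report(pred, truth, ec, families = "9.9"),
               class = "empty_class_error")
  perfect <- per_class_report(truth, truth, ec)
  expect_true(all(perfect$acc_interacting == 1 & perfect$acc_non_interacting == 1))
})

test_that("model bundles round-trip with bit-identical predictions", {
  b <- tiny_bundle()
  gen <- tiny_gen()
  X <- featurize_table(gen$pairs[1:20, ], gen$descriptors, b$profiles, b$selected)
  p1 <- predict(b$model, X)

  path2 <- tempfile(fileext = ".json")
  save_model(b$model, b$profiles, b$selected, path2)
  b2 <- load_model(path2)
  expect_identical(b2$model$wts, b$model$wts)
  expect_identical(predict(b2$model, X), p1)
  expect_equal(b2$profiles$ec_family, b$profiles$ec_family)

  # schema tampering is refused
  j <- jsonlite::read_json(path2)
  j$schema_version <- "other-schema-9"
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(j, bad, auto_unbox = TRUE)
  expect_error(load_model(bad), class = "version_mismatch_error")
})

test_that("repeat_model_search ranks fresh split-and-train runs", {
  gen <- tiny_gen()
  pairs <- curate_pairs(gen$pairs)
  search <- repeat_model_search(pairs, gen$descriptors,
                                selected = c("ring_count", "petitjean", "balaban_j"),
                                n_models = 3L, hidden_range = c(5L, 5L),
                                master_seed = 2L, maxit = 60L)
  expect_length(search$entries, 3L)
  acc <- search$summary$accuracy_overall
  expect_true(all(diff(acc) <= 0))            # ranked best first
  expect_true(all(search$summary$topology == "MLP 9-5-2"))
  splits <- vapply(search$entries, function(e) paste(e$split, collapse = ""), character(1))
  expect_equal(length(unique(splits)), 3L)    # each model has its own split
})
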