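#' @importFrom nnet nnet class.ind
NULL

.SCHEMA_VERSION <- "mtqsar-bundle-1"

#' Random 70/30 training/validation split
#'
#' Uniform random assignment at the pair level, reproducible for a fixed
#' seed. Validation records are never touched during training, so the
#' validation partition behaves as an external test set.
#'
#' @param n number of records.
#' @param fraction training fraction (default 0.70).
#' @param seed integer seed.
#' @return character vector of tags `"training"`/`"validation"` of length
#'   `n`, with attributes `fraction` and `seed`. `round(fraction * n)`
#'   records are tagged training.
#' @export
split_dataset <- function(n, fraction = 0.70, seed) {
  stopifnot(n >= 1L, fraction > 0, fraction < 1)
  n_train <- round(fraction * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tags <- rep("validation", n)
  tags[sample.int(n, n_train)] <- "training"
  structure(tags, fraction = fraction, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Train the two-output MLP
#'
#' A single-hidden-layer perceptron with logistic hidden units and a softmax
#' output pair (interacting / non-interacting), fitted by \pkg{nnet}'s BFGS
#' optimizer on the cross-entropy loss. Initial weights are random, so
#' different seeds generally yield different networks — the rationale for
#' the repeated-training protocol — while a fixed seed is fully
#' reproducible. Features are z-standardized internally and the parameters
#' are frozen into the model.
#'
#' Early stopping monitors a carve-out of the training partition (never the
#' validation partition, which stays an external test set): optimization
#' proceeds in blocks of `block` iterations and halts once the carve-out
#' misclassification rate has not improved for `patience` blocks, keeping
#' the best-scoring weights. This guards against memorizing pair-level noise
#' through drug fingerprints. Set `early_stop_frac = 0` for a plain single
#' fit of `maxit` iterations.
#'
#' @param X numeric feature matrix (rows = pairs).
#' @param y binary labels (0 = non-interacting, 1 = interacting).
#' @param n_hidden hidden units (>= 1).
#' @param seed integer seed for the random initial weights.
#' @param maxit,decay optimizer iteration cap and weight decay.
#' @param early_stop_frac fraction of the rows carved out for early stopping.
#' @param patience,block early-stopping patience (in blocks) and block size.
#' @return an `mlp_model`: weight vector, layer sizes, input names, frozen
#'   standardization, seed and topology string (e.g. `"MLP 39-50-2"`).
#' @export
train_mlp <- function(X, y, n_hidden, seed, maxit = 300L, decay = 1e-2,
                      early_stop_frac = 0.15, patience = 3L, block = 25L) {
  if (n_hidden < 1L)
    mtq_stop("degenerate_input_error", "n_hidden must be >= 1")
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  std <- standardize_fit(X)
  Y <- nnet::class.ind(factor(y, levels = c(0L, 1L)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(X)
  if (early_stop_frac > 0 && round(early_stop_frac * n) >= 1L) {
    carve <- sample.int(n, round(early_stop_frac * n))
    fitX <- std$X[-carve, , drop = FALSE]; fitY <- Y[-carve, , drop = FALSE]
    evX <- std$X[carve, , drop = FALSE]; evy <- y[carve]
    wts <- NULL; best <- NULL; best_err <- Inf; stall <- 0L
    for (b in seq_len(max(1L, ceiling(maxit / block)))) {
      fit <- if (is.null(wts)) {
        nnet::nnet(fitX, fitY, size = n_hidden, softmax = TRUE, maxit = block,
                   decay = decay, trace = FALSE, MaxNWts = 100000L)
      } else {
        nnet::nnet(fitX, fitY, size = n_hidden, softmax = TRUE, maxit = block,
                   decay = decay, trace = FALSE, MaxNWts = 100000L, Wts = wts)
      }
      wts <- fit$wts
      pr <- .mlp_forward(wts, ncol(X), n_hidden, 2L, evX)
      err <- mean((pr[, 2L] > 0.5) != (evy == 1L))
      if (err < best_err - 1e-9) { best_err <- err; best <- wts; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= patience) break
    }
    final_wts <- best
  } else {
    fit <- nnet::nnet(std$X, Y, size = n_hidden, softmax = TRUE,
                      maxit = maxit, decay = decay, trace = FALSE,
                      MaxNWts = 100000L)
    final_wts <- fit$wts
  }
  structure(list(
    wts = final_wts,
    n_inputs = ncol(X), n_hidden = as.integer(n_hidden), n_outputs = 2L,
    input_names = colnames(X),
    std = list(center = std$center, scale = std$scale),
    seed = as.integer(seed),
    activation = c(hidden = "logistic", output = "softmax"),
    topology = sprintf("MLP %d-%d-2", ncol(X), n_hidden)
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s (seed %d)\n", x$topology, x$seed))
  invisible(x)
}

#' Class probabilities from an `mlp_model`
#'
#' The forward pass is computed directly from the stored weight vector
#' (\pkg{nnet} layout), so a freshly trained and a reloaded model follow the
#' identical code path.
#'
#' @param object an `mlp_model`.
#' @param newdata numeric matrix on the original (unstandardized) scale.
#' @param ... unused.
#' @return matrix with columns `non_interacting`, `interacting`; rows sum to 1.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- standardize_apply(as.matrix(newdata), object$std)
  stopifnot(ncol(X) == object$n_inputs)
  P <- .mlp_forward(object$wts, object$n_inputs, object$n_hidden,
                    object$n_outputs, X)
  colnames(P) <- c("non_interacting", "interacting")
  P
}

# forward pass in nnet weight layout: [bias; input weights] per hidden unit,
# then [bias; hidden weights] per output; logistic hidden, softmax output
.mlp_forward <- function(wts, p, h, k, X) {
  stopifnot(length(wts) == h * (p + 1L) + k * (h + 1L))
  W1 <- matrix(wts[seq_len(h * (p + 1L))], nrow = p + 1L)
  W2 <- matrix(wts[h * (p + 1L) + seq_len(k * (h + 1L))], nrow = h + 1L)
  Z <- 1 / (1 + exp(-(cbind(1, X) %*% W1)))
  A <- cbind(1, Z) %*% W2
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  E / rowSums(E)
}

#' Confusion-matrix statistics from predicted and true labels
#'
#' @param predicted,truth binary vectors (1 = interacting) of equal length.
#' @return `confusion_stats` (see [confusion_from_counts()]).
#' @export
confusion_stats <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    mtq_stop("length_mismatch_error",
             sprintf("predicted (%d) and truth (%d) differ in length",
                     length(predicted), length(truth)))
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  confusion_from_counts(tp = sum(predicted == 1L & truth == 1L),
                        tn = sum(predicted == 0L & truth == 0L),
                        fp = sum(predicted == 1L & truth == 0L),
                        fn = sum(predicted == 0L & truth == 1L))
}

#' Confusion-matrix statistics from raw counts
#'
#' Derived quantities: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' overall accuracy (TP+TN)/total, and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). When any
#' factor of the MCC denominator is zero (a degenerate one-class situation)
#' the MCC is defined as 0 and the result is flagged.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return `confusion_stats`: list of the four counts plus `sensitivity`,
#'   `specificity`, `accuracy`, `mcc`, `total`, and `degenerate` flag.
#' @export
confusion_from_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  total <- tp + tn + fp + fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- den == 0
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn, total = total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = if (total > 0) (tp + tn) / total else NA_real_,
    mcc = if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(den),
    degenerate = degenerate
  ), class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("<confusion_stats> TP=%g TN=%g FP=%g FN=%g | acc=%.4f sens=%.4f spec=%.4f MCC=%.4f%s\n",
              x$tp, x$tn, x$fp, x$fn, x$accuracy, x$sensitivity, x$specificity,
              x$mcc, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' ROC curve and area under it
#'
#' The curve is the step function of (FPR, TPR) over all score thresholds;
#' the area is computed by the trapezoid rule. A random scorer has expected
#' area 0.5.
#'
#' @param scores interacting-class probabilities in [0, 1].
#' @param labels binary truth (1 = interacting).
#' @return list with `points` (data.frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    mtq_stop("length_mismatch_error", "scores and labels differ in length")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    mtq_stop("degenerate_labels_error", "ROC needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tpr <- c(0, cumsum(l == 1L)[!duplicated(s, fromLast = TRUE)] / n_pos)
  fpr <- c(0, cumsum(l == 0L)[!duplicated(s, fromLast = TRUE)] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Per-subclass accuracy report
#'
#' One row per enzyme subclass: total entries, accuracy on the interacting
#' pairs and accuracy on the non-interacting pairs of that subclass.
#'
#' @param predicted,truth binary vectors.
#' @param ec_family subclass label per record.
#' @param families subclasses to report (default: all present, EC-sorted);
#'   requesting a family with no records raises `empty_class_error`.
#' @return data.frame: `ec_family`, `total`, `acc_interacting`,
#'   `acc_non_interacting` (NA when a subclass lacks that label).
#' @export
per_class_report <- function(predicted, truth, ec_family, families = NULL) {
  stopifnot(length(predicted) == length(truth), length(truth) == length(ec_family))
  present <- unique(ec_family)
  families <- families %||% sort_ec_families(present)
  absent <- setdiff(families, present)
  if (length(absent) > 0L)
    mtq_stop("empty_class_error",
             sprintf("no records for subclass(es): %s", paste(absent, collapse = ", ")))
  rows <- lapply(families, function(cl) {
    sel <- ec_family == cl
    pos <- sel & truth == 1L; neg <- sel & truth == 0L
    data.frame(ec_family = cl, total = sum(sel),
               acc_interacting = if (any(pos)) mean(predicted[pos] == 1L) else NA_real_,
               acc_non_interacting = if (any(neg)) mean(predicted[neg] == 0L) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeated split-and-train model search
#'
#' Emulates the protocol of training many networks, each with its own fresh
#' random 70/30 split, its own random initial weights and its own hidden
#' size drawn from `hidden_range`, then ranking by overall accuracy. Class
#' profiles are rebuilt from each model's training partition. Per-model
#' seeds are derived deterministically from `master_seed`.
#'
#' @param pairs a curated `pair_table`.
#' @param descriptors descriptor matrix (rownames = drug_id).
#' @param selected base descriptor names feeding the model.
#' @param n_models number of networks to train.
#' @param hidden_range inclusive integer range of hidden sizes.
#' @param fraction training fraction.
#' @param master_seed integer master seed.
#' @param maxit optimizer cap per network.
#' @return `model_search`: list with `entries` (each: model, split, profiles,
#'   stats_overall/train/validation) ranked by overall accuracy, and
#'   `summary` data.frame.
#' @export
repeat_model_search <- function(pairs, descriptors, selected, n_models,
                                hidden_range = c(40L, 50L), fraction = 0.70,
                                master_seed = 1L, maxit = 200L) {
  stopifnot(n_models >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(master_seed)
  split_seeds <- sample.int(2^30, n_models)
  train_seeds <- sample.int(2^30, n_models)
  sizes <- seq(hidden_range[1L], hidden_range[2L])
  hidden <- sizes[sample.int(length(sizes), n_models, replace = TRUE)]

  entries <- lapply(seq_len(n_models), function(i) {
    tags <- split_dataset(nrow(pairs), fraction, split_seeds[i])
    tr <- pairs[tags == "training", , drop = FALSE]
    profiles <- build_class_profiles(tr, descriptors)
    # families absent from a training partition cannot be featurized; the
    # split is re-drawn in that (rare, small-data) case
    if (!all(unique(pairs$ec_family) %in% profiles$ec_family)) {
      tags <- split_dataset(nrow(pairs), fraction, split_seeds[i] + 1L)
      tr <- pairs[tags == "training", , drop = FALSE]
      profiles <- build_class_profiles(tr, descriptors)
    }
    Xtr <- featurize_table(tr, descriptors, profiles, selected)
    model <- train_mlp(Xtr, tr$label, n_hidden = hidden[i],
                       seed = train_seeds[i], maxit = maxit)
    Xall <- featurize_table(pairs, descriptors, profiles, selected)
    pred <- as.integer(predict(model, Xall)[, "interacting"] > 0.5)
    va <- tags == "validation"
    list(model = model, split = tags, profiles = profiles,
         stats_overall = confusion_stats(pred, pairs$label),
         stats_training = confusion_stats(pred[!va], pairs$label[!va]),
         stats_validation = confusion_stats(pred[va], pairs$label[va]))
  })
  acc <- vapply(entries, function(e) e$stats_overall$accuracy, numeric(1))
  ord <- order(acc, decreasing = TRUE)
  entries <- entries[ord]
  summary <- data.frame(
    rank = seq_along(entries),
    topology = vapply(entries, function(e) e$model$topology, character(1)),
    accuracy_overall = vapply(entries, function(e) e$stats_overall$accuracy, numeric(1)),
    accuracy_training = vapply(entries, function(e) e$stats_training$accuracy, numeric(1)),
    accuracy_validation = vapply(entries, function(e) e$stats_validation$accuracy, numeric(1)),
    mcc_overall = vapply(entries, function(e) e$stats_overall$mcc, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(entries = entries, summary = summary, master_seed = master_seed),
            class = "model_search")
}

#' @export
print.model_search <- function(x, ...) {
  cat(sprintf("<model_search> %d model(s), master seed %d\n",
              length(x$entries), x$master_seed))
  print(x$summary)
  invisible(x)
}

# ---- model bundle serialization (plain JSON, IEEE-754 round-trip) ----------

.num_out <- function(x) sprintf("%.17g", x)
.num_in <- function(x) as.numeric(x)

#' Save a fitted model bundle
#'
#' The bundle embeds everything prediction needs: network weights, layer
#' sizes, frozen standardization, the selected descriptor list, the class
#' profiles and the descriptor-registry version. Numerics are written with
#' 17 significant digits, so a save/load round trip reproduces the weights
#' bit-identically.
#'
#' @param model an `mlp_model`.
#' @param profiles a `class_profiles` object.
#' @param selected base descriptor names the model consumes.
#' @param path output file (JSON).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, profiles, selected, path) {
  desc_cols <- setdiff(colnames(profiles), c("ec_family", "n_pairs"))
  bundle <- list(
    schema_version = .SCHEMA_VERSION,
    registry_version = attr(profiles, "version") %||% .REGISTRY_VERSION,
    selected = selected,
    model = list(
      wts = .num_out(model$wts),
      n_inputs = model$n_inputs, n_hidden = model$n_hidden,
      n_outputs = model$n_outputs,
      input_names = model$input_names,
      center = .num_out(model$std$center), scale = .num_out(model$std$scale),
      seed = model$seed, activation = as.list(model$activation),
      topology = model$topology
    ),
    profiles = list(
      ec_family = profiles$ec_family,
      n_pairs = profiles$n_pairs,
      descriptor_names = desc_cols,
      means = lapply(seq_len(nrow(profiles)),
                     function(i) .num_out(as.numeric(profiles[i, desc_cols])))
    )
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a model bundle
#'
#' @param path JSON bundle written by [save_model()].
#' @return `model_bundle`: list with `model` (`mlp_model`), `profiles`
#'   (`class_profiles`), `selected`, `registry_version`.
#' @export
load_model <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$schema_version, .SCHEMA_VERSION))
    mtq_stop("version_mismatch_error",
             sprintf("bundle schema '%s' incompatible with '%s'",
                     b$schema_version %||% "<missing>", .SCHEMA_VERSION))
  if (!identical(b$registry_version, .REGISTRY_VERSION))
    mtq_stop("version_mismatch_error",
             sprintf("bundle descriptor registry '%s' incompatible with '%s'",
                     b$registry_version %||% "<missing>", .REGISTRY_VERSION))
  model <- structure(list(
    wts = .num_in(b$model$wts),
    n_inputs = as.integer(b$model$n_inputs),
    n_hidden = as.integer(b$model$n_hidden),
    n_outputs = as.integer(b$model$n_outputs),
    input_names = b$model$input_names,
    std = list(center = stats::setNames(.num_in(b$model$center), b$model$input_names),
               scale = stats::setNames(.num_in(b$model$scale), b$model$input_names)),
    seed = as.integer(b$model$seed),
    activation = unlist(b$model$activation),
    topology = b$model$topology
  ), class = "mlp_model")
  m_raw <- b$profiles$means
  means <- if (is.matrix(m_raw)) {
    matrix(.num_in(m_raw), nrow(m_raw), ncol(m_raw))
  } else {
    do.call(rbind, lapply(m_raw, .num_in))
  }
  colnames(means) <- b$profiles$descriptor_names
  profiles <- data.frame(ec_family = b$profiles$ec_family,
                         n_pairs = as.integer(b$profiles$n_pairs),
                         means, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(profiles) <- profiles$ec_family
  profiles <- structure(profiles, version = b$registry_version,
                        class = c("class_profiles", "data.frame"))
  structure(list(model = model, profiles = profiles,
                 selected = b$selected, registry_version = b$registry_version),
            class = "model_bundle")
}
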