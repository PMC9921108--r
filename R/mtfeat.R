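#' @importFrom stats glm binomial pchisq setNames sd
NULL

#' Per-subclass descriptor means (the moving-average reference profiles)
#'
#' For each enzyme subclass present in `pairs`, computes the arithmetic mean
#' of every descriptor over the contributing records. These class means
#' <MD> are what make a single classifier target-aware: each (drug, class)
#' pair is later described by the drug's descriptor MD, the class mean <MD>,
#' and the deviation DMD = MD - <MD>.
#'
#' By default profiles should be built from the training partition only and
#' then frozen for validation and prediction, so no validation label
#' information leaks into the features. All pairs of a subclass contribute
#' regardless of label; set `actives_only = TRUE` for the actives-only
#' variant.
#'
#' @param pairs a `pair_table`.
#' @param descriptors descriptor matrix with rownames = `drug_id`
#'   (see [compute_descriptor_table()]).
#' @param classes subclasses to profile; default all present in `pairs`.
#'   Requesting an absent subclass raises `empty_class_error`.
#' @param actives_only if `TRUE`, only interacting pairs contribute.
#' @return `class_profiles`: data.frame with `ec_family`, `n_pairs`, one
#'   column per descriptor; attribute `version` carries the registry stamp.
#' @export
build_class_profiles <- function(pairs, descriptors, classes = NULL,
                                 actives_only = FALSE) {
  if (actives_only) pairs <- pairs[pairs$label == 1L, , drop = FALSE]
  present <- unique(pairs$ec_family)
  classes <- classes %||% sort_ec_families(present)
  absent <- setdiff(classes, present)
  if (length(absent) > 0L)
    mtq_stop("empty_class_error",
             sprintf("no records contribute to subclass(es): %s",
                     paste(absent, collapse = ", ")))
  idx <- match(pairs$drug_id, rownames(descriptors))
  if (anyNA(idx))
    mtq_stop("format_error",
             sprintf("%d pair(s) have no descriptor row", sum(is.na(idx))))
  X <- descriptors[idx, , drop = FALSE]
  rows <- lapply(classes, function(cl) {
    sel <- pairs$ec_family == cl
    colMeans(X[sel, , drop = FALSE])
  })
  out <- data.frame(ec_family = classes,
                    n_pairs = vapply(classes, function(cl) sum(pairs$ec_family == cl), integer(1)),
                    do.call(rbind, rows),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- out$ec_family
  structure(out, version = attr(descriptors, "version"),
            actives_only = actives_only,
            class = c("class_profiles", "data.frame"))
}

#' Order EC subclass labels numerically (class, then subclass)
#' @param x character vector of dotted labels such as "1.1", "3.2", "7.2".
#' @return `x` sorted so that 1.1 < 1.2 < ... < 7.2.
#' @export
sort_ec_families <- function(x) {
  parts <- do.call(rbind, strsplit(x, ".", fixed = TRUE))
  x[order(as.integer(parts[, 1]), as.integer(parts[, 2]))]
}

#' Build the (MD, <MD>, DMD) feature triple for one (drug, subclass) pair
#'
#' @param dv named descriptor vector for the drug.
#' @param profile one row of a `class_profiles` object (the target subclass).
#' @param selected base descriptor names to emit, in order.
#' @return numeric vector of length `3 * length(selected)`, named
#'   `<desc>_md`, `<desc>_mean`, `<desc>_dmd` triple-wise; exact arithmetic,
#'   so `md = mean + dmd` to machine precision.
#' @export
featurize_pair <- function(dv, profile, selected) {
  missing_p <- setdiff(selected, colnames(profile))
  if (length(missing_p) > 0L)
    mtq_stop("unknown_descriptor_error",
             sprintf("selected descriptor(s) missing from profile: %s",
                     paste(missing_p, collapse = ", ")))
  missing_d <- setdiff(selected, names(dv))
  if (length(missing_d) > 0L)
    mtq_stop("unknown_descriptor_error",
             sprintf("selected descriptor(s) missing from descriptor vector: %s",
                     paste(missing_d, collapse = ", ")))
  md <- as.numeric(dv[selected])
  mn <- as.numeric(profile[1L, selected])
  out <- as.numeric(rbind(md, mn, md - mn))
  names(out) <- as.vector(rbind(paste0(selected, "_md"),
                                paste0(selected, "_mean"),
                                paste0(selected, "_dmd")))
  out
}

#' Feature matrix for a pair table
#'
#' Row i is [featurize_pair()] applied to pair i's drug descriptors and the
#' profile of pair i's subclass.
#'
#' @param pairs a `pair_table`.
#' @param descriptors descriptor matrix with rownames = `drug_id`.
#' @param profiles a `class_profiles` object covering every subclass in `pairs`.
#' @param selected base descriptor names.
#' @return numeric matrix, `nrow(pairs)` x `3 * length(selected)`.
#' @export
featurize_table <- function(pairs, descriptors, profiles, selected) {
  absent <- setdiff(unique(pairs$ec_family), profiles$ec_family)
  if (length(absent) > 0L)
    mtq_stop("empty_class_error",
             sprintf("no profile for subclass(es): %s", paste(absent, collapse = ", ")))
  idx <- match(pairs$drug_id, rownames(descriptors))
  MD <- descriptors[idx, selected, drop = FALSE]
  MN <- as.matrix(profiles[pairs$ec_family, selected, drop = FALSE])
  out <- matrix(0, nrow(pairs), 3L * length(selected))
  out[, seq(1L, ncol(out), by = 3L)] <- MD
  out[, seq(2L, ncol(out), by = 3L)] <- MN
  out[, seq(3L, ncol(out), by = 3L)] <- MD - MN
  colnames(out) <- as.vector(rbind(paste0(selected, "_md"),
                                   paste0(selected, "_mean"),
                                   paste0(selected, "_dmd")))
  rownames(out) <- NULL
  out
}

#' Forward-stepwise descriptor selection
#'
#' Greedy selection on a logistic-regression surrogate: at each step the
#' candidate whose entry most improves the model (largest likelihood-ratio
#' statistic) enters if its LRT p-value passes `p_enter`; then any included
#' candidate whose conditional contribution has decayed beyond `p_remove`
#' leaves. The loop stops when neither move applies or `max_features` is
#' reached. `p_enter < p_remove` prevents enter/remove cycling. Ties are
#' broken by lexicographic candidate name, so the procedure is fully
#' deterministic.
#'
#' @param X numeric feature matrix (rows = pairs). With the default
#'   `groups = NULL` every column is its own candidate; in the multi-target
#'   pipeline, `groups` maps columns to base-descriptor candidates so that a
#'   descriptor's feature forms enter or leave together.
#' @param y binary labels (0/1), length `nrow(X)`.
#' @param max_features stop after this many candidates are in the model.
#' @param p_enter,p_remove LRT p-value thresholds (defaults 0.05 / 0.10).
#' @param groups optional character vector, length `ncol(X)`, naming the
#'   candidate each column belongs to.
#' @return `stepwise_selection`: list with `selected` (candidate names, entry
#'   order) and `log` (data.frame: step, action, name, p_value).
#' @export
forward_stepwise_select <- function(X, y, max_features = ncol(X),
                                    p_enter = 0.05, p_remove = 0.10,
                                    groups = NULL) {
  stopifnot(p_enter <= p_remove, max_features >= 0L)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  groups <- groups %||% colnames(X)
  stopifnot(length(groups) == ncol(X))
  y <- as.integer(y)

  keep_col <- apply(X, 2L, function(v) sd(v) > 0)
  candidates <- sort(unique(groups[keep_col]))
  if (length(candidates) == 0L)
    mtq_stop("degenerate_input_error", "all candidate features are constant")

  dev_of <- function(members) {
    cols <- which(groups %in% members & keep_col)
    if (length(cols) == 0L) {
      fit <- glm(y ~ 1, family = binomial())
    } else {
      df <- data.frame(X[, cols, drop = FALSE])
      fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    }
    c(dev = fit$deviance, df = fit$df.residual)
  }

  lrt_p <- function(small, big) {
    # small nested in big; p-value of the deviance drop
    stat <- max(0, small["dev"] - big["dev"])
    ddf <- max(1, small["df"] - big["df"])
    unname(pchisq(stat, df = ddf, lower.tail = FALSE))
  }

  selected <- character(0)
  log_rows <- list()
  cur <- dev_of(selected)
  step <- 0L
  if (max_features > 0L) repeat {
    moved <- FALSE
    # forward entry
    if (length(selected) < max_features) {
      pool <- setdiff(candidates, selected)
      if (length(pool) > 0L) {
        fits <- lapply(pool, function(cn) dev_of(c(selected, cn)))
        ps <- vapply(fits, function(f) lrt_p(cur, f), numeric(1))
        best <- which(ps == min(ps))[1L]   # pool is sorted: lexicographic tie-break
        if (ps[best] <= p_enter) {
          selected <- c(selected, pool[best])
          cur <- fits[[best]]
          step <- step + 1L
          log_rows[[length(log_rows) + 1L]] <-
            data.frame(step = step, action = "enter", name = pool[best],
                       p_value = ps[best], stringsAsFactors = FALSE)
          moved <- TRUE
        }
      }
    }
    # backward removal
    if (length(selected) > 1L) {
      drops <- lapply(selected, function(cn) dev_of(setdiff(selected, cn)))
      ps <- vapply(drops, function(f) lrt_p(f, cur), numeric(1))
      worst <- which(ps == max(ps))[1L]
      if (ps[worst] > p_remove) {
        cur <- drops[[worst]]
        step <- step + 1L
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(step = step, action = "remove", name = selected[worst],
                     p_value = ps[worst], stringsAsFactors = FALSE)
        selected <- setdiff(selected, selected[worst])
        moved <- TRUE
      }
    }
    if (!moved || length(selected) >= max_features) break
  }
  structure(list(selected = selected,
                 log = if (length(log_rows) > 0L) do.call(rbind, log_rows)
                       else data.frame(step = integer(0), action = character(0),
                                       name = character(0), p_value = numeric(0))),
            class = "stepwise_selection")
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat(sprintf("<stepwise_selection> %d descriptor(s): %s\n",
              length(x$selected), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Column standardization (training statistics)
#'
#' @param X numeric matrix.
#' @return list `center`, `scale` (constant columns get scale 1), and the
#'   standardized matrix `X`.
#' @export
standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale,
       X = sweep(sweep(X, 2L, center), 2L, scale, "/"))
}

#' Apply frozen standardization parameters
#' @param X numeric matrix.
#' @param std list with `center` and `scale` (see [standardize_fit()]).
#' @return standardized matrix.
#' @export
standardize_apply <- function(X, std) {
  sweep(sweep(X, 2L, std$center), 2L, std$scale, "/")
}
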