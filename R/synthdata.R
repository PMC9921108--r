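#' @importFrom stats rnorm runif rbinom dnorm
NULL

# realistic two-level EC subclass labels to draw class names from
.EC_POOL <- c("1.1", "1.2", "1.5", "2.1", "2.7", "3.1", "3.2", "4.2",
              "1.11", "2.5", "3.4", "5.3", "5.6", "7.2", "1.3", "1.4",
              "2.3", "2.6", "3.3", "3.5", "4.6", "1.8", "1.17")

#' Synthetic-dataset configuration
#'
#' Defaults are the package's reference study conditions: 8 enzyme
#' subclasses, 500 distinct drugs, 4,000 (drug, subclass) pairs, a 43%
#' interacting fraction (the composition of large curated drug-enzyme
#' interaction sets), effect size d = 2, 5 signal-bearing descriptors and a
#' 2% label-flip noise rate emulating assay error.
#'
#' @param n_classes number of enzyme subclasses.
#' @param n_drugs distinct drugs in the pool.
#' @param n_pairs total (drug, subclass) pairs.
#' @param label_balance interacting fraction, in (0, 1).
#' @param effect_size d, the standardized tilt separating interacting from
#'   non-interacting drugs along each informative descriptor (0 = no signal).
#' @param n_informative number of signal-bearing base descriptors.
#' @param noise_rate label-flip probability.
#' @param seed mandatory integer seed.
#' @return `synth_config` list.
#' @export
synth_config <- function(n_classes = 8L, n_drugs = 500L, n_pairs = 4000L,
                         label_balance = 0.43, effect_size = 2,
                         n_informative = 5L, noise_rate = 0.02, seed) {
  stopifnot(n_classes >= 1L, n_drugs >= 1L, n_pairs >= 1L,
            label_balance > 0, label_balance < 1, effect_size >= 0,
            n_informative >= 1L, noise_rate >= 0, noise_rate < 0.5)
  if (missing(seed)) stop("seed is mandatory")
  structure(list(n_classes = as.integer(n_classes), n_drugs = as.integer(n_drugs),
                 n_pairs = as.integer(n_pairs), label_balance = label_balance,
                 effect_size = effect_size, n_informative = as.integer(n_informative),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# one random valence-respecting molecule: a random tree over C/N/O plus up
# to two ring-closing bonds; occasional double bonds where valence allows
.random_molecule <- function(n_atoms) {
  val <- c(C = 4L, N = 3L, O = 2L)
  sym <- sample(names(val), n_atoms, replace = TRUE, prob = c(0.70, 0.15, 0.15))
  free <- unname(val[sym])
  parent <- integer(n_atoms)
  pord <- integer(n_atoms)      # bond order to parent
  if (n_atoms > 1L) for (i in 2:n_atoms) {
    cand <- which(free[seq_len(i - 1L)] >= 1L)
    if (length(cand) == 0L) return(NULL)
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    o <- if (free[p] >= 2L && free[i] >= 2L && runif(1) < 0.15) 2L else 1L
    parent[i] <- p; pord[i] <- o
    free[p] <- free[p] - o; free[i] <- free[i] - o
  }
  ring <- matrix(integer(0), 0L, 2L)
  if (n_atoms >= 3L) {
    n_rings <- sample(0:2, 1L, prob = c(0.35, 0.45, 0.20))
    for (r in seq_len(n_rings)) {
      ok_u <- which(free >= 1L)
      if (length(ok_u) < 2L) break
      pair <- sample(ok_u, 2L)
      u <- min(pair); v <- max(pair)
      adjacent <- parent[v] == u || parent[u] == v ||
        any(ring[, 1] == u & ring[, 2] == v)
      if (adjacent) next
      ring <- rbind(ring, c(u, v))
      free[u] <- free[u] - 1L; free[v] <- free[v] - 1L
    }
  }
  list(sym = sym, parent = parent, pord = pord, ring = ring)
}

# depth-first SMILES writer over the spanning tree; ring bonds become
# ring-closure digits on both endpoint atoms
.write_smiles <- function(mol) {
  n <- length(mol$sym)
  kids <- vector("list", n)
  if (n > 1L) for (i in 2:n) kids[[mol$parent[i]]] <- c(kids[[mol$parent[i]]], i)
  ringtok <- character(n)
  if (nrow(mol$ring) > 0L) for (r in seq_len(nrow(mol$ring))) {
    ringtok[mol$ring[r, 1]] <- paste0(ringtok[mol$ring[r, 1]], r)
    ringtok[mol$ring[r, 2]] <- paste0(ringtok[mol$ring[r, 2]], r)
  }
  rec <- function(v) {
    out <- paste0(mol$sym[v], ringtok[v])
    ch <- kids[[v]]
    for (k in seq_along(ch)) {
      sub <- paste0(if (mol$pord[ch[k]] == 2L) "=" else "", rec(ch[k]))
      out <- paste0(out, if (k < length(ch)) paste0("(", sub, ")") else sub)
    }
    out
  }
  rec(1L)
}

#' Generate random valid SMILES
#'
#' Random valence-respecting molecular trees over C/N/O with occasional
#' double bonds and up to two rings, written out as SMILES. Every output
#' parses with [parse_smiles()] and molecules are unique by canonical
#' SMILES, so downstream curation never collapses two generated drugs.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @param size_range inclusive range of heavy-atom counts.
#' @return data.frame with `drug_id`, `smiles`, `canonical`.
#' @export
generate_molecules <- function(n, seed, size_range = c(5L, 18L)) {
  stopifnot(n >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  smiles <- character(0); canon <- character(0)
  guard <- 0L
  while (length(smiles) < n) {
    guard <- guard + 1L
    if (guard > 50L * n)
      mtq_stop("infeasible_config_error", "molecule generator failed to reach n unique molecules")
    mol <- .random_molecule(sample(seq(size_range[1L], size_range[2L]), 1L))
    if (is.null(mol)) next
    s <- .write_smiles(mol)
    cs <- canonical_smiles(s)
    if (is.na(cs) || cs %in% canon) next
    smiles <- c(smiles, s); canon <- c(canon, cs)
  }
  data.frame(drug_id = sprintf("D%04d", seq_len(n)), smiles = smiles,
             canonical = canon, stringsAsFactors = FALSE)
}

#' Generate a synthetic drug-enzyme pair table with planted structure
#'
#' Molecules are generated first and their real topological descriptors are
#' computed; the multi-target signal is then planted entirely by how
#' (drug, subclass) pair labels are assigned, never by editing descriptor
#' values, so the full descriptor engine stays in the loop.
#'
#' Each subclass receives a latent unit signal direction u over the z-scored
#' informative descriptors (positive orthant, so per-descriptor shifts
#' reinforce across classes while the per-class weights differ). A drug's
#' affinity score for the subclass is s = u . z. Interacting pairs are the
#' top `label_balance` fraction of the subclass's drugs ranked by the noisy
#' score r = s + tau * e, with tau chosen so that the realized standardized
#' shift between interacting and non-interacting groups along u equals
#' min(d, Dmax), where Dmax(b) = dnorm(qnorm(1-b)) * (1/b + 1/(1-b)) is the
#' largest shift any top-b/bottom-(1-b) split of a unit-variance pool can
#' realize (about 1.6 at b = 0.43). Thus d = 0 yields pure noise and
#' d >= Dmax a deterministic rule; in between, d is the realized shift.
#' Finally a `noise_rate` fraction of labels is flipped (assay noise).
#'
#' @param cfg a `synth_config`.
#' @return list with `pairs` (a `pair_table` with `canonical` column),
#'   `descriptors` (matrix, rownames = drug_id), `molecules`, and `truth`
#'   (informative descriptor names, per-class `directions`, per-class
#'   `realized_shift` along u, intended labels before noise, config).
#' @export
generate_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  per_class <- floor(cfg$n_pairs / cfg$n_classes)
  extra <- cfg$n_pairs - per_class * cfg$n_classes
  n_by_class <- rep(per_class, cfg$n_classes) + c(rep(1L, extra), rep(0L, cfg$n_classes - extra))
  if (max(n_by_class) > cfg$n_drugs)
    mtq_stop("infeasible_config_error",
             sprintf("%d pairs per class requested but only %d distinct drugs",
                     max(n_by_class), cfg$n_drugs))
  mols <- generate_molecules(cfg$n_drugs, seed = cfg$seed)
  desc <- compute_descriptor_table(mols$smiles, ids = mols$drug_id)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  sds <- apply(desc, 2L, stats::sd)
  eligible <- colnames(desc)[sds > 0]
  if (length(eligible) < cfg$n_informative)
    mtq_stop("infeasible_config_error", "not enough non-constant descriptors")
  # plant signal only on identifiable descriptors: topological descriptors
  # share a dominant size factor, and a planted descriptor with a
  # near-perfect registry proxy (|r| ~ 0.99) could be replaced by that proxy
  # in any model, making "which descriptors carry the signal" unrecoverable
  # by construction. Candidates must have no external proxy above |r| 0.9
  # and be mutually correlated at most 0.85 (both measured on this pool).
  Cd <- abs(stats::cor(desc[, eligible, drop = FALSE]))
  diag(Cd) <- 0
  plantable <- eligible[apply(Cd, 1L, max) <= 0.9]
  informative <- NULL
  for (try in seq_len(100L)) {
    perm <- sample(plantable)
    if (length(perm) == 0L) break
    chosen <- perm[1L]
    for (nm in perm[-1L]) {
      if (length(chosen) >= cfg$n_informative) break
      if (all(Cd[nm, chosen] <= 0.85)) chosen <- c(chosen, nm)
    }
    if (length(chosen) == cfg$n_informative) { informative <- sort(chosen); break }
  }
  if (is.null(informative))
    mtq_stop("infeasible_config_error",
             "no identifiable, mutually non-redundant descriptor subset of the requested size")
  Z <- scale(desc[, informative, drop = FALSE])

  families <- .EC_POOL[seq_len(min(cfg$n_classes, length(.EC_POOL)))]
  if (cfg$n_classes > length(.EC_POOL))
    families <- c(families, paste0("9.", seq_len(cfg$n_classes - length(.EC_POOL))))

  b <- cfg$label_balance
  d_max <- dnorm(qnorm(1 - b)) * (1 / b + 1 / (1 - b))
  rho <- min(cfg$effect_size, d_max) / d_max
  tau <- if (rho <= 0) Inf else if (rho >= 1) 0 else sqrt(1 / rho^2 - 1)

  directions <- matrix(0, cfg$n_classes, cfg$n_informative,
                       dimnames = list(families, informative))
  realized <- stats::setNames(numeric(cfg$n_classes), families)
  rows <- vector("list", cfg$n_classes)
  for (c_i in seq_len(cfg$n_classes)) {
    n_c <- n_by_class[c_i]
    n_int <- round(b * n_c)
    # positive weights bounded away from zero: every informative descriptor
    # contributes materially to every class's rule, while the weight profile
    # still varies between classes
    u <- 1 + 0.5 * abs(rnorm(cfg$n_informative))
    u <- u / sqrt(sum(u^2))
    directions[c_i, ] <- u
    in_class <- sample(cfg$n_drugs, n_c)        # drugs appearing in this subclass
    s <- as.numeric(Z[in_class, , drop = FALSE] %*% u)
    s_sd <- stats::sd(s)
    r <- if (is.infinite(tau)) rnorm(n_c) else s + tau * s_sd * rnorm(n_c)
    ord <- in_class[order(r, decreasing = TRUE)]
    label <- integer(n_c)
    label[seq_len(n_int)] <- 1L
    s_ord <- s[match(ord, in_class)]
    realized[c_i] <- (mean(s_ord[label == 1L]) - mean(s_ord[label == 0L])) / s_sd
    rows[[c_i]] <- data.frame(drug_id = mols$drug_id[ord],
                              smiles = mols$smiles[ord],
                              canonical = mols$canonical[ord],
                              ec_family = families[c_i],
                              label = label,
                              stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  intended <- pairs$label
  flip <- runif(nrow(pairs)) < cfg$noise_rate
  pairs$label <- ifelse(flip, 1L - intended, intended)
  rownames(pairs) <- NULL
  pairs <- .as_pair_table(pairs[, c("drug_id", "smiles", "ec_family", "label", "canonical")])
  list(pairs = pairs, descriptors = desc, molecules = mols,
       truth = list(informative = informative, directions = directions,
                    realized_shift = realized, intended_labels = intended,
                    config = cfg))
}

#' Synthetic i.i.d. feature table with planted informative columns
#'
#' For selector unit tests: standard-normal noise columns plus informative
#' columns whose class means differ by `d` standard deviations.
#'
#' @param n rows.
#' @param k_informative,m_noise column counts.
#' @param d standardized class separation on informative columns.
#' @param seed integer seed.
#' @param balance positive-class fraction.
#' @return list `X` (matrix, columns `inf*` then `noise*`), `y`,
#'   `informative` (column names).
#' @export
generate_feature_table <- function(n, k_informative, m_noise, d, seed,
                                   balance = 0.5) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  y <- rbinom(n, 1L, balance)
  X <- matrix(rnorm(n * (k_informative + m_noise)), n)
  colnames(X) <- c(sprintf("inf%02d", seq_len(k_informative)),
                   sprintf("noise%02d", seq_len(m_noise)))
  for (j in seq_len(k_informative)) X[, j] <- X[, j] + d * (y - balance)
  list(X = X, y = y, informative = colnames(X)[seq_len(k_informative)])
}

#' Run the full multi-target QSAR pipeline on synthetic data
#'
#' Generation, curation, 70/30 split, training-only class profiles,
#' forward-stepwise descriptor selection, MLP training and the evaluation
#' battery, end to end. When no candidate passes the entry threshold (the
#' d = 0 null), the selector's verdict is respected: the network is fitted
#' on an intercept-only input and so reproduces the training base rate,
#' which is what a no-signal model should predict.
#'
#' @param cfg a `synth_config`.
#' @param n_hidden hidden units (default 40).
#' @param fraction training fraction.
#' @param max_features stepwise cap (default 13).
#' @param maxit optimizer iteration cap.
#' @return list: `selection`, `selected`, `model`, `profiles`,
#'   `stats_training`, `stats_validation`, `roc` (validation), `per_class`
#'   (validation), `recovery` (fraction of planted informative descriptors
#'   selected), `majority_rate`, `truth`.
#' @export
run_pipeline <- function(cfg, n_hidden = 40L, fraction = 0.70,
                         max_features = 13L, maxit = 300L) {
  gen <- generate_pairs(cfg)
  pairs <- curate_pairs(gen$pairs)
  desc <- gen$descriptors

  tags <- split_dataset(nrow(pairs), fraction, seed = cfg$seed + 2L)
  tr <- pairs[tags == "training", , drop = FALSE]
  va <- pairs[tags == "validation", , drop = FALSE]
  profiles <- build_class_profiles(tr, desc)

  base <- descriptor_names()
  Xtr_all <- featurize_table(tr, desc, profiles, base)
  md_dmd <- as.vector(rbind(paste0(base, "_md"), paste0(base, "_dmd")))
  sel <- forward_stepwise_select(Xtr_all[, md_dmd, drop = FALSE], tr$label,
                                 max_features = max_features,
                                 groups = rep(base, each = 2L))
  selected <- sel$selected
  if (length(selected) > 0L) {
    Xtr <- featurize_table(tr, desc, profiles, selected)
    Xva <- featurize_table(va, desc, profiles, selected)
  } else {
    Xtr <- matrix(0, nrow(tr), 1L, dimnames = list(NULL, "intercept_only"))
    Xva <- matrix(0, nrow(va), 1L, dimnames = list(NULL, "intercept_only"))
  }
  model <- train_mlp(Xtr, tr$label, n_hidden = n_hidden,
                     seed = cfg$seed + 3L, maxit = maxit)
  p_tr <- predict(model, Xtr)[, "interacting"]
  p_va <- predict(model, Xva)[, "interacting"]
  pred_va <- as.integer(p_va > 0.5)
  list(selection = sel, selected = selected, model = model, profiles = profiles,
       stats_training = confusion_stats(as.integer(p_tr > 0.5), tr$label),
       stats_validation = confusion_stats(pred_va, va$label),
       roc = roc_auc(p_va, va$label),
       per_class = per_class_report(pred_va, va$label, va$ec_family),
       recovery = mean(gen$truth$informative %in% sel$selected),
       majority_rate = max(mean(va$label), 1 - mean(va$label)),
       truth = gen$truth)
}
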