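# Build a molecular_graph directly from an atom count and a bond list, so
# graph-level tests do not depend on the SMILES parser.
mg <- function(n, bonds = NULL, symbols = rep("C", n)) {
  b <- if (is.null(bonds) || nrow(bonds) == 0L) {
    data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    data.frame(from = as.integer(bonds[, 1]), to = as.integer(bonds[, 2]),
               order = if (ncol(bonds) >= 3L) as.integer(bonds[, 3]) else 1L)
  }
  structure(list(atoms = data.frame(symbol = symbols, aromatic = FALSE,
                                    stringsAsFactors = FALSE),
                 bonds = b),
            class = "molecular_graph")
}

path_graph <- function(n) {
  if (n == 1L) return(mg(1L))
  mg(n, cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

cycle_graph <- function(n) mg(n, cbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L)))

star_graph <- function(n_leaves) mg(n_leaves + 1L, cbind(1L, seq_len(n_leaves) + 1L))

# random connected graph: random tree plus a few extra edges
random_graph <- function(n_atoms) {
  bonds <- NULL
  if (n_atoms > 1L) {
    parent <- vapply(2:n_atoms, function(i) sample.int(i - 1L, 1L), integer(1))
    bonds <- cbind(parent, 2:n_atoms)
    extra <- sample(0:2, 1L)
    for (e in seq_len(extra)) {
      u <- sample.int(n_atoms, 2L)
      present <- any((bonds[, 1] == min(u) & bonds[, 2] == max(u)) |
                     (bonds[, 1] == max(u) & bonds[, 2] == min(u)))
      if (!present && u[1] != u[2]) bonds <- rbind(bonds, c(min(u), max(u)))
    }
  }
  mg(n_atoms, bonds,
     symbols = sample(c("C", "N", "O"), n_atoms, replace = TRUE, prob = c(.7, .15, .15)))
}

# relabel atoms by a permutation, remapping bonds accordingly
permute_graph <- function(g, perm) {
  inv <- order(perm)   # inv[old index] = new index
  b <- g$bonds
  b$from <- inv[b$from]; b$to <- inv[b$to]
  structure(list(atoms = g$atoms[perm, , drop = FALSE], bonds = b),
            class = "molecular_graph")
}

# Small fitted bundle shared across prediction tests; built once per session.
.tiny_env <- new.env(parent = emptyenv())
tiny_bundle <- function() {
  if (!is.null(.tiny_env$bundle)) return(.tiny_env$bundle)
  cfg <- synth_config(n_classes = 3L, n_drugs = 80L, n_pairs = 180L, seed = 101L)
  gen <- generate_pairs(cfg)
  pairs <- curate_pairs(gen$pairs)
  profiles <- build_class_profiles(pairs, gen$descriptors)
  selected <- c("ring_count", "petitjean", "balaban_j")
  X <- featurize_table(pairs, gen$descriptors, profiles, selected)
  model <- train_mlp(X, pairs$label, n_hidden = 6L, seed = 5L, maxit = 100L)
  path <- tempfile(fileext = ".json")
  save_model(model, profiles, selected, path)
  .tiny_env$bundle <- load_model(path)
  .tiny_env$gen <- gen
  .tiny_env$bundle
}
tiny_gen <- function() { tiny_bundle(); .tiny_env$gen }

write_batch_tsv <- function(rows, path = tempfile(fileext = ".tsv"),
                            header = c("id", "SMILE")) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(seq_len(nrow(rows)), function(i)
                 paste(rows[i, 1], rows[i, 2], sep = "\t"), character(1))),
             path)
  path
}
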