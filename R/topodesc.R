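#' @importFrom igraph graph_from_data_frame distances components degree
NULL

.REGISTRY_VERSION <- "topo-1.0"

#' All-pairs topological distance matrix
#'
#' Entry (i, j) is the minimum number of bonds on a path between atoms i and
#' j (0 on the diagonal). Pairs in different fragments get the sentinel `NA`
#' rather than a numeric infinity, so no descriptor can silently consume an
#' infinite distance.
#'
#' @param g a `molecular_graph`.
#' @return symmetric integer matrix with `NA` marking disconnected pairs.
#' @export
distance_matrix <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L) mtq_stop("format_error", "empty molecular graph")
  ig <- .as_igraph(g)
  d <- igraph::distances(ig)
  d[is.infinite(d)] <- NA
  m <- matrix(as.integer(d), n, n)
  dimnames(m) <- NULL
  m
}

.as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = g$bonds$from, to = g$bonds$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(g$atoms)))
  )
}

# Largest connected fragment plus everything the fast descriptor paths need.
.graph_ctx <- function(g) {
  n_total <- nrow(g$atoms)
  ig <- .as_igraph(g)
  comp <- igraph::components(ig)
  n_frag_total <- comp$no
  if (comp$no > 1L) {
    keep <- which(comp$membership == which.max(comp$csize))
    remap <- match(seq_len(n_total), keep)
    sel <- g$bonds$from %in% keep & g$bonds$to %in% keep
    bonds <- g$bonds[sel, , drop = FALSE]
    bonds$from <- remap[bonds$from]; bonds$to <- remap[bonds$to]
    g <- list(atoms = g$atoms[keep, , drop = FALSE], bonds = bonds)
    class(g) <- "molecular_graph"
    ig <- .as_igraph(g)
  }
  n <- nrow(g$atoms)
  deg <- if (n > 0L) as.integer(igraph::degree(ig)) else integer(0)
  D <- igraph::distances(ig)
  A <- matrix(0L, n, n)
  if (nrow(g$bonds) > 0L) {
    A[cbind(g$bonds$from, g$bonds$to)] <- 1L
    A[cbind(g$bonds$to, g$bonds$from)] <- 1L
  }
  list(g = g, n = n, m = nrow(g$bonds), deg = deg, D = D, A = A,
       multi_fragment = n_frag_total > 1L)
}

# ---- fast descriptor implementations (operate on a .graph_ctx) -------------

.fast <- list(
  heavy_atoms = function(ctx) ctx$n,
  bond_count  = function(ctx) ctx$m,
  ring_count  = function(ctx) ctx$m - ctx$n + 1L,
  wiener      = function(ctx) sum(ctx$D) / 2,
  zagreb_m1   = function(ctx) sum(ctx$deg^2),
  zagreb_m2   = function(ctx) sum(ctx$deg[ctx$g$bonds$from] * ctx$deg[ctx$g$bonds$to]),
  randic      = function(ctx) {
    if (ctx$m == 0L) return(0)
    sum(1 / sqrt(ctx$deg[ctx$g$bonds$from] * ctx$deg[ctx$g$bonds$to]))
  },
  chi0 = function(ctx) sum(1 / sqrt(ctx$deg[ctx$deg > 0L])),
  chi2 = function(ctx) {
    # sum over 2-paths i-j-k of (d_i d_j d_k)^(-1/2)
    tot <- 0
    for (j in seq_len(ctx$n)) {
      nb <- which(ctx$A[j, ] == 1L)
      if (length(nb) < 2L) next
      pr <- utils::combn(nb, 2L)
      tot <- tot + sum(1 / sqrt(ctx$deg[pr[1, ]] * ctx$deg[j] * ctx$deg[pr[2, ]]))
    }
    tot
  },
  kappa1 = function(ctx) {
    if (ctx$m == 0L) return(0)
    ctx$n * (ctx$n - 1)^2 / ctx$m^2
  },
  kappa2 = function(ctx) {
    p2 <- sum(choose(ctx$deg, 2L))
    if (p2 == 0 || ctx$n < 3L) return(0)
    (ctx$n - 1) * (ctx$n - 2)^2 / p2^2
  },
  kappa3 = function(ctx) {
    p3 <- .count_p3(ctx)
    if (p3 == 0 || ctx$n < 4L) return(0)
    if (ctx$n %% 2L == 1L) (ctx$n - 1) * (ctx$n - 3)^2 / p3^2
    else (ctx$n - 3) * (ctx$n - 2)^2 / p3^2
  },
  balaban_j = function(ctx) {
    if (ctx$m == 0L) return(0)
    s <- rowSums(ctx$D)
    mu <- ctx$m - ctx$n + 1L
    (ctx$m / (mu + 1)) *
      sum(1 / sqrt(s[ctx$g$bonds$from] * s[ctx$g$bonds$to]))
  },
  eccentric_connectivity = function(ctx) {
    if (ctx$n == 1L) return(0)
    sum(ctx$deg * apply(ctx$D, 1L, max))
  },
  diameter = function(ctx) if (ctx$n == 1L) 0 else max(ctx$D),
  radius   = function(ctx) if (ctx$n == 1L) 0 else min(apply(ctx$D, 1L, max)),
  petitjean = function(ctx) {
    if (ctx$n == 1L) return(0)
    ecc <- apply(ctx$D, 1L, max)
    r <- min(ecc)
    if (r == 0) 0 else (max(ecc) - r) / r
  }
)

# paths of length 3 (3 edges, 4 distinct vertices):
# sum over edges (u,v) of (d_u - 1)(d_v - 1) minus 3 * triangle count
.count_p3 <- function(ctx) {
  if (ctx$m == 0L) return(0)
  tri <- sum(diag(ctx$A %*% ctx$A %*% ctx$A)) / 6
  sum((ctx$deg[ctx$g$bonds$from] - 1L) * (ctx$deg[ctx$g$bonds$to] - 1L)) - 3 * tri
}

# ---- brute-force oracles (independent of igraph and of the fast paths) -----

# degrees recomputed by scanning the bond list
.o_deg <- function(g) {
  d <- integer(nrow(g$atoms))
  for (b in seq_len(nrow(g$bonds))) {
    d[g$bonds$from[b]] <- d[g$bonds$from[b]] + 1L
    d[g$bonds$to[b]] <- d[g$bonds$to[b]] + 1L
  }
  d
}

# Floyd-Warshall over the full graph; Inf for disconnected pairs
.o_floyd <- function(g) {
  n <- nrow(g$atoms)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (b in seq_len(nrow(g$bonds))) {
    D[g$bonds$from[b], g$bonds$to[b]] <- 1
    D[g$bonds$to[b], g$bonds$from[b]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# largest fragment by flood fill from each seed atom
.o_largest_fragment <- function(g) {
  D <- .o_floyd(g)
  n <- nrow(g$atoms)
  seen <- rep(FALSE, n); best <- integer(0)
  for (i in seq_len(n)) {
    if (seen[i]) next
    memb <- which(is.finite(D[i, ]))
    seen[memb] <- TRUE
    if (length(memb) > length(best)) best <- memb
  }
  remap <- match(seq_len(n), best)
  sel <- g$bonds$from %in% best & g$bonds$to %in% best
  bonds <- g$bonds[sel, , drop = FALSE]
  bonds$from <- remap[bonds$from]; bonds$to <- remap[bonds$to]
  out <- list(atoms = g$atoms[best, , drop = FALSE], bonds = bonds)
  class(out) <- "molecular_graph"
  out
}

.o_adj <- function(g) {
  n <- nrow(g$atoms)
  A <- matrix(FALSE, n, n)
  for (b in seq_len(nrow(g$bonds))) {
    A[g$bonds$from[b], g$bonds$to[b]] <- TRUE
    A[g$bonds$to[b], g$bonds$from[b]] <- TRUE
  }
  A
}

# enumerate simple paths with k edges by depth-first walk; returns count of
# undirected paths (each counted once)
.o_count_paths <- function(g, k) {
  A <- .o_adj(g); n <- nrow(A)
  count <- 0L
  walk <- function(path) {
    if (length(path) == k + 1L) { count <<- count + 1L; return(invisible()) }
    last <- path[length(path)]
    for (nxt in which(A[last, ])) if (!nxt %in% path) walk(c(path, nxt))
  }
  for (s in seq_len(n)) walk(s)
  count / 2
}

.oracle <- list(
  heavy_atoms = function(g) nrow(.o_largest_fragment(g)$atoms),
  bond_count  = function(g) nrow(.o_largest_fragment(g)$bonds),
  ring_count  = function(g) { f <- .o_largest_fragment(g); nrow(f$bonds) - nrow(f$atoms) + 1L },
  wiener = function(g) {
    f <- .o_largest_fragment(g); D <- .o_floyd(f)
    tot <- 0
    n <- nrow(f$atoms)
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) tot <- tot + D[i, j]
    tot
  },
  zagreb_m1 = function(g) { f <- .o_largest_fragment(g); sum(.o_deg(f)^2) },
  zagreb_m2 = function(g) {
    f <- .o_largest_fragment(g); d <- .o_deg(f)
    tot <- 0
    for (b in seq_len(nrow(f$bonds))) tot <- tot + d[f$bonds$from[b]] * d[f$bonds$to[b]]
    tot
  },
  randic = function(g) {
    f <- .o_largest_fragment(g); d <- .o_deg(f)
    tot <- 0
    for (b in seq_len(nrow(f$bonds)))
      tot <- tot + 1 / sqrt(d[f$bonds$from[b]] * d[f$bonds$to[b]])
    tot
  },
  chi0 = function(g) {
    f <- .o_largest_fragment(g); d <- .o_deg(f)
    sum(vapply(d, function(x) if (x > 0L) 1 / sqrt(x) else 0, numeric(1)))
  },
  chi2 = function(g) {
    f <- .o_largest_fragment(g); d <- .o_deg(f); A <- .o_adj(f)
    n <- nrow(A); tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
      if (i < k && j != i && j != k && A[i, j] && A[j, k])
        tot <- tot + 1 / sqrt(d[i] * d[j] * d[k])
    tot
  },
  kappa1 = function(g) {
    f <- .o_largest_fragment(g)
    n <- nrow(f$atoms); m <- .o_count_paths(f, 1L)
    if (m == 0) 0 else n * (n - 1)^2 / m^2
  },
  kappa2 = function(g) {
    f <- .o_largest_fragment(g)
    n <- nrow(f$atoms); p2 <- .o_count_paths(f, 2L)
    if (p2 == 0 || n < 3L) 0 else (n - 1) * (n - 2)^2 / p2^2
  },
  kappa3 = function(g) {
    f <- .o_largest_fragment(g)
    n <- nrow(f$atoms); p3 <- .o_count_paths(f, 3L)
    if (p3 == 0 || n < 4L) 0
    else if (n %% 2L == 1L) (n - 1) * (n - 3)^2 / p3^2
    else (n - 3) * (n - 2)^2 / p3^2
  },
  balaban_j = function(g) {
    f <- .o_largest_fragment(g)
    m <- nrow(f$bonds)
    if (m == 0L) return(0)
    D <- .o_floyd(f)
    s <- rowSums(D)
    mu <- m - nrow(f$atoms) + 1L
    tot <- 0
    for (b in seq_len(m)) tot <- tot + 1 / sqrt(s[f$bonds$from[b]] * s[f$bonds$to[b]])
    m / (mu + 1) * tot
  },
  eccentric_connectivity = function(g) {
    f <- .o_largest_fragment(g)
    if (nrow(f$atoms) == 1L) return(0)
    D <- .o_floyd(f); d <- .o_deg(f)
    sum(d * apply(D, 1L, max))
  },
  diameter = function(g) {
    f <- .o_largest_fragment(g)
    if (nrow(f$atoms) == 1L) 0 else max(.o_floyd(f))
  },
  radius = function(g) {
    f <- .o_largest_fragment(g)
    if (nrow(f$atoms) == 1L) 0 else min(apply(.o_floyd(f), 1L, max))
  },
  petitjean = function(g) {
    f <- .o_largest_fragment(g)
    if (nrow(f$atoms) == 1L) return(0)
    ecc <- apply(.o_floyd(f), 1L, max)
    if (min(ecc) == 0) 0 else (max(ecc) - min(ecc)) / min(ecc)
  }
)

#' The topological descriptor registry
#'
#' An ordered, version-stamped set of 17 classic topological descriptors:
#' heavy-atom and bond counts, cyclomatic ring count, Wiener index, first and
#' second Zagreb indices, Randic connectivity (the order-1 chi path index),
#' Kier-Hall chi path indices of orders 0 and 2 (simple vertex-degree
#' variants), Kier kappa shape indices 1-3, Balaban J, eccentric
#' connectivity, graph diameter, radius and the Petitjean shape index.
#' Multi-fragment molecules are reduced to their largest fragment before any
#' descriptor is computed.
#'
#' @return list with `version` and `names` (registry order).
#' @export
descriptor_registry <- function() {
  list(version = .REGISTRY_VERSION, names = names(.fast))
}

#' Names of the registered descriptors, in registry order
#' @return character vector.
#' @export
descriptor_names <- function() names(.fast)

#' Compute all registered descriptors for one molecule
#'
#' @param g a `molecular_graph` (see [parse_smiles()]).
#' @return named numeric vector in registry order, with attributes
#'   `version` and `multi_fragment` (TRUE when the molecule had several
#'   fragments and was reduced to the largest).
#' @examples
#' compute_descriptors(parse_smiles("CCCC"))[["wiener"]]  # 10
#' @export
compute_descriptors <- function(g) {
  ctx <- .graph_ctx(g)
  v <- vapply(.fast, function(f) as.numeric(f(ctx)), numeric(1))
  stopifnot(all(is.finite(v)))
  structure(v, version = .REGISTRY_VERSION, multi_fragment = ctx$multi_fragment)
}

#' Descriptor table for many molecules
#'
#' @param smiles character vector of SMILES, or a list of `molecular_graph`s.
#' @param ids row names (defaults to names of `smiles` or an index).
#' @return numeric matrix, one row per molecule, columns in registry order;
#'   attribute `version` carries the registry stamp.
#' @export
compute_descriptor_table <- function(smiles, ids = NULL) {
  graphs <- if (is.character(smiles)) lapply(smiles, parse_smiles) else smiles
  X <- t(vapply(graphs, function(g) as.numeric(compute_descriptors(g)),
                numeric(length(.fast))))
  colnames(X) <- names(.fast)
  rownames(X) <- ids %||% names(smiles) %||% as.character(seq_along(graphs))
  structure(X, version = .REGISTRY_VERSION)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare the fast and brute-force value of one descriptor
#'
#' The oracle route recomputes the descriptor from first principles
#' (Floyd-Warshall distances, explicit path enumeration, degree counts from
#' the bond list) with no shared code with the fast route.
#'
#' @param g a `molecular_graph`.
#' @param name registered descriptor name.
#' @return named numeric vector `c(fast = , oracle = )`.
#' @export
oracle_check <- function(g, name) {
  if (!name %in% names(.fast))
    mtq_stop("unknown_descriptor_error", sprintf("unknown descriptor '%s'", name))
  c(fast = as.numeric(.fast[[name]](.graph_ctx(g))),
    oracle = as.numeric(.oracle[[name]](g)))
}
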