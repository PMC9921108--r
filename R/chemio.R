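#' @importFrom utils read.delim write.table head
NULL

# Organic-subset atom tokens legal outside brackets, longest first.
.smiles_organic <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I",
                     "b", "c", "n", "o", "p", "s")

#' Validate a SMILES string without building a molecule
#'
#' Lexical and structural checks: legal tokens only, balanced parentheses,
#' no empty branches, every ring-bond digit opened and closed. The underlying
#' Open Babel parser silently repairs some malformed inputs (an unbalanced
#' parenthesis, for instance), so this check runs first and is what gives
#' [parse_smiles()] its strict failure contract.
#'
#' @param text SMILES string.
#' @return `TRUE` invisibly, or signals `malformed_smiles_error`.
#' @export
validate_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    mtq_stop("malformed_smiles_error", "SMILES must be a single character string")
  s <- trimws(text)
  if (!nzchar(s))
    mtq_stop("malformed_smiles_error", "empty SMILES string")

  depth <- 0L
  rings <- integer(0)        # open ring-closure labels
  i <- 1L; n <- nchar(s)
  prev_open <- FALSE
  saw_atom <- FALSE
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0)
        mtq_stop("malformed_smiles_error", sprintf("unclosed bracket atom in '%s'", s))
      if (j == 2)
        mtq_stop("malformed_smiles_error", sprintf("empty bracket atom in '%s'", s))
      saw_atom <- TRUE; prev_open <- FALSE
      i <- i + j
    } else if (ch == "(") {
      if (!saw_atom)
        mtq_stop("malformed_smiles_error", sprintf("branch before any atom in '%s'", s))
      depth <- depth + 1L; prev_open <- TRUE; i <- i + 1L
    } else if (ch == ")") {
      if (prev_open)
        mtq_stop("malformed_smiles_error", sprintf("empty branch in '%s'", s))
      depth <- depth - 1L
      if (depth < 0L)
        mtq_stop("malformed_smiles_error", sprintf("unbalanced ')' in '%s'", s))
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\", ".")) {
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      lab <- as.integer(ch)
      rings <- if (lab %in% rings) setdiff(rings, lab) else c(rings, lab)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(s, i + 1L, i + 2L)))
        mtq_stop("malformed_smiles_error", sprintf("bad %% ring closure in '%s'", s))
      lab <- as.integer(substr(s, i + 1L, i + 2L))
      rings <- if (lab %in% rings) setdiff(rings, lab) else c(rings, lab)
      i <- i + 3L
    } else {
      tok <- .smiles_organic[startsWith(substr(s, i, n), .smiles_organic)]
      if (length(tok) == 0L)
        mtq_stop("malformed_smiles_error",
                 sprintf("illegal token '%s' at position %d in '%s'", ch, i, s))
      saw_atom <- TRUE; prev_open <- FALSE
      i <- i + nchar(tok[1L])
    }
  }
  if (depth != 0L)
    mtq_stop("malformed_smiles_error", sprintf("unbalanced '(' in '%s'", s))
  if (length(rings) > 0L)
    mtq_stop("malformed_smiles_error",
             sprintf("unclosed ring bond(s) %s in '%s'",
                     paste(rings, collapse = ","), s))
  if (!saw_atom)
    mtq_stop("malformed_smiles_error", sprintf("no atoms in '%s'", s))
  invisible(TRUE)
}

#' Parse a SMILES string into a hydrogen-suppressed molecular graph
#'
#' Parsing (including aromatic perception and kekulization) is delegated to
#' Open Babel through \pkg{ChemmineR}; explicit hydrogens are removed so the
#' result is the heavy-atom skeleton on which topological descriptors are
#' defined.
#'
#' @param text SMILES string.
#' @return A `molecular_graph`: list with `atoms` (data.frame: `symbol`,
#'   `aromatic`) and `bonds` (data.frame: `from`, `to`, `order`; undirected,
#'   1-based contiguous atom indices, no self-loops or duplicates).
#' @examples
#' g <- parse_smiles("CCO")
#' nrow(g$atoms)  # 3 heavy atoms
#' @export
parse_smiles <- function(text) {
  validate_smiles(text)
  s <- trimws(text)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, "mol"))),
    error = function(e)
      mtq_stop("malformed_smiles_error",
               sprintf("parser rejected SMILES '%s': %s", s, conditionMessage(e)))
  )
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L)
    mtq_stop("malformed_smiles_error", sprintf("parser produced no atoms for '%s'", s))
  symbols <- sub("_[0-9]+$", "", rownames(ab))
  bb <- ChemmineR::bondblock(mol)
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  # hydrogen suppression (explicit H can appear via bracket atoms)
  heavy <- which(symbols != "H")
  if (length(heavy) < length(symbols)) {
    remap <- match(seq_along(symbols), heavy)
    keep <- bonds$from %in% heavy & bonds$to %in% heavy
    bonds <- bonds[keep, , drop = FALSE]
    bonds$from <- remap[bonds$from]; bonds$to <- remap[bonds$to]
    symbols <- symbols[heavy]
  }
  aromatic <- .aromatic_flags(s, symbols)
  g <- list(
    atoms = data.frame(symbol = symbols, aromatic = aromatic,
                       stringsAsFactors = FALSE),
    bonds = bonds
  )
  class(g) <- "molecular_graph"
  g
}

# Mark atoms written with lowercase aromatic tokens; SMILES token order
# matches Open Babel's heavy-atom order for inputs without explicit H.
.aromatic_flags <- function(s, symbols) {
  flags <- logical(length(symbols))
  toks <- character(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      inner <- substr(s, i + 1L, i + j - 2L)
      toks <- c(toks, if (grepl("^[a-z]", inner)) "arom" else "plain")
      i <- i + j
    } else if (ch == "%") {
      i <- i + 3L
    } else {
      tok <- .smiles_organic[startsWith(substr(s, i, n), .smiles_organic)]
      if (length(tok) > 0L) {
        toks <- c(toks, if (grepl("^[a-z]", tok[1L])) "arom" else "plain")
        i <- i + nchar(tok[1L])
      } else i <- i + 1L
    }
  }
  if (length(toks) == length(symbols)) flags <- toks == "arom"
  flags
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %d atoms, %d bonds (%s)\n",
              nrow(x$atoms), nrow(x$bonds),
              paste(x$atoms$symbol, collapse = "")))
  invisible(x)
}

#' Read a batch of SMILES from a tab-separated file
#'
#' The file must carry the `.txt` or `.tsv` extension and a header naming an
#' id column and a SMILES column (`id` and `SMILE`; `SMILES` also accepted,
#' case-insensitive). At most `cap` data rows are retained; longer files are
#' truncated with a warning, since the batch predictor analyses only the
#' first 100 compounds.
#'
#' @param path input file path.
#' @param cap maximum number of data rows retained (default 100).
#' @param force_format if `TRUE`, accept any file extension.
#' @return A `smiles_batch`: data.frame with columns `row_id`, `smiles`, in
#'   file order; attribute `warnings` collects truncation/empty notices.
#' @export
read_smiles_batch <- function(path, cap = 100L, force_format = FALSE) {
  if (!file.exists(path))
    mtq_stop("format_error", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (!force_format && !ext %in% c("txt", "tsv"))
    mtq_stop("format_error",
             sprintf("expected a .txt or .tsv file, got '.%s' (use force_format to override)", ext))
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  warns <- character(0)
  id_col <- grep("^id$", names(df), ignore.case = TRUE)
  smi_col <- grep("^smiles?$", names(df), ignore.case = TRUE)
  if (length(id_col) == 0L || length(smi_col) == 0L)
    mtq_stop("format_error",
             sprintf("header must name an 'id' and a 'SMILE' column; found: %s",
                     paste(names(df), collapse = ", ")))
  if (nrow(df) == 0L) {
    warns <- c(warns, "empty batch file")
    warning("empty batch file: ", path)
  }
  if (nrow(df) > cap) {
    warns <- c(warns,
               sprintf("input has %d rows; only the first %d will be analyzed",
                       nrow(df), cap))
    warning(sprintf("only the first %d of %d SMILES rows will be analyzed", cap, nrow(df)))
    df <- df[seq_len(cap), , drop = FALSE]
  }
  out <- data.frame(row_id = df[[id_col[1L]]], smiles = df[[smi_col[1L]]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, warnings = warns, source = path,
            class = c("smiles_batch", "data.frame"))
}

#' Read a drug-enzyme pair table
#'
#' Loads a delimited table of (drug, enzyme subclass, interaction label)
#' observations — the format of curated interaction exports and of the
#' synthetic generator. Column names are mapped via `col_map`; label
#' encodings are normalized via `positive`/`negative`.
#'
#' @param path TSV (`.tsv`/`.txt`, tab) or CSV (`.csv`, comma) file.
#' @param col_map named character vector mapping the roles `drug_id`,
#'   `smiles`, `ec_family`, `label` to column names in the file.
#' @param positive,negative label encodings mapped to interacting (1) and
#'   non-interacting (0); matching is case-insensitive.
#' @return A `pair_table`: data.frame with columns `drug_id`, `smiles`,
#'   `ec_family`, `label` (integer 0/1). Rows whose `ec_family` does not
#'   match the dotted `digits.digits` pattern are dropped and collected in
#'   attribute `row_errors`.
#' @export
read_pair_table <- function(path,
                            col_map = c(drug_id = "drug_id", smiles = "smiles",
                                        ec_family = "ec_family", label = "label"),
                            positive = c("1", "active", "interacting", "true"),
                            negative = c("0", "inactive", "non-interacting", "false")) {
  if (!file.exists(path))
    mtq_stop("format_error", sprintf("file not found: %s", path))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  need <- c("drug_id", "smiles", "ec_family", "label")
  miss <- setdiff(need, names(col_map))
  if (length(miss) > 0L)
    mtq_stop("format_error", sprintf("col_map lacks roles: %s", paste(miss, collapse = ", ")))
  absent <- setdiff(unname(col_map[need]), names(df))
  if (length(absent) > 0L)
    mtq_stop("format_error",
             sprintf("cannot map columns %s onto file header (%s)",
                     paste(absent, collapse = ", "), paste(names(df), collapse = ", ")))
  if (nrow(df) == 0L) {
    warning("empty pair table: ", path)
    return(.as_pair_table(data.frame(drug_id = character(0), smiles = character(0),
                                     ec_family = character(0), label = integer(0))))
  }
  out <- data.frame(drug_id = df[[col_map[["drug_id"]]]],
                    smiles = df[[col_map[["smiles"]]]],
                    ec_family = df[[col_map[["ec_family"]]]],
                    label_raw = tolower(trimws(df[[col_map[["label"]]]])),
                    stringsAsFactors = FALSE)
  lab <- ifelse(out$label_raw %in% tolower(positive), 1L,
                ifelse(out$label_raw %in% tolower(negative), 0L, NA_integer_))
  if (anyNA(lab))
    mtq_stop("format_error",
             sprintf("unrecognized label value(s): %s",
                     paste(unique(out$label_raw[is.na(lab)]), collapse = ", ")))
  out$label <- lab
  out$label_raw <- NULL

  bad_ec <- !grepl("^[0-9]+\\.[0-9]+$", out$ec_family)
  row_errors <- data.frame(row = which(bad_ec),
                           ec_family = out$ec_family[bad_ec],
                           reason = rep("invalid EC subclass pattern", sum(bad_ec)),
                           stringsAsFactors = FALSE)
  if (any(bad_ec)) {
    warning(sprintf("%d row(s) dropped: invalid EC subclass pattern", sum(bad_ec)))
    out <- out[!bad_ec, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(.as_pair_table(out), row_errors = row_errors)
}

.as_pair_table <- function(df) {
  class(df) <- c("pair_table", "data.frame")
  df
}

#' Canonicalize SMILES for deduplication
#'
#' Keeps the largest dot-separated fragment (salt stripping), neutralizes
#' common single-atom charges, then asks Open Babel for the canonical form.
#' Unparsable input yields `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, `NA` where malformed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    ok <- tryCatch({ validate_smiles(s); TRUE },
                   malformed_smiles_error = function(e) FALSE)
    if (!ok) return(NA_character_)
    frags <- strsplit(trimws(s), ".", fixed = TRUE)[[1]]
    frag <- frags[which.max(nchar(frags))]
    # neutralize simple charged bracket atoms: [O-] -> O, [NH3+] -> N
    frag <- gsub("\\[(Cl|Br|[BCNOPSFI])H?[0-9]?[+-]\\]", "\\1", frag)
    can <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", frag),
      error = function(e) NA_character_
    )
    if (is.na(can)) return(NA_character_)
    can <- strsplit(can, "[\t\n]")[[1]][1]
    if (!nzchar(can)) NA_character_ else can
  }, character(1), USE.NAMES = FALSE)
}

#' Curate a pair table
#'
#' Applies the dataset curation rules: alternative forms of the same compound
#' (identical canonical SMILES) interacting with the same enzyme subclass are
#' collapsed to a single record, while the same compound under different
#' subclasses is retained — the multi-target structure of the data. Records
#' whose SMILES cannot be parsed are dropped (count reported in attribute
#' `n_malformed_dropped`). Contradictory labels for one (compound, subclass)
#' key indicate corrupt input and raise `conflict_error`.
#'
#' @param pairs a `pair_table` (see [read_pair_table()]).
#' @return Curated `pair_table` with an added `canonical` column; idempotent.
#' @export
curate_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) {
    pairs$canonical <- character(0)
    return(.as_pair_table(pairs))
  }
  can <- if (!is.null(pairs$canonical)) {
    pairs$canonical
  } else {
    u <- unique(pairs$smiles)
    canonical_smiles(u)[match(pairs$smiles, u)]
  }
  dropped <- sum(is.na(can))
  keep <- !is.na(can)
  df <- pairs[keep, , drop = FALSE]
  df$canonical <- can[keep]

  key <- paste(df$canonical, df$ec_family, sep = "\r")
  n_labels <- tapply(df$label, key, function(x) length(unique(x)))
  conflicts <- names(n_labels)[n_labels > 1L]
  if (length(conflicts) > 0L)
    mtq_stop("conflict_error",
             sprintf("conflicting interaction labels for %d (compound, subclass) key(s): %s",
                     length(conflicts),
                     paste(gsub("\r", " / ", head(conflicts, 5L)), collapse = "; ")),
             keys = gsub("\r", " / ", conflicts))
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  structure(.as_pair_table(df), n_malformed_dropped = dropped)
}
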