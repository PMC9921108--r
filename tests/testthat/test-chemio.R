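test_that("parse_smiles builds the heavy-atom skeleton", {
  g <- parse_smiles("CCO")
  expect_s3_class(g, "molecular_graph")
  expect_equal(nrow(g$atoms), 3L)
  expect_equal(nrow(g$bonds), 2L)
  expect_setequal(g$atoms$symbol, c("C", "O"))

  ring <- parse_smiles("C1CC1")
  expect_equal(nrow(ring$atoms), 3L)
  expect_equal(nrow(ring$bonds), 3L)

  benz <- parse_smiles("c1ccccc1")
  expect_equal(nrow(benz$atoms), 6L)
  expect_equal(nrow(benz$bonds), 6L)
  expect_true(all(benz$atoms$aromatic))
})

test_that("parse_smiles and validate_smiles reject malformed input", {
  for (bad in c("C(C", "CC)", "C1CC", "C()C", "XX##", "", "  ", "%1C", "[")) {
    expect_error(parse_smiles(bad), class = "malformed_smiles_error")
  }
  expect_true(validate_smiles("CC(=O)Oc1ccccc1C(=O)O"))
})

test_that("molecular graphs satisfy structural invariants", {
  for (s in c("CCO", "C1CCCCC1", "CC(C)(C)C", "N1CCOCC1", "O=C(O)CC")) {
    g <- parse_smiles(s)
    expect_true(all(g$bonds$from >= 1 & g$bonds$from <= nrow(g$atoms)))
    expect_true(all(g$bonds$to >= 1 & g$bonds$to <= nrow(g$atoms)))
    expect_true(all(g$bonds$from != g$bonds$to))
    key <- paste(pmin(g$bonds$from, g$bonds$to), pmax(g$bonds$from, g$bonds$to))
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("read_smiles_batch preserves order, caps rows and checks format", {
  p <- write_batch_tsv(cbind(paste0("m", 1:3), c("CCO", "CCC", "CCN")))
  b <- read_smiles_batch(p)
  expect_equal(b$row_id, paste0("m", 1:3))
  expect_equal(b$smiles, c("CCO", "CCC", "CCN"))

  big <- write_batch_tsv(cbind(paste0("m", 1:150), rep("CCO", 150)))
  expect_warning(b150 <- read_smiles_batch(big), "first 100")
  expect_equal(nrow(b150), 100L)
  expect_equal(b150$row_id, paste0("m", 1:100))
  expect_match(attr(b150, "warnings"), "100", all = FALSE)

  noid <- tempfile(fileext = ".tsv")
  writeLines(c("name\tSMILE", "a\tCCO"), noid)
  expect_error(read_smiles_batch(noid), class = "format_error")

  csv <- tempfile(fileext = ".csv")
  writeLines(c("id\tSMILE", "a\tCCO"), csv)
  expect_error(read_smiles_batch(csv), class = "format_error")
  expect_equal(nrow(read_smiles_batch(csv, force_format = TRUE)), 1L)

  empty <- tempfile(fileext = ".tsv")
  writeLines("id\tSMILE", empty)
  expect_warning(be <- read_smiles_batch(empty), "empty")
  expect_equal(nrow(be), 0L)
})

test_that("read_pair_table maps columns, normalizes labels and collects row errors", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tsmiles\tec_family\tlabel",
               "d1\tCCO\t1.1\t1", "d2\tCCC\t2.7\tactive",
               "d3\tCCN\tabc\t0", "d4\tCCCC\t3.2\tinactive"), p)
  expect_warning(tab <- read_pair_table(p), "invalid EC")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$label, c(1L, 1L, 0L))
  expect_equal(nrow(attr(tab, "row_errors")), 1L)
  expect_equal(attr(tab, "row_errors")$ec_family, "abc")

  # configurable column mapping, CSV dialect
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("compound,structure,family,interacts",
               "d1,CCO,1.1,true", "d2,CCC,7.2,false"), p2)
  tab2 <- read_pair_table(p2, col_map = c(drug_id = "compound", smiles = "structure",
                                          ec_family = "family", label = "interacts"))
  expect_equal(tab2$label, c(1L, 0L))

  expect_error(read_pair_table(p2), class = "format_error")
})

test_that("curate_pairs collapses duplicates but keeps cross-subclass records", {
  tab <- structure(data.frame(
    drug_id = c("a", "b", "c", "d", "e"),
    smiles = c("OCC", "C(O)C", "CCO", "CCN", "C(C"),   # first three are ethanol
    ec_family = c("1.1", "1.1", "3.2", "1.1", "2.7"),
    label = c(1L, 1L, 1L, 0L, 1L),
    stringsAsFactors = FALSE), class = c("pair_table", "data.frame"))
  cur <- curate_pairs(tab)
  # ethanol under 1.1 collapsed to one record; ethanol under 3.2 kept
  expect_equal(nrow(cur), 3L)
  expect_equal(sum(cur$canonical == "CCO"), 2L)
  expect_equal(attr(cur, "n_malformed_dropped"), 1L)

  # idempotent
  cur2 <- curate_pairs(cur)
  for (col in c("drug_id", "canonical", "ec_family", "label"))
    expect_identical(cur2[[col]], cur[[col]])

  # conflicting labels for one (compound, subclass) key abort
  bad <- structure(data.frame(
    drug_id = c("a", "b"), smiles = c("OCC", "CCO"),
    ec_family = c("1.1", "1.1"), label = c(1L, 0L),
    stringsAsFactors = FALSE), class = c("pair_table", "data.frame"))
  expect_error(curate_pairs(bad), class = "conflict_error")

  # empty input passes through
  empty <- structure(data.frame(drug_id = character(0), smiles = character(0),
                                ec_family = character(0), label = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("pair_table", "data.frame"))
  expect_equal(nrow(curate_pairs(empty)), 0L)
})

test_that("canonical_smiles strips salts and is idempotent", {
  can <- canonical_smiles(c("OCC", "C(O)C", "CCO.Cl", "C(C"))
  expect_equal(can[1], can[2])
  expect_equal(can[3], can[1])       # largest fragment is ethanol
  expect_true(is.na(can[4]))
  expect_equal(canonical_smiles(can[1]), can[1])
})
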