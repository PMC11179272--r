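test_that("the demo knowledge base is deterministic and file-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  build_demo_kb(42, dir = d1)
  build_demo_kb(42, dir = d2)
  for (f in c("compounds.tsv", "reactions.tsv", "schema.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("the demo fixtures load back and cached vectors match recomputation", {
  dir <- withr::local_tempdir()
  kb0 <- build_demo_kb(42, dir = dir)
  kb <- suppressMessages(load_kb(dir))
  expect_identical(kb$vectors, kb0$vectors)
  sch <- kb$schema
  for (r in seq_len(nrow(kb$compounds))) {
    v <- featurize(parse_structure(kb$compounds$smiles[r]), sch)
    expect_equal(unname(kb$vectors[kb$compounds$id[r], ]),
                 unname(as.integer(v)), info = kb$compounds$id[r])
  }
})

test_that("the demo KB holds the four core enzyme pairs and enough decoys", {
  kb <- build_demo_kb(42)
  core <- kb$reactions[kb$reactions$source == "core", ]
  expect_setequal(core$ec, c("1.14.14.36", "1.2.3.1", "4.1.1.28", "1.4.3.4"))
  expect_equal(nrow(core), 4L)
  expect_gte(sum(kb$compounds$source == "decoy"), 10L)
  expect_gte(sum(kb$reactions$source == "decoy"), 5L)
  # the holdout aldoxime structure is present but not searchable
  expect_true("X00001" %in% kb$compounds$id)
  expect_false("X00001" %in% pathminer:::kb_searchable_ids(kb))
})

test_that("no decoy delta equals the case-study query delta", {
  kb <- build_demo_kb(42)
  d <- query_delta(kb, "C00355", "C04043")
  decoy_pairs <- kb$reactions$pair_id[kb$reactions$source == "decoy"]
  feats <- unique(kb$members$feature_id[kb$members$pair_id %in% decoy_pairs])
  for (f in feats) {
    expect_false(all(kb$deltas[f, ] == d), info = f)
  }
})

test_that("delta vectors are consistent with compound featurization", {
  kb <- build_demo_kb(42)
  for (r in seq_len(nrow(kb$reactions))) {
    rx <- kb$reactions[r, ]
    fid <- kb$members$feature_id[kb$members$pair_id == rx$pair_id &
                                   kb$members$direction == "forward"]
    expect_equal(kb$vectors[rx$substrate_id, ] + kb$deltas[fid, ],
                 kb$vectors[rx$product_id, ], info = rx$pair_id)
  }
})

test_that("reversible pairs get exact negated reverse deltas", {
  sch <- feature_schema()
  idx <- suppressMessages(pathminer:::compound_index(data.frame(
    id = c("A", "B"), name = c("ethanol", "acetaldehyde"),
    smiles = c("CCO", "CC=O"), stringsAsFactors = FALSE), sch))
  rset <- pathminer:::reaction_set(data.frame(
    pair_id = "R1", ec = "1.1.1.1", substrate_id = "A", product_id = "B",
    reversible = TRUE, stringsAsFactors = FALSE), idx)
  expect_equal(nrow(rset$members), 2L)
  fwd <- rset$deltas[rset$members$feature_id[1], ]
  rev <- rset$deltas[rset$members$feature_id[2], ]
  expect_equal(rev, -fwd)
  # an identity pair has an all-zero delta
  rset0 <- pathminer:::reaction_set(data.frame(
    pair_id = "R0", ec = "5.1.1.1", substrate_id = "A", product_id = "A",
    reversible = FALSE, stringsAsFactors = FALSE), idx)
  expect_true(all(rset0$deltas == 0L))
})

test_that("loader errors name the offending rows and ids", {
  sch <- feature_schema()
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "compounds.tsv")

  writeLines(c("id\tname\tsmiles", "C00355\tL-DOPA\tNC(Cc1ccc(O)c(O)c1)C(O)=O",
               "C00355\tdup\tO"), tsv)
  expect_error(load_compounds(tsv, sch), "duplicate compound id.*C00355")

  writeLines(c("id\tname\tsmiles", "OK\twater\tO", "BAD\tbroken\tC1CC"), tsv)
  expect_error(load_compounds(tsv, sch), "row 2 \\(id BAD\\)")

  writeLines("id\tname\tsmiles", tsv)
  expect_warning(idx <- load_compounds(tsv, sch), "empty")
  expect_equal(nrow(idx$compounds), 0L)

  writeLines(c("id\tname\tsmiles", "A\twater\tO", "B\tmethane\tC"), tsv)
  idx <- suppressMessages(load_compounds(tsv, sch))
  expect_equal(nrow(idx$compounds), 2L)
  rtsv <- file.path(dir, "reactions.tsv")
  writeLines(c("pair_id\tec\tsubstrate_id\tproduct_id\treversible",
               "R1\t1.1.1.1\tA\tC99999\tFALSE"), rtsv)
  expect_error(load_reaction_pairs(rtsv, idx), "unknown compound id.*R1")
  writeLines(c("pair_id\tec\tsubstrate_id\tproduct_id\treversible",
               "R1\tnot-an-ec\tA\tB\tFALSE"), rtsv)
  expect_error(load_reaction_pairs(rtsv, idx), "malformed EC")
})

test_that("EC wildcards are accepted", {
  sch <- feature_schema()
  idx <- suppressMessages(pathminer:::compound_index(data.frame(
    id = c("A", "B"), name = c("a", "b"), smiles = c("CCO", "CC=O"),
    stringsAsFactors = FALSE), sch))
  rset <- pathminer:::reaction_set(data.frame(
    pair_id = "R1", ec = "1.14.13.-", substrate_id = "A", product_id = "B",
    reversible = FALSE, stringsAsFactors = FALSE), idx)
  expect_equal(rset$members$ec, "1.14.13.-")
})
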