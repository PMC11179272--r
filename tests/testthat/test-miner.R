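kb <- build_demo_kb(42)

feature_ecs <- function(kb, sol) {
  sort(unique(kb$members$ec[kb$members$feature_id %in% names(sol)]))
}

test_that("the query delta is the hand-counted composite transformation", {
  d <- query_delta(kb, "C00355", "C04043")
  # C9H11NO4 -> C8H8O3: lose one secondary carbon, the nitrogen, one
  # oxygen and three hydrogens (deamination + decarboxylation composite)
  expect_equal(d[["C.2"]], -1L)
  expect_equal(d[["N"]], -1L)
  expect_equal(d[["O"]], -1L)
  expect_equal(d[["H"]], -3L)
  atom_keys <- !grepl(":", names(d))
  expect_equal(sum(d[atom_keys]), -6L)  # net atom change incl. H
  expect_true(all(query_delta(kb, "C00355", "C00355") == 0L))
  expect_equal(query_delta(kb, "C00355", "C04043"),
               -query_delta(kb, "C04043", "C00355"))
  expect_error(query_delta(kb, "NOPE", "C04043"), "not in knowledge base")
})

test_that("the combination search finds both two-step routes", {
  d <- query_delta(kb, "C00355", "C04043")
  sols <- find_combinations(kb, d, k_max = 2L, exhaustive = TRUE)
  ecs <- lapply(sols, feature_ecs, kb = kb)
  expect_true(any(vapply(ecs, function(e) {
    all(c("1.14.14.36", "1.2.3.1") %in% e)
  }, logical(1))))
  expect_true(any(vapply(ecs, function(e) {
    all(c("4.1.1.28", "1.4.3.4") %in% e)
  }, logical(1))))
  # every solution satisfies the exact vector-sum constraint
  for (sol in sols) {
    total <- colSums(kb$deltas[names(sol), , drop = FALSE] * as.integer(sol))
    expect_equal(unname(total), unname(as.integer(d)))
    expect_lte(sum(sol), 2L)
  }
})

test_that("a zero query delta yields only the empty solution when allowed", {
  d0 <- query_delta(kb, "C00355", "C00355")
  expect_length(find_combinations(kb, d0, exhaustive = TRUE), 0L)
  sols <- find_combinations(kb, d0, exhaustive = TRUE, allow_empty = TRUE)
  expect_equal(sols, list(setNames(integer(0), character(0))[0]),
               ignore_attr = TRUE)
  expect_length(sols, 1L)
  expect_length(sols[[1]], 0L)
})

test_that("exhaustive enumeration matches the brute-force oracle", {
  for (seed in 1:12) {
    inst <- random_delta_instance(seed, m = 25L, p = 6L)
    skb <- synthetic_delta_kb(inst$D)
    sols <- find_combinations(skb, inst$d, k_max = 3L, exhaustive = TRUE)
    expect_identical(solution_keys(sols),
                     brute_force_solutions(inst$D, inst$d, k_max = 3L),
                     info = paste("seed", seed))
  }
})

test_that("multiplicity caps above one are honored and oracle-consistent", {
  inst <- random_delta_instance(4L, m = 10L, p = 5L)
  skb <- synthetic_delta_kb(inst$D)
  d2 <- 2L * inst$D[3, ]
  sols <- find_combinations(skb, d2, k_max = 3L, c_max = 2L,
                            exhaustive = TRUE)
  expect_identical(solution_keys(sols),
                   brute_force_solutions(inst$D, d2, k_max = 3L, c_max = 2L))
  expect_true(any(vapply(sols, function(s) any(s == 2L), logical(1))))
})

test_that("random subsampling returns a subset of the exhaustive solutions", {
  d <- query_delta(kb, "C00355", "C04043")
  full <- solution_keys(find_combinations(kb, d, exhaustive = TRUE))
  sub <- find_combinations(kb, d, iterations = 50L, subset_size = 4L,
                           seed = 7L)
  expect_true(all(solution_keys(sub) %in% full))
  # and with a subset size covering the whole index it recovers everything
  all_in <- find_combinations(kb, d, iterations = 5L,
                              subset_size = nrow(kb$deltas), seed = 7L)
  expect_identical(solution_keys(all_in), full)
})

test_that("adding decoys never removes an exhaustive solution", {
  kb_plain <- build_demo_kb(42, decoys = FALSE)
  d <- query_delta(kb_plain, "C00355", "C04043")
  plain <- solution_keys(find_combinations(kb_plain, d, exhaustive = TRUE))
  with_decoys <- find_combinations(kb, query_delta(kb, "C00355", "C04043"),
                                   exhaustive = TRUE)
  # compare by EC content (feature ids are KB-specific)
  plain_ecs <- lapply(find_combinations(kb_plain, d, exhaustive = TRUE),
                      feature_ecs, kb = kb_plain)
  rich_ecs <- lapply(with_decoys, feature_ecs, kb = kb)
  for (e in plain_ecs) {
    expect_true(any(vapply(rich_ecs, function(x) all(e %in% x), logical(1))),
                info = paste(e, collapse = "+"))
  }
  expect_length(plain, 2L)
})

test_that("ordering keeps only admissible step sequences", {
  d <- query_delta(kb, "C00355", "C04043")
  sols <- find_combinations(kb, d, exhaustive = TRUE)
  ecs <- lapply(sols, feature_ecs, kb = kb)
  oxime_sol <- sols[[which(vapply(ecs, function(e) {
    all(c("1.14.14.36", "1.2.3.1") %in% e)
  }, logical(1)))[1]]]
  cands <- order_and_match(kb, oxime_sol, "C00355", "C04043")
  # only the monooxygenase-first order is admissible: applying the
  # oxime-removal delta to L-DOPA first would need a C=N bond it lacks
  expect_length(cands, 1L)
  first_ec <- kb$members$ec[kb$members$feature_id ==
                              cands[[1]]$order[1]][1]
  expect_equal(first_ec, "1.14.14.36")
  # the reversed order is pruned because an intermediate count goes negative
  rev_delta <- kb$deltas[cands[[1]]$order[2], ]
  expect_true(any(kb$vectors["C00355", ] + rev_delta < 0L))
  # its putative intermediate vector equals the held-out aldoxime structure
  expect_equal(cands[[1]]$steps[[1]]$to, kb$vectors["X00001", ])
  expect_length(cands[[1]]$steps[[1]]$matched_ids, 0L)
})

test_that("single-step solutions admit exactly one ordering", {
  d1 <- query_delta(kb, "C00355", "C03758")
  sols <- find_combinations(kb, d1, k_max = 1L, exhaustive = TRUE)
  expect_length(sols, 1L)
  cands <- order_and_match(kb, sols[[1]], "C00355", "C03758")
  expect_length(cands, 1L)
  expect_length(cands[[1]]$steps, 1L)
})

test_that("exact known steps score 1 and analog steps score below 1", {
  res <- mine(kb, "C00355", "C04043", exhaustive = TRUE)
  df <- as.data.frame(res)
  exact <- which(df$ecs == "4.1.1.28 > 1.4.3.4")
  expect_equal(res$pathways[[exact]]$score, 1.0)
  expect_true(all(res$pathways[[exact]]$steps$step_score == 1.0))
  oxi <- which(df$ecs == "1.14.14.36 > 1.2.3.1")
  expect_lt(res$pathways[[oxi]]$score, 1.0)
  for (p in res$pathways) {
    expect_true(all(p$steps$step_score >= 0 & p$steps$step_score <= 1))
    expect_gte(p$score, 0); expect_lte(p$score, 1)
  }
})

test_that("mining ranks the exact two-step route first, deterministically", {
  res1 <- mine(kb, "C00355", "C04043", seed = 42L)
  res2 <- mine(kb, "C00355", "C04043", seed = 42L)
  expect_identical(as.data.frame(res1), as.data.frame(res2))
  expect_equal(nrow(res1$pathways[[1]]$steps), 2L)
  expect_equal(res1$pathways[[1]]$score, 1.0)
  expect_error(mine(kb, "MISSING", "C04043"), "not in knowledge base")
})

test_that("putative-step compound candidates respect the threshold", {
  res <- mine(kb, "C00355", "C04043", seed = 42L, theta = 0.7)
  oxi <- which(vapply(res$pathways, function(p) {
    identical(p$steps$ec, c("1.14.14.36", "1.2.3.1"))
  }, logical(1)))
  cands <- res$pathways[[oxi]]$compound_candidates[[1]]
  expect_true(all(cands$similarity >= 0.7))
  # the closest known compound to the putative aldoxime is its
  # phenol analog
  expect_equal(cands$id[1], "C04353")
  # the holdout structure itself never appears as a candidate
  expect_false("X00001" %in% cands$id)
})
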