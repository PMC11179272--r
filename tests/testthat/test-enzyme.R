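test_that("ortholog filtering is strict at both thresholds", {
  tab <- data.frame(query = "q", subject = c("a", "b", "c", "d"),
                    score = c(1031, 1030, 2000, 900),
                    similarity = c(40, 50, 39, 80))
  kept <- filter_orthologs(tab)
  expect_equal(kept$subject, "a")  # 1030 and 39 are exclusive bounds
  expect_equal(nrow(filter_orthologs(tab[0, ])), 0L)
  expect_error(filter_orthologs(data.frame(query = 1)), "columns")
  tab$score[2] <- NA
  expect_error(filter_orthologs(tab), "malformed.*2")
})

test_that("p-distance counts mismatches over pairwise gap-free columns", {
  seqs <- c(s1 = "ACDE", s2 = "ACDF", s3 = "AC-E", s4 = "ACDE")
  dm <- p_distance(seqs)
  expect_equal(dm["s1", "s4"], 0)
  expect_equal(dm["s1", "s2"], 0.25)       # 1 mismatch / 4 columns
  expect_equal(dm["s3", "s4"], 0)          # 3 gap-free columns, all equal
  expect_equal(dm["s3", "s2"], 1 / 3)      # E vs F over 3 columns
  expect_equal(dm, t(dm))
  expect_error(p_distance(c(a = "ACDE", b = "ACD")), "equal length")
  expect_error(p_distance(c(a = "ACDE", b = "ACDF")), "at least 3")
})

test_that("neighbor joining recovers a hand-built additive 4-taxon tree", {
  # tree ((A:1,B:2):3,(C:4,D:5)) gives these pairwise path lengths
  dm <- matrix(c(0, 3, 8, 9,
                 3, 0, 9, 10,
                 8, 9, 0, 9,
                 9, 10, 9, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"),
                               c("A", "B", "C", "D")))
  tree <- nj_tree(dm)
  cp <- ape::cophenetic.phylo(tree)[rownames(dm), colnames(dm)]
  expect_equal(cp, dm, tolerance = 1e-12)
  # A and B are siblings
  expect_true(ape::is.monophyletic(ape::unroot(tree), c("A", "B")))
})

test_that("NJ is exact on random additive matrices (n = 4..8)", {
  for (n in 4:8) {
    set.seed(100 + n)
    ref <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.1, 2))
    dm <- ape::cophenetic.phylo(ref)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    tree <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tree)), 0,
                 ignore_attr = TRUE, info = paste("n =", n))
    cp <- ape::cophenetic.phylo(tree)[rownames(dm), colnames(dm)]
    expect_equal(max(abs(cp - dm)), 0, tolerance = 1e-9,
                 info = paste("n =", n))
  }
})

test_that("three taxa resolve to the closed-form star lengths", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- nj_tree(dm)
  # a = (dxy + dxz - dyz) / 2 etc.
  lens <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                   tree$tip.label)
  expect_equal(lens, c(x = 1, y = 1, z = 3))
})

test_that("invalid distance matrices are rejected and ties are stable", {
  dm <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(dm), "symmetric|at least 3")
  dm4 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm4) <- 0
  t1 <- nj_tree(dm4); t2 <- nj_tree(dm4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("distance matrices round-trip through TSV", {
  dm <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(dm, path)
  expect_equal(read_distance_tsv(path), dm)
})

test_that("hydropathy profiles match a naive sliding-window oracle", {
  for (seed in 1:5) {
    s <- random_protein(80, seed)
    expect_equal(unname(hydropathy_profile(s, 19)), naive_hydropathy(s, 19),
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_length(hydropathy_profile(s, 19), 80 - 19 + 1)
  }
  expect_error(hydropathy_profile("ACDEX", 3), "non-standard residue")
  expect_error(hydropathy_profile("ACDE", 19), "shorter than the window")
})

test_that("anchor detection finds hydrophobic heads and skips acidic ones", {
  hydro_head <- paste0(strrep("I", 30), strrep("D", 40))
  seg <- detect_nterm_anchor(hydro_head)
  expect_equal(seg[["start"]], 1L)
  expect_null(detect_nterm_anchor(strrep("D", 60)))
})

test_that("anchor coordinates agree with direct window computation", {
  s <- paste0(strrep("D", 40), strrep("I", 25), strrep("D", 20))
  prof <- naive_hydropathy(s, 19)
  hot <- which(prof >= 1.6)
  expect_equal(unname(detect_nterm_anchor(s)),
               c(min(hot), max(hot) + 19 - 1))
  # an anchor starting beyond the search limit is ignored
  far <- paste0(strrep("D", 70), strrep("I", 25), strrep("D", 20))
  expect_null(detect_nterm_anchor(far))
})

test_that("truncation removes the anchor and restores the initiator Met", {
  s <- paste0(strrep("I", 19), strrep("Q", 81))  # 100-mer
  seg <- detect_nterm_anchor(s)
  out <- truncate_nterm(s, seg)
  expect_equal(substr(out, 1, 1), "M")
  expect_equal(nchar(out), 100 - seg[["end"]] + 1)
  expect_identical(truncate_nterm(s, NULL), s)
  expect_error(truncate_nterm("ACD", c(start = 1, end = 5)), "out of bounds")
  # after truncation no anchor remains in the designed sequence
  expect_null(detect_nterm_anchor(out))
})
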