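# Shared fixtures and independent oracles.

# Fixture SMILES with formulas frozen from an independent cheminformatics
# toolkit (RDKit) run on exactly these strings.
FIXTURE_FORMULAS <- list(
  list(id = "C00355", smiles = "NC(Cc1ccc(O)c(O)c1)C(O)=O", formula = "C9H11NO4"),
  list(id = "C04043", smiles = "O=CCc1ccc(O)c(O)c1", formula = "C8H8O3"),
  list(id = "C00082", smiles = "NC(Cc1ccc(O)cc1)C(O)=O", formula = "C9H11NO3"),
  list(id = "C04353", smiles = "ON=CCc1ccc(O)cc1", formula = "C8H9NO2"),
  list(id = "CID5464950", smiles = "CC(=NO)c1ccccc1", formula = "C8H9NO"),
  list(id = "C07113", smiles = "CC(=O)c1ccccc1", formula = "C8H8O"),
  list(id = "C03758", smiles = "NCCc1ccc(O)c(O)c1", formula = "C8H11NO2"),
  list(id = "X00001", smiles = "ON=CCc1ccc(O)c(O)c1", formula = "C8H9NO3"),
  list(id = "glucose", smiles = "OCC1OC(O)C(O)C(O)C1O", formula = "C6H12O6")
)

# Independent brute-force oracle for the combination search: enumerate all
# multisets over the delta rows (each row used at most c_max times, total
# multiplicity <= k_max) via utils::combn on a row-expanded index, and keep
# those whose column sums equal d. Returns a sorted character set of
# canonical solution keys, comparable with solution_keys() below.
brute_force_solutions <- function(D, d, k_max = 3L, c_max = 1L) {
  m <- nrow(D)
  expanded <- rep(seq_len(m), each = c_max)
  keys <- character(0)
  for (k in seq_len(k_max)) {
    if (k > length(expanded)) break
    combs <- utils::combn(length(expanded), k)
    for (c in seq_len(ncol(combs))) {
      rows <- expanded[combs[, c]]
      if (!all(colSums(D[rows, , drop = FALSE]) == d)) next
      tab <- table(rownames(D)[rows])
      keys <- c(keys, paste(names(tab), as.integer(tab),
                            sep = "x", collapse = "+"))
    }
  }
  sort(unique(keys))
}

solution_keys <- function(sols) {
  sort(unique(vapply(sols, function(s) {
    paste(names(s), s, sep = "x", collapse = "+")
  }, character(1))))
}

# A tiny synthetic knowledge base wrapping an arbitrary delta matrix, for
# solver tests that do not need real chemistry.
synthetic_delta_kb <- function(D) {
  rownames(D) <- sprintf("DF%04d", seq_len(nrow(D)))
  members <- data.frame(feature_id = rownames(D),
                        pair_id = sprintf("RP%04d", seq_len(nrow(D))),
                        direction = "forward", ec = "1.1.1.1",
                        stringsAsFactors = FALSE)
  structure(list(schema = NULL, compounds = NULL,
                 vectors = matrix(0L, 0, ncol(D),
                                  dimnames = list(NULL, colnames(D))),
                 reactions = NULL, deltas = D, members = members),
            class = "pathway_kb")
}

# Seeded random delta matrix: m reactions over p features, entries in
# -3..3, plus a target that is the sum of a random small multiset (so the
# instance is feasible about half the time and infeasible otherwise).
random_delta_instance <- function(seed, m = 40L, p = 8L, k_max = 3L) {
  set.seed(seed)
  D <- matrix(sample(-3:3, m * p, replace = TRUE), m, p,
              dimnames = list(sprintf("DF%04d", 1:m),
                              paste0("f", 1:p)))
  if (seed %% 2 == 0) {
    rows <- sample(m, sample(k_max, 1))
    d <- colSums(D[rows, , drop = FALSE])
  } else {
    d <- stats::setNames(sample(-4:4, p, replace = TRUE), colnames(D))
  }
  list(D = D, d = d)
}

# Naive sliding-window hydropathy oracle (direct re-computation, no
# cumulative-sum trick), kept independent of the package implementation.
KD_ORACLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

naive_hydropathy <- function(seq, window) {
  res <- strsplit(seq, "")[[1]]
  vapply(seq_len(length(res) - window + 1), function(k) {
    mean(KD_ORACLE[res[k:(k + window - 1)]])
  }, numeric(1))
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(names(KD_ORACLE), n, replace = TRUE), collapse = "")
}
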