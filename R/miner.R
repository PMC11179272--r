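# Pathway mining: find multisets of reaction delta features that sum to the
# query delta, order them into step sequences with admissible (elementwise
# non-negative) intermediates, match intermediates against known compounds,
# and rank by average Tanimoto similarity to the mimicked known reactions.

#' Query delta vector
#'
#' The pathway feature vector of a query: `f(target) - f(source)`. Any
#' admissible combination of reaction deltas must sum to it exactly.
#'
#' @param kb A `pathway_kb`.
#' @param source,target Compound ids present in the knowledge base.
#' @return A named integer vector over the schema keys (may be negative).
#' @export
query_delta <- function(kb, source, target) {
  stopifnot(inherits(kb, "pathway_kb"))
  kb_vector(kb, target) - kb_vector(kb, source)
}

# Exact enumeration of all x in {0..c_max}^m with sum(x) <= k_max and
# t(D) %*% x == d, by depth-first branch and prune. The bound uses the
# suffix maximum of the L1 norms of the remaining delta rows: if the
# residual's L1 norm exceeds (steps left) * (largest remaining row norm),
# no completion exists. Solutions are recorded at the leaves, so each
# multiset is emitted exactly once.
enumerate_combinations <- function(D, d, k_max, c_max = 1L,
                                   max_solutions = Inf,
                                   allow_empty = FALSE) {
  m <- nrow(D)
  sols <- list()
  truncated <- FALSE
  if (m == 0L) {
    if (all(d == 0) && allow_empty) sols <- list(integer(0))
    return(structure(sols, truncated = truncated))
  }
  l1 <- apply(abs(D), 1, sum)
  sufmax <- rev(cummax(rev(l1)))

  rec <- function(j, residual, steps, x) {
    if (truncated) return()
    if (j > m) {
      if (all(residual == 0) && (steps > 0L || allow_empty)) {
        sols[[length(sols) + 1L]] <<- x
        if (length(sols) >= max_solutions) truncated <<- TRUE
      }
      return()
    }
    left <- k_max - steps
    if (sum(abs(residual)) > left * sufmax[j]) return()
    for (xj in 0:min(c_max, left)) {
      x[j] <- xj
      rec(j + 1L, residual - xj * D[j, ], steps + xj, x)
      if (truncated) return()
    }
  }
  rec(1L, d, 0L, integer(m))
  structure(sols, truncated = truncated)
}

solution_key <- function(sol) paste(names(sol), sol, sep = "x", collapse = "+")

#' Find delta combinations that solve a query
#'
#' Searches for multisets of reaction delta features whose vector sum
#' equals the query delta `d` exactly, using at most `k_max` steps and each
#' feature at most `c_max` times. By default the search space is controlled
#' by iterative random subsampling: in each iteration a random subset of
#' delta features is drawn and the exact enumerator runs on the subset;
#' solutions are pooled and deduplicated across iterations. With
#' `exhaustive = TRUE` the enumerator runs once on the full delta index and
#' returns all solutions within the bounds.
#'
#' @param kb A `pathway_kb`.
#' @param d Query delta vector (see [query_delta()]).
#' @param k_max Maximum number of steps (default 3).
#' @param c_max Maximum multiplicity per delta feature (default 1).
#' @param exhaustive Bypass subsampling and enumerate everything.
#' @param iterations,subset_size Random-subsampling controls.
#' @param seed Optional seed for the subsampling RNG.
#' @param max_solutions Solution cap for the enumerator.
#' @param allow_empty Return the empty combination when `d` is all-zero.
#' @return A list of solutions, each a named integer vector
#'   (delta feature id -> multiplicity), sorted by feature id. An empty
#'   list means no combination exists within the bounds.
#' @export
find_combinations <- function(kb, d, k_max = 3L, c_max = 1L,
                              exhaustive = FALSE, iterations = 200L,
                              subset_size = 20L, seed = NULL,
                              max_solutions = 10000L, allow_empty = FALSE) {
  stopifnot(inherits(kb, "pathway_kb"))
  D <- kb$deltas
  if (nrow(D) == 0L) stop("knowledge base has no reaction deltas",
                          call. = FALSE)
  if (!identical(colnames(D), names(d))) {
    stop("query delta does not match the knowledge-base schema",
         call. = FALSE)
  }
  pack <- function(x, ids) {
    nz <- which(x > 0L)
    sol <- stats::setNames(as.integer(x[nz]), ids[nz])
    sol[order(names(sol))]
  }
  if (exhaustive) {
    raw <- enumerate_combinations(D, d, k_max, c_max, max_solutions,
                                  allow_empty)
    sols <- lapply(raw, pack, ids = rownames(D))
  } else {
    runner <- function() {
      pool <- list()
      for (it in seq_len(iterations)) {
        idx <- sort(sample.int(nrow(D), min(subset_size, nrow(D))))
        raw <- enumerate_combinations(D[idx, , drop = FALSE], d, k_max,
                                      c_max, max_solutions, allow_empty)
        pool <- c(pool, lapply(raw, pack, ids = rownames(D)[idx]))
      }
      pool
    }
    sols <- if (is.null(seed)) runner() else with_local_seed(seed, runner())
  }
  sols[!duplicated(vapply(sols, solution_key, character(1)))]
}

# Unique permutations of a character vector (k <= k_max, tiny).
unique_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in unique_permutations(rest)) {
      out[[length(out) + 1L]] <- c(v, p)
    }
  }
  out
}

#' Order a combination into admissible pathway candidates
#'
#' Tries every permutation of the solution multiset, keeps orders in which
#' every partial-sum intermediate vector is elementwise non-negative, and
#' matches each intermediate vector against the knowledge-base compounds by
#' exact vector equality (unmatched intermediates become putative
#' compounds, carried as bare feature vectors).
#'
#' @param kb A `pathway_kb`.
#' @param solution A named integer vector (feature id -> multiplicity).
#' @param source,target Compound ids of the query.
#' @return A list of pathway candidates; empty when no ordering is
#'   admissible. Each candidate has `order` (feature ids) and `steps`
#'   (per step: feature id, from/to vectors, matched compound ids).
#' @export
order_and_match <- function(kb, solution, source, target) {
  stopifnot(inherits(kb, "pathway_kb"))
  f_source <- kb_vector(kb, source)
  f_target <- kb_vector(kb, target)
  seqn <- rep(names(solution), solution)
  searchable <- kb_searchable_ids(kb)
  vkeys <- apply(kb$vectors[searchable, , drop = FALSE], 1, paste,
                 collapse = ",")

  out <- list()
  for (perm in unique_permutations(seqn)) {
    vec <- as.integer(f_source)
    steps <- vector("list", length(perm))
    ok <- TRUE
    for (s in seq_along(perm)) {
      nxt <- vec + kb$deltas[perm[s], ]
      if (any(nxt < 0L)) { ok <- FALSE; break }
      matched <- searchable[vkeys == paste(nxt, collapse = ",")]
      steps[[s]] <- list(feature_id = perm[s],
                         from = vec, to = nxt,
                         matched_ids = matched)
      vec <- nxt
    }
    if (!ok) next
    if (!all(vec == as.integer(f_target))) next  # defensive; exactness
    out[[length(out) + 1L]] <- list(order = perm, steps = steps,
                                    source = source, target = target)
  }
  out
}

#' Score a pathway candidate
#'
#' For each step, every known reaction sharing the step's delta feature is
#' a candidate annotation; the step score for a candidate known pair
#' `(ks -> kp)` mimicked by the query pair `(qs -> qp)` is the aggregate
#' (mean by default, optionally min) of `tanimoto(f(qs), f(ks))` and
#' `tanimoto(f(qp), f(kp))`, computed on feature vectors so that putative
#' intermediates score like any other compound. The best-scoring known
#' reaction is reported per step; the pathway score is the arithmetic mean
#' of the step scores.
#'
#' @param kb A `pathway_kb`.
#' @param candidate A pathway candidate from [order_and_match()].
#' @param step_agg `"mean"` (default) or `"min"` aggregation of the
#'   substrate-side and product-side similarities.
#' @return A `scored_pathway`: list with `steps` (data frame), `score`,
#'   `source`, `target`.
#' @export
score_pathway <- function(kb, candidate, step_agg = c("mean", "min")) {
  step_agg <- match.arg(step_agg)
  agg <- if (step_agg == "mean") mean else min
  fv <- function(x) structure(as.integer(x),
                              names = colnames(kb$vectors),
                              class = "feature_vector")
  rows <- list()
  for (s in seq_along(candidate$steps)) {
    st <- candidate$steps[[s]]
    mem <- kb$members[kb$members$feature_id == st$feature_id, , drop = FALSE]
    best <- NULL
    for (r in seq_len(nrow(mem))) {
      pair <- kb$reactions[kb$reactions$pair_id == mem$pair_id[r], ]
      ks <- pair$substrate_id; kp <- pair$product_id
      if (mem$direction[r] == "reverse") { tmp <- ks; ks <- kp; kp <- tmp }
      sc <- agg(c(tanimoto(fv(st$from), kb_vector(kb, ks)),
                  tanimoto(fv(st$to), kb_vector(kb, kp))))
      if (is.null(best) || sc > best$score ||
          (sc == best$score && mem$pair_id[r] < best$pair_id)) {
        best <- list(score = sc, pair_id = mem$pair_id[r],
                     ec = mem$ec[r], direction = mem$direction[r])
      }
    }
    matched <- st$matched_ids
    rows[[s]] <- data.frame(
      position = s, feature_id = st$feature_id, pair_id = best$pair_id,
      ec = best$ec, direction = best$direction, step_score = best$score,
      intermediate_id = if (length(matched)) matched[1] else NA_character_,
      putative = length(matched) == 0L, stringsAsFactors = FALSE)
  }
  steps <- do.call(rbind, rows)
  structure(list(steps = steps,
                 intermediates = lapply(candidate$steps, `[[`, "to"),
                 score = mean(steps$step_score),
                 source = candidate$source, target = candidate$target),
            class = "scored_pathway")
}

#' @export
print.scored_pathway <- function(x, ...) {
  cat(sprintf("<scored_pathway> %s -> %s, %d step(s), score %.4f\n",
              x$source, x$target, nrow(x$steps), x$score))
  for (s in seq_len(nrow(x$steps))) {
    r <- x$steps[s, ]
    inter <- if (s == nrow(x$steps)) x$target
             else if (r$putative) "putative"
             else r$intermediate_id
    cat(sprintf("  %d. EC %s (%s%s)  step score %.4f  -> %s\n",
                s, r$ec, r$pair_id,
                if (r$direction == "reverse") ", reverse" else "",
                r$step_score, inter))
  }
  invisible(x)
}

pathway_identity <- function(p) {
  paste(paste(p$steps$pair_id, p$steps$direction, sep = ":"),
        collapse = ">")
}

#' Mine ranked pathways between two compounds
#'
#' The full pipeline: compute the query delta, find delta combinations,
#' order each combination into admissible candidates, score candidates,
#' deduplicate, and rank. For putative intermediates, known compounds with
#' Tanimoto similarity at least `theta` are attached as per-step compound
#' candidates (compounds below the threshold are dropped from that list).
#'
#' Ranking is by score (descending), then fewer steps, then fewer putative
#' intermediates, then the lexicographic concatenation of step pair ids --
#' a fixed tie-break so runs are reproducible.
#'
#' @param kb A `pathway_kb`.
#' @param source,target Compound ids of the query.
#' @param k_max Maximum pathway length in steps (default 3).
#' @param theta Similarity threshold for per-step compound candidates
#'   (default 0.7).
#' @param c_max Maximum multiplicity per delta feature (default 1).
#' @param exhaustive,iterations,subset_size,seed Passed to
#'   [find_combinations()].
#' @param step_agg Step-score aggregation, see [score_pathway()].
#' @return A `pathway_ranking`: list with `pathways` (ranked list of
#'   `scored_pathway`s), `query` and `provenance`.
#' @examples
#' kb <- build_demo_kb(42)
#' res <- mine(kb, "C00355", "C04043", seed = 42)
#' res
#' @export
mine <- function(kb, source, target, k_max = 3L, theta = 0.7, c_max = 1L,
                 exhaustive = FALSE, iterations = 200L, subset_size = 20L,
                 seed = 1L, step_agg = "mean") {
  stopifnot(inherits(kb, "pathway_kb"))
  ids <- rownames(kb$vectors)
  missing <- setdiff(c(source, target), ids)
  if (length(missing)) {
    stop("query compound(s) not in knowledge base: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- query_delta(kb, source, target)
  sols <- find_combinations(kb, d, k_max = k_max, c_max = c_max,
                            exhaustive = exhaustive, iterations = iterations,
                            subset_size = subset_size, seed = seed)
  pathways <- list()
  for (sol in sols) {
    for (cand in order_and_match(kb, sol, source, target)) {
      pathways[[length(pathways) + 1L]] <- score_pathway(kb, cand, step_agg)
    }
  }
  pathways <- pathways[!duplicated(vapply(pathways, pathway_identity,
                                          character(1)))]

  # per-step compound candidates for putative intermediates
  searchable <- kb_searchable_ids(kb)
  for (p in seq_along(pathways)) {
    pw <- pathways[[p]]
    cands <- vector("list", nrow(pw$steps))
    for (s in seq_len(nrow(pw$steps))) {
      if (!pw$steps$putative[s]) next
      iv <- structure(as.integer(pw$intermediates[[s]]),
                      names = colnames(kb$vectors), class = "feature_vector")
      sims <- vapply(searchable, function(id) {
        tanimoto(iv, kb_vector(kb, id))
      }, numeric(1))
      keep <- sims >= theta
      cands[[s]] <- data.frame(id = searchable[keep],
                               similarity = unname(sims[keep]),
                               stringsAsFactors = FALSE)
      if (nrow(cands[[s]])) {
        cands[[s]] <- cands[[s]][order(-cands[[s]]$similarity,
                                       cands[[s]]$id), , drop = FALSE]
      }
    }
    pathways[[p]]$compound_candidates <- cands
  }

  ord <- order(-vapply(pathways, `[[`, numeric(1), "score"),
               vapply(pathways, function(p) nrow(p$steps), integer(1)),
               vapply(pathways, function(p) sum(p$steps$putative), integer(1)),
               vapply(pathways, function(p) paste(p$steps$pair_id,
                                                  collapse = "|"),
                      character(1)))
  structure(list(pathways = pathways[ord],
                 query = list(source = source, target = target,
                              k_max = k_max, theta = theta, c_max = c_max),
                 provenance = list(seed = seed, exhaustive = exhaustive,
                                   iterations = iterations,
                                   subset_size = subset_size,
                                   step_agg = step_agg,
                                   n_solutions = length(sols))),
            class = "pathway_ranking")
}

#' @export
print.pathway_ranking <- function(x, ...) {
  cat(sprintf("<pathway_ranking> %s -> %s: %d pathway(s)\n",
              x$query$source, x$query$target, length(x$pathways)))
  for (i in seq_along(utils::head(x$pathways, 10))) {
    p <- x$pathways[[i]]
    cat(sprintf("  #%d score %.4f: %s\n", i, p$score,
                paste(p$steps$ec, collapse = " > ")))
  }
  invisible(x)
}

#' @export
as.data.frame.pathway_ranking <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$pathways), function(i) {
    p <- x$pathways[[i]]
    data.frame(rank = i, score = p$score, n_steps = nrow(p$steps),
               n_putative = sum(p$steps$putative),
               ecs = paste(p$steps$ec, collapse = " > "),
               pair_ids = paste(p$steps$pair_id, collapse = " > "),
               stringsAsFactors = FALSE)
  }))
}
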