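# Knowledge base: compounds, substrate->product reaction pairs, and the
# precomputed reaction delta vectors that drive the combination search.
#
# Identical delta vectors are grouped into "delta features": one feature id
# per distinct vector, carrying the list of member reactions. A pathway
# step therefore references a delta feature, and every known reaction with
# that same delta is a candidate annotation for the step (the scorer
# enumerates them and reports the best).

EC_PATTERN <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"

#' Load a compound table
#'
#' Reads compounds from a tab-separated file with columns `id`, `name`,
#' `smiles` and optionally `source` (rows with source `"holdout"` are kept
#' out of intermediate matching), or from an SDF file (`.sdf`; ids and
#' names from the title line). Every structure is parsed and featurized.
#'
#' @param path Path to a `.tsv`/`.smi`-style table or an `.sdf` file.
#' @param schema A `feature_schema`.
#' @return A `compound_index`: list with `compounds` (data frame) and
#'   `vectors` (integer matrix, one row per compound id).
#' @export
load_compounds <- function(path, schema) {
  stopifnot(file.exists(path), inherits(schema, "feature_schema"))
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    df <- read_sdf_compounds(path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) {
      warning("compound table is empty: ", path)
      return(compound_index(df_empty_compounds(), schema))
    }
    need <- c("id", "name", "smiles")
    if (!all(need %in% names(df))) {
      stop("compound table must have columns id, name, smiles: ", path,
           call. = FALSE)
    }
    if (is.null(df$source)) df$source <- "user"
  }
  compound_index(df, schema)
}

df_empty_compounds <- function() {
  data.frame(id = character(0), name = character(0), smiles = character(0),
             source = character(0), stringsAsFactors = FALSE)
}

read_sdf_compounds <- function(path) {
  txt <- readLines(path)
  recs <- split(txt, cumsum(c(1, utils::head(txt, -1) == "$$$$")))
  recs <- lapply(recs, function(r) r[r != "$$$$"])
  recs <- recs[vapply(recs, function(r) any(nzchar(r)), logical(1))]
  ids <- vapply(recs, function(r) trimws(r[1]), character(1))
  data.frame(id = ids, name = ids,
             smiles = NA_character_,
             molblock = vapply(recs, paste, character(1), collapse = "\n"),
             source = "user", stringsAsFactors = FALSE)
}

compound_index <- function(df, schema) {
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stop("duplicate compound id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vectors <- matrix(0L, nrow = nrow(df), ncol = length(schema$keys),
                    dimnames = list(df$id, schema$keys))
  for (r in seq_len(nrow(df))) {
    mol <- tryCatch({
      if (!is.null(df$molblock) && !is.na(df$molblock[r])) {
        parse_structure(df$molblock[r], "mol")
      } else {
        parse_structure(df$smiles[r], "smiles")
      }
    }, error = function(e) {
      stop(sprintf("row %d (id %s): unparseable structure: %s",
                   r, df$id[r], conditionMessage(e)), call. = FALSE)
    })
    vectors[r, ] <- featurize(mol, schema)
  }
  df$molblock <- NULL
  if (is.null(df$source)) df$source <- "user"
  message(sprintf("loaded %d compound record(s)", nrow(df)))
  structure(list(compounds = df, vectors = vectors, schema = schema),
            class = "compound_index")
}

#' Load a reaction-pair table
#'
#' Reads substrate->product pairs from a tab-separated file with columns
#' `pair_id`, `ec`, `substrate_id`, `product_id`, `reversible` and computes
#' the delta vector of each pair (plus the negated delta for reversible
#' pairs).
#'
#' @param path Path to the TSV file.
#' @param compounds A `compound_index` resolving all compound ids.
#' @return A `reaction_set`: list with `reactions` (data frame), `deltas`
#'   (integer matrix of distinct delta vectors, one per delta feature) and
#'   `members` (data frame mapping feature id -> pair id, direction, EC).
#' @export
load_reaction_pairs <- function(path, compounds) {
  stopifnot(file.exists(path), inherits(compounds, "compound_index"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "ec", "substrate_id", "product_id", "reversible")
  if (!all(need %in% names(df))) {
    stop("reaction table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  reaction_set(df, compounds)
}

reaction_set <- function(df, compounds) {
  df$reversible <- as.logical(df$reversible)
  if (is.null(df$source)) df$source <- "user"
  bad_ec <- df$pair_id[!grepl(EC_PATTERN, df$ec)]
  if (length(bad_ec)) {
    stop("malformed EC number for pair(s): ", paste(bad_ec, collapse = ", "),
         call. = FALSE)
  }
  known <- rownames(compounds$vectors)
  dangling <- df$pair_id[!(df$substrate_id %in% known) |
                           !(df$product_id %in% known)]
  if (length(dangling)) {
    stop("reaction pair(s) reference unknown compound id: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  dup <- unique(df$pair_id[duplicated(df$pair_id)])
  if (length(dup)) {
    stop("duplicate pair id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }

  rows <- list(); info <- list()
  for (r in seq_len(nrow(df))) {
    delta <- compounds$vectors[df$product_id[r], ] -
      compounds$vectors[df$substrate_id[r], ]
    rows[[length(rows) + 1L]] <- delta
    info[[length(info) + 1L]] <-
      data.frame(pair_id = df$pair_id[r], direction = "forward",
                 ec = df$ec[r], stringsAsFactors = FALSE)
    if (isTRUE(df$reversible[r])) {
      rows[[length(rows) + 1L]] <- -delta
      info[[length(info) + 1L]] <-
        data.frame(pair_id = df$pair_id[r], direction = "reverse",
                   ec = df$ec[r], stringsAsFactors = FALSE)
    }
  }
  all_deltas <- do.call(rbind, rows)
  members <- do.call(rbind, info)

  # group identical delta vectors into features
  keys <- apply(all_deltas, 1, paste, collapse = ",")
  uniq <- !duplicated(keys)
  feature_ids <- sprintf("DF%04d", cumsum(uniq))[match(keys, keys[uniq])]
  members$feature_id <- feature_ids
  deltas <- all_deltas[uniq, , drop = FALSE]
  rownames(deltas) <- feature_ids[uniq]

  structure(list(reactions = df, deltas = deltas,
                 members = members[, c("feature_id", "pair_id",
                                       "direction", "ec")]),
            class = "reaction_set")
}

#' Assemble a knowledge base
#'
#' Binds a compound index and a reaction set (sharing one schema) into the
#' searchable knowledge base used by [mine()] and friends.
#'
#' @param compounds A `compound_index`.
#' @param reactions A `reaction_set` built against `compounds`.
#' @return A `pathway_kb` object.
#' @export
knowledge_base <- function(compounds, reactions) {
  stopifnot(inherits(compounds, "compound_index"),
            inherits(reactions, "reaction_set"))
  structure(list(schema = compounds$schema,
                 compounds = compounds$compounds,
                 vectors = compounds$vectors,
                 reactions = reactions$reactions,
                 deltas = reactions$deltas,
                 members = reactions$members),
            class = "pathway_kb")
}

#' @export
print.pathway_kb <- function(x, ...) {
  cat(sprintf(paste0("<pathway_kb> %d compounds (%d searchable), ",
                     "%d reaction pairs, %d distinct delta features\n"),
              nrow(x$compounds), sum(x$compounds$source != "holdout"),
              nrow(x$reactions), nrow(x$deltas)))
  invisible(x)
}

kb_vector <- function(kb, id) {
  if (!id %in% rownames(kb$vectors)) {
    stop("compound not in knowledge base: ", id, call. = FALSE)
  }
  v <- kb$vectors[id, ]
  structure(v, class = "feature_vector", schema_version = kb$schema$version)
}

# ids of compounds eligible as matched intermediates
kb_searchable_ids <- function(kb) {
  kb$compounds$id[kb$compounds$source != "holdout"]
}

# --- packaged demonstration knowledge base ---------------------------------

# Core compounds of the arylacetaldoxime bypass case study. Ids are KEGG
# C-numbers / a PubChem CID used as opaque strings; structures are the
# standard ones for those ids (formulas noted for independent checking).
DEMO_CORE_COMPOUNDS <- data.frame(
  id = c("C00355", "C04043", "C00082", "C04353", "CID5464950", "C07113",
         "C03758", "X00001"),
  name = c("L-DOPA", "DHPAA", "L-tyrosine", "4HPAA-oxime",
           "acetophenone oxime", "acetophenone", "dopamine", "DHPAA-oxime"),
  smiles = c(
    "NC(Cc1ccc(O)c(O)c1)C(O)=O",   # C9H11NO4
    "O=CCc1ccc(O)c(O)c1",          # C8H8O3
    "NC(Cc1ccc(O)cc1)C(O)=O",      # C9H11NO3
    "ON=CCc1ccc(O)cc1",            # C8H9NO2
    "CC(=NO)c1ccccc1",             # C8H9NO
    "CC(=O)c1ccccc1",              # C8H8O
    "NCCc1ccc(O)c(O)c1",           # C8H11NO2
    "ON=CCc1ccc(O)c(O)c1"          # C8H9NO3, putative bypass intermediate
  ),
  source = c(rep("core", 7), "holdout"),
  stringsAsFactors = FALSE
)

# Decoy aromatics. The first block is always present (decoy reactions refer
# to it); the pool block is sampled by seed.
DEMO_FIXED_DECOYS <- data.frame(
  id = sprintf("D%05d", 1:9),
  name = c("benzaldehyde", "benzoic acid", "phenylacetaldehyde",
           "phenylacetic acid", "toluene", "benzyl alcohol",
           "2-phenylethylamine", "phenol", "catechol"),
  smiles = c("O=Cc1ccccc1", "OC(=O)c1ccccc1", "O=CCc1ccccc1",
             "OC(=O)Cc1ccccc1", "Cc1ccccc1", "OCc1ccccc1",
             "NCCc1ccccc1", "Oc1ccccc1", "Oc1ccccc1O"),
  source = "decoy", stringsAsFactors = FALSE
)

DEMO_POOL_DECOYS <- data.frame(
  id = sprintf("D%05d", 10:16),
  name = c("tyramine", "4-hydroxybenzaldehyde", "anisole", "benzylamine",
           "styrene", "cinnamic acid", "salicylaldehyde"),
  smiles = c("NCCc1ccc(O)cc1", "O=Cc1ccc(O)cc1", "COc1ccccc1",
             "NCc1ccccc1", "C=Cc1ccccc1", "OC(=O)C=Cc1ccccc1",
             "O=Cc1ccccc1O"),
  source = "decoy", stringsAsFactors = FALSE
)

DEMO_CORE_REACTIONS <- data.frame(
  pair_id = sprintf("RP%04d", 1:4),
  ec = c("1.14.14.36", "1.2.3.1", "4.1.1.28", "1.4.3.4"),
  substrate_id = c("C00082", "CID5464950", "C00355", "C03758"),
  product_id = c("C04353", "C07113", "C03758", "C04043"),
  reversible = FALSE, source = "core", stringsAsFactors = FALSE
)

DEMO_DECOY_REACTIONS <- data.frame(
  pair_id = sprintf("RD%04d", 1:6),
  ec = c("1.1.1.90", "1.2.1.28", "1.2.1.39", "1.14.13.243", "1.4.3.21",
         "1.14.13.244"),
  substrate_id = c("D00006", "D00001", "D00003", "D00005", "D00007",
                   "D00008"),
  product_id = c("D00001", "D00002", "D00004", "D00006", "D00003",
                 "D00009"),
  reversible = FALSE, source = "decoy", stringsAsFactors = FALSE
)

#' Build the packaged demonstration knowledge base
#'
#' Assembles a small KEGG-like knowledge base around the arylacetaldoxime
#' bypass case study: the core compounds (L-DOPA, DHPAA, L-tyrosine,
#' 4HPAA-oxime, acetophenone oxime, acetophenone, dopamine, and the
#' DHPAA-oxime holdout structure, which is excluded from intermediate
#' matching), the four core reaction pairs (tyrosine N-monooxygenase
#' EC 1.14.14.36, aldehyde oxidase EC 1.2.3.1, DODC EC 4.1.1.28, MAO
#' EC 1.4.3.4), plus seeded decoy aromatics and decoy reactions that make
#' ranking non-trivial. At build time it is verified that no decoy pair by
#' itself solves the L-DOPA to DHPAA query.
#'
#' @param seed Integer seed controlling decoy selection (fixture files are
#'   byte-identical across runs with the same seed).
#' @param dir Optional directory; when given, `compounds.tsv`,
#'   `reactions.tsv` and `schema.json` are written there.
#' @param decoys Include decoy compounds/reactions (default `TRUE`).
#' @param n_pool_decoys How many pool decoys to sample (default 4, on top
#'   of the 9 fixed ones).
#' @return A `pathway_kb`.
#' @examples
#' kb <- build_demo_kb(42)
#' @export
build_demo_kb <- function(seed = 42L, dir = NULL, decoys = TRUE,
                          n_pool_decoys = 4L) {
  schema <- feature_schema()
  compounds_df <- DEMO_CORE_COMPOUNDS
  reactions_df <- DEMO_CORE_REACTIONS
  if (decoys) {
    picked <- with_local_seed(seed, {
      sample(nrow(DEMO_POOL_DECOYS), min(n_pool_decoys, nrow(DEMO_POOL_DECOYS)))
    })
    pool <- DEMO_POOL_DECOYS[sort(picked), , drop = FALSE]
    compounds_df <- rbind(compounds_df, DEMO_FIXED_DECOYS, pool)
    reactions_df <- rbind(reactions_df, DEMO_DECOY_REACTIONS)
  }

  idx <- suppressMessages(compound_index(compounds_df, schema))
  rset <- reaction_set(reactions_df, idx)
  kb <- knowledge_base(idx, rset)

  # decoys must not trivially solve the case-study query
  d <- kb$vectors["C04043", ] - kb$vectors["C00355", ]
  decoy_features <- unique(kb$members$feature_id[
    kb$members$pair_id %in% DEMO_DECOY_REACTIONS$pair_id])
  for (f in decoy_features) {
    if (all(kb$deltas[f, ] == d)) {
      stop("internal error: a decoy pair alone solves the demo query",
           call. = FALSE)
    }
  }

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(compounds_df, file.path(dir, "compounds.tsv"))
    write_tsv_plain(reactions_df, file.path(dir, "reactions.tsv"))
    write_schema(schema, file.path(dir, "schema.json"))
  }
  kb
}

#' Load a knowledge base from a fixture directory
#'
#' Reads `compounds.tsv`, `reactions.tsv` and `schema.json` as written by
#' [build_demo_kb()].
#'
#' @param dir Directory containing the three files.
#' @return A `pathway_kb`.
#' @export
load_kb <- function(dir) {
  schema <- read_schema(file.path(dir, "schema.json"))
  idx <- load_compounds(file.path(dir, "compounds.tsv"), schema)
  rset <- load_reaction_pairs(file.path(dir, "reactions.tsv"), idx)
  knowledge_base(idx, rset)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, qmethod = "double")
}

# Run code under a temporary RNG state so library calls do not disturb the
# caller's random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
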