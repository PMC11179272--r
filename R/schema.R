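# Feature schema and count-vector featurization.
#
# The schema is the contract that makes vectors comparable: a fixed, ordered
# list of feature keys covering (a) atom classes and (b) bond types.
#
# Atom classes: carbon is split by substitution class, i.e. the number of
# carbon neighbors (0..4 aliphatic -> "C.0".."C.4"; 1..3 aromatic ->
# "C.ar1".."C.ar3"), so primary/secondary/tertiary/quaternary carbons are
# counted separately. Every other element (hydrogen included) is a plain
# element count. Hydrogens are counted from implicit H assignments, which
# keeps reaction deltas mass-balanced for amine/oxime interconversions.
#
# Bond types: unordered element pair x bond order, with BARE element pairs
# (not substitution-refined atom types). This is deliberate: it lets a
# reaction delta learned on one scaffold transfer to an analog context
# (e.g. a ketoxime-to-ketone delta applies unchanged to an aldoxime),
# which is what makes cross-scaffold reaction transfer work at all.
# Bonds to implicit hydrogens are counted as (element, H, single) keys.

SCHEMA_ORDERS <- c("1", "2", "3", "ar")

#' Construct a feature schema
#'
#' Builds the ordered key list for count-vector featurization: carbon
#' substitution classes, plain element counts for all other elements, and
#' unordered element-pair-by-bond-order bond keys. The dimension is fixed
#' at construction; vectors from different schemas never compare.
#'
#' @param elements Elements the schema can represent. Hydrogen must be
#'   included when implicit hydrogens are to be counted (the default).
#' @return A `feature_schema` object.
#' @seealso [featurize()], [write_schema()]
#' @export
feature_schema <- function(elements = c("H", "B", "C", "N", "O", "F",
                                        "P", "S", "Cl", "Br", "I")) {
  elements <- unique(elements)
  atom_keys <- character(0)
  for (e in elements) {
    if (e == "C") {
      atom_keys <- c(atom_keys, paste0("C.", 0:4), paste0("C.ar", 1:3))
    } else {
      atom_keys <- c(atom_keys, e)
    }
  }
  pairs <- t(utils::combn(sort(elements), 2))
  pairs <- rbind(pairs, cbind(sort(elements), sort(elements)))
  bond_keys <- as.vector(t(outer(
    paste0(pairs[, 1], "-", pairs[, 2]), SCHEMA_ORDERS, paste, sep = ":")))
  keys <- c(atom_keys, sort(bond_keys))
  stopifnot(!anyDuplicated(keys))
  structure(list(version = "pathminer-schema/1", elements = elements,
                 keys = keys), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema %s> %d keys over elements: %s\n",
              x$version, length(x$keys), paste(x$elements, collapse = " ")))
  invisible(x)
}

#' Serialize / restore a feature schema
#'
#' Schemas are written as JSON so that vectors computed in different runs
#' (or by the command-line tools) remain comparable.
#'
#' @param schema A `feature_schema`.
#' @param path File path.
#' @return `write_schema` returns `path` invisibly; `read_schema` returns
#'   the restored `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$version) || !identical(x$version, "pathminer-schema/1")) {
    stop("not a pathminer schema file: ", path, call. = FALSE)
  }
  structure(list(version = x$version, elements = x$elements, keys = x$keys),
            class = "feature_schema")
}

bond_key <- function(e1, e2, order) {
  p <- sort(c(e1, e2))
  paste0(p[1], "-", p[2], ":", order)
}

#' Featurize a molecule as an integer count vector
#'
#' Counts every atom into exactly one atom-class key and every bond
#' (including bonds to implicit hydrogens) into exactly one bond key of the
#' schema. Elements outside the schema raise an error rather than being
#' dropped silently.
#'
#' @param mol A `molecular_graph` (see [parse_structure()]).
#' @param schema A `feature_schema`.
#' @return A `feature_vector`: a named integer vector over `schema$keys`.
#' @examples
#' sch <- feature_schema()
#' v <- featurize(parse_structure("CC"), sch)  # ethane
#' v[["C.1"]]      # 2 primary carbons
#' v[["C-C:1"]]    # 1 C-C single bond
#' v[["H"]]        # 6 hydrogens
#' @export
featurize <- function(mol, schema) {
  stopifnot(inherits(mol, "molecular_graph"), inherits(schema, "feature_schema"))
  v <- stats::setNames(integer(length(schema$keys)), schema$keys)
  atoms <- mol$atoms; bonds <- mol$bonds
  bad <- setdiff(unique(atoms$element), schema$elements)
  if (length(bad)) {
    stop("unknown element(s) not representable in schema: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  ncarbon <- integer(nrow(atoms))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (atoms$element[j] == "C") ncarbon[i] <- ncarbon[i] + 1L
    if (atoms$element[i] == "C") ncarbon[j] <- ncarbon[j] + 1L
  }

  bump <- function(key, by = 1L) {
    if (!key %in% names(v)) {
      stop("feature key outside schema: ", key, call. = FALSE)
    }
    v[key] <<- v[key] + as.integer(by)
  }
  for (a in seq_len(nrow(atoms))) {
    el <- atoms$element[a]
    key <- if (el == "C") {
      if (atoms$aromatic[a]) paste0("C.ar", ncarbon[a]) else paste0("C.", ncarbon[a])
    } else el
    bump(key)
    hc <- atoms$hcount[a]
    if (hc > 0L) {
      if (!"H" %in% schema$elements) {
        stop("schema lacks element H but molecule has implicit hydrogens",
             call. = FALSE)
      }
      bump("H", hc)
      bump(bond_key(el, "H", "1"), hc)
    }
  }
  for (k in seq_len(nrow(bonds))) {
    bump(bond_key(atoms$element[bonds$i[k]], atoms$element[bonds$j[k]],
                  bonds$order[k]))
  }
  structure(v, class = "feature_vector",
            schema_version = schema$version)
}

check_same_schema <- function(a, b) {
  if (!identical(names(a), names(b))) {
    stop("feature vectors use different schemas (key sets differ)",
         call. = FALSE)
  }
}

#' Tanimoto similarity between two count vectors
#'
#' Count-vector Tanimoto `sum(min(a, b)) / sum(max(a, b))`. A binary
#' variant (Jaccard on feature supports) is available via `mode`.
#' Two all-zero vectors are defined to have similarity 1 (the empty
#' molecule is identical to itself); zero against non-zero gives 0.
#'
#' @param a,b Non-negative `feature_vector`s sharing a schema.
#' @param mode `"count"` (default) or `"binary"`.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b, mode = c("count", "binary")) {
  mode <- match.arg(mode)
  check_same_schema(a, b)
  if (any(a < 0) || any(b < 0)) {
    stop("tanimoto is defined for non-negative (real-molecule) vectors",
         call. = FALSE)
  }
  if (mode == "binary") {
    a <- as.integer(a > 0); b <- as.integer(b > 0)
  }
  den <- sum(pmax(a, b))
  if (den == 0) return(1)
  sum(pmin(a, b)) / den
}

#' @export
print.feature_vector <- function(x, ...) {
  nz <- x[x != 0]
  cat(sprintf("<feature_vector> %d/%d non-zero features\n", length(nz), length(x)))
  print(stats::setNames(as.integer(nz), names(nz)))
  invisible(x)
}
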