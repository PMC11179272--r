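# Molecular graph parsing: SMILES and MDL mol blocks.
#
# The graph model is deliberately minimal: atoms carry (element, formal
# charge, aromatic flag, implicit H count), bonds carry (i, j, order) with
# order one of "1", "2", "3", "ar". Aromaticity is taken from the input
# notation (lowercase SMILES atoms / MDL bond order 4), not re-perceived,
# so a kekulized and an aromatic form of the same ring are distinct inputs.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s")

# Default valence lists used to assign implicit hydrogens (lowest valence
# not smaller than the rounded-up bond-order sum wins).
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, H = c(0, 1)
)

new_molecular_graph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "molecular_graph")
}

#' Parse a chemical structure
#'
#' Parses a SMILES string or an MDL (V2000) mol block into a molecular
#' graph with aromatic flags and implicit hydrogen counts assigned.
#'
#' @param text A SMILES string, or the text of an MDL mol block.
#' @param format `"auto"` (default; mol block detected by the `V2000` tag),
#'   `"smiles"`, or `"mol"`.
#' @return A `molecular_graph`: a list with data frames `atoms`
#'   (`element`, `charge`, `aromatic`, `hcount`, `explicit_h`) and `bonds`
#'   (`i`, `j`, `order` with order in `"1"`, `"2"`, `"3"`, `"ar"`).
#' @examples
#' water <- parse_structure("O")
#' water$atoms$hcount  # 2 implicit hydrogens
#' @export
parse_structure <- function(text, format = c("auto", "smiles", "mol")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\n", text) && grepl("V2000", text)) "mol" else "smiles"
  }
  if (format == "mol") parse_molblock(text) else parse_smiles(text)
}

smiles_error <- function(msg, pos, token) {
  stop(sprintf("SMILES parse error at position %d (token '%s'): %s",
               pos, token, msg), call. = FALSE)
}

parse_smiles <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty SMILES string", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)

  elements <- character(0); charges <- integer(0)
  aromatics <- logical(0); hcounts <- integer(0); explicit <- logical(0)
  bi <- integer(0); bj <- integer(0); border <- character(0)

  prev <- NA_integer_
  pending <- NA_character_
  stack <- integer(0)
  rings <- list()

  add_bond <- function(a, b, order) {
    if (a == b) smiles_error("self-bond", i, chars[i])
    bi <<- c(bi, a); bj <<- c(bj, b); border <<- c(border, order)
  }
  connect <- function(idx) {
    if (!is.na(prev)) {
      ord <- if (!is.na(pending)) pending
             else if (aromatics[prev] && aromatics[idx]) "ar" else "1"
      add_bond(prev, idx, ord)
    }
    pending <<- NA_character_
    prev <<- idx
  }
  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_) {
    elements <<- c(elements, element)
    charges <<- c(charges, as.integer(charge))
    aromatics <<- c(aromatics, aromatic)
    hcounts <<- c(hcounts, as.integer(hcount))
    explicit <<- c(explicit, !is.na(hcount))
    connect(length(elements))
  }
  ring_closure <- function(key) {
    if (is.na(prev)) smiles_error("ring bond before any atom", i, key)
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      ord <- if (!is.na(pending)) pending
             else if (!is.na(open$order)) open$order
             else if (aromatics[open$atom] && aromatics[prev]) "ar" else "1"
      add_bond(open$atom, prev, ord)
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <<- list(atom = prev, order = pending)
    }
    pending <<- NA_character_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) smiles_error("branch before any atom", i, ch)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) smiles_error("unmatched ')'", i, ch)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = "1", "=" = "2", "#" = "3",
                        ":" = "ar", "/" = "1", "\\" = "1")
      i <- i + 1L
    } else if (ch == ".") {
      smiles_error("disconnected components are not supported", i, ch)
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[i + 1:2]))) {
        smiles_error("'%' must be followed by two digits", i, ch)
      }
      ring_closure(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      ring_closure(ch)
      i <- i + 1L
    } else if (ch == "[") {
      close <- NA_integer_
      if (i < n) {
        for (j in (i + 1L):n) if (chars[j] == "]") { close <- j; break }
      }
      if (is.na(close)) smiles_error("unterminated bracket atom", i, ch)
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]+)?([A-Z][a-z]?|[bcnops])(@{1,2})?(H([0-9]+)?)?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) smiles_error("malformed bracket atom", i, body)
      sym <- m[3]
      aromatic <- sym %in% AROMATIC_SYMBOLS
      element <- if (aromatic) toupper(sym) else sym
      hc <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      chg <- 0L
      if (nzchar(m[7])) {
        cs <- m[7]
        sign <- if (substr(cs, 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", cs)
        chg <- if (nzchar(digits)) sign * as.integer(digits)
               else sign * nchar(cs)
      }
      add_atom(element, aromatic, chg, hc)
      i <- close + 1L
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE); i <- i + 1L
      } else if (ch %in% AROMATIC_SYMBOLS) {
        add_atom(toupper(ch), TRUE); i <- i + 1L
      } else {
        smiles_error("unrecognized token", i, ch)
      }
    }
  }
  if (length(stack) > 0L) smiles_error("unmatched '('", n, "(")
  if (length(rings) > 0L) {
    smiles_error(sprintf("unclosed ring bond(s): %s",
                         paste(names(rings), collapse = ", ")), n, "ring")
  }
  if (length(elements) == 0L) stop("SMILES contains no atoms", call. = FALSE)

  atoms <- data.frame(element = elements, charge = charges,
                      aromatic = aromatics, hcount = hcounts,
                      explicit_h = explicit, stringsAsFactors = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = border, stringsAsFactors = FALSE)
  mol <- new_molecular_graph(atoms, bonds)
  assign_implicit_h(mol)
}

# Lowest default valence accommodating the (rounded-up) bond order sum;
# aromatic bonds contribute 1.5 so benzene carbons end up with one H.
assign_implicit_h <- function(mol) {
  ordsum <- numeric(nrow(mol$atoms))
  val <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5)
  for (k in seq_len(nrow(mol$bonds))) {
    w <- val[[mol$bonds$order[k]]]
    ordsum[mol$bonds$i[k]] <- ordsum[mol$bonds$i[k]] + w
    ordsum[mol$bonds$j[k]] <- ordsum[mol$bonds$j[k]] + w
  }
  for (a in seq_len(nrow(mol$atoms))) {
    if (mol$atoms$explicit_h[a]) next
    el <- mol$atoms$element[a]
    vals <- DEFAULT_VALENCES[[el]]
    deg <- ceiling(ordsum[a] - 1e-9)
    if (is.null(vals)) {
      mol$atoms$hcount[a] <- 0L
      next
    }
    fit <- vals[vals >= deg]
    mol$atoms$hcount[a] <- if (length(fit) == 0L) 0L else as.integer(min(fit) - deg)
  }
  mol
}

parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("mol block too short", call. = FALSE)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) {
    stop("mol block: malformed counts line: ", counts, call. = FALSE)
  }
  atom_lines <- lines[4L + seq_len(natoms)]
  bond_lines <- lines[4L + natoms + seq_len(nbonds)]

  elements <- trimws(substr(atom_lines, 32, 34))
  hhh <- suppressWarnings(as.integer(substr(atom_lines, 43, 45)))
  hhh[is.na(hhh)] <- 0L
  bi <- as.integer(substr(bond_lines, 1, 3))
  bj <- as.integer(substr(bond_lines, 4, 6))
  bo <- as.integer(substr(bond_lines, 7, 9))
  if (any(is.na(bi)) || any(is.na(bj)) || any(is.na(bo))) {
    stop("mol block: malformed bond block", call. = FALSE)
  }
  if (any(bi < 1 | bi > natoms | bj < 1 | bj > natoms)) {
    stop("mol block: bond references atom out of range", call. = FALSE)
  }
  order <- ifelse(bo == 4L, "ar", as.character(bo))
  if (!all(order %in% c("1", "2", "3", "ar"))) {
    stop("mol block: unsupported bond order", call. = FALSE)
  }

  charges <- integer(natoms)
  for (ln in lines[grepl("^M  CHG", lines)]) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    cnt <- f[1]
    for (k in seq_len(cnt)) {
      charges[f[2 * k]] <- f[2 * k + 1]
    }
  }

  aromatic <- logical(natoms)
  aromatic[unique(c(bi[order == "ar"], bj[order == "ar"]))] <- TRUE

  atoms <- data.frame(element = elements, charge = charges,
                      aromatic = aromatic,
                      hcount = ifelse(hhh > 0L, hhh - 1L, NA_integer_),
                      explicit_h = hhh > 0L, stringsAsFactors = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = order, stringsAsFactors = FALSE)
  assign_implicit_h(new_molecular_graph(atoms, bonds))
}

#' Write a molecular graph as an MDL mol block
#'
#' Coordinates are zeroed (the package has no geometry), aromatic bonds are
#' written as order 4, implicit hydrogen counts go into the atom-block
#' hydrogen-count field, and formal charges into `M  CHG` lines, so that
#' re-parsing the output reproduces the input graph exactly.
#'
#' @param mol A `molecular_graph`.
#' @param title Optional molecule title line.
#' @return A single string holding the mol block.
#' @export
write_structure <- function(mol, title = "") {
  stopifnot(inherits(mol, "molecular_graph"))
  na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  header <- c(title, "  pathminer", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  atom_lines <- vapply(seq_len(na), function(a) {
    sprintf("%10.4f%10.4f%10.4f %-3s%2d%3d%3d%3d%3d%3d%3d%3d%3d%3d%3d%3d",
            0, 0, 0, mol$atoms$element[a], 0L, 0L, 0L,
            mol$atoms$hcount[a] + 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  }, character(1))
  omap <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 4L)
  bond_lines <- vapply(seq_len(nb), function(k) {
    sprintf("%3d%3d%3d%3d", mol$bonds$i[k], mol$bonds$j[k],
            omap[[mol$bonds$order[k]]], 0L)
  }, character(1))
  chg <- which(mol$atoms$charge != 0L)
  chg_lines <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf("%4d%4d", chg, mol$atoms$charge[chg]), collapse = ""))
  } else character(0)
  paste(c(header, counts, atom_lines, bond_lines, chg_lines, "M  END"),
        collapse = "\n")
}

#' Molecular formula of a graph
#'
#' Element counts including implicit hydrogens.
#'
#' @param mol A `molecular_graph`.
#' @return A named integer vector of element counts
#'   (class `molecular_formula`).
#' @examples
#' formula_string(molecular_formula(parse_structure("ON=CCc1ccc(O)c(O)c1")))
#' # "C8H9NO3"
#' @export
molecular_formula <- function(mol) {
  stopifnot(inherits(mol, "molecular_graph"))
  counts <- table(mol$atoms$element)
  f <- stats::setNames(as.integer(counts), names(counts))
  nh <- sum(mol$atoms$hcount) + if ("H" %in% names(f)) f[["H"]] else 0L
  f <- f[names(f) != "H"]
  if (nh > 0L) f <- c(f, H = as.integer(nh))
  structure(f[order(names(f))], class = "molecular_formula")
}

#' @rdname molecular_formula
#' @param formula A `molecular_formula` or named integer vector.
#' @export
formula_string <- function(formula) {
  f <- unclass(formula)
  hill <- c(intersect(c("C", "H"), names(f)),
            sort(setdiff(names(f), c("C", "H"))))
  paste(vapply(hill, function(e) {
    if (f[[e]] == 1L) e else paste0(e, f[[e]])
  }, character(1)), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(formula_string(x), "\n")
  invisible(x)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d heavy atoms, %d bonds\n",
              formula_string(molecular_formula(x)),
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# Parse "C8H9NO3"-style strings into a molecular_formula.
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    stop("malformed molecular formula: ", text, call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  els <- gsub("[0-9]", "", parts)
  cnt <- as.integer(ifelse(gsub("[A-Za-z]", "", parts) == "", "1",
                           gsub("[A-Za-z]", "", parts)))
  f <- tapply(cnt, els, sum)
  structure(stats::setNames(as.integer(f), names(f))[order(names(f))],
            class = "molecular_formula")
}
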