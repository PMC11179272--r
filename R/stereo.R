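# E/Z stereoisomer counting over C=C and C=N double bonds.
#
# A double bond is stereogenic when each terminus carries two
# distinguishable substituents. Substituents are compared by a canonical
# branch signature (element, charge, aromaticity, H count, recursively
# over sorted children; ring re-entry is marked). For divalent nitrogen
# termini (imines, oximes) the lone pair occupies the second coordination
# site and is treated as distinguishable from any substituent, so an
# aldoxime C=N-OH is stereogenic. Tetrahedral centers are never counted,
# and double bonds inside rings are excluded (no E/Z in small rings).

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# A bond is in a ring iff its endpoints stay connected after removing it.
bond_in_ring <- function(mol, bond_idx) {
  i0 <- mol$bonds$i[bond_idx]; j0 <- mol$bonds$j[bond_idx]
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    if (k == bond_idx) next
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- i0; seen[i0] <- TRUE
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (b in adj[[a]]) {
      if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
    }
  }
  seen[j0]
}

branch_signature <- function(mol, adj, atom, from, path) {
  if (atom %in% path) return("&ring")
  a <- mol$atoms[atom, ]
  children <- setdiff(adj[[atom]], from)
  kid_sigs <- character(0)
  for (ch in children) {
    k <- which((mol$bonds$i == atom & mol$bonds$j == ch) |
                 (mol$bonds$j == atom & mol$bonds$i == ch))[1]
    kid_sigs <- c(kid_sigs, paste0(mol$bonds$order[k], "~",
                                   branch_signature(mol, adj, ch, atom,
                                                    c(path, atom))))
  }
  paste0(a$element, if (a$aromatic) "a" else "", ":", a$charge,
         ":H", a$hcount,
         "(", paste(sort(kid_sigs), collapse = ","), ")")
}

terminus_substituents <- function(mol, adj, end, other_end) {
  sigs <- character(0)
  for (nb in setdiff(adj[[end]], other_end)) {
    sigs <- c(sigs, branch_signature(mol, adj, nb, end, end))
  }
  sigs <- c(sigs, rep("H()", mol$atoms$hcount[end]))
  sigs
}

#' Count double-bond (E/Z) stereoisomers
#'
#' Returns `2^k`, where `k` is the number of stereogenic C=C or C=N double
#' bonds: bonds whose two termini each carry two distinguishable
#' substituents (for divalent nitrogen, the lone pair counts as a
#' distinguishable substituent). Tetrahedral stereocenters are not counted.
#'
#' @param mol A `molecular_graph`.
#' @return An integer; 1 when no stereogenic double bond exists.
#' @examples
#' count_db_stereoisomers(parse_structure("C=C"))              # 1
#' count_db_stereoisomers(parse_structure("ON=CCc1ccc(O)c(O)c1"))  # 2 (E/Z)
#' count_db_stereoisomers(parse_structure("CC=CC=CC"))         # 4
#' @export
count_db_stereoisomers <- function(mol) {
  stopifnot(inherits(mol, "molecular_graph"))
  adj <- adjacency_list(mol)
  k <- 0L
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] != "2") next
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    els <- mol$atoms$element[c(i, j)]
    if (!(all(els == "C") || setequal(els, c("C", "N")))) next
    if (bond_in_ring(mol, b)) next
    ok <- TRUE
    for (end in c(i, j)) {
      other <- if (end == i) j else i
      subs <- terminus_substituents(mol, adj, end, other)
      if (mol$atoms$element[end] == "N" && length(subs) < 2L) {
        subs <- c(subs, "&lonepair")
      }
      if (length(subs) != 2L || subs[1] == subs[2]) { ok <- FALSE; break }
    }
    if (ok) k <- k + 1L
  }
  as.integer(2^k)
}
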