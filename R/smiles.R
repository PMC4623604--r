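# Internal SMILES / molecular-graph helpers built on ChemmineR + OpenBabel.
# Only the graph algorithms that no installed package exposes (Murcko
# pruning, rotor counting, ring membership) live here; parsing, descriptors
# and canonicalisation go through OpenBabel.

ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

#' @noRd
has_isotope <- function(smiles) {
  stringr::str_detect(smiles, "\\[[0-9]+[A-Za-z]")
}

# Element symbols appearing in a SMILES string (without parsing the full
# grammar: bracket atoms are inspected individually, the remainder is
# scanned for organic-subset tokens).
#' @noRd
smiles_elements <- function(smiles) {
  brackets <- stringr::str_match_all(smiles, "\\[([^\\]]+)\\]")[[1]][, 2]
  bracket_el <- vapply(brackets, function(b) {
    b <- stringr::str_remove(b, "^[0-9]+") # isotope mass
    if (stringr::str_sub(b, 1, 2) %in% c("se", "as")) {
      return(stringr::str_to_title(stringr::str_sub(b, 1, 2)))
    }
    first <- stringr::str_sub(b, 1, 1)
    if (first %in% c("b", "c", "n", "o", "p", "s")) return(toupper(first))
    m <- stringr::str_match(b, "^([A-Z][a-z]?)")[, 2]
    m %ifna% ""
  }, character(1), USE.NAMES = FALSE)
  rest <- stringr::str_remove_all(smiles, "\\[[^\\]]+\\]")
  plain <- stringr::str_match_all(rest, "Cl|Br|[BCNOPSFI]|[bcnops]")[[1]][, 1]
  plain <- ifelse(stringr::str_detect(plain, "^[a-z]"), toupper(plain), plain)
  unique(c(bracket_el[bracket_el != ""], plain))
}

#' @noRd
smiles_parses <- function(smiles) {
  !is.null(parse_smiles_one(smiles))
}

# Parse a single SMILES into a ChemmineR SDF object, or NULL on failure.
# OpenBabel writes its complaints to C-level stderr; they are informational.
#' @noRd
parse_smiles_one <- function(smiles) {
  res <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(res) || length(res) == 0) return(NULL)
  sdf <- res[[1]]
  ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  sdf
}

# Heavy-atom bond graph of an SDF: elements, bond matrix (a1, a2, order),
# and adjacency list. OpenBabel-written SDFs carry implicit hydrogens, so
# every atom row is heavy unless explicitly H.
#' @noRd
mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  el <- stringr::str_remove(rownames(ab), "_.*$")
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    matrix(numeric(0), ncol = 3)
  } else {
    unname(cbind(bb[, 1], bb[, 2], bb[, 3]))
  }
  heavy <- which(el != "H")
  keep_b <- bonds[, 1] %in% heavy & bonds[, 2] %in% heavy
  bonds <- bonds[keep_b, , drop = FALSE]
  n <- nrow(ab)
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  list(elements = el, heavy = heavy, bonds = bonds, adj = adj,
       coords = ab[, 1:2, drop = FALSE])
}

#' @noRd
graph_components <- function(n_atoms, adj, subset = seq_len(n_atoms)) {
  seen <- rep(FALSE, n_atoms)
  in_sub <- rep(FALSE, n_atoms); in_sub[subset] <- TRUE
  comps <- 0L
  for (s in subset) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (in_sub[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
  }
  comps
}

# Circuit rank = bonds - atoms + components: the SSSR ring count.
#' @noRd
graph_ring_count <- function(g, subset = g$heavy) {
  bonds <- g$bonds
  keep <- bonds[, 1] %in% subset & bonds[, 2] %in% subset
  m <- sum(keep)
  n <- length(subset)
  if (n == 0) return(0L)
  as.integer(m - n + graph_components(length(g$elements), g$adj, subset))
}

# A bond is in a ring iff its endpoints stay connected after removing it.
#' @noRd
bond_in_ring <- function(g, bi, subset = g$heavy) {
  a <- g$bonds[bi, 1]; b <- g$bonds[bi, 2]
  in_sub <- rep(FALSE, length(g$elements)); in_sub[subset] <- TRUE
  seen <- rep(FALSE, length(g$elements))
  queue <- a; seen[a] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in g$adj[[v]]) {
      # skip the bond under test (both orientations)
      if ((v == a && w == b) || (v == b && w == a)) next
      if (in_sub[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  seen[b]
}

# Rotatable bonds: acyclic single bonds between heavy atoms that each have
# at least one further heavy neighbour (i.e. neither end is terminal).
#' @noRd
graph_rotatable_bonds <- function(g, subset = g$heavy) {
  bonds <- g$bonds
  if (nrow(bonds) == 0) return(0L)
  in_sub <- seq_len(length(g$elements)) %in% subset
  deg <- vapply(seq_along(g$adj), function(i) {
    sum(in_sub[g$adj[[i]]])
  }, numeric(1))
  count <- 0L
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    if (!in_sub[a] || !in_sub[b]) next
    if (bonds[i, 3] != 1) next
    if (deg[a] < 2 || deg[b] < 2) next
    if (bond_in_ring(g, i, subset)) next
    count <- count + 1L
  }
  count
}

# Murcko core: iteratively prune heavy atoms of degree <= 1 within the
# remaining set. What survives is exactly the ring systems plus the linkers
# between them; acyclic molecules prune to nothing.
#' @noRd
murcko_core <- function(g) {
  keep <- g$heavy
  repeat {
    in_keep <- seq_along(g$elements) %in% keep
    deg <- vapply(keep, function(i) sum(in_keep[g$adj[[i]]]), numeric(1))
    drop <- keep[deg <= 1]
    if (length(drop) == 0 || length(keep) == 0) break
    keep <- setdiff(keep, drop)
  }
  keep
}

#' @noRd
alpha_atoms <- function(g, core) {
  if (length(core) == 0) return(integer(0))
  in_core <- seq_along(g$elements) %in% core
  nb <- unique(unlist(g$adj[core]))
  nb <- nb[!in_core[nb]]
  intersect(nb, g$heavy)
}

# Serialise a subgraph as a minimal V2000 molfile and canonicalise through
# OpenBabel. Bond orders are carried over from the (kekulised) parent.
#' @noRd
subgraph_cansmi <- function(g, atoms) {
  if (length(atoms) == 0) return("")
  map <- setNames(seq_along(atoms), atoms)
  bonds <- g$bonds[g$bonds[, 1] %in% atoms & g$bonds[, 2] %in% atoms, , drop = FALSE]
  hdr <- c("scaffold", "  idpfrag", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   length(atoms), nrow(bonds)))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        g$coords[atoms, 1], g$coords[atoms, 2], 0,
                        g$elements[atoms])
  bond_lines <- if (nrow(bonds) > 0) {
    sprintf("%3d%3d%3d  0  0  0  0",
            map[as.character(bonds[, 1])], map[as.character(bonds[, 2])],
            bonds[, 3])
  } else {
    character(0)
  }
  txt <- c(hdr, atom_lines, bond_lines, "M  END", "$$$$")
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(txt)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(NA_character_)
  tryCatch(ChemmineR::propOB(sdf)$cansmi, error = function(e) NA_character_)
}

#' @noRd
canonical_smiles <- function(sdfset) {
  ChemmineR::propOB(sdfset)$cansmi
}

# Run an obabel SMARTS filter over named SMILES; returns the ids that match.
#' @noRd
obabel_smarts_filter <- function(smiles, ids, smarts) {
  stopifnot(length(smiles) == length(ids))
  keep <- nzchar(smiles) & !is.na(smiles)
  if (!any(keep)) return(character(0))
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste(smiles[keep], ids[keep]), inp)
  out <- suppressWarnings(system2(
    "obabel", c(inp, "-osmi", "-s", shQuote(smarts)),
    stdout = TRUE, stderr = FALSE
  ))
  if (length(out) == 0) return(character(0))
  vapply(strsplit(trimws(out), "[ \t]+"), function(x) x[length(x)], character(1))
}
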