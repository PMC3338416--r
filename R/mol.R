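# Internal molecular graph layer on top of ChemmineR / OpenBabel.
#
# Molecules are parsed in batch (one OpenBabel call per library, not per
# compound) into plain R lists carrying everything the descriptor and
# scaffold code needs: element symbols, formal charges, implicit hydrogen
# counts, bond table, aromatic-atom flags and the topological (shortest
# path) distance matrix.

# MDL atom-block charge codes: 1..3 -> +3..+1, 4 -> radical, 5..7 -> -1..-3
.mdl_charge <- function(code) {
  out <- integer(length(code))
  out[code %in% 1:3] <- 4L - code[code %in% 1:3]
  out[code %in% 5:7] <- 4L - code[code %in% 5:7]
  out
}

# standard organic-subset valences used for implicit hydrogen counting
.default_valence <- c(
  C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, B = 3L,
  F = 1L, Cl = 1L, Br = 1L, I = 1L, Si = 4L, Se = 2L
)

.implicit_h <- function(element, charge, bond_order_sum) {
  val <- .default_valence[element]
  val[is.na(val)] <- 0L
  adj <- ifelse(element %in% c("N", "P"), charge,
         ifelse(element %in% c("O", "S", "Se"), charge, -abs(charge)))
  pmax(0L, as.integer(val + adj - bond_order_sum))
}

#' Canonicalize SMILES strings
#'
#' Batch-canonicalizes SMILES via OpenBabel. Strings that fail to parse are
#' flagged rather than dropped, so callers can build parse reports.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns \code{smiles} (input), \code{canonical}
#'   (canonical SMILES or \code{NA}), and logical \code{ok}.
#' @keywords internal
canonicalize_smiles <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(smiles = as.character(smiles),
                    canonical = rep(NA_character_, n),
                    ok = rep(FALSE, n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  tag <- sprintf("mol%08d", seq_len(n))
  blk <- paste(paste(smiles, tag), collapse = "\n")
  res <- suppressWarnings(tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", blk),
    error = function(e) ""))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "[ \t]+")
    can <- vapply(parts, `[`, "", 1L)
    got <- vapply(parts, function(p) p[length(p)], "")
    idx <- match(got, tag)
    keep <- !is.na(idx) & nzchar(can)
    out$canonical[idx[keep]] <- can[keep]
    out$ok[idx[keep]] <- TRUE
  }
  # an empty canonical string or a parse with no heavy atom is a failure
  out$ok[!is.na(out$canonical) & out$canonical == ""] <- FALSE
  out
}

#' Parse molecules into graph objects
#'
#' Converts SMILES into internal molecule objects used by the descriptor,
#' feature-perception and scaffold code. Parsing is batched through one
#' OpenBabel conversion; aromaticity comes from ChemmineR ring perception.
#'
#' @param smiles character vector of (preferably canonical) SMILES.
#' @param ids character vector of unique identifiers, same length.
#' @return named list of molecule objects; each is a list with elements
#'   \code{id}, \code{smiles}, \code{n_atoms}, \code{element}, \code{charge},
#'   \code{n_h} (implicit hydrogens), \code{aromatic} (logical per atom),
#'   \code{bonds} (data.frame a1, a2, order), \code{dist} (topological
#'   distance matrix), and \code{degree}.
#' @keywords internal
parse_molecules <- function(smiles, ids = names(smiles)) {
  stopifnot(length(smiles) == length(ids), !anyDuplicated(ids))
  if (length(smiles) == 0L) return(structure(list(), names = character()))
  x <- as.character(smiles)
  names(x) <- ids
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(x))
  lapply(seq_along(sdf@SDF), function(i) {
    s <- sdf@SDF[[i]]
    ab <- s@atomblock
    bb <- s@bondblock
    if (length(ab) == 0L || is.null(dim(ab)) || ncol(ab) < 3L) {
      # ChemmineR mangles zero-bond molecules; reparse the molblock directly
      mb <- .read_molblock(suppressWarnings(
        ChemmineOB::convertFormat("SMI", "SDF", paste0(x[i], "\n"))))
      elem <- mb$element
      n <- length(elem)
      charge <- mb$charge
      bonds <- mb$bonds
    } else {
      elem <- sub("_.*$", "", rownames(ab))
      n <- length(elem)
      # MDL atom-line fields: x y z (C1..C3), symbol (rowname), mass diff
      # (C5), charge code (C6)
      charge <- if ("C6" %in% colnames(ab)) .mdl_charge(as.integer(ab[, "C6"])) else integer(n)
      if (length(bb) == 0L || is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
        bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
      } else {
        bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                            order = as.integer(bb[, 3]))
      }
    }
    bsum <- integer(n)
    deg <- integer(n)
    if (nrow(bonds)) {
      for (k in seq_len(nrow(bonds))) {
        bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + bonds$order[k]
        bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + bonds$order[k]
        deg[bonds$a1[k]] <- deg[bonds$a1[k]] + 1L
        deg[bonds$a2[k]] <- deg[bonds$a2[k]] + 1L
      }
    }
    arom <- logical(n)
    if (nrow(bonds)) {
      rr <- tryCatch(ChemmineR::rings(sdf[i], type = "all", arom = TRUE),
                     error = function(e) NULL)
      if (!is.null(rr) && length(rr$RINGS)) {
        for (j in seq_along(rr$RINGS)) {
          if (isTRUE(rr$AROMATIC[[j]])) {
            at <- as.integer(sub("^.*_", "", rr$RINGS[[j]]))
            arom[at] <- TRUE
          }
        }
      }
    }
    if (nrow(bonds)) {
      g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
      if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
      dmat <- igraph::distances(g)
    } else {
      dmat <- matrix(0, n, n)
    }
    list(id = names(x)[i], smiles = unname(x[i]), n_atoms = n,
         element = elem, charge = charge,
         n_h = .implicit_h(elem, charge, bsum),
         aromatic = arom, bonds = bonds, dist = dmat, degree = deg)
  }) -> mols
  names(mols) <- ids
  mols
}

# Minimal V2000 molblock text parser, used only as a fallback for molecules
# whose SDF representation ChemmineR cannot hold (zero-bond molecules).
.read_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  cnt <- lines[4]
  na <- as.integer(substr(cnt, 1, 3))
  nb <- as.integer(substr(cnt, 4, 6))
  atoms <- lines[4 + seq_len(na)]
  elem <- trimws(substr(atoms, 32, 34))
  code <- suppressWarnings(as.integer(trimws(substr(atoms, 37, 39))))
  code[is.na(code)] <- 0L
  charge <- .mdl_charge(code)
  bonds <- if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    data.frame(a1 = as.integer(substr(bl, 1, 3)),
               a2 = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(a1 = integer(), a2 = integer(), order = integer())
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charge[f[2 * j]] <- f[2 * j + 1]
  }
  list(element = elem, charge = charge, bonds = bonds)
}

# Write a minimal V2000 molblock for an induced subgraph of a molecule.
.subgraph_molblock <- function(mol, keep, title = "frag") {
  keep <- sort(keep)
  idx <- match(seq_len(mol$n_atoms), keep)  # old -> new index or NA
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  na <- length(keep)
  nb <- nrow(b)
  atoms <- vapply(seq_len(na), function(j) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            j * 1.0, 0, 0, mol$element[keep[j]])
  }, "")
  bondl <- if (nb) vapply(seq_len(nb), function(k) {
    sprintf("%3d%3d%3d  0  0  0  0", idx[b$a1[k]], idx[b$a2[k]], b$order[k])
  }, "") else character()
  chg <- which(mol$charge[keep] != 0L)
  chgl <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf(" %3d %3d", chg, mol$charge[keep][chg]), collapse = ""))
  } else character()
  paste(c(title, "", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
          atoms, bondl, chgl, "M  END", "$$$$"), collapse = "\n")
}

# Canonical SMILES for one induced subgraph (used by the scaffold code).
.subgraph_smiles_batch <- function(mols, keeps) {
  stopifnot(length(mols) == length(keeps))
  if (!length(mols)) return(character())
  blocks <- vapply(seq_along(mols), function(i) {
    .subgraph_molblock(mols[[i]], keeps[[i]], title = sprintf("frag%08d", i))
  }, "")
  res <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN",
                                                    paste(blocks, collapse = "\n")))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  out <- rep(NA_character_, length(mols))
  if (length(lines)) {
    parts <- strsplit(lines, "[ \t]+")
    can <- vapply(parts, `[`, "", 1L)
    got <- vapply(parts, function(p) p[length(p)], "")
    idx <- match(got, sprintf("frag%08d", seq_along(mols)))
    out[idx[!is.na(idx)]] <- can[!is.na(idx)]
  }
  out
}

#' Generate alternative SMILES writings of the same molecule
#'
#' Produces non-canonical SMILES by permuting atom order before conversion;
#' used to test that descriptors are invariant under atom renumbering.
#'
#' @param smiles a single SMILES string.
#' @param n number of alternative writings.
#' @param seed integer seed for the permutations.
#' @return character vector of SMILES (possibly with duplicates), all
#'   describing the same molecular graph.
#' @keywords internal
randomize_smiles <- function(smiles, n = 5L, seed = 1L) {
  mol <- parse_molecules(smiles, "x")[[1]]
  set.seed(seed)
  blocks <- vapply(seq_len(n), function(i) {
    perm <- sample.int(mol$n_atoms)
    m2 <- mol
    m2$element <- mol$element[perm]
    m2$charge <- mol$charge[perm]
    inv <- order(perm)  # old atom index -> new position
    m2$bonds <- data.frame(a1 = inv[mol$bonds$a1], a2 = inv[mol$bonds$a2],
                           order = mol$bonds$order)
    .subgraph_molblock(m2, seq_len(m2$n_atoms), title = sprintf("r%08d", i))
  }, "")
  res <- suppressWarnings(ChemmineOB::convertFormat("SDF", "SMI",
                                                    paste(blocks, collapse = "\n")))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[ \t]+"), `[`, "", 1L)
}
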