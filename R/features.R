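# Pharmacophore feature perception and the three 2D descriptor spaces used
# for ligand-based target profiling: SHED-style feature-pair distance
# entropies (fuzziest), FPD feature-pair distance histograms, and PHRAG
# feature-sequence path fragments (most structure-preserving). All three
# are functions of the molecular graph only, hence invariant under atom
# renumbering / alternative SMILES writings.

.features <- c("donor", "acceptor", "positive", "negative",
               "hydrophobic", "aromatic")
.feature_abbrev <- c(donor = "D", acceptor = "A", positive = "P",
                     negative = "N", hydrophobic = "H", aromatic = "R")
.dist_cap <- 10L

.feature_pairs <- local({
  p <- expand.grid(i = seq_along(.features), j = seq_along(.features))
  p <- p[p$i <= p$j, ]
  data.frame(f = .features[p$i], g = .features[p$j],
             name = paste(.features[p$i], .features[p$j], sep = ":"),
             stringsAsFactors = FALSE)
})

.as_mol <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    m <- parse_molecules(x, "query")
    if (!length(m)) stop("unparseable SMILES: ", x)
    m[[1]]
  } else x
}

#' Assign pharmacophore features to atoms
#'
#' Rule set: donor = N/O bearing at least one hydrogen; acceptor = N/O with
#' a lone pair (i.e. not positively charged); positive / negative = sign of
#' the formal charge; hydrophobic = carbon with no N/O neighbor; aromatic =
#' member of an aromatic ring. An atom may carry several features or none.
#'
#' @param x SMILES string or an internal molecule object.
#' @return logical matrix, one row per heavy atom, columns \code{donor},
#'   \code{acceptor}, \code{positive}, \code{negative}, \code{hydrophobic},
#'   \code{aromatic}.
#' @export
perceive_features <- function(x) {
  mol <- .as_mol(x)
  n <- mol$n_atoms
  no <- mol$element %in% c("N", "O")
  # neighbors-of-N/O mask for the hydrophobic rule
  near_no <- logical(n)
  if (nrow(mol$bonds)) {
    b <- mol$bonds
    near_no[b$a1[no[b$a2]]] <- TRUE
    near_no[b$a2[no[b$a1]]] <- TRUE
  }
  m <- cbind(
    donor = no & mol$n_h >= 1L,
    acceptor = no & mol$charge <= 0L,
    positive = mol$charge > 0L,
    negative = mol$charge < 0L,
    hydrophobic = mol$element == "C" & !near_no,
    aromatic = mol$aromatic
  )
  rownames(m) <- paste0(mol$element, "_", seq_len(n))
  m
}

# Capped topological distances for one feature pair as a count vector over
# distances 1..cap. Unordered atom pairs {a, b}, a != b, where one atom
# carries f and the other carries g (in either orientation), counted once.
.pair_distance_counts <- function(dmat, fa, ga) {
  n <- nrow(dmat)
  if (!any(fa) || !any(ga)) return(integer(.dist_cap))
  sel <- (outer(fa, ga, `&`) | outer(ga, fa, `&`)) & upper.tri(dmat)
  d <- dmat[sel]
  if (!length(d)) return(integer(.dist_cap))
  d[!is.finite(d) | d > .dist_cap] <- .dist_cap
  tabulate(as.integer(d), nbins = .dist_cap)
}

.shannon_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' SHED-style feature-pair entropy descriptor
#'
#' For each of the 21 unordered pharmacophore feature pairs, the topological
#' shortest-path distances between atoms carrying the two features are
#' collected (capped at 10 bonds) and the entry is the Shannon entropy
#' (bits) of the normalized distance distribution; pairs with no atom pair
#' contribute 0. The fuzziest of the three descriptor spaces.
#'
#' @param x SMILES string or molecule object.
#' @return numeric vector of length 21 with attribute \code{space = "SHED"}.
#' @export
shed_descriptor <- function(x) {
  mol <- .as_mol(x)
  fm <- perceive_features(mol)
  v <- vapply(seq_len(nrow(.feature_pairs)), function(k) {
    .shannon_bits(.pair_distance_counts(mol$dist, fm[, .feature_pairs$f[k]],
                                        fm[, .feature_pairs$g[k]]))
  }, 0)
  names(v) <- .feature_pairs$name
  structure(v, space = "SHED")
}

#' FPD feature-pair distance-histogram descriptor
#'
#' Concatenation of the 21 per-feature-pair histograms of topological
#' distances 1..10 (longer paths pooled into the last bin), each histogram
#' normalized to sum 1 or left all-zero when the pair is absent.
#'
#' @param x SMILES string or molecule object.
#' @return numeric vector of length 210 with attribute \code{space = "FPD"}.
#' @export
fpd_descriptor <- function(x) {
  mol <- .as_mol(x)
  fm <- perceive_features(mol)
  v <- unlist(lapply(seq_len(nrow(.feature_pairs)), function(k) {
    ct <- .pair_distance_counts(mol$dist, fm[, .feature_pairs$f[k]],
                                fm[, .feature_pairs$g[k]])
    s <- sum(ct)
    h <- if (s > 0) ct / s else rep(0, .dist_cap)
    names(h) <- paste0(.feature_pairs$name[k], "|d", seq_len(.dist_cap))
    h
  }))
  structure(v, space = "FPD")
}

# composite per-atom label: sorted feature abbreviations, "0" if featureless
.atom_labels <- function(fm) {
  apply(fm, 1L, function(r) {
    ab <- .feature_abbrev[.features[r]]
    if (!length(ab)) "0" else paste(sort(ab), collapse = "")
  })
}

#' PHRAG feature-sequence fragment descriptor
#'
#' Bag (multiset) of length-3 pharmacophore-feature sequences read along
#' shortest paths: for every central atom and every pair of its neighbors
#' at topological distance 2 from each other, the sequence of composite
#' atom feature labels is recorded (direction-canonicalized). The most
#' structure-preserving of the three spaces.
#'
#' @param x SMILES string or molecule object.
#' @return named integer vector (fragment -> count) with attribute
#'   \code{space = "PHRAG"}.
#' @export
phrag_descriptor <- function(x) {
  mol <- .as_mol(x)
  fm <- perceive_features(mol)
  lab <- .atom_labels(fm)
  frags <- character()
  if (nrow(mol$bonds)) {
    adj <- lapply(seq_len(mol$n_atoms), function(i) integer())
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    for (j in seq_len(mol$n_atoms)) {
      nb <- adj[[j]]
      if (length(nb) < 2L) next
      cmb <- utils::combn(nb, 2L)
      for (c2 in seq_len(ncol(cmb))) {
        i <- cmb[1, c2]; k <- cmb[2, c2]
        if (mol$dist[i, k] != 2) next  # triangle: i-j-k is not a shortest path
        fwd <- paste(lab[i], lab[j], lab[k], sep = "-")
        rev <- paste(lab[k], lab[j], lab[i], sep = "-")
        frags <- c(frags, min(fwd, rev))
      }
    }
  }
  bag <- if (length(frags)) {
    t <- table(frags)
    structure(as.integer(t), names = names(t))
  } else structure(integer(), names = character())
  structure(bag, space = "PHRAG")
}

#' Compute all three descriptor spaces for a molecule
#'
#' @param x SMILES string or molecule object.
#' @return list with elements \code{SHED}, \code{FPD}, \code{PHRAG}.
#' @export
descriptor_set <- function(x) {
  mol <- .as_mol(x)
  list(SHED = shed_descriptor(mol), FPD = fpd_descriptor(mol),
       PHRAG = phrag_descriptor(mol))
}

#' Distance between two descriptor vectors
#'
#' SHED and FPD use Euclidean distance; PHRAG uses one minus the multiset
#' Jaccard similarity (intersection over union of fragment counts). Both
#' vectors must come from the same descriptor space.
#'
#' @param a,b descriptor vectors as returned by the descriptor functions.
#' @return non-negative distance; 0 for identical descriptors.
#' @export
molecule_distance <- function(a, b) {
  sa <- attr(a, "space"); sb <- attr(b, "space")
  if (is.null(sa) || is.null(sb) || sa != sb)
    stop("descriptor space mismatch: ", sa %||% "?", " vs ", sb %||% "?")
  if (sa %in% c("SHED", "FPD")) {
    sqrt(sum((as.numeric(a) - as.numeric(b))^2))
  } else if (sa == "PHRAG") {
    keys <- union(names(a), names(b))
    if (!length(keys)) return(0)
    ca <- structure(integer(length(keys)), names = keys)
    cb <- ca
    ca[names(a)] <- a
    cb[names(b)] <- b
    inter <- sum(pmin(ca, cb))
    uni <- sum(pmax(ca, cb))
    if (uni == 0) 0 else 1 - inter / uni
  } else stop("unknown descriptor space: ", sa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
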