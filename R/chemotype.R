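# Chemotype analysis: Bemis-Murcko framework assignment, scaffold
# clustering, cytotoxicity enrichment scoring, enrichment-guided expansion
# of the screening set, and a generic greedy MaxMin diversity picker.

# Iteratively prune atoms of degree <= 1; what survives is the ring +
# linker framework. Returns the kept atom indices (empty for acyclic).
.framework_atoms <- function(mol) {
  keep <- rep(TRUE, mol$n_atoms)
  b <- mol$bonds
  repeat {
    deg <- integer(mol$n_atoms)
    bb <- b[keep[b$a1] & keep[b$a2], , drop = FALSE]
    if (nrow(bb)) {
      t1 <- table(factor(bb$a1, levels = seq_len(mol$n_atoms)))
      t2 <- table(factor(bb$a2, levels = seq_len(mol$n_atoms)))
      deg <- as.integer(t1) + as.integer(t2)
    }
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  which(keep)
}

# Batch scaffold keys for a list of parsed molecules.
.murcko_keys <- function(mols) {
  keeps <- lapply(mols, .framework_atoms)
  ringy <- lengths(keeps) > 0L
  keys <- vapply(mols, `[[`, "", "smiles")  # acyclic: own canonical SMILES
  if (any(ringy)) {
    fr <- .subgraph_smiles_batch(mols[ringy], keeps[ringy])
    # canonicalize through the same SMILES pipeline for a stable key
    can <- canonicalize_smiles(fr)
    fr[can$ok] <- can$canonical[can$ok]
    keys[ringy] <- fr
  }
  names(keys) <- names(mols)
  keys
}

#' Bemis-Murcko chemotype key of a compound
#'
#' Ring-containing molecules map to the canonical SMILES of their
#' ring-plus-linker framework (all side-chain atoms pruned); acyclic
#' molecules are their own singleton chemotype (canonical SMILES of the
#' whole molecule).
#'
#' @param x SMILES string or molecule object.
#' @return scaffold key (canonical SMILES string).
#' @export
assign_chemotype <- function(x) {
  if (is.character(x)) {
    can <- canonicalize_smiles(x)
    if (!can$ok[1]) stop("unparseable SMILES: ", x)
    x <- parse_molecules(can$canonical[1], "query")[[1]]
  }
  unname(.murcko_keys(list(q = x)))
}

#' Cluster a compound library by chemotype
#'
#' Partitions the library by Bemis-Murcko scaffold key; every compound falls
#' in exactly one cluster.
#'
#' @param lib \code{compound_library}.
#' @return data frame of class \code{chemotype_clusters}: \code{scaffold_key},
#'   \code{n_members}, and list-column \code{member_ids}; plus a
#'   \code{membership} attribute (named chr vector compound id -> key).
#' @export
cluster_library <- function(lib) {
  if (nrow(lib) == 0L) {
    out <- data.frame(scaffold_key = character(), n_members = integer())
    out$member_ids <- list()
    attr(out, "membership") <- character()
    class(out) <- c("chemotype_clusters", "data.frame")
    return(out)
  }
  mols <- parse_molecules(lib$smiles, lib$id)
  keys <- .murcko_keys(mols)
  sp <- split(names(keys), keys)
  out <- data.frame(scaffold_key = names(sp),
                    n_members = lengths(sp), stringsAsFactors = FALSE)
  out$member_ids <- unname(sp)
  out <- out[order(-out$n_members, out$scaffold_key), ]
  rownames(out) <- NULL
  attr(out, "membership") <- keys
  class(out) <- c("chemotype_clusters", "data.frame")
  out
}

#' Cytotoxicity enrichment score of a chemotype cluster
#'
#' score = |members in the selective set| / |members in the tested set|;
#' undefined (NA) when no member was tested.
#'
#' @param member_ids compound ids of the cluster.
#' @param selective_ids ids in the selective (e.g. tumor_strong) set; must
#'   be a subset of \code{tested_ids}.
#' @param tested_ids ids with dose-response data.
#' @return numeric score in [0, 1], or NA when no member was tested.
#' @export
enrichment_score <- function(member_ids, selective_ids, tested_ids) {
  if (!all(selective_ids %in% tested_ids))
    stop("selective_ids must be a subset of tested_ids")
  n_tested <- length(intersect(member_ids, tested_ids))
  if (n_tested == 0L) return(NA_real_)
  length(intersect(member_ids, selective_ids)) / n_tested
}

#' Score every chemotype cluster
#'
#' @param clusters \code{chemotype_clusters} from \code{\link{cluster_library}}.
#' @inheritParams enrichment_score
#' @return the cluster table with added columns \code{n_tested},
#'   \code{n_selective}, \code{enrichment} (NA when untested).
#' @export
score_clusters <- function(clusters, selective_ids, tested_ids) {
  if (!all(selective_ids %in% tested_ids))
    stop("selective_ids must be a subset of tested_ids")
  clusters$n_tested <- vapply(clusters$member_ids, function(m)
    length(intersect(m, tested_ids)), 0L)
  clusters$n_selective <- vapply(clusters$member_ids, function(m)
    length(intersect(m, selective_ids)), 0L)
  clusters$enrichment <- ifelse(clusters$n_tested > 0L,
                                clusters$n_selective / pmax(clusters$n_tested, 1L),
                                NA_real_)
  clusters
}

#' Select untested compounds from enriched chemotypes
#'
#' Returns the untested members of every cluster whose enrichment is
#' defined and strictly greater than the hit-rate threshold, ordered by
#' cluster enrichment (descending) then compound id.
#'
#' @param clusters scored clusters (see \code{\link{score_clusters}}).
#' @param untested_ids pool of compounds without dose-response data.
#' @param hit_rate_threshold strict lower bound on cluster enrichment
#'   (default 0.20, i.e. "higher than 20% hit rate").
#' @return character vector of selected compound ids.
#' @export
select_expansion <- function(clusters, untested_ids, hit_rate_threshold = 0.20) {
  stopifnot(hit_rate_threshold >= 0, hit_rate_threshold <= 1,
            "enrichment" %in% names(clusters))
  keep <- !is.na(clusters$enrichment) & clusters$enrichment > hit_rate_threshold
  if (!any(keep)) return(character())
  rows <- clusters[keep, ]
  picks <- lapply(seq_len(nrow(rows)), function(i) {
    ids <- sort(intersect(rows$member_ids[[i]], untested_ids))
    if (length(ids)) data.frame(id = ids, enr = rows$enrichment[i]) else NULL
  })
  picks <- do.call(rbind, picks)
  if (is.null(picks)) return(character())
  picks <- picks[order(-picks$enr, picks$id), ]
  unique(picks$id)
}

#' Greedy MaxMin diversity selection
#'
#' Starts from the compound with the largest summed distance to all others
#' and greedily adds the compound whose minimum distance to the chosen set
#' is maximal; ties are broken by compound id. Distances are Euclidean in
#' SHED descriptor space unless a precomputed distance matrix is supplied.
#' The procedure is deterministic; \code{seed} is accepted for interface
#' stability but not used.
#'
#' @param lib \code{compound_library}.
#' @param k number of compounds to select (0 <= k <= nrow(lib)).
#' @param seed unused; the start rule is deterministic.
#' @param dist_matrix optional symmetric distance matrix with dimnames
#'   matching the library ids.
#' @return character vector of k selected compound ids (selection order).
#' @export
diversity_select <- function(lib, k, seed = NULL, dist_matrix = NULL) {
  n <- nrow(lib)
  if (k > n) stop("k exceeds library size")
  if (k <= 0L) return(character())
  ids <- lib$id
  if (is.null(dist_matrix)) {
    mols <- parse_molecules(lib$smiles, ids)
    desc <- vapply(mols, function(m) as.numeric(shed_descriptor(m)), numeric(21))
    dist_matrix <- as.matrix(stats::dist(t(desc)))
    dimnames(dist_matrix) <- list(ids, ids)
  } else {
    dist_matrix <- dist_matrix[ids, ids]
  }
  ord <- order(ids)  # id order for tie-breaking
  total <- rowSums(dist_matrix)
  cand <- which(total == max(total))
  chosen <- cand[order(ids[cand])][1]
  sel <- chosen
  mind <- dist_matrix[, chosen]
  while (length(sel) < k) {
    rest <- setdiff(seq_len(n), sel)
    best <- max(mind[rest])
    cand <- rest[mind[rest] == best]
    nxt <- cand[order(ids[cand])][1]
    sel <- c(sel, nxt)
    mind <- pmin(mind, dist_matrix[, nxt])
  }
  ids[sel]
}
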