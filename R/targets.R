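# Ligand-based virtual target profiling: per-protein ensembles of ligand
# descriptors define a target model; a query compound is predicted against
# a model by inverse-distance-weighted (IDW) interpolation of the known
# ligand affinities, restricted to neighbors inside the model's
# applicability radius (per descriptor space).

.spaces <- c("SHED", "FPD", "PHRAG")

# nearest-neighbor distance of each reference to the other references;
# exact descriptor duplicates (distance 0) are not informative neighbors,
# so the NN is the smallest positive distance per reference
.nn_distances <- function(desc_list) {
  n <- length(desc_list)
  if (n < 2L) return(numeric())
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- molecule_distance(desc_list[[i]], desc_list[[j]])
  }
  nn <- vapply(seq_len(n), function(i) {
    v <- d[i, -i]
    v <- v[v > 0]
    if (length(v)) min(v) else NA_real_
  }, 0)
  nn[!is.na(nn)]
}

#' Build ligand-based target models from a chemogenomics database
#'
#' One model per target holds the descriptors (in all three spaces) and
#' pAct values of every ligand with measured affinity for that target,
#' plus a per-space applicability radius. By default the radius is the 95th
#' percentile of the target's intra-ensemble nearest-neighbor distances
#' (floored at 1e-6); single-ligand targets fall back to the pooled
#' percentile across all targets.
#'
#' @param db \code{chemogenomics_db}.
#' @param min_ligands minimum number of reference ligands a target needs;
#'   targets below it are excluded (and listed in the result's
#'   \code{excluded} attribute).
#' @param radius optional named numeric (per space) fixed applicability
#'   radius overriding the data-driven default.
#' @param radius_quantile quantile of nearest-neighbor distances used for
#'   the data-driven radius.
#' @param radius_floor lower bound on any radius.
#' @return object of class \code{target_model_set}: named list of models,
#'   each with \code{target_id}, \code{ligand_id}, \code{pact},
#'   \code{descriptors} (per space) and \code{radius} (per space).
#' @export
build_target_models <- function(db, min_ligands = 1L, radius = NULL,
                                radius_quantile = 0.95, radius_floor = 1e-6) {
  if (nrow(db) == 0L) stop("empty chemogenomics database")
  lig <- unique(as.data.frame(db)[c("ligand_id", "smiles")])
  mols <- parse_molecules(lig$smiles, lig$ligand_id)
  desc <- lapply(mols, descriptor_set)
  sp <- split(as.data.frame(db), db$target_id)
  n_lig <- vapply(sp, nrow, 0L)
  excluded <- names(sp)[n_lig < min_ligands]
  sp <- sp[n_lig >= min_ligands]
  if (!length(sp)) stop("no target has >= ", min_ligands, " ligands")
  models <- lapply(sp, function(d) {
    dd <- lapply(.spaces, function(s) lapply(desc[d$ligand_id], `[[`, s))
    names(dd) <- .spaces
    list(target_id = d$target_id[1], ligand_id = d$ligand_id,
         pact = d$pact, descriptors = dd)
  })
  # per-space radii: per-target NN percentile. Targets without a defined
  # NN spread (single ligand, or all references descriptor-identical) fall
  # back to the pooled median NN distance -- the typical nearest-neighbor
  # spacing in the database -- rather than the pooled upper percentile,
  # since a degenerate ensemble is maximally tight, not maximally wide.
  nn <- lapply(.spaces, function(s)
    lapply(models, function(m) .nn_distances(m$descriptors[[s]])))
  names(nn) <- .spaces
  pooled <- vapply(.spaces, function(s) {
    v <- unlist(nn[[s]])
    if (length(v)) max(radius_floor, stats::median(v))
    else radius_floor
  }, 0)
  for (t in names(models)) {
    models[[t]]$radius <- vapply(.spaces, function(s) {
      if (!is.null(radius) && s %in% names(radius)) return(max(radius_floor, radius[[s]]))
      v <- nn[[s]][[t]]
      if (length(v)) max(radius_floor, stats::quantile(v, radius_quantile, names = FALSE))
      else pooled[[s]]
    }, 0)
  }
  structure(models, class = "target_model_set", excluded = excluded,
            radius_quantile = radius_quantile)
}

#' @export
print.target_model_set <- function(x, ...) {
  cat(sprintf("Target model set: %d targets (%d excluded), %s ligands/target median\n",
              length(x), length(attr(x, "excluded")),
              format(stats::median(vapply(x, function(m) length(m$pact), 0)))))
  invisible(x)
}

#' Predict the affinity of a compound for one target model
#'
#' Neighbors are the model's reference ligands within the applicability
#' radius of the chosen descriptor space. With no neighbor the compound is
#' outside the applicability domain and no prediction is made. Exact
#' descriptor matches (distance 0) return the mean pAct of the matching
#' references; otherwise the prediction is the inverse-distance-weighted
#' mean sum(d^-power * pAct) / sum(d^-power), which is always bounded by
#' the neighbors' pAct range.
#'
#' @param x SMILES, molecule object, or a descriptor list from
#'   \code{\link{descriptor_set}}.
#' @param model a single target model from \code{\link{build_target_models}}.
#' @param space descriptor space, one of \code{"SHED"}, \code{"FPD"},
#'   \code{"PHRAG"}.
#' @param power IDW exponent (default 2).
#' @return list with \code{pact} and \code{n_neighbors}, or \code{NULL}
#'   when the compound is outside the applicability domain.
#' @export
predict_affinity <- function(x, model, space = "SHED", power = 2) {
  stopifnot(space %in% .spaces)
  d <- if (is.list(x) && !is.null(x[[space]])) x[[space]]
       else descriptor_set(.as_mol(x))[[space]]
  dist <- vapply(model$descriptors[[space]], function(r)
    molecule_distance(d, r), 0)
  nb <- which(dist <= model$radius[[space]])
  if (!length(nb)) return(NULL)
  zero <- nb[dist[nb] == 0]
  pact <- if (length(zero)) {
    mean(model$pact[zero])
  } else {
    w <- dist[nb]^(-power)
    sum(w * model$pact[nb]) / sum(w)
  }
  list(pact = pact, n_neighbors = length(nb))
}

#' Predict the full target profile of a compound
#'
#' Runs \code{\link{predict_affinity}} against every model in all three
#' descriptor spaces. A target is reported when at least one space yields a
#' prediction; the reported pAct is the maximum over predicting spaces
#' (permissive consensus) and the producing space is recorded.
#'
#' @param x SMILES, molecule object or descriptor list.
#' @param models \code{target_model_set}.
#' @param compound_id id to stamp on the result rows.
#' @param power IDW exponent.
#' @return data frame: compound_id, target_id, pact_pred, space,
#'   n_neighbors (possibly 0 rows when the compound is outside every
#'   model's applicability domain).
#' @export
profile_compound <- function(x, models, compound_id = "query", power = 2) {
  desc <- if (is.list(x) && all(.spaces %in% names(x))) x
          else descriptor_set(.as_mol(x))
  rows <- lapply(models, function(m) {
    best <- NULL
    for (s in .spaces) {
      p <- predict_affinity(desc, m, s, power)
      if (!is.null(p) && (is.null(best) || p$pact > best$pact))
        best <- c(p, space = s)
    }
    if (is.null(best)) return(NULL)
    data.frame(compound_id = compound_id, target_id = m$target_id,
               pact_pred = best$pact, space = best$space,
               n_neighbors = best$n_neighbors, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(compound_id = character(), target_id = character(),
                      pact_pred = numeric(), space = character(),
                      n_neighbors = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Profile every compound of a library against a model set
#'
#' @param lib \code{compound_library}.
#' @param models \code{target_model_set}.
#' @param power IDW exponent.
#' @return data frame of predicted interactions (see
#'   \code{\link{profile_compound}}).
#' @export
profile_library <- function(lib, models, power = 2) {
  if (nrow(lib) == 0L)
    return(profile_compound("C", list(), "drop"))  # empty frame, right shape
  mols <- parse_molecules(lib$smiles, lib$id)
  out <- do.call(rbind, lapply(lib$id, function(id)
    profile_compound(descriptor_set(mols[[id]]), models, id, power)))
  rownames(out) <- NULL
  out
}

#' Filter predicted interactions by potency
#'
#' @param interactions data frame with a \code{pact_pred} column.
#' @param pact_min inclusive pAct cutoff (default 6, i.e. 1 uM or better).
#' @return filtered data frame.
#' @export
filter_potent <- function(interactions, pact_min = 6.0) {
  interactions[interactions$pact_pred >= pact_min, , drop = FALSE]
}

#' Coverage statistics of a profiling run
#'
#' @param compound_ids ids of all compounds that were profiled (the
#'   denominator of the coverage percentage).
#' @param interactions predicted interactions for those compounds.
#' @param pact_min potency filter applied for the filtered statistics.
#' @return list: n_compounds, n_covered (>= 1 prediction), pct_covered
#'   (rounded to integer), n_interactions, n_filtered,
#'   n_molecules_filtered, n_targets_filtered, targets_per_molecule
#'   (filtered interactions per predicted molecule, rounded to integer).
#' @export
profile_summary <- function(compound_ids, interactions, pact_min = 6.0) {
  n <- length(compound_ids)
  covered <- unique(interactions$compound_id)
  filt <- filter_potent(interactions, pact_min)
  nm <- length(unique(filt$compound_id))
  list(n_compounds = n,
       n_covered = length(covered),
       pct_covered = if (n > 0) round(100 * length(covered) / n) else 0,
       n_interactions = nrow(interactions),
       n_filtered = nrow(filt),
       n_molecules_filtered = nm,
       n_targets_filtered = length(unique(filt$target_id)),
       targets_per_molecule = if (nm > 0) round(nrow(filt) / nm) else 0)
}
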