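# Differential target-set analytics: Venn partition of the tumor- and
# normal-profile target lists, protein family / enzyme class composition,
# OncoScore prioritization, drug polypharmacology ranking and pathway
# overlap counting.

#' Partition two target sets into a Venn diagram
#'
#' @param tumor_targets targets predicted for the tumor-selective compounds.
#' @param normal_targets targets predicted for the normal-selective
#'   compounds.
#' @return list of class \code{venn_partition}: \code{tumor_unique},
#'   \code{shared}, \code{normal_unique} (sorted character vectors) and
#'   \code{sizes} (named integer vector).
#' @export
venn_partition <- function(tumor_targets, normal_targets) {
  t <- unique(as.character(tumor_targets))
  n <- unique(as.character(normal_targets))
  out <- list(tumor_unique = sort(setdiff(t, n)),
              shared = sort(intersect(t, n)),
              normal_unique = sort(setdiff(n, t)))
  out$sizes <- c(tumor_unique = length(out$tumor_unique),
                 shared = length(out$shared),
                 normal_unique = length(out$normal_unique))
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition: %d tumor-unique | %d shared | %d normal-unique\n",
              x$sizes[1], x$sizes[2], x$sizes[3]))
  invisible(x)
}

.annot_lookup <- function(target_set, annotations, column) {
  i <- match(target_set, annotations$target_id)
  annotations[[column]][i]
}

#' Protein family composition of a target set
#'
#' Targets missing from the annotations are counted as family "other".
#'
#' @param target_set character vector of target ids.
#' @param annotations \code{target_annotations}.
#' @return list with \code{counts} (named integer) and \code{percent}
#'   (named, rounded to nearest integer); empty for an empty set.
#' @export
family_composition <- function(target_set, annotations) {
  target_set <- unique(target_set)
  if (!length(target_set)) return(list(counts = integer(), percent = numeric()))
  fam <- .annot_lookup(target_set, annotations, "family")
  fam[is.na(fam)] <- "other"
  counts <- table(factor(fam, levels = .family_levels))
  counts <- counts[counts > 0]
  list(counts = structure(as.integer(counts), names = names(counts)),
       percent = structure(round(100 * as.integer(counts) / length(target_set)),
                           names = names(counts)))
}

#' Enzyme class composition of a target set
#'
#' As \code{\link{family_composition}} but restricted to the enzymes in the
#' set, with percentages over the enzyme count.
#'
#' @inheritParams family_composition
#' @return list with \code{counts} and \code{percent} per EC top class;
#'   empty when the set contains no annotated enzyme.
#' @export
enzyme_class_composition <- function(target_set, annotations) {
  target_set <- unique(target_set)
  fam <- .annot_lookup(target_set, annotations, "family")
  enz <- target_set[!is.na(fam) & fam == "enzyme"]
  if (!length(enz)) return(list(counts = integer(), percent = numeric()))
  ec <- .annot_lookup(enz, annotations, "ec_class")
  counts <- table(factor(ec, levels = setdiff(.ec_levels, "none")))
  counts <- counts[counts > 0]
  list(counts = structure(as.integer(counts), names = names(counts)),
       percent = structure(round(100 * as.integer(counts) / length(enz)),
                           names = names(counts)))
}

#' Percentage of a target set with OncoScore above a cutoff
#'
#' Strictly-above comparison; targets without a score stay in the
#' denominator (they can never exceed the cutoff), mirroring how the NA
#' category is carried in cumulative OncoScore curves.
#'
#' @param target_set character vector of target ids.
#' @param annotations \code{target_annotations}.
#' @param cutoff OncoScore cutoff in [0, 1].
#' @return percentage rounded to one decimal.
#' @export
oncoscore_cumulative <- function(target_set, annotations, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  target_set <- unique(target_set)
  if (!length(target_set)) return(0)
  sc <- .annot_lookup(target_set, annotations, "oncoscore")
  round(100 * sum(!is.na(sc) & sc > cutoff) / length(target_set), 1)
}

#' High-OncoScore subset of a target set
#'
#' @param target_set character vector of target ids.
#' @param annotations \code{target_annotations}.
#' @param cutoff strict OncoScore cutoff (default 0.7).
#' @return data frame of the members with score strictly above the cutoff,
#'   sorted by score descending then gene name ascending, with regulation
#'   flags carried through.
#' @export
high_score_subset <- function(target_set, annotations, cutoff = 0.7) {
  target_set <- unique(target_set)
  a <- as.data.frame(annotations)
  a <- a[a$target_id %in% target_set & !is.na(a$oncoscore) &
           a$oncoscore > cutoff, , drop = FALSE]
  a <- a[order(-a$oncoscore, a$gene), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Count regulation-flagged rows
#'
#' @param table data frame with a \code{regulation} column.
#' @return number of rows flagged \code{up} or \code{down}.
#' @export
count_regulation_flagged <- function(table) {
  sum(table$regulation %in% c("up", "down"))
}

#' Rank drugs by their coverage of a target list
#'
#' For every drug in the affinity table, counts the targets of the given
#' list hit with experimental pAffinity at or above \code{paff_min}; drugs
#' hitting strictly more than \code{min_targets} such targets are kept,
#' with their qualifying affinities binned into [6,7), [7,8), [8,9),
#' [9,Inf).
#'
#' @param drug_db \code{chemogenomics_db} (or data frame) of experimental
#'   drug-target affinities (columns ligand_id, target_id, pact).
#' @param tumor_unique character vector of target ids (the list to cover).
#' @param paff_min inclusive pAffinity cutoff (default 6).
#' @param min_targets strict lower bound on the qualifying-target count
#'   (default 5, i.e. "more than 5").
#' @return data frame: drug_id, n_targets, bin_6_7, bin_7_8, bin_8_9,
#'   bin_9_plus, sorted by n_targets descending then drug_id.
#' @export
rank_drugs <- function(drug_db, tumor_unique, paff_min = 6.0, min_targets = 5L) {
  df <- as.data.frame(drug_db)
  df <- df[df$target_id %in% tumor_unique & df$pact >= paff_min, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(drug_id = character(), n_targets = integer(),
                      bin_6_7 = integer(), bin_7_8 = integer(),
                      bin_8_9 = integer(), bin_9_plus = integer(),
                      stringsAsFactors = FALSE))
  rows <- lapply(split(df, df$ligand_id), function(d) {
    d <- d[!duplicated(d$target_id), ]
    data.frame(drug_id = d$ligand_id[1], n_targets = nrow(d),
               bin_6_7 = sum(d$pact >= 6 & d$pact < 7),
               bin_7_8 = sum(d$pact >= 7 & d$pact < 8),
               bin_8_9 = sum(d$pact >= 8 & d$pact < 9),
               bin_9_plus = sum(d$pact >= 9), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_targets > min_targets, , drop = FALSE]
  out <- out[order(-out$n_targets, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of pathway gene sets with a gene list
#'
#' @param pathways \code{pathway_sets} (see \code{\link{read_pathways_gmt}}).
#' @param gene_set character vector of gene symbols (case-insensitive).
#' @return list with \code{overlap} (data frame pathway, n_overlap, sorted
#'   by overlap descending) and \code{summary} (n_pathways, n_ge2, n_ge5).
#' @export
pathway_overlap <- function(pathways, gene_set) {
  genes <- unique(toupper(gene_set))
  ov <- vapply(pathways, function(p) length(intersect(p$genes, genes)), 0L)
  df <- data.frame(pathway = names(ov), n_overlap = as.integer(ov),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_overlap, df$pathway), ]
  rownames(df) <- NULL
  list(overlap = df,
       summary = list(n_pathways = length(ov),
                      n_ge2 = sum(ov >= 2L), n_ge5 = sum(ov >= 5L)))
}
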