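# Readers and writers for the tabular formats the pipeline touches:
# SMILES tables (TSV), SDF libraries, chemogenomics affinity databases,
# target annotations and GMT pathway sets. All identity comparisons use
# canonical SMILES computed at read time; potencies are stored as pAct
# (-log10 molar) throughout.

.family_levels <- c("GPCR", "enzyme", "ion_channel", "nuclear_receptor",
                    "transporter", "other")
.ec_levels <- c("oxidoreductase", "transferase", "hydrolase", "lyase",
                "isomerase", "ligase", "none")
.regulation_levels <- c("up", "down", "none")

.new_parse_report <- function(total, accepted, rejected_rows = data.frame()) {
  list(total = total, accepted = accepted, rejected = total - accepted,
       rejected_rows = rejected_rows)
}

#' Parse report of a reader result
#'
#' Every reader attaches a report with the number of input rows accepted and
#' rejected (and why). \code{accepted + rejected == total} always holds.
#'
#' @param x object returned by one of the \code{read_*} functions.
#' @return list with elements \code{total}, \code{accepted}, \code{rejected},
#'   \code{rejected_rows}.
#' @export
parse_report <- function(x) attr(x, "parse_report")

#' Construct a compound library
#'
#' A compound library is a data frame with columns \code{id}, \code{smiles}
#' (canonical) and \code{source}. Ids must be unique and non-empty; SMILES
#' that fail to parse to a molecular graph with at least one heavy atom are
#' dropped and counted in the parse report.
#'
#' @param id character vector of unique compound identifiers.
#' @param smiles character vector of SMILES strings.
#' @param source optional character vector of free-text source tags.
#' @return object of class \code{compound_library}.
#' @export
compound_library <- function(id, smiles, source = "") {
  id <- as.character(id)
  if (any(!nzchar(id) | is.na(id))) stop("compound ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "))
  stopifnot(length(smiles) == length(id))
  source <- rep_len(as.character(source), length(id))
  can <- canonicalize_smiles(smiles)
  rej <- data.frame(id = id[!can$ok], smiles = smiles[!can$ok],
                    reason = rep("unparseable SMILES", sum(!can$ok)),
                    stringsAsFactors = FALSE)
  lib <- data.frame(id = id[can$ok], smiles = can$canonical[can$ok],
                    source = source[can$ok], stringsAsFactors = FALSE)
  structure(lib, class = c("compound_library", "data.frame"),
            parse_report = .new_parse_report(length(id), nrow(lib), rej))
}

#' @export
print.compound_library <- function(x, ...) {
  rep <- parse_report(x)
  cat(sprintf("Compound library: %d compounds (%d input rows, %d rejected)\n",
              nrow(x), rep$total, rep$rejected))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read a compound library from a SMILES table
#'
#' @param path TSV file with header columns \code{id} and \code{smiles};
#'   a \code{source} column is carried through, any other extra columns are
#'   collapsed into the source tag as \code{name=value} pairs.
#' @return \code{compound_library}; see \code{\link{parse_report}} for
#'   rejected-row accounting.
#' @export
read_smiles_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    if (!all(c("id", "smiles") %in% names(df)))
      stop("SMILES table must have columns 'id' and 'smiles': ", path)
    warning("empty SMILES table: ", path)
    return(compound_library(character(), character()))
  }
  if (!all(c("id", "smiles") %in% names(df)))
    stop("SMILES table must have columns 'id' and 'smiles': ", path)
  extra <- setdiff(names(df), c("id", "smiles", "source"))
  src <- if ("source" %in% names(df)) as.character(df$source) else rep("", nrow(df))
  if (length(extra)) {
    tags <- apply(df[extra], 1L, function(r)
      paste(paste0(extra, "=", r), collapse = ";"))
    src <- ifelse(nzchar(src), paste(src, tags, sep = ";"), tags)
  }
  compound_library(df$id, df$smiles, src)
}

#' Read a compound library from an SDF file
#'
#' @param path SDF file; molecule titles (or \code{CMP<i>} fallbacks) become
#'   compound ids.
#' @return \code{compound_library}.
#' @export
read_sdf_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sdf <- ChemmineR::read.SDFset(path)
  ids <- vapply(seq_along(sdf@SDF), function(i) {
    t <- sdf@SDF[[i]]@header[["Molecule_Name"]]
    if (is.null(t) || !nzchar(t)) sprintf("CMP%d", i) else t
  }, "")
  smi <- as.character(ChemmineR::sdf2smiles(sdf))
  compound_library(ids, smi)
}

#' Write a compound library as a SMILES table
#'
#' @param lib \code{compound_library}.
#' @param path output TSV path.
#' @export
write_smiles_table <- function(lib, path) {
  utils::write.table(as.data.frame(lib)[c("id", "smiles", "source")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chemogenomics affinity database
#'
#' Reads a ligand-target affinity table (TSV with columns \code{ligand_id},
#' \code{smiles}, \code{target_id}, \code{pact} and optional \code{source}).
#' Rows with non-numeric pAct or unparseable SMILES are rejected and counted;
#' duplicate (ligand, target) pairs are aggregated keeping the maximum pAct.
#'
#' @param path TSV path.
#' @return object of class \code{chemogenomics_db}: a data frame of unique
#'   interactions with a parse report and a \code{counts} attribute
#'   (unique ligands, targets, interactions).
#' @export
read_affinity_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("ligand_id", "smiles", "target_id", "pact")
  if (!all(need %in% names(df)))
    stop("affinity DB must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty affinity database: ", path)
  if (!"source" %in% names(df)) df$source <- ""
  pact <- suppressWarnings(as.numeric(df$pact))
  bad <- is.na(pact) | !is.finite(pact)
  rej <- data.frame(ligand_id = df$ligand_id[bad], target_id = df$target_id[bad],
                    reason = rep("non-numeric pact", sum(bad)),
                    stringsAsFactors = FALSE)
  df <- df[!bad, , drop = FALSE]
  pact <- pact[!bad]
  can <- canonicalize_smiles(df$smiles)
  badsmi <- !can$ok
  if (any(badsmi)) {
    rej <- rbind(rej, data.frame(ligand_id = df$ligand_id[badsmi],
                                 target_id = df$target_id[badsmi],
                                 reason = rep("unparseable SMILES", sum(badsmi)),
                                 stringsAsFactors = FALSE))
  }
  df$smiles <- can$canonical
  df$pact <- pact
  df <- df[!badsmi, , drop = FALSE]
  chemogenomics_db(df, n_input = length(bad), rejected_rows = rej)
}

#' Construct a chemogenomics database from an interaction data frame
#'
#' @param interactions data frame with columns \code{ligand_id},
#'   \code{smiles}, \code{target_id}, \code{pact}, optional \code{source}.
#' @param n_input,rejected_rows parse bookkeeping (internal use).
#' @return \code{chemogenomics_db} with duplicate (ligand, target) pairs
#'   aggregated by maximum pAct.
#' @export
chemogenomics_db <- function(interactions, n_input = nrow(interactions),
                             rejected_rows = data.frame()) {
  df <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (!"source" %in% names(df)) df$source <- ""
  stopifnot(all(c("ligand_id", "smiles", "target_id", "pact") %in% names(df)))
  if (nrow(df)) {
    key <- paste(df$ligand_id, df$target_id, sep = "\r")
    ord <- order(key, -df$pact)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
    df <- df[order(df$target_id, df$ligand_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  counts <- list(ligands = length(unique(df$ligand_id)),
                 targets = length(unique(df$target_id)),
                 interactions = nrow(df))
  structure(df[c("ligand_id", "smiles", "target_id", "pact", "source")],
            class = c("chemogenomics_db", "data.frame"),
            counts = counts,
            parse_report = .new_parse_report(n_input,
                                             n_input - nrow(rejected_rows),
                                             rejected_rows))
}

#' @export
print.chemogenomics_db <- function(x, ...) {
  ct <- attr(x, "counts")
  cat(sprintf("Chemogenomics DB: %d interactions, %d ligands, %d targets\n",
              ct$interactions, ct$ligands, ct$targets))
  invisible(x)
}

#' Interaction/ligand/target counts of a chemogenomics database
#'
#' @param db \code{chemogenomics_db}.
#' @return list with \code{ligands}, \code{targets}, \code{interactions}.
#' @export
db_counts <- function(db) attr(db, "counts")

#' Write a chemogenomics database
#'
#' @param db \code{chemogenomics_db}.
#' @param path output TSV path.
#' @export
write_affinity_db <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read target annotations
#'
#' Annotations carry the protein family, enzyme class, oncogene probability
#' (OncoScore) and colon-cancer regulation flag per target. Gene symbols are
#' upper-cased; rows violating the vocabulary or the enzyme/EC-class
#' consistency rule (\code{ec_class == "none"} exactly when the family is
#' not \code{enzyme}) are rejected with a report.
#'
#' @param path TSV with columns \code{target_id}, \code{gene}, \code{family},
#'   \code{ec_class}, \code{oncoscore}, \code{regulation}.
#' @return data frame of class \code{target_annotations}.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("target_id", "gene", "family", "ec_class", "oncoscore", "regulation")
  if (!all(need %in% names(df)))
    stop("annotations must have columns ", paste(need, collapse = ", "))
  target_annotations(df)
}

#' Construct a target annotation table
#'
#' @param df data frame with the annotation columns (see
#'   \code{\link{read_annotations}}).
#' @return validated data frame of class \code{target_annotations}.
#' @export
target_annotations <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene <- toupper(as.character(df$gene))
  df$oncoscore <- suppressWarnings(as.numeric(df$oncoscore))
  df$regulation[is.na(df$regulation)] <- "none"
  n <- nrow(df)
  bad_fam <- !(df$family %in% .family_levels)
  bad_ec <- !(df$ec_class %in% .ec_levels) |
    (df$family == "enzyme" & df$ec_class == "none") |
    (df$family != "enzyme" & df$ec_class != "none")
  bad_score <- !is.na(df$oncoscore) & (df$oncoscore < 0 | df$oncoscore > 1)
  bad_reg <- !(df$regulation %in% .regulation_levels)
  bad <- bad_fam | bad_ec | bad_score | bad_reg
  rej <- data.frame(target_id = df$target_id[bad],
                    reason = ifelse(bad_fam[bad], "unknown family",
                             ifelse(bad_ec[bad], "ec_class inconsistent",
                             ifelse(bad_score[bad], "oncoscore out of [0,1]",
                                    "unknown regulation flag"))),
                    stringsAsFactors = FALSE)
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("target_annotations", "data.frame"),
            parse_report = .new_parse_report(n, nrow(df), rej))
}

#' Write target annotations
#'
#' @param annot \code{target_annotations}.
#' @param path output TSV path.
#' @export
write_annotations <- function(annot, path) {
  utils::write.table(as.data.frame(annot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member genes. Symbols are upper-cased and de-duplicated; lines with
#' fewer than three fields are rejected and reported by line number.
#'
#' @param path GMT file path.
#' @return named list of class \code{pathway_sets}; each element is a list
#'   with \code{name}, \code{description} and \code{genes}.
#' @export
read_pathways_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- nzchar(lines)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lines_keep & lengths(fields) >= 3L
  nbad <- sum(lines_keep & !ok)
  rej <- data.frame(line = which(lines_keep & !ok),
                    reason = rep("fewer than 3 tab-separated fields", nbad),
                    stringsAsFactors = FALSE)
  sets <- lapply(fields[ok], function(f) {
    list(name = f[1], description = f[2],
         genes = unique(toupper(f[-(1:2)][nzchar(f[-(1:2)])])))
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  structure(sets, class = "pathway_sets",
            parse_report = .new_parse_report(sum(lines_keep), length(sets), rej))
}

#' Write gene sets in GMT format
#'
#' @param sets \code{pathway_sets} or plain named list of gene vectors.
#' @param path output path.
#' @export
write_pathways_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) s <- list(name = names(sets)[i], description = "na", genes = s)
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
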