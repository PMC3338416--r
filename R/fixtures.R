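# Published reference data and synthetic completions used by the
# differential analytics: the 42-protein high-OncoScore table (published
# values, shipped as a TSV fixture) and a synthetic completion of the
# 115-protein tumor-unique panel for analyses that need the full
# denominator.

#' Load the published 42-protein high-OncoScore table
#'
#' The table lists the proteins with oncogene probability (OncoScore)
#' above 0.7 among the 115 targets hit uniquely by tumor-selective
#' compounds, with up/down colon-cancer regulation flags on 10 of them.
#' These are published values, not synthetic data.
#'
#' @return data frame: gene, protein, oncoscore, regulation.
#' @export
load_oncoscore_table <- function() {
  utils::read.delim(system.file("extdata", "high_oncoscore_targets.tsv",
                                package = "diviss"),
                    stringsAsFactors = FALSE)
}

#' Synthetic completion of the 115-target tumor-unique panel
#'
#' Combines the 42 published high-OncoScore proteins with 73 synthetic
#' filler targets carrying OncoScores at or below 0.7 (or missing), so the
#' panel has the full 115-target denominator. Family and EC-class labels
#' are synthetic, allocated to match the published composition (67 enzymes
#' of which 29 transferases, 18 GPCRs); per-target assignments beyond
#' those totals are arbitrary.
#'
#' @param seed seed for the synthetic filler scores.
#' @return \code{target_annotations} with 115 rows; the published rows
#'   keep their gene symbols, filler targets are named \code{SYNxxx}.
#' @export
synthetic_tumor_panel <- function(seed = 1L) {
  t1 <- load_oncoscore_table()
  set.seed(seed)
  n_fill <- 115L - nrow(t1)
  fill_scores <- stats::runif(n_fill, 0, 0.7)
  fill_scores[seq_len(round(0.18 * n_fill))] <- NA_real_  # NA category
  genes <- c(t1$gene, sprintf("SYN%03d", seq_len(n_fill)))
  scores <- c(t1$oncoscore, fill_scores)
  reg <- c(t1$regulation, rep("none", n_fill))
  # composition matching the published totals: 67 enzymes (29 transferases),
  # 18 GPCRs, remainder spread over the other families
  family <- rep("other", 115L)
  family[1:67] <- "enzyme"
  family[68:85] <- "GPCR"
  family[86:93] <- "ion_channel"
  family[94:101] <- "nuclear_receptor"
  family[102:108] <- "transporter"
  ec <- rep("none", 115L)
  ec[1:29] <- "transferase"
  ec[30:39] <- "oxidoreductase"
  ec[40:54] <- "hydrolase"
  ec[55:59] <- "lyase"
  ec[60:63] <- "isomerase"
  ec[64:67] <- "ligase"
  target_annotations(data.frame(
    target_id = genes, gene = genes, family = family, ec_class = ec,
    oncoscore = scores, regulation = reg, stringsAsFactors = FALSE))
}

#' Synthetic pathway fixture around the published pathway memberships
#'
#' Gene sets whose intersections with the high-OncoScore table reproduce
#' the published overlap counts: a MAPK signaling set containing the seven
#' named probable oncogenes (BRAF, MAP2K1, MAP3K8, MAPK10, RAF1, STAT1,
#' TGFBR1), an Erk1/Erk2 MAPK set containing the six named ones (EGFR,
#' MAP2K1, PDGFRA, RAF1, SRC, STAT3), and a disjoint control set. Filler
#' members are synthetic.
#'
#' @return \code{pathway_sets}.
#' @export
synthetic_pathway_fixture <- function() {
  sets <- list(
    MAPK_SIGNALING = list(
      name = "MAPK_SIGNALING", description = "synthetic fixture",
      genes = c("BRAF", "MAP2K1", "MAP3K8", "MAPK10", "RAF1", "STAT1",
                "TGFBR1", "FILLER1", "FILLER2")),
    ERK1_ERK2_MAPK = list(
      name = "ERK1_ERK2_MAPK", description = "synthetic fixture",
      genes = c("EGFR", "MAP2K1", "PDGFRA", "RAF1", "SRC", "STAT3",
                "FILLER3")),
    UNRELATED_SET = list(
      name = "UNRELATED_SET", description = "synthetic fixture",
      genes = c("FILLER4", "FILLER5", "FILLER6")))
  structure(sets, class = "pathway_sets",
            parse_report = .new_parse_report(3L, 3L))
}
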