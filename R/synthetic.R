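# Synthetic screening campaign generator. Emulates a differential
# cytotoxicity campaign end to end: a compound library built from a
# scaffold x substituent grammar with latent target activities, duplicate
# single-point plate screens with controls, two-cell-line dose-response
# data, a chemogenomics affinity database with planted neighbor structure,
# and target annotations. Ground truth is exported so every downstream
# stage can be tested for parameter recovery.
#
# The viability law is a Hill curve (bottom 0, top 100); a compound's true
# cell-line IC50 derives from its planted binding potency pAct and the
# target's cell-line relevance weight w in [0, 1]:
#   IC50(uM) = 10^(6 - pAct) * cell_potency_shift / w   (Inf when w = 0),
# i.e. cellular potency is the binding potency attenuated by one
# configurable log-unit shift and by how much the cell line depends on the
# target.

#' Load the scaffold x substituent structure grammar
#'
#' @param path grammar TSV (columns kind, name, smiles); defaults to the
#'   fixture shipped with the package (40 scaffolds, 38 substituents).
#' @return list with \code{scaffolds} (data.frame name, smiles template
#'   with \code{{R1}}/\code{{R2}} attachment slots) and \code{substituents}
#'   (data.frame name, smiles).
#' @export
load_scaffold_grammar <- function(path = system.file("extdata",
                                                     "scaffold_grammar.tsv",
                                                     package = "diviss")) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"tag" %in% names(g)) g$tag <- ""
  out <- list(scaffolds = g[g$kind == "scaffold", c("name", "smiles")],
              substituents = g[g$kind == "substituent",
                               c("name", "smiles", "tag")])
  if (nrow(out$scaffolds) == 0L || nrow(out$substituents) == 0L)
    stop("empty scaffold grammar: ", path)
  out
}

# fill the {R1}/{R2} slots of a scaffold template; empty substituent
# removes the slot (and its branch parentheses)
.fill_template <- function(tpl, r1 = "", r2 = "") {
  for (slot in list(c("{R1}", r1), c("{R2}", r2))) {
    tok <- paste0("(", slot[1], ")")
    if (grepl(tok, tpl, fixed = TRUE)) {
      tpl <- sub(tok, if (nzchar(slot[2])) paste0("(", slot[2], ")") else "",
                 tpl, fixed = TRUE)
    } else {
      tpl <- sub(slot[1], slot[2], tpl, fixed = TRUE)
    }
  }
  tpl
}

#' Configuration of a synthetic screening campaign
#'
#' Defaults mirror the screening design the package models: single-point
#' duplicate screening at 50 uM, 6-point 3-fold dose-response in duplicate
#' on a tumor and a normal cell line, ~14% cytotoxic compounds of which
#' ~11% are tumor-selective and ~10% normal-selective, resazurin-like plate
#' controls with S/B ~ 10, and 5% viability noise.
#'
#' @param n_compounds library size.
#' @param frac_cytotoxic probability a compound is cytotoxic on the tumor
#'   line (true tumor IC50 <= the screening concentration).
#' @param frac_tumor_selective,frac_normal_selective conditional on being
#'   cytotoxic, probability of tumor-selective / normal-selective planting.
#' @param n_cancer_targets,n_normal_targets,n_housekeeping_targets planted
#'   target panel sizes (cancer targets drive tumor-selective toxicity).
#' @param screen_conc_um single-point screening concentration.
#' @param conc_top_um,dilution_factor,n_conc dose-response scheme.
#' @param n_replicates replicates per measurement.
#' @param hill_slope Hill slope of the viability law.
#' @param viab_noise_sd additive Gaussian noise on viability (%).
#' @param pos_mean,pos_cv,neg_mean,neg_cv plate control signal means (AU)
#'   and coefficients of variation.
#' @param n_control_wells control wells of each kind per plate.
#' @param compounds_per_plate compounds per 384-well plate (2 wells each
#'   plus 2 x n_control_wells controls).
#' @param archetype_pact_range range of planted archetype potencies (pAct).
#' @param target_substituent_pool size of the per-target substituent
#'   sub-pool its ligands and actives are decorated from.
#' @param db_ligands_per_target reference ligands generated per target.
#' @param db_pact_sd spread of DB ligand potencies around the archetype.
#' @param cell_potency_shift multiplicative shift from binding potency to
#'   cellular IC50 (10 = one log unit).
#' @param family_proportions named numeric, sampling weights for protein
#'   families in the annotations.
#' @param regulation_fraction fraction of cancer targets flagged up/down.
#' @param oncoscore_na_fraction fraction of targets with missing OncoScore.
#' @param seed integer master seed; each generator stage derives its own
#'   substream from it.
#' @return validated list of class \code{campaign_config}.
#' @export
campaign_config <- function(n_compounds = 2000L,
                            frac_cytotoxic = 0.139,
                            frac_tumor_selective = 0.107,
                            frac_normal_selective = 0.101,
                            n_cancer_targets = 20L,
                            n_normal_targets = 10L,
                            n_housekeeping_targets = 10L,
                            screen_conc_um = 50,
                            conc_top_um = 50,
                            dilution_factor = 3,
                            n_conc = 6L,
                            n_replicates = 2L,
                            hill_slope = 1,
                            viab_noise_sd = 5,
                            pos_mean = 50000, pos_cv = 0.10,
                            neg_mean = 5000, neg_cv = 0.056,
                            n_control_wells = 32L,
                            compounds_per_plate = 160L,
                            archetype_pact_range = c(6.5, 7.5),
                            target_substituent_pool = 5L,
                            db_ligands_per_target = 15L,
                            db_pact_sd = 0.3,
                            cell_potency_shift = 10,
                            family_proportions = c(enzyme = 0.45, GPCR = 0.25,
                                                   ion_channel = 0.10,
                                                   nuclear_receptor = 0.08,
                                                   transporter = 0.07,
                                                   other = 0.05),
                            regulation_fraction = 0.25,
                            oncoscore_na_fraction = 0.10,
                            seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("frac_cytotoxic", "frac_tumor_selective", "frac_normal_selective",
              "regulation_fraction", "oncoscore_na_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$frac_tumor_selective + cfg$frac_normal_selective > 1)
    stop("selective fractions must sum to at most 1")
  if (cfg$n_compounds < 0) stop("n_compounds must be >= 0")
  if (cfg$n_conc < 4) stop("n_conc must be >= 4 for IC50 fitting")
  if (cfg$dilution_factor <= 1) stop("dilution_factor must be > 1")
  if (!all(names(cfg$family_proportions) %in% .family_levels))
    stop("unknown family in family_proportions")
  if (cfg$seed >= 2^31 - 10) stop("seed too large")
  class(cfg) <- "campaign_config"
  cfg
}

.stage_seed <- function(config, offset) as.integer(config$seed) + offset

# planted target panel: cancer targets drive tumor-selective toxicity
# (tumor weight 1, small normal weight), normal targets the reverse,
# housekeeping targets hit both lines equally
.make_targets <- function(config, grammar) {
  n <- config$n_cancer_targets + config$n_normal_targets +
    config$n_housekeeping_targets
  if (n > nrow(grammar$scaffolds))
    stop("target panel larger than the scaffold grammar (", n, " > ",
         nrow(grammar$scaffolds), ")")
  group <- rep(c("cancer", "normal", "housekeeping"),
               c(config$n_cancer_targets, config$n_normal_targets,
                 config$n_housekeeping_targets))
  # every target carries a pharmacophore anchor: one substituent present in
  # all of its ligands and actives (the recognition motif), plus a small
  # pool of secondary decorations drawn from feature-light ("mild")
  # substituents. Shared anchor + shared scaffold + mild peripheral
  # variation keep the ligand ensemble (hence the applicability radius)
  # tight, while foreign chemotypes differ in scaffold and anchor.
  ns <- nrow(grammar$substituents)
  mild <- which(grammar$substituents$tag == "mild")
  if (!length(mild)) mild <- seq_len(ns)
  anchor <- rep_len(sample(ns), n)
  sub_pool <- vapply(seq_len(n), function(i)
    paste(sort(sample(setdiff(mild, anchor[i]),
                      min(config$target_substituent_pool,
                          length(setdiff(mild, anchor[i]))))),
          collapse = ","), "")
  tumor_w <- ifelse(group == "cancer", 1,
             ifelse(group == "normal", stats::runif(n, 0.10, 0.19), 1))
  normal_w <- ifelse(group == "cancer", stats::runif(n, 0.02, 0.15),
              ifelse(group == "normal", 1, 1))
  data.frame(
    target_id = sprintf("T%03d", seq_len(n)),
    gene = sprintf("GENE%03d", seq_len(n)),
    group = group,
    is_cancer = group == "cancer",
    tumor_weight = tumor_w,
    normal_weight = normal_w,
    scaffold = grammar$scaffolds$name[seq_len(n)],
    scaffold_smiles = grammar$scaffolds$smiles[seq_len(n)],
    anchor = grammar$substituents$smiles[anchor],
    sub_pool = sub_pool,
    archetype_smiles = vapply(seq_len(n), function(i)
      .fill_template(grammar$scaffolds$smiles[i],
                     grammar$substituents$smiles[anchor[i]]), ""),
    archetype_pact = stats::runif(n, config$archetype_pact_range[1],
                                  config$archetype_pact_range[2]),
    stringsAsFactors = FALSE)
}

.true_ic50 <- function(pact, weight, shift) {
  ifelse(is.na(pact) | weight <= 0, Inf, 10^(6 - pact) * shift / weight)
}

# random decorated structure on a given scaffold template; decoration is
# sparse (R1 usually present, R2 occasionally) so ensembles stay compact
.random_structure <- function(template, subs, p_r1 = 0.9, p_r2 = 0.4) {
  r1 <- if (stats::runif(1) < p_r1) sample(subs, 1L) else ""
  r2 <- if (stats::runif(1) < p_r2) sample(subs, 1L) else ""
  .fill_template(template, r1, r2)
}

# active / reference ligand of a target: always carries the target's
# anchor substituent, with an occasional secondary decoration
.anchored_structure <- function(template, anchor, pool, p_r2 = 0.4) {
  r2 <- if (stats::runif(1) < p_r2) sample(pool, 1L) else ""
  .fill_template(template, anchor, r2)
}

#' Generate a synthetic compound library with ground truth
#'
#' Compounds are built from the scaffold grammar. Each compound is planted
#' as tumor-selective, normal-selective, unselectively cytotoxic or
#' inactive according to the configured fractions; cytotoxic compounds are
#' structural decorations of their planted target's archetype scaffold, so
#' that selective compounds are recoverable by the ligand-based target
#' models later. Tumor-selective compounds are assigned to cancer targets
#' round-robin, guaranteeing panel coverage whenever there are at least as
#' many selective compounds as cancer targets.
#'
#' @param config \code{campaign_config}.
#' @param grammar structure grammar (default: shipped fixture).
#' @return list with \code{library} (a \code{compound_library}) and
#'   \code{truth} (class \code{ground_truth}: \code{targets} and
#'   \code{compounds} data frames plus the config).
#' @export
generate_library <- function(config, grammar = load_scaffold_grammar()) {
  set.seed(.stage_seed(config, 1L))
  targets <- .make_targets(config, grammar)
  n <- config$n_compounds
  subs <- grammar$substituents$smiles
  if (n == 0L) {
    lib <- compound_library(character(), character())
    truth <- structure(list(targets = targets,
                            compounds = data.frame(id = character(),
                                                   smiles = character(),
                                                   role = character(),
                                                   target_id = character(),
                                                   pact = numeric(),
                                                   ic50_tumor_um = numeric(),
                                                   ic50_normal_um = numeric(),
                                                   stringsAsFactors = FALSE),
                            config = config), class = "ground_truth")
    return(list(library = lib, truth = truth))
  }
  cyto <- stats::runif(n) < config$frac_cytotoxic
  u <- stats::runif(n)
  role <- ifelse(!cyto, "inactive",
          ifelse(u < config$frac_tumor_selective, "tumor_selective",
          ifelse(u < config$frac_tumor_selective + config$frac_normal_selective,
                 "normal_selective", "cytotoxic_unselective")))
  tid <- rep(NA_character_, n)
  grp <- split(seq_len(n), role)
  pool <- list(tumor_selective = targets$target_id[targets$group == "cancer"],
               normal_selective = targets$target_id[targets$group == "normal"],
               cytotoxic_unselective = targets$target_id[targets$group == "housekeeping"])
  for (r in names(pool)) {
    idx <- grp[[r]]
    if (length(idx)) tid[idx] <- rep_len(pool[[r]], length(idx))
  }
  ti <- match(tid, targets$target_id)
  pact <- rep(NA_real_, n)
  act <- !is.na(ti)
  pact[act] <- stats::rnorm(sum(act), targets$archetype_pact[ti[act]],
                            config$db_pact_sd)
  pools <- lapply(strsplit(targets$sub_pool, ","), function(k)
    subs[as.integer(k)])
  smiles <- vapply(seq_len(n), function(i) {
    if (is.na(ti[i]))
      .random_structure(sample(grammar$scaffolds$smiles, 1L), subs)
    else
      .anchored_structure(targets$scaffold_smiles[ti[i]],
                          targets$anchor[ti[i]], pools[[ti[i]]])
  }, "")
  compounds <- data.frame(
    id = sprintf("C%05d", seq_len(n)),
    smiles = smiles, role = role, target_id = tid, pact = pact,
    ic50_tumor_um = .true_ic50(pact, targets$tumor_weight[ti],
                               config$cell_potency_shift),
    ic50_normal_um = .true_ic50(pact, targets$normal_weight[ti],
                                config$cell_potency_shift),
    stringsAsFactors = FALSE)
  lib <- compound_library(compounds$id, compounds$smiles,
                          source = "synthetic")
  if (parse_report(lib)$rejected > 0L)
    stop("structure grammar produced unparseable SMILES")  # contract violation
  # store canonical structures in the truth too
  compounds$smiles <- lib$smiles[match(compounds$id, lib$id)]
  truth <- structure(list(targets = targets, compounds = compounds,
                          config = config), class = "ground_truth")
  list(library = lib, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d compounds (%s), %d targets (%d cancer)\n",
              nrow(x$compounds),
              paste(names(table(x$compounds$role)),
                    table(x$compounds$role), sep = ":", collapse = ", "),
              nrow(x$targets), sum(x$targets$is_cancer)))
  invisible(x)
}

#' Simulate the single-point primary screen
#'
#' Each compound gets duplicate wells at the screening concentration on the
#' tumor line; plates carry positive (untreated) and negative (background)
#' control wells drawn from the configured means and CVs. Expected
#' viability follows the Hill law of the ground truth; Gaussian noise
#' (viability scale) is added, then viability is mapped to a raw
#' fluorescence signal between the true control means.
#'
#' @param lib \code{compound_library}.
#' @param truth \code{ground_truth} covering all compounds in \code{lib}.
#' @param config \code{campaign_config}.
#' @return data frame with columns plate_id, well, compound_id, cell_line,
#'   concentration_um, replicate, raw_signal.
#' @export
simulate_primary_screen <- function(lib, truth, config) {
  if (!all(lib$id %in% truth$compounds$id))
    stop("ground truth does not cover all compounds")
  set.seed(.stage_seed(config, 2L))
  n <- nrow(lib)
  i <- match(lib$id, truth$compounds$id)
  ic50 <- truth$compounds$ic50_tumor_um[i]
  plate_of <- ceiling(seq_len(max(n, 1L)) / config$compounds_per_plate)
  rows <- list()
  for (p in unique(plate_of[seq_len(n)])) {
    pid <- sprintf("P%03d", p)
    nc <- config$n_control_wells
    ctrl <- data.frame(
      plate_id = pid,
      well = sprintf("CTL%03d", seq_len(2 * nc)),
      compound_id = rep(c("CONTROL_POS", "CONTROL_NEG"), each = nc),
      cell_line = "HCT116", concentration_um = NA_real_,
      replicate = seq_len(2 * nc),
      raw_signal = c(stats::rnorm(nc, config$pos_mean,
                                  config$pos_cv * config$pos_mean),
                     stats::rnorm(nc, config$neg_mean,
                                  config$neg_cv * config$neg_mean)),
      stringsAsFactors = FALSE)
    idx <- which(plate_of[seq_len(n)] == p)
    viab_true <- hill_viability(config$screen_conc_um, ic50[idx],
                                config$hill_slope)
    cmp <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      viab <- viab_true + stats::rnorm(length(idx), 0, config$viab_noise_sd)
      data.frame(plate_id = pid,
                 well = sprintf("W%03d_%d", seq_along(idx), r),
                 compound_id = lib$id[idx], cell_line = "HCT116",
                 concentration_um = config$screen_conc_um, replicate = r,
                 raw_signal = config$neg_mean +
                   viab / 100 * (config$pos_mean - config$neg_mean),
                 stringsAsFactors = FALSE)
    }))
    rows[[length(rows) + 1L]] <- rbind(ctrl, cmp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate dose-response measurements for a set of compounds
#'
#' @param compound_ids compounds to measure.
#' @param truth \code{ground_truth}.
#' @param cell_line \code{"HCT116"} (tumor) or \code{"MRC5"} (normal).
#' @param config \code{campaign_config}.
#' @return data frame: compound_id, cell_line, concentration_um, replicate,
#'   viability (percent, Hill law + Gaussian noise).
#' @export
simulate_dose_response <- function(compound_ids, truth, cell_line, config) {
  if (!cell_line %in% c("HCT116", "MRC5"))
    stop("unknown cell line: ", cell_line)
  if (!all(compound_ids %in% truth$compounds$id))
    stop("ground truth does not cover all compounds")
  set.seed(.stage_seed(config, if (cell_line == "HCT116") 3L else 4L))
  conc <- config$conc_top_um / config$dilution_factor^(0:(config$n_conc - 1L))
  i <- match(compound_ids, truth$compounds$id)
  ic50 <- if (cell_line == "HCT116") truth$compounds$ic50_tumor_um[i]
          else truth$compounds$ic50_normal_um[i]
  grid <- expand.grid(ci = seq_along(conc), rep = seq_len(config$n_replicates),
                      k = seq_along(compound_ids))
  viab <- hill_viability(conc[grid$ci], ic50[grid$k], config$hill_slope) +
    stats::rnorm(nrow(grid), 0, config$viab_noise_sd)
  out <- data.frame(compound_id = compound_ids[grid$k], cell_line = cell_line,
                    concentration_um = conc[grid$ci], replicate = grid$rep,
                    viability = viab, stringsAsFactors = FALSE)
  out[order(out$compound_id, -out$concentration_um, out$replicate), ]
}

#' Generate the synthetic chemogenomics affinity database
#'
#' Every planted target receives reference ligands generated as structural
#' decorations of its archetype scaffold, with pAct drawn around the
#' archetype potency; the undecorated archetype itself is always included,
#' so a probe compound equal to the archetype sits at distance zero inside
#' its own target model (planted recoverability).
#'
#' @param truth \code{ground_truth}.
#' @param config \code{campaign_config}.
#' @return \code{chemogenomics_db}.
#' @export
generate_chemogenomics_db <- function(truth, config) {
  set.seed(.stage_seed(config, 5L))
  grammar <- load_scaffold_grammar()
  subs <- grammar$substituents$smiles
  t <- truth$targets
  pools <- lapply(strsplit(t$sub_pool, ","), function(k) subs[as.integer(k)])
  rows <- lapply(seq_len(nrow(t)), function(i) {
    nl <- config$db_ligands_per_target
    smi <- c(t$archetype_smiles[i],
             vapply(seq_len(max(nl - 1L, 0L)), function(j)
               .anchored_structure(t$scaffold_smiles[i], t$anchor[i],
                                   pools[[i]]), ""))
    data.frame(ligand_id = sprintf("L_%s_%02d", t$target_id[i], seq_along(smi)),
               smiles = smi, target_id = t$target_id[i],
               pact = c(t$archetype_pact[i],
                        stats::rnorm(length(smi) - 1L, t$archetype_pact[i],
                                     config$db_pact_sd)),
               source = "synthetic", stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  can <- canonicalize_smiles(df$smiles)
  if (!all(can$ok)) stop("structure grammar produced unparseable SMILES")
  df$smiles <- can$canonical
  chemogenomics_db(df)
}

#' Generate synthetic target annotations
#'
#' Families and EC classes are sampled from the configured proportions;
#' planted cancer targets draw OncoScores from Beta(8, 2) (mean 0.8),
#' other targets from Beta(2, 8) (mean 0.2); a configured fraction of
#' scores is missing, and a configured fraction of cancer targets carries
#' an up/down regulation flag.
#'
#' @param truth \code{ground_truth}.
#' @param config \code{campaign_config}.
#' @return \code{target_annotations}.
#' @export
generate_annotations <- function(truth, config) {
  set.seed(.stage_seed(config, 6L))
  t <- truth$targets
  n <- nrow(t)
  fam <- sample(names(config$family_proportions), n, replace = TRUE,
                prob = config$family_proportions)
  ec <- ifelse(fam == "enzyme",
               sample(setdiff(.ec_levels, "none"), n, replace = TRUE,
                      prob = c(0.15, 0.43, 0.22, 0.08, 0.06, 0.06)),
               "none")
  score <- ifelse(t$is_cancer, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
  score[stats::runif(n) < config$oncoscore_na_fraction] <- NA_real_
  reg <- rep("none", n)
  flag <- t$is_cancer & stats::runif(n) < config$regulation_fraction
  reg[flag] <- sample(c("up", "down"), sum(flag), replace = TRUE)
  target_annotations(data.frame(
    target_id = t$target_id, gene = t$gene, family = fam, ec_class = ec,
    oncoscore = score, regulation = reg, stringsAsFactors = FALSE))
}

#' Generate a complete synthetic campaign
#'
#' Convenience wrapper running all generators under one config.
#'
#' @param config \code{campaign_config}.
#' @return list: \code{library}, \code{truth}, \code{plates} (primary
#'   screen), \code{db}, \code{annotations}.
#' @export
simulate_campaign <- function(config = campaign_config()) {
  gl <- generate_library(config)
  list(library = gl$library, truth = gl$truth,
       plates = simulate_primary_screen(gl$library, gl$truth, config),
       db = generate_chemogenomics_db(gl$truth, config),
       annotations = generate_annotations(gl$truth, config))
}
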