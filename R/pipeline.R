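# End-to-end orchestration of the differential screening pipeline:
# simulate -> screen -> fit -> select -> profile -> differential, with a
# YAML configuration, per-stage caching keyed on parameter/input hashes,
# and a JSON run manifest holding the campaign counts at every stage.

.default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "diviss_run",
    stages = list(simulate = TRUE, screen = TRUE, fit = TRUE,
                  select = TRUE, profile = TRUE, differential = TRUE),
    inputs = list(library = NULL, plates = NULL, dose_response = NULL,
                  db = NULL, annotations = NULL, pathways = NULL,
                  drugs = NULL),
    simulate = list(n_compounds = 2000L),
    screen = list(hit_threshold = 20),
    fit = list(initial_fraction = 0.8, tumor_line = "HCT116",
               normal_line = "MRC5"),
    select = list(enrichment_threshold = 0.20, diversity_fraction = 0.08),
    profile = list(pact_min = 6.0, idw_power = 2, min_ligands = 1L,
                   radius_quantile = 0.95),
    differential = list(oncoscore_cutoff = 0.7, drug_paff_min = 6.0,
                        drug_min_targets = 5L,
                        ratio_edges = c(0.2, 0.5, 2, 5))
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    p <- if (nzchar(path)) paste0(path, ".", k) else k
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], p)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate (and normalize) a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills every default, and
#' checks each threshold against its documented domain; all violations are
#' reported together with their field paths. An empty file yields the full
#' default configuration.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return normalized config of class \code{pipeline_config}.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("unreadable config file: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- .merge_config(.default_pipeline_config(), config)
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == as.integer(cfg$seed) &&
        cfg$seed < 2^31 - 10, "seed: must be a 32-bit integer")
  chk(cfg$screen$hit_threshold >= 0 && cfg$screen$hit_threshold <= 100,
      "screen.hit_threshold: must be in [0, 100]")
  chk(cfg$fit$initial_fraction > 0 && cfg$fit$initial_fraction <= 1,
      "fit.initial_fraction: must be in (0, 1]")
  chk(cfg$select$enrichment_threshold >= 0 && cfg$select$enrichment_threshold <= 1,
      "select.enrichment_threshold: must be in [0, 1]")
  chk(cfg$select$diversity_fraction >= 0 && cfg$select$diversity_fraction <= 1,
      "select.diversity_fraction: must be in [0, 1]")
  chk(cfg$profile$pact_min >= 0, "profile.pact_min: must be >= 0")
  chk(cfg$profile$idw_power > 0, "profile.idw_power: must be > 0")
  chk(cfg$profile$radius_quantile > 0 && cfg$profile$radius_quantile <= 1,
      "profile.radius_quantile: must be in (0, 1]")
  chk(cfg$differential$oncoscore_cutoff >= 0 && cfg$differential$oncoscore_cutoff <= 1,
      "differential.oncoscore_cutoff: must be in [0, 1]")
  chk(length(cfg$differential$ratio_edges) == 4L &&
        all(diff(cfg$differential$ratio_edges) > 0) &&
        cfg$differential$ratio_edges[1] > 0,
      "differential.ratio_edges: must be four ascending positive values")
  chk(cfg$differential$drug_min_targets >= 0,
      "differential.drug_min_targets: must be >= 0")
  if (length(errs)) stop("invalid pipeline config:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.hash_files <- function(paths) {
  paths <- paths[!vapply(paths, is.null, TRUE)]
  paths <- unlist(paths)
  if (!length(paths)) return(character())
  unname(tools::md5sum(paths[file.exists(paths)]))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the differential screening pipeline
#'
#' Executes the enabled stages in order (simulate, screen, fit, select,
#' profile, differential), writing each stage's outputs and a JSON run
#' manifest under \code{config$out_dir}. A stage whose parameters and
#' inputs are unchanged since the previous run (same hash in the existing
#' manifest, outputs present) is skipped and its outputs reloaded from
#' disk; the manifest marks it \code{cached}. Stage outputs are
#' deterministic given the seed, so an unchanged rerun is byte-identical.
#'
#' @param config \code{pipeline_config}, config list, or YAML path (see
#'   \code{\link{validate_config}}).
#' @return (invisibly) list with \code{manifest} and in-memory
#'   \code{results} of each executed stage.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  old <- if (file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  manifest <- list(config = unclass(cfg), stages = list())
  res <- list()
  p <- function(...) file.path(out, ...)

  stage <- function(name, params, input_files, outputs, compute, load) {
    key <- .hash_obj(list(params = params, seed = cfg$seed,
                          inputs = .hash_files(input_files)))
    cached <- !is.null(old) && identical(old$stages[[name]]$hash, key) &&
      all(file.exists(unlist(outputs)))
    r <- if (cached) load() else compute()
    manifest$stages[[name]] <<- list(
      hash = key, cached = cached, outputs = unlist(outputs),
      counts = r$counts)
    r$value
  }

  skip <- function(name) {
    manifest$stages[[name]] <<- list(skipped = TRUE)
  }

  ## ---- simulate -------------------------------------------------------
  if (isTRUE(cfg$stages$simulate)) {
    sim_files <- list(library = p("library.tsv"), plates = p("plates.tsv"),
                      db = p("affinity_db.tsv"), annotations = p("annotations.tsv"),
                      truth_compounds = p("truth_compounds.tsv"),
                      truth_targets = p("truth_targets.tsv"))
    ccfg <- do.call(campaign_config, c(cfg$simulate, list(seed = cfg$seed)))
    res$simulate <- stage("simulate", params = unclass(ccfg),
      input_files = list(), outputs = sim_files,
      compute = function() {
        camp <- simulate_campaign(ccfg)
        write_smiles_table(camp$library, sim_files$library)
        .write_tsv(camp$plates, sim_files$plates)
        write_affinity_db(camp$db, sim_files$db)
        write_annotations(camp$annotations, sim_files$annotations)
        .write_tsv(camp$truth$compounds, sim_files$truth_compounds)
        .write_tsv(camp$truth$targets, sim_files$truth_targets)
        list(value = c(camp, list(config = ccfg)),
             counts = list(n_compounds = nrow(camp$library),
                           n_targets = nrow(camp$truth$targets)))
      },
      load = function() {
        truth <- structure(list(
          compounds = utils::read.delim(sim_files$truth_compounds,
                                        stringsAsFactors = FALSE),
          targets = utils::read.delim(sim_files$truth_targets,
                                      stringsAsFactors = FALSE),
          config = ccfg), class = "ground_truth")
        lib <- read_smiles_table(sim_files$library)
        list(value = list(library = lib, truth = truth,
                          plates = utils::read.delim(sim_files$plates,
                                                     stringsAsFactors = FALSE),
                          db = read_affinity_db(sim_files$db),
                          annotations = read_annotations(sim_files$annotations),
                          config = ccfg),
             counts = list(n_compounds = nrow(lib),
                           n_targets = nrow(truth$targets)))
      })
    lib <- res$simulate$library
    truth <- res$simulate$truth
    plates <- res$simulate$plates
    db <- res$simulate$db
    annotations <- res$simulate$annotations
  } else {
    skip("simulate")
    truth <- NULL
    need <- function(x, what) {
      if (is.null(x)) stop("stage requires input '", what,
                           "' when simulation is disabled")
      x
    }
    lib <- if (!is.null(cfg$inputs$library)) read_smiles_table(cfg$inputs$library)
    plates <- if (!is.null(cfg$inputs$plates))
      utils::read.delim(cfg$inputs$plates, stringsAsFactors = FALSE)
    db <- if (!is.null(cfg$inputs$db)) read_affinity_db(cfg$inputs$db)
    annotations <- if (!is.null(cfg$inputs$annotations))
      read_annotations(cfg$inputs$annotations)
  }
  pathways <- if (!is.null(cfg$inputs$pathways))
    read_pathways_gmt(cfg$inputs$pathways)
  drug_db <- if (!is.null(cfg$inputs$drugs)) read_affinity_db(cfg$inputs$drugs)
    else db

  ## ---- screen ---------------------------------------------------------
  if (isTRUE(cfg$stages$screen)) {
    if (is.null(plates)) stop("stage 'screen' requires plate data")
    out_files <- list(viability = p("screen_viability.tsv"),
                      qc = p("screen_qc.json"), hits = p("hits.tsv"))
    res$screen <- stage("screen", params = cfg$screen,
      input_files = if (isTRUE(cfg$stages$simulate)) list() else
        list(cfg$inputs$plates),
      outputs = out_files,
      compute = function() {
        ps <- compute_plate_stats(plates)
        wells <- plates[!plates$compound_id %in% c("CONTROL_POS", "CONTROL_NEG"), ]
        viab <- do.call(rbind, lapply(split(wells, wells$plate_id), function(w) {
          data.frame(compound_id = w$compound_id, replicate = w$replicate,
                     viability = normalize_viability(w$raw_signal,
                                                     ps[[w$plate_id[1]]]),
                     stringsAsFactors = FALSE)
        }))
        rownames(viab) <- NULL
        viab <- viab[order(viab$compound_id, viab$replicate), ]
        hits <- call_cytotoxic_hits(viab, cfg$screen$hit_threshold)
        conc <- duplicate_concordance(viab)
        qc <- list(n_plates = length(ps),
                   zprime_mean = mean(vapply(ps, zprime, 0)),
                   zprime_range = range(vapply(ps, zprime, 0)),
                   sb_mean = mean(vapply(ps, signal_to_background, 0)),
                   duplicate_correlation = conc$correlation,
                   n_compounds = length(unique(viab$compound_id)),
                   n_hits = length(hits),
                   hit_rate = length(hits) / max(1, length(unique(viab$compound_id))))
        .write_tsv(viab, out_files$viability)
        .write_json(qc, out_files$qc)
        .write_tsv(data.frame(compound_id = hits), out_files$hits)
        list(value = list(viability = viab, hits = hits, qc = qc),
             counts = list(n_screened = qc$n_compounds, n_hits = qc$n_hits))
      },
      load = function() {
        viab <- utils::read.delim(out_files$viability, stringsAsFactors = FALSE)
        hits <- utils::read.delim(out_files$hits, stringsAsFactors = FALSE)$compound_id
        qc <- jsonlite::read_json(out_files$qc, simplifyVector = TRUE)
        list(value = list(viability = viab, hits = hits, qc = qc),
             counts = list(n_screened = qc$n_compounds, n_hits = qc$n_hits))
      })
  } else skip("screen")

  ## ---- fit (initial dose-response) ------------------------------------
  if (isTRUE(cfg$stages$fit)) {
    hits <- res$screen$hits
    out_files <- list(fits = p("fits_initial.tsv"),
                      tested = p("tested_initial.tsv"))
    res$fit <- stage("fit",
      params = c(cfg$fit, list(n_hits = length(hits))),
      input_files = if (is.null(cfg$inputs$dose_response)) list() else
        list(cfg$inputs$dose_response),
      outputs = out_files,
      compute = function() {
        if (!is.null(truth)) {
          hit_lib <- lib[lib$id %in% hits, ]
          class(hit_lib) <- class(lib)
          k <- round(cfg$fit$initial_fraction * nrow(hit_lib))
          tested <- if (k < nrow(hit_lib))
            diversity_select(hit_lib, k) else hit_lib$id
          dr <- rbind(simulate_dose_response(tested, truth,
                                             cfg$fit$tumor_line,
                                             res$simulate$config),
                      simulate_dose_response(tested, truth,
                                             cfg$fit$normal_line,
                                             res$simulate$config))
        } else {
          if (is.null(cfg$inputs$dose_response))
            stop("stage 'fit' requires inputs.dose_response when simulation is disabled")
          dr <- utils::read.csv(cfg$inputs$dose_response,
                                stringsAsFactors = FALSE)
          tested <- unique(dr$compound_id)
        }
        fits <- fit_dose_response(dr)
        .write_tsv(fits, out_files$fits)
        .write_tsv(data.frame(compound_id = sort(tested)), out_files$tested)
        list(value = list(fits = fits, tested = sort(tested)),
             counts = list(n_tested = length(tested)))
      },
      load = function() {
        fits <- utils::read.delim(out_files$fits, stringsAsFactors = FALSE)
        tested <- utils::read.delim(out_files$tested,
                                    stringsAsFactors = FALSE)$compound_id
        list(value = list(fits = fits, tested = tested),
             counts = list(n_tested = length(tested)))
      })
  } else skip("fit")

  ## ---- select (chemotype expansion + pooled selectivity) --------------
  if (isTRUE(cfg$stages$select)) {
    out_files <- list(chemotypes = p("chemotypes.tsv"),
                      expansion = p("expansion.tsv"),
                      fits = p("fits_all.tsv"),
                      selectivity = p("selectivity.tsv"))
    res$select <- stage("select", params = cfg$select,
      input_files = list(), outputs = out_files,
      compute = function() {
        fits <- res$fit$fits
        tested <- res$fit$tested
        sel0 <- selectivity_table(fits, cfg$fit$tumor_line, cfg$fit$normal_line,
                                  cfg$differential$ratio_edges)
        selective <- sel0$compound_id[sel0$class == "tumor_strong"]
        clusters <- cluster_library(lib)
        scored <- score_clusters(clusters, selective, tested)
        untested_hits <- setdiff(res$screen$hits, tested)
        expansion <- select_expansion(scored, untested_hits,
                                      cfg$select$enrichment_threshold)
        k_div <- round(cfg$select$diversity_fraction *
                         length(setdiff(untested_hits, expansion)))
        div_pool <- setdiff(untested_hits, expansion)
        div_ids <- if (k_div > 0 && length(div_pool)) {
          pool_lib <- lib[lib$id %in% div_pool, ]
          class(pool_lib) <- class(lib)
          diversity_select(pool_lib, min(k_div, nrow(pool_lib)))
        } else character()
        extra <- union(expansion, div_ids)
        all_fits <- fits
        if (length(extra) && !is.null(truth)) {
          dr2 <- rbind(simulate_dose_response(extra, truth,
                                              cfg$fit$tumor_line,
                                              res$simulate$config),
                       simulate_dose_response(extra, truth,
                                              cfg$fit$normal_line,
                                              res$simulate$config))
          all_fits <- rbind(all_fits, fit_dose_response(dr2))
        }
        sel <- selectivity_table(all_fits, cfg$fit$tumor_line,
                                 cfg$fit$normal_line,
                                 cfg$differential$ratio_edges)
        ct <- scored
        ct$member_ids <- vapply(ct$member_ids, paste, "", collapse = ",")
        .write_tsv(ct, out_files$chemotypes)
        .write_tsv(data.frame(compound_id = extra,
                              via = c(rep("chemotype", length(expansion)),
                                      rep("diversity", length(div_ids)))),
                   out_files$expansion)
        .write_tsv(all_fits, out_files$fits)
        .write_tsv(sel, out_files$selectivity)
        list(value = list(selectivity = sel, fits = all_fits,
                          expansion = expansion, diversity = div_ids,
                          clusters = scored),
             counts = list(n_expansion = length(expansion),
                           n_diversity = length(div_ids),
                           n_tested_total = length(unique(sel$compound_id)),
                           n_tumor_selective = sum(sel$class == "tumor_strong"),
                           n_normal_selective = sum(sel$class == "normal_strong")))
      },
      load = function() {
        sel <- utils::read.delim(out_files$selectivity, stringsAsFactors = FALSE)
        all_fits <- utils::read.delim(out_files$fits, stringsAsFactors = FALSE)
        exp <- utils::read.delim(out_files$expansion, stringsAsFactors = FALSE)
        list(value = list(selectivity = sel, fits = all_fits,
                          expansion = exp$compound_id[exp$via == "chemotype"],
                          diversity = exp$compound_id[exp$via == "diversity"],
                          clusters = NULL),
             counts = list(n_expansion = sum(exp$via == "chemotype"),
                           n_diversity = sum(exp$via == "diversity"),
                           n_tested_total = length(unique(sel$compound_id)),
                           n_tumor_selective = sum(sel$class == "tumor_strong"),
                           n_normal_selective = sum(sel$class == "normal_strong")))
      })
  } else skip("select")

  ## ---- profile --------------------------------------------------------
  if (isTRUE(cfg$stages$profile)) {
    if (is.null(db)) stop("stage 'profile' requires an affinity database")
    out_files <- list(tumor = p("predictions_tumor.tsv"),
                      normal = p("predictions_normal.tsv"),
                      summary = p("profile_summary.json"))
    res$profile <- stage("profile", params = cfg$profile,
      input_files = if (isTRUE(cfg$stages$simulate)) list() else
        list(cfg$inputs$db),
      outputs = out_files,
      compute = function() {
        sel <- res$select$selectivity
        tumor_ids <- sel$compound_id[sel$class == "tumor_strong"]
        normal_ids <- sel$compound_id[sel$class == "normal_strong"]
        models <- build_target_models(db, min_ligands = cfg$profile$min_ligands,
                                      radius_quantile = cfg$profile$radius_quantile)
        sub_lib <- function(ids) {
          l <- lib[lib$id %in% ids, ]
          class(l) <- class(lib)
          l
        }
        pt <- profile_library(sub_lib(tumor_ids), models, cfg$profile$idw_power)
        pn <- profile_library(sub_lib(normal_ids), models, cfg$profile$idw_power)
        st <- profile_summary(tumor_ids, pt, cfg$profile$pact_min)
        sn <- profile_summary(normal_ids, pn, cfg$profile$pact_min)
        .write_tsv(pt, out_files$tumor)
        .write_tsv(pn, out_files$normal)
        .write_json(list(tumor = st, normal = sn), out_files$summary)
        list(value = list(tumor = pt, normal = pn,
                          summary = list(tumor = st, normal = sn),
                          tumor_ids = tumor_ids, normal_ids = normal_ids),
             counts = list(n_tumor_compounds = length(tumor_ids),
                           n_tumor_covered = st$n_covered,
                           n_normal_compounds = length(normal_ids),
                           n_normal_covered = sn$n_covered))
      },
      load = function() {
        pt <- utils::read.delim(out_files$tumor, stringsAsFactors = FALSE)
        pn <- utils::read.delim(out_files$normal, stringsAsFactors = FALSE)
        sm <- jsonlite::read_json(out_files$summary, simplifyVector = TRUE)
        sel <- res$select$selectivity
        list(value = list(tumor = pt, normal = pn, summary = sm,
                          tumor_ids = sel$compound_id[sel$class == "tumor_strong"],
                          normal_ids = sel$compound_id[sel$class == "normal_strong"]),
             counts = list(n_tumor_compounds = length(sel$compound_id[sel$class == "tumor_strong"]),
                           n_tumor_covered = sm$tumor$n_covered,
                           n_normal_compounds = length(sel$compound_id[sel$class == "normal_strong"]),
                           n_normal_covered = sm$normal$n_covered))
      })
  } else skip("profile")

  ## ---- differential ---------------------------------------------------
  if (isTRUE(cfg$stages$differential)) {
    out_files <- list(venn = p("venn.json"),
                      families = p("composition_family.tsv"),
                      ec = p("composition_ec.tsv"),
                      prioritized = p("prioritized_targets.tsv"),
                      drugs = p("drug_rank.tsv"),
                      pathways = p("pathway_overlap.tsv"),
                      report = p("differential_report.json"))
    res$differential <- stage("differential", params = cfg$differential,
      input_files = list(cfg$inputs$annotations, cfg$inputs$pathways,
                         cfg$inputs$drugs),
      outputs = out_files,
      compute = function() {
        pmin_ <- cfg$profile$pact_min
        tum <- filter_potent(res$profile$tumor, pmin_)
        nor <- filter_potent(res$profile$normal, pmin_)
        venn <- venn_partition(tum$target_id, nor$target_id)
        fam <- if (!is.null(annotations))
          family_composition(venn$tumor_unique, annotations)
        ecc <- if (!is.null(annotations))
          enzyme_class_composition(venn$tumor_unique, annotations)
        pri <- if (!is.null(annotations))
          high_score_subset(venn$tumor_unique, annotations,
                            cfg$differential$oncoscore_cutoff)
        pct <- if (!is.null(annotations))
          oncoscore_cumulative(venn$tumor_unique, annotations,
                               cfg$differential$oncoscore_cutoff)
        dr <- rank_drugs(drug_db, venn$tumor_unique,
                         cfg$differential$drug_paff_min,
                         cfg$differential$drug_min_targets)
        po <- if (!is.null(pathways) && !is.null(pri) && nrow(pri))
          pathway_overlap(pathways, pri$gene)
        .write_json(list(sizes = as.list(venn$sizes),
                         tumor_unique = venn$tumor_unique,
                         shared = venn$shared,
                         normal_unique = venn$normal_unique), out_files$venn)
        .write_tsv(if (!is.null(fam) && length(fam$counts))
          data.frame(family = names(fam$counts), n = fam$counts,
                     percent = fam$percent) else
          data.frame(family = character(), n = integer(), percent = numeric()),
          out_files$families)
        .write_tsv(if (!is.null(ecc) && length(ecc$counts))
          data.frame(ec_class = names(ecc$counts), n = ecc$counts,
                     percent = ecc$percent) else
          data.frame(ec_class = character(), n = integer(), percent = numeric()),
          out_files$ec)
        .write_tsv(if (!is.null(pri)) pri else data.frame(), out_files$prioritized)
        .write_tsv(dr, out_files$drugs)
        .write_tsv(if (!is.null(po)) po$overlap else
          data.frame(pathway = character(), n_overlap = integer()),
          out_files$pathways)
        report <- list(venn_sizes = as.list(venn$sizes),
                       pct_high_oncoscore = pct,
                       n_prioritized = if (!is.null(pri)) nrow(pri) else NA,
                       n_flagged = if (!is.null(pri))
                         count_regulation_flagged(pri) else NA,
                       n_drugs_ranked = nrow(dr),
                       pathway_summary = if (!is.null(po)) po$summary else NULL)
        .write_json(report, out_files$report)
        list(value = list(venn = venn, families = fam, ec = ecc,
                          prioritized = pri, drugs = dr, pathways = po,
                          report = report),
             counts = report[c("venn_sizes", "n_prioritized", "n_flagged")])
      },
      load = function() {
        venn_js <- jsonlite::read_json(out_files$venn, simplifyVector = TRUE)
        venn <- venn_partition(c(venn_js$tumor_unique, venn_js$shared),
                               c(venn_js$normal_unique, venn_js$shared))
        report <- jsonlite::read_json(out_files$report, simplifyVector = TRUE)
        pri <- utils::read.delim(out_files$prioritized, stringsAsFactors = FALSE)
        dr <- utils::read.delim(out_files$drugs, stringsAsFactors = FALSE)
        list(value = list(venn = venn, prioritized = pri, drugs = dr,
                          report = report),
             counts = report[c("venn_sizes", "n_prioritized", "n_flagged")])
      })
  } else skip("differential")

  .write_json(manifest, manifest_path)
  invisible(list(manifest = manifest, results = res))
}
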