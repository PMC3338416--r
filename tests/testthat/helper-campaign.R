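# Shared synthetic-campaign fixture, built once per test run.
# Small scale (300 compounds) keeps module tests fast; the acceptance
# suite runs the full-size campaign itself.

.camp_cache <- new.env(parent = emptyenv())

small_campaign <- function() {
  if (is.null(.camp_cache$camp)) {
    cfg <- campaign_config(n_compounds = 300L, seed = 42L)
    .camp_cache$camp <- simulate_campaign(cfg)
    .camp_cache$cfg <- cfg
  }
  list(camp = .camp_cache$camp, cfg = .camp_cache$cfg)
}

# viability table from a plate data frame (duplicated from the pipeline
# stage on purpose: tests should not depend on pipeline plumbing)
normalize_plates <- function(plates) {
  ps <- compute_plate_stats(plates)
  wells <- plates[!plates$compound_id %in% c("CONTROL_POS", "CONTROL_NEG"), ]
  out <- do.call(rbind, lapply(split(wells, wells$plate_id), function(w)
    data.frame(compound_id = w$compound_id, replicate = w$replicate,
               viability = normalize_viability(w$raw_signal, ps[[w$plate_id[1]]]),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# synthetic SHED-space descriptor with a given vector (for IDW unit tests)
fake_shed <- function(v) structure(v, space = "SHED")

# minimal hand-built target model in SHED space
fake_model <- function(vectors, pacts, radius = 100) {
  list(target_id = "FAKE", ligand_id = sprintf("L%d", seq_along(pacts)),
       pact = pacts,
       descriptors = list(SHED = lapply(vectors, fake_shed),
                          FPD = lapply(vectors, function(v)
                            structure(v, space = "FPD")),
                          PHRAG = lapply(seq_along(pacts), function(i)
                            structure(integer(), names = character(),
                                      space = "PHRAG"))),
       radius = c(SHED = radius, FPD = radius, PHRAG = radius))
}
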