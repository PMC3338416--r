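# Single-point screening analysis: viability normalization against plate
# controls, plate quality statistics (Z' factor, signal-to-background),
# cytotoxic hit calling and campaign bookkeeping.

#' Plate control statistics
#'
#' @param plate_id plate identifier.
#' @param pos_mean,pos_sd mean and sd of the positive (untreated, full
#'   signal) control wells.
#' @param neg_mean,neg_sd mean and sd of the negative (background) control
#'   wells.
#' @return object of class \code{plate_stats}.
#' @export
plate_stats <- function(plate_id, pos_mean, pos_sd, neg_mean, neg_sd) {
  stopifnot(pos_sd >= 0, neg_sd >= 0)
  structure(list(plate_id = as.character(plate_id),
                 pos_mean = pos_mean, pos_sd = pos_sd,
                 neg_mean = neg_mean, neg_sd = neg_sd),
            class = "plate_stats")
}

#' Compute per-plate control statistics from well-level plate data
#'
#' @param plates data frame with columns \code{plate_id}, \code{compound_id}
#'   (control wells labelled \code{CONTROL_POS} / \code{CONTROL_NEG}) and
#'   \code{raw_signal}.
#' @return named list of \code{plate_stats}, one per plate.
#' @export
compute_plate_stats <- function(plates) {
  stopifnot(all(c("plate_id", "compound_id", "raw_signal") %in% names(plates)))
  out <- lapply(split(plates, plates$plate_id), function(p) {
    pos <- p$raw_signal[p$compound_id == "CONTROL_POS"]
    neg <- p$raw_signal[p$compound_id == "CONTROL_NEG"]
    if (!length(pos) || !length(neg))
      stop("plate ", p$plate_id[1], " lacks control wells")
    plate_stats(p$plate_id[1], mean(pos), stats::sd(pos), mean(neg), stats::sd(neg))
  })
  out[order(names(out))]
}

#' Normalize a raw fluorescence signal to percent viability
#'
#' viability = 100 (raw - mu_n) / (mu_p - mu_n), where mu_p and mu_n are the
#' positive- and negative-control means of the well's plate. Values below 0
#' or above 100 are preserved (never clipped); callers may flag them.
#'
#' @param raw_signal numeric vector of raw fluorescence values (AU).
#' @param plate \code{plate_stats} for the plate the wells came from.
#' @return numeric vector of viability percentages.
#' @export
normalize_viability <- function(raw_signal, plate) {
  span <- plate$pos_mean - plate$neg_mean
  if (span == 0) stop("degenerate plate ", plate$plate_id,
                      ": positive and negative control means are equal")
  if (span < 0) stop("unusable plate ", plate$plate_id,
                     ": positive control mean below negative control mean")
  100 * (raw_signal - plate$neg_mean) / span
}

#' Z' factor of a plate
#'
#' Z' = 1 - 3 (sigma_p + sigma_n) / |mu_p - mu_n| (Zhang, Chung & Oldenburg
#' 1999). Values approach 1 for perfectly separated controls; screens are
#' conventionally usable above ~0.5.
#'
#' @param plate \code{plate_stats}.
#' @return Z' statistic (always <= 1).
#' @export
zprime <- function(plate) {
  span <- abs(plate$pos_mean - plate$neg_mean)
  if (span == 0) stop("degenerate plate ", plate$plate_id,
                      ": control means are equal")
  1 - 3 * (plate$pos_sd + plate$neg_sd) / span
}

#' Signal-to-background ratio of a plate
#'
#' @param plate \code{plate_stats}.
#' @return S/B = mu_p / mu_n.
#' @export
signal_to_background <- function(plate) {
  if (plate$neg_mean <= 0) stop("signal_to_background requires a positive ",
                                "negative-control mean (plate ", plate$plate_id, ")")
  plate$pos_mean / plate$neg_mean
}

#' Call cytotoxic hits from single-point viability records
#'
#' Replicate viabilities are averaged per compound first; a compound is a hit
#' when its mean viability is at or below the threshold (inclusive).
#'
#' @param records data frame with columns \code{compound_id} and
#'   \code{viability}.
#' @param threshold hit threshold in percent viability (default 20).
#' @return character vector of hit compound ids (sorted).
#' @export
call_cytotoxic_hits <- function(records, threshold = 20) {
  stopifnot(all(c("compound_id", "viability") %in% names(records)))
  m <- tapply(records$viability, records$compound_id, mean)
  sort(names(m)[m <= threshold])
}

#' Per-compound replicate pairs and their correlation
#'
#' @param records data frame with columns \code{compound_id},
#'   \code{replicate} (1 or 2) and \code{viability}; compounds lacking
#'   either replicate are excluded and counted.
#' @return list with \code{pairs} (data.frame compound_id, rep1, rep2),
#'   Pearson \code{correlation}, and \code{n_excluded}.
#' @export
duplicate_concordance <- function(records) {
  stopifnot(all(c("compound_id", "replicate", "viability") %in% names(records)))
  sp <- split(records, records$compound_id)
  rows <- lapply(sp, function(r) {
    v1 <- r$viability[r$replicate == 1]
    v2 <- r$viability[r$replicate == 2]
    if (length(v1) == 1L && length(v2) == 1L)
      data.frame(compound_id = r$compound_id[1], rep1 = v1, rep2 = v2)
    else NULL
  })
  excluded <- sum(vapply(rows, is.null, TRUE))
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(pairs)) pairs <- data.frame(compound_id = character(),
                                          rep1 = numeric(), rep2 = numeric())
  rownames(pairs) <- NULL
  r <- if (nrow(pairs) >= 2L) stats::cor(pairs$rep1, pairs$rep2) else NA_real_
  list(pairs = pairs, correlation = r, n_excluded = excluded)
}

#' Total number of cytotoxicity measurements in a campaign
#'
#' total = n_single * n_single_reps +
#'         n_dr * n_conc * n_dr_reps * n_cell_lines.
#'
#' @param n_single compounds in the single-point screen.
#' @param n_single_reps replicates per compound in the single-point screen.
#' @param n_dr compounds taken into dose-response screening.
#' @param n_conc concentrations per dose-response curve.
#' @param n_dr_reps replicates per concentration.
#' @param n_cell_lines number of cell lines screened in dose-response.
#' @return total measurement count.
#' @export
count_data_points <- function(n_single, n_single_reps, n_dr, n_conc,
                              n_dr_reps, n_cell_lines) {
  stopifnot(n_single >= 0, n_single_reps >= 0, n_dr >= 0, n_conc >= 0,
            n_dr_reps >= 0, n_cell_lines >= 0)
  n_single * n_single_reps + n_dr * n_conc * n_dr_reps * n_cell_lines
}
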