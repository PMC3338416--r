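# Dose-response analysis: logistic (Hill) curve fitting with censoring at
# the top tested concentration, p-log potency conversion, and the
# tumor/normal differential selectivity ratio and its classification.

#' Hill viability model
#'
#' viability(c) = bottom + (top - bottom) / (1 + (c / ic50)^slope).
#' With the defaults (bottom 0, top 100, slope 1) this is the standard
#' cytotoxicity dose-response law; it is also the generating model of the
#' synthetic campaign, so a noise-free simulated curve is exactly refittable.
#'
#' @param conc concentration(s), same unit as \code{ic50} (conventionally uM).
#' @param ic50 midpoint concentration.
#' @param slope Hill slope.
#' @param top,bottom asymptotes in percent viability.
#' @return viability percentage(s).
#' @export
hill_viability <- function(conc, ic50, slope = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (conc / ic50)^slope)
}

#' Fit a dose-response curve and extract the IC50
#'
#' Least-squares fit of a logistic curve with bottom fixed at 0, top fixed
#' at 100 and Hill slope constrained to [0.3, 5]; only the IC50 and slope
#' are free. Replicate points enter individually (not pre-averaged). The
#' result is censored at the top tested concentration when the per-
#' concentration mean viability never falls below 50% or when the fitted
#' IC50 lies above the tested range; censored curves report the bound
#' (\code{> cmax}) instead of extrapolating.
#'
#' @param concentration numeric vector of concentrations (uM), one entry per
#'   measured point (replicates repeat the concentration).
#' @param viability numeric vector of viability percentages, same length.
#' @param slope_bounds permitted Hill slope range.
#' @return object of class \code{ic50_result}: list with \code{ic50} (uM or
#'   \code{NA} when censored), \code{censored}, \code{censor_limit},
#'   \code{hill_slope}, \code{top}, \code{bottom}, \code{rmse},
#'   \code{converged}.
#' @export
fit_curve <- function(concentration, viability, slope_bounds = c(0.3, 5)) {
  stopifnot(length(concentration) == length(viability),
            all(is.finite(concentration)), all(concentration > 0))
  concs <- sort(unique(concentration))
  if (length(concs) < 4L)
    stop("dose-response fitting requires >= 4 distinct concentrations")
  cmax <- max(concs)
  res <- list(ic50 = NA_real_, censored = TRUE, censor_limit = cmax,
              hill_slope = NA_real_, top = 100, bottom = 0,
              rmse = NA_real_, converged = TRUE)
  class(res) <- "ic50_result"
  mean_v <- tapply(viability, concentration, mean)
  if (min(mean_v) > 50) return(res)

  sse <- function(p) {
    pred <- hill_viability(concentration, 10^p[1], p[2])
    sum((viability - pred)^2)
  }
  lic_lo <- log10(min(concs)) - 2
  lic_hi <- log10(cmax) + 2
  grid <- expand.grid(lic = seq(lic_lo, lic_hi, length.out = 12),
                      slope = c(0.5, 1, 2))
  start <- as.numeric(grid[which.min(apply(grid, 1L, sse)), ])
  opt <- tryCatch(
    stats::optim(start, sse, method = "L-BFGS-B",
                 lower = c(lic_lo, slope_bounds[1]),
                 upper = c(lic_hi, slope_bounds[2])),
    error = function(e) NULL)
  if (is.null(opt)) {
    res$converged <- FALSE
    return(res)
  }
  ic50 <- 10^opt$par[1]
  res$hill_slope <- opt$par[2]
  res$rmse <- sqrt(opt$value / length(viability))
  if (ic50 > cmax) return(res)  # 50% crossing outside tested range
  res$ic50 <- ic50
  res$censored <- FALSE
  res
}

#' @export
print.ic50_result <- function(x, ...) {
  if (x$censored) cat(sprintf("IC50 > %g uM (censored)\n", x$censor_limit))
  else cat(sprintf("IC50 = %.3g uM (slope %.2f, rmse %.2f)\n",
                   x$ic50, x$hill_slope, x$rmse))
  invisible(x)
}

#' Fit dose-response curves for every compound/cell-line group
#'
#' @param data data frame with columns \code{compound_id}, \code{cell_line},
#'   \code{concentration_um}, \code{viability}.
#' @return data frame with one row per (compound, cell line): ic50_um,
#'   censored, censor_limit, hill_slope, rmse, converged.
#' @export
fit_dose_response <- function(data) {
  stopifnot(all(c("compound_id", "cell_line", "concentration_um", "viability")
                %in% names(data)))
  grp <- interaction(data$compound_id, data$cell_line, drop = TRUE)
  rows <- lapply(split(data, grp), function(d) {
    f <- fit_curve(d$concentration_um, d$viability)
    data.frame(compound_id = d$compound_id[1], cell_line = d$cell_line[1],
               ic50_um = f$ic50, censored = f$censored,
               censor_limit = f$censor_limit, hill_slope = f$hill_slope,
               rmse = f$rmse, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$compound_id, out$cell_line), ]
}

#' Convert a molar potency to its p-log value
#'
#' p = -log10(concentration in mol/L); e.g. 1 uM -> 6. This is the pAct /
#' pIC50 / pGI50 scale used throughout the package.
#'
#' @param value potency as a molar concentration (> 0).
#' @return p-log value.
#' @seealso \code{\link{plog_to_potency}}
#' @export
potency_to_plog <- function(value) {
  if (any(!is.finite(value) | value <= 0))
    stop("potency must be a positive molar concentration")
  -log10(value)
}

#' Convert a p-log value back to a molar concentration
#'
#' Exact inverse of \code{\link{potency_to_plog}}.
#'
#' @param p p-log value.
#' @return molar concentration.
#' @export
plog_to_potency <- function(p) 10^(-p)

#' Differential selectivity ratio between normal and tumor IC50s
#'
#' R = IC50(normal) / IC50(tumor); values above 1 mean the compound is more
#' cytotoxic to the tumor line. When the normal-line IC50 is censored the
#' ratio is reported as a lower bound (censor limit / tumor IC50); when the
#' tumor IC50 is censored the compound is non-toxic (NT) regardless of the
#' normal line.
#'
#' @param ic50_normal,ic50_tumor \code{ic50_result} objects for the normal
#'   (MRC-5-like) and tumor (HCT116-like) cell lines.
#' @return list with \code{ratio} (NA for NT), \code{type} one of
#'   \code{"exact"}, \code{"lower_bound"}, \code{"nt"}.
#' @export
selectivity_ratio <- function(ic50_normal, ic50_tumor) {
  if (ic50_tumor$censored) return(list(ratio = NA_real_, type = "nt"))
  if (ic50_normal$censored)
    return(list(ratio = ic50_normal$censor_limit / ic50_tumor$ic50,
                type = "lower_bound"))
  list(ratio = ic50_normal$ic50 / ic50_tumor$ic50, type = "exact")
}

#' Classify a selectivity ratio
#'
#' Bins partition (0, Inf): R >= 5 tumor_strong; 2 <= R < 5 tumor_moderate;
#' 0.5 < R < 2 unselective; 0.2 < R <= 0.5 normal_moderate; R <= 0.2
#' normal_strong. Non-toxic records (censored tumor IC50) are class NT.
#' Lower-bound ratios are classified by the bound itself, which can only
#' understate tumor selectivity.
#'
#' @param ratio numeric ratio, or the list returned by
#'   \code{\link{selectivity_ratio}}.
#' @param edges the four ascending bin edges (defaults
#'   \code{c(0.2, 0.5, 2, 5)}); the normal-side edges are closed, the
#'   tumor-side edges are closed from above.
#' @return character class.
#' @export
classify_selectivity <- function(ratio, edges = c(0.2, 0.5, 2, 5)) {
  stopifnot(length(edges) == 4L, all(diff(edges) > 0), edges[1] > 0)
  if (is.list(ratio)) {
    if (identical(ratio$type, "nt")) return("NT")
    ratio <- ratio$ratio
  }
  if (is.na(ratio)) return("NT")
  stopifnot(ratio > 0)
  if (ratio >= edges[4]) "tumor_strong"
  else if (ratio >= edges[3]) "tumor_moderate"
  else if (ratio > edges[2]) "unselective"
  else if (ratio > edges[1]) "normal_moderate"
  else "normal_strong"
}

#' Build the per-compound selectivity table from fitted IC50s
#'
#' @param fits data frame from \code{\link{fit_dose_response}} covering two
#'   cell lines.
#' @param tumor_line,normal_line cell-line labels.
#' @return data frame: compound_id, ic50_tumor, ic50_normal, censored flags,
#'   ratio, ratio_type, class.
#' @export
selectivity_table <- function(fits, tumor_line = "HCT116",
                              normal_line = "MRC5",
                              edges = c(0.2, 0.5, 2, 5)) {
  tum <- fits[fits$cell_line == tumor_line, ]
  nor <- fits[fits$cell_line == normal_line, ]
  ids <- intersect(tum$compound_id, nor$compound_id)
  rows <- lapply(ids, function(id) {
    t <- tum[tum$compound_id == id, ][1, ]
    n <- nor[nor$compound_id == id, ][1, ]
    tt <- list(ic50 = t$ic50_um, censored = t$censored,
               censor_limit = t$censor_limit)
    nn <- list(ic50 = n$ic50_um, censored = n$censored,
               censor_limit = n$censor_limit)
    r <- selectivity_ratio(nn, tt)
    data.frame(compound_id = id,
               ic50_tumor = t$ic50_um, censored_tumor = t$censored,
               ic50_normal = n$ic50_um, censored_normal = n$censored,
               ratio = r$ratio, ratio_type = r$type,
               class = classify_selectivity(r, edges), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(compound_id = character(), ic50_tumor = numeric(),
                      censored_tumor = logical(), ic50_normal = numeric(),
                      censored_normal = logical(), ratio = numeric(),
                      ratio_type = character(), class = character())
  rownames(out) <- NULL
  out[order(out$compound_id), ]
}
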