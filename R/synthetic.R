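# Synthetic multi-cell-line melting panel generator.
#
# Each protein melts as a two-state sigmoid
#   a(T) = plateau + (1 - plateau) / (1 + exp(s * (T - Tm)))
# and the ten-point profile is anchored to its own 37-degree value (so the
# noise-free anchored curve equals exactly 1 at 37 C), mirroring how CETSA
# relative abundances are standardised.  Cell-line individuality enters as a
# per-(protein, cell line) thermal shift of Tm; measurement error as additive
# Gaussian noise after anchoring, truncated at 0.

#' Configuration of the melting-panel simulator
#'
#' Defaults describe a desk-scale three-cell-line study: 1000 proteins,
#' melting temperatures centred at 52 C (sd 5 C), sigmoid slopes around
#' 0.7 /C, a 5% non-melting baseline, per-cell-line thermal shifts of
#' sd 1.5 C and additive noise of sd 0.02.
#'
#' @param n_proteins Number of proteins.
#' @param cell_lines Character vector of 2-5 cell-line names.
#' @param tm_mean,tm_sd Mean and sd of the protein melting temperature (C).
#' @param slope_mean,slope_sd Mean and sd of the sigmoid slope (1/C); draws
#'   are truncated below at 0.05 to keep every curve melting.
#' @param plateau Non-melting baseline fraction in `[0, 0.3]`.
#' @param shift_sd Scale (C) of the per-(protein, cell line) thermal shift.
#' @param curve_link `"shifted_tm"` (default; per-cell-line Tm shifts),
#'   `"shared_tm"` (identical Tm in every cell line) or `"independent"`
#'   (fresh Tm per cell line).
#' @param noise_sd Additive Gaussian noise sd applied after anchoring.
#' @param missing_fraction Per-cell-line fraction of proteins dropped.
#' @param grid A [temperature_grid()].
#' @param seed Integer seed.
#' @return A `melt_sim_config` list.
#' @export
melt_sim_config <- function(n_proteins = 1000L,
                            cell_lines = c("A", "B", "C"),
                            tm_mean = 52, tm_sd = 5,
                            slope_mean = 0.7, slope_sd = 0.15,
                            plateau = 0.05,
                            shift_sd = 1.5,
                            curve_link = c("shifted_tm", "shared_tm",
                                           "independent"),
                            noise_sd = 0.02,
                            missing_fraction = 0,
                            grid = temperature_grid(),
                            seed = 1L) {
  curve_link <- match.arg(curve_link)
  if (!is_count(n_proteins)) {
    abort_cycletsa("`n_proteins` must be a positive integer.",
                   "cycletsa_argument_error")
  }
  if (!is.character(cell_lines) || length(cell_lines) < 2L ||
      length(cell_lines) > 5L || anyDuplicated(cell_lines)) {
    abort_cycletsa("`cell_lines` must be 2-5 distinct names.",
                   "cycletsa_argument_error")
  }
  for (nm in c("tm_sd", "slope_sd", "shift_sd", "noise_sd")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) {
      abort_cycletsa(sprintf("`%s` must be a non-negative number.", nm),
                     "cycletsa_argument_error")
    }
  }
  if (!is_number(plateau) || plateau < 0 || plateau > 0.3) {
    abort_cycletsa("`plateau` must lie in [0, 0.3].", "cycletsa_argument_error")
  }
  if (!is_number(missing_fraction) || missing_fraction < 0 ||
      missing_fraction >= 1) {
    abort_cycletsa("`missing_fraction` must lie in [0, 1).",
                   "cycletsa_argument_error")
  }
  structure(list(n_proteins = as.integer(n_proteins), cell_lines = cell_lines,
                 tm_mean = tm_mean, tm_sd = tm_sd, slope_mean = slope_mean,
                 slope_sd = slope_sd, plateau = plateau, shift_sd = shift_sd,
                 curve_link = curve_link, noise_sd = noise_sd,
                 missing_fraction = missing_fraction, grid = grid,
                 seed = check_seed(seed)),
            class = "melt_sim_config")
}

# Two-state sigmoid melting curve before anchoring.
melt_curve <- function(temps, tm, slope, plateau) {
  plateau + (1 - plateau) / (1 + exp(slope * (temps - tm)))
}

#' Simulate aligned multi-cell-line melting panels with known ground truth
#'
#' @param config A [melt_sim_config()].
#' @return A list with `panel` (a `cetsa_multipanel`) and `truth` (a tibble
#'   of the true per-protein, per-cell-line Tm, slope and plateau).
#' @export
#' @examples
#' sim <- simulate_panels(melt_sim_config(n_proteins = 20, seed = 7))
#' sim$panel
simulate_panels <- function(config = melt_sim_config()) {
  stopifnot(inherits(config, "melt_sim_config"))
  n <- config$n_proteins
  temps <- unclass(config$grid)
  acc <- sprintf("P%05d", seq_len(n))
  anchor_col <- 1L  # profiles are anchored at the first (lowest) temperature

  out <- withr::with_seed(config$seed, {
    tm_base <- stats::rnorm(n, config$tm_mean, config$tm_sd)
    slope <- pmax(stats::rnorm(n, config$slope_mean, config$slope_sd), 0.05)
    panels <- list()
    truth <- list()
    for (cl in config$cell_lines) {
      tm_cl <- switch(config$curve_link,
        shared_tm   = tm_base,
        shifted_tm  = tm_base + stats::rnorm(n, 0, config$shift_sd),
        independent = stats::rnorm(n, config$tm_mean, config$tm_sd))
      raw <- t(vapply(seq_len(n), function(i) {
        melt_curve(temps, tm_cl[i], slope[i], config$plateau)
      }, numeric(length(temps))))
      anchored <- raw / raw[, anchor_col]
      if (config$noise_sd > 0) {
        anchored <- anchored + matrix(stats::rnorm(length(anchored), 0,
                                                   config$noise_sd),
                                      nrow = n)
      }
      anchored <- pmax(anchored, 0)
      rownames(anchored) <- acc
      panels[[cl]] <- cell_line_panel(cl, anchored, config$grid)
      truth[[cl]] <- tibble::tibble(accession = acc, cell_line = cl,
                                    tm = tm_cl, slope = slope,
                                    plateau = config$plateau)
    }
    list(panels = panels, truth = do.call(rbind, truth))
  })

  mp <- multi_panel(out$panels)
  if (config$missing_fraction > 0) {
    mp <- apply_missingness(mp, config$missing_fraction,
                            seed = config$seed + 1L)
  }
  list(panel = mp, truth = out$truth)
}

#' Drop a random fraction of proteins from each cell-line panel
#'
#' Emulates proteins quantified in only a subset of cell lines: each panel
#' independently loses `floor(fraction * n)` proteins, and the common
#' intersection shrinks accordingly.
#'
#' @param multipanel A `cetsa_multipanel`.
#' @param fraction Fraction in `[0, 1)` of each panel's proteins to drop.
#' @param seed Integer seed.
#' @return A `cetsa_multipanel` over the reduced panels (any split is
#'   discarded because the common index changes).
#' @export
apply_missingness <- function(multipanel, fraction, seed = 1L) {
  stopifnot(inherits(multipanel, "cetsa_multipanel"))
  if (!is_number(fraction) || fraction < 0 || fraction >= 1) {
    abort_cycletsa("`fraction` must lie in [0, 1).", "cycletsa_argument_error")
  }
  if (fraction == 0) return(multipanel)
  seed <- check_seed(seed)
  panels <- withr::with_seed(seed, lapply(multipanel$panels, function(p) {
    acc <- panel_accessions(p)
    n_drop <- floor(fraction * length(acc))
    keep <- setdiff(acc, sample(acc, n_drop))
    cell_line_panel(p$cell_line, p$values[keep, , drop = FALSE], p$grid,
                    nonnegative = FALSE)
  }))
  multi_panel(panels, allow_empty = TRUE)
}

#' Noise-free consensus panel from simulator ground truth
#'
#' Rebuilds each protein's anchored melting curve from its cell-line-averaged
#' true parameters (mean Tm across cell lines, slope, plateau), giving the
#' cell-line-independent "biology" underneath the simulated panels. Useful as
#' the driver of downstream signals (e.g. co-aggregation-based interaction
#' scores) that should not be tied to any single measured panel.
#'
#' @param truth The `truth` tibble returned by [simulate_panels()].
#' @param grid A [temperature_grid()].
#' @param accessions Optional subset of accessions.
#' @return A `cetsa_panel` named `"consensus"`.
#' @export
consensus_panel <- function(truth, grid = temperature_grid(),
                            accessions = NULL) {
  stopifnot(is.data.frame(truth),
            all(c("accession", "tm", "slope", "plateau") %in% names(truth)))
  acc <- accessions %||% unique(truth$accession)
  temps <- unclass(grid)
  vals <- t(vapply(acc, function(a) {
    rows <- truth[truth$accession == a, ]
    raw <- melt_curve(temps, mean(rows$tm), rows$slope[1L], rows$plateau[1L])
    raw / raw[1L]
  }, numeric(length(temps))))
  rownames(vals) <- acc
  cell_line_panel("consensus", vals, grid)
}

#' Estimate Tm from a noise-free anchored curve by half-height scanning
#'
#' Brute-force check used to validate the simulator: finds where the anchored
#' curve crosses half of its span by linear interpolation between grid points.
#'
#' @param values Numeric vector over the grid (anchored profile).
#' @param grid A [temperature_grid()].
#' @return Estimated melting temperature in degrees C (NA if no crossing).
#' @export
half_height_tm <- function(values, grid = temperature_grid()) {
  temps <- unclass(grid)
  half <- (max(values) + min(values)) / 2
  above <- values >= half
  i <- which(above[-length(above)] & !above[-1L])[1L]
  if (is.na(i)) return(NA_real_)
  # linear interpolation between the straddling grid points
  t0 <- temps[i]; t1 <- temps[i + 1L]
  v0 <- values[i]; v1 <- values[i + 1L]
  t0 + (half - v0) * (t1 - t0) / (v1 - v0)
}
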