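#' One strain's entry in a plate design
#'
#' @param strain Unique strain label.
#' @param params A [curve_params()] for phenomenological wells, or an
#'   [assemble_model()] result to derive the well from the mechanistic flux
#'   model (fluorescence linear in reduced phenazine).
#' @param n_bio Number of biological replicates.
#' @param n_tech Technical replicates per biological replicate.
#' @param type `"biological"` or `"abiotic"`; abiotic entries are not
#'   jittered across biological replicates.
#' @export
plate_entry <- function(strain, params, n_bio = 3L, n_tech = 3L,
                        type = c("biological", "abiotic")) {
  type <- match.arg(type)
  if (!inherits(params, "curve_params") && !inherits(params, "etc_model")) {
    stop("`params` must be curve_params or etc_model", call. = FALSE)
  }
  stopifnot(n_bio >= 1L, n_tech >= 1L)
  list(strain = strain, params = params, n_bio = as.integer(n_bio),
       n_tech = as.integer(n_tech), type = type)
}

#' Default two-strain-plus-abiotic plate design
#'
#' A fast-oxidizing strain (the default curve family), a slower strain with
#' a longer lag, and a drifting abiotic control carried as three single-well
#' replicates.
#'
#' @export
default_plate_design <- function() {
  list(
    plate_entry("fast", curve_params()),
    plate_entry("slow", curve_params(lag_h = 8, k_fast = 0.08, k_slow = 0.02)),
    plate_entry("abiotic", abiotic_params(), n_bio = 3L, n_tech = 1L,
                type = "abiotic")
  )
}

# lognormal multiplier with coefficient of variation ~ cv
jitter_lognorm <- function(cv) if (cv <= 0) 1 else exp(rnorm(1, 0, cv) - cv^2 / 2)

jitter_curve_params <- function(p, bio_cv, lag_sd) {
  curve_params(
    F0 = p$F0 * jitter_lognorm(bio_cv / 5),
    lag_h = max(p$lag_h + rnorm(1, 0, lag_sd), 0),
    k_fast = p$k_fast * jitter_lognorm(bio_cv),
    k_slow = p$k_slow * jitter_lognorm(bio_cv),
    w_fast = p$w_fast, floor_frac = p$floor_frac,
    rise_amp = p$rise_amp, rise_tau = p$rise_tau, lag_smooth = p$lag_smooth
  )
}

jitter_etc_model <- function(m, bio_cv) {
  p <- m$params
  p2 <- model_params(
    k2 = p$k2 * jitter_lognorm(bio_cv), k1 = p$k1 * jitter_lognorm(bio_cv),
    k3 = p$k3, Vmax = p$Vmax * jitter_lognorm(bio_cv), K_TEA = p$K_TEA,
    PCA_red0 = p$PCA_red0, Q_tot = p$Q_tot, TEA0 = p$TEA0,
    PCA_ox0 = p$PCA_ox0, q_red_frac0 = p$q_red_frac0,
    k_reduce = p$k_reduce, lag = p$lag
  )
  assemble_model(m$genotype, p2, m$condition, m$acceptor)
}

etc_noiseless_curve <- function(model, t_grid, calibration) {
  tr <- simulate_etc(model, t_grid)
  calibration * tr$PCA_red
}

# numerical ground truth for a mechanistic well, on a fine grid
etc_truth <- function(model, t_range, threshold, calibration) {
  tt <- seq(t_range[1], t_range[2], by = 0.02)
  tr <- simulate_etc(model, tt)
  p <- model$params
  gate <- if (p$lag > 0) 1 / (1 + exp(-(tt - p$lag) / max(p$lag * 0.02, 1e-3))) else 1
  gate_red <- gate * p$k_reduce * pmax(p$PCA_red0 + p$PCA_ox0 - tr$PCA_red, 0)
  rate <- calibration * (tr$ox_flux - gate_red)
  i <- which.max(rate)
  target <- (1 - threshold) * tr$PCA_red[1]
  below <- which(tr$PCA_red <= target)
  if (length(below)) {
    j <- below[1]
    t_half <- if (j == 1L) tt[1] else
      tt[j - 1L] + (tr$PCA_red[j - 1L] - target) /
        (tr$PCA_red[j - 1L] - tr$PCA_red[j]) * (tt[j] - tt[j - 1L])
    detected <- TRUE
  } else {
    t_half <- NA_real_; detected <- FALSE
  }
  list(max_rate = rate[i], t_at_max = tt[i], t_half = t_half, detected = detected)
}

#' Generate a synthetic plate with known ground truth
#'
#' Builds a long-format plate table from a design. Each biological
#' replicate draws jittered parameters around its strain's ground truth
#' (lognormal spread `bio_cv` on the rate parameters, Gaussian `lag_sd`
#' hours on the lag); technical replicates share the biological draw and
#' differ only in measurement noise. The returned ground-truth table holds
#' the analytic maximum oxidation rate and time-to-half-oxidation of each
#' biological replicate's noiseless curve.
#'
#' @param design List of [plate_entry()] rows; strain labels must be unique.
#' @param t_grid Common time grid (h) across wells.
#' @param noise A [noise_model()].
#' @param seed Integer seed for the parameter jitter and noise draws.
#' @param bio_cv Biological spread (coefficient of variation) on rates.
#' @param lag_sd Biological spread (h) on the lag.
#' @param threshold Oxidized fraction used for the ground-truth `t_half`.
#' @param calibration Fluorescence units per uM reduced phenazine, for
#'   mechanistic entries.
#' @return List with `plate` (tibble: `time_h`, `well`, `strain`,
#'   `replicate_id`, `replicate_type`, `fluorescence`) and `truth` (tibble:
#'   `strain`, `replicate_id`, `max_rate`, `t_at_max`, `t_half`, `detected`).
#' @export
generate_plate <- function(design = default_plate_design(),
                           t_grid = seq(0, 48, by = 0.25),
                           noise = noise_model(), seed = NULL,
                           bio_cv = 0.1, lag_sd = 0.3, threshold = 0.5,
                           calibration = 10) {
  strains <- vapply(design, `[[`, character(1), "strain")
  if (anyDuplicated(strains)) {
    stop("duplicate strain label(s): ",
         paste(unique(strains[duplicated(strains)]), collapse = ", "), call. = FALSE)
  }
  run <- function() {
    plate_rows <- list(); truth_rows <- list()
    t_range <- range(t_grid)
    for (entry in design) {
      for (b in seq_len(entry$n_bio)) {
        mech <- inherits(entry$params, "etc_model")
        drawn <- if (entry$type == "abiotic") entry$params
          else if (mech) jitter_etc_model(entry$params, bio_cv)
          else jitter_curve_params(entry$params, bio_cv, lag_sd)
        if (mech) {
          expected <- etc_noiseless_curve(drawn, t_grid, calibration)
          tru <- etc_truth(drawn, t_range, threshold, calibration)
        } else {
          expected <- curve_value(drawn, t_grid)
          tru <- curve_truth(drawn, t_range, threshold)
        }
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          strain = entry$strain, replicate_id = b, max_rate = tru$max_rate,
          t_at_max = tru$t_at_max, t_half = tru$t_half, detected = tru$detected)
        rep_type <- if (entry$type == "abiotic") "abiotic"
          else if (entry$n_tech > 1L) "technical" else "biological"
        for (k in seq_len(entry$n_tech)) {
          vals <- apply_noise(expected, noise)
          plate_rows[[length(plate_rows) + 1L]] <- tibble(
            time_h = t_grid,
            well = sprintf("%s_b%d_t%d", entry$strain, b, k),
            strain = entry$strain, replicate_id = b,
            replicate_type = rep_type, fluorescence = vals)
        }
      }
    }
    list(plate = dplyr::bind_rows(plate_rows), truth = dplyr::bind_rows(truth_rows))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Simulated chronoamperometry current trace
#'
#' Runs the flux model in electrode mode (reduced phenazine clamped by the
#' poised working electrode) and converts the instantaneous oxidation flux
#' to current: two electrons per phenazine, `I = 2 F * flux * volume`.
#' Current falls to zero as the terminal electron acceptor exhausts and
#' resumes at each spike.
#'
#' @param model An [assemble_model()] result (use `PCA_red0 = 0` in its
#'   params for a no-phenazine control).
#' @param t_grid Times (h).
#' @param spikes Optional tibble `time`/`amount` of TEA additions (uM),
#'   sorted by time.
#' @param noise A [noise_model()] applied to the current (uA).
#' @param volume_L Reactor working volume in liters.
#' @return Tibble `time_h`, `current_uA`, with attributes `charge_C` (exact
#'   noiseless cumulative charge) and `pca_mol` (phenazine equivalents
#'   oxidized).
#' @export
generate_current_trace <- function(model, t_grid = seq(0, 120, by = 0.1),
                                   spikes = NULL, noise = noise_model(0, 0),
                                   volume_L = 0.1) {
  if (!is.null(spikes) && nrow(spikes) > 0 && is.unsorted(spikes$time)) {
    stop("`spikes` must be sorted by time", call. = FALSE)
  }
  tr <- simulate_etc(model, t_grid, spikes = spikes, clamp_pca = TRUE)
  current <- tr$ox_flux * volume_L * 2 * FARADAY / 3600  # uM/h * L -> uA
  vals <- if (!is.null(noise$seed)) {
    withr::with_seed(noise$seed, apply_noise(current, noise))
  } else {
    apply_noise(current, noise)
  }
  out <- tibble(time_h = tr$time_h, current_uA = vals)
  attr(out, "charge_C") <- 2 * FARADAY * volume_L * 1e-6 * tr$cum_ox[nrow(tr)]
  attr(out, "pca_mol") <- volume_L * 1e-6 * tr$cum_ox[nrow(tr)]
  out
}
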