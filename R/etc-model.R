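#' Kinetic parameters for the electron transport chain flux model
#'
#' Concentrations in micromolar, time in hours. The model couples reduced
#' phenazine (PCA_red) to a terminal electron acceptor (TEA) through three
#' reaction categories: mass-action transfer into the oxidized quinone pool
#' (category 2, rate constants `k2`, per uM per hour, one per quinone
#' species), direct transfer to an expressed terminal reductase saturable in
#' the TEA (category 1, `k1`, per hour), and the direct chemical reaction
#' with the TEA (category 3, `k3`, per uM per hour). Quinol re-oxidation by
#' each reductase is Michaelis-Menten in the TEA (`Vmax`, uM/h quinol
#' turnover; `K_TEA`, uM). Defaults put category-2 throughput roughly an
#' order of magnitude above category 1, the regime in which oxidation by
#' quinones is the main component of the phenazine oxidation rate.
#'
#' @param k2 Named per-quinone rate constants (1/uM/h) for PCA -> quinone.
#' @param k1 Named per-reductase rate constants (1/h) for PCA -> reductase.
#' @param k3 Abiotic PCA -> TEA rate constant (1/uM/h).
#' @param Vmax Named per-reductase quinol turnover capacities (uM/h).
#' @param K_TEA TEA half-saturation (uM).
#' @param PCA_red0 Initial reduced phenazine (uM).
#' @param Q_tot Named per-quinone pool totals (uM). Membrane pools are small
#'   relative to the phenazine stock.
#' @param TEA0 Initial terminal electron acceptor (uM); 10 mM by default.
#' @param PCA_ox0 Initially oxidized phenazine (uM, default 0); the
#'   substrate of the optional net-reduction term.
#' @param q_red_frac0 Initial reduced fraction of each quinone pool; pools
#'   start reduced (1) after hypoxic carryover with no other electron donor.
#' @param k_reduce Optional net PCA-reduction rate (1/h) applied to oxidized
#'   phenazine by the cells; off (0) by default. Turning it on reproduces
#'   negative observed oxidation rates.
#' @param lag Transport-delay lag (h) before cellular fluxes activate; 0
#'   reproduces the no-lag model exactly.
#' @return A validated `model_params` list.
#' @export
model_params <- function(k2 = c(UQ = 0.15, MQ = 0.15, DMQ = 0.15),
                         k1 = setNames(rep(0.004, length(REDUCTASE_GENES)), REDUCTASE_GENES),
                         k3 = 1e-7,
                         Vmax = setNames(rep(4, length(REDUCTASE_GENES)), REDUCTASE_GENES),
                         K_TEA = 100,
                         PCA_red0 = 100,
                         Q_tot = c(UQ = 0.3, MQ = 0.3, DMQ = 0.3),
                         TEA0 = 10000,
                         PCA_ox0 = 0,
                         q_red_frac0 = 1,
                         k_reduce = 0,
                         lag = 0) {
  k2 <- fill_named(k2, QUINONE_SPECIES, "k2")
  Q_tot <- fill_named(Q_tot, QUINONE_SPECIES, "Q_tot")
  k1 <- fill_named(k1, REDUCTASE_GENES, "k1")
  Vmax <- fill_named(Vmax, REDUCTASE_GENES, "Vmax")
  vals <- c(k2, k1, k3 = k3, Vmax, K_TEA = K_TEA, PCA_red0 = PCA_red0,
            Q_tot, TEA0 = TEA0, PCA_ox0 = PCA_ox0, k_reduce = k_reduce,
            lag = lag)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all rates and concentrations must be finite and >= 0", call. = FALSE)
  }
  if (q_red_frac0 < 0 || q_red_frac0 > 1) {
    stop("`q_red_frac0` must lie in [0, 1]", call. = FALSE)
  }
  if (K_TEA <= 0) stop("`K_TEA` must be positive", call. = FALSE)
  structure(list(k2 = k2, k1 = k1, k3 = k3, Vmax = Vmax, K_TEA = K_TEA,
                 PCA_red0 = PCA_red0, Q_tot = Q_tot, TEA0 = TEA0,
                 PCA_ox0 = PCA_ox0, q_red_frac0 = q_red_frac0,
                 k_reduce = k_reduce, lag = lag),
            class = "model_params")
}

fill_named <- function(x, nms, what) {
  out <- setNames(rep(0, length(nms)), nms)
  if (is.null(names(x))) {
    if (length(x) == 1L) { out[] <- x; return(out) }
    if (length(x) == length(nms)) { out[] <- x; return(out) }
    stop("`", what, "` must be named or length 1", call. = FALSE)
  }
  bad <- setdiff(names(x), nms)
  if (length(bad)) stop("unknown name(s) in `", what, "`: ", paste(bad, collapse = ", "), call. = FALSE)
  out[names(x)] <- x
  out
}

#' Assemble the branched-chain flux model
#'
#' Combines a genotype, kinetic parameters, a pregrowth condition and a
#' terminal electron acceptor into a flux system. Knocked-out genes and
#' quinones the genotype cannot synthesize contribute zero flux; reductases
#' not serving the chosen acceptor are inactive; each active reductase
#' oxidizes only the quinol species it is compatible with. A genotype with
#' no active reductase and `k3 = 0` yields a valid but inert model.
#'
#' @param genotype A [genotype()].
#' @param params A [model_params()].
#' @param condition A [pregrowth_condition()].
#' @param acceptor `"nitrate"`, `"fumarate"`, `"DMSO"` or `"TMAO"`.
#' @param compat Quinone-reductase compatibility, [default_compatibility()].
#' @return An `etc_model` object.
#' @export
assemble_model <- function(genotype, params = model_params(),
                           condition = pregrowth_condition("hypoxic"),
                           acceptor = "nitrate",
                           compat = default_compatibility()) {
  stopifnot(inherits(genotype, "genotype"), inherits(params, "model_params"),
            inherits(condition, "pregrowth_condition"))
  reds <- acceptor_reductases(acceptor)  # errors on unknown acceptor
  active <- reds[genotype[reds]]
  e_w <- condition$weights[active]
  quin <- names(which(quinones_present(genotype) & params$Q_tot > 0))
  structure(list(
    genotype = genotype,
    params = params,
    condition = condition,
    acceptor = acceptor,
    reductases = active,          # expressed catalytic subunits for this TEA
    weights = e_w,                # pregrowth expression weight per reductase
    quinones = quin,              # quinone species with nonzero pools
    compat = compat[active, QUINONE_SPECIES, drop = FALSE]
  ), class = "etc_model")
}

#' @export
print.etc_model <- function(x, ...) {
  cat(sprintf("<etc_model> acceptor: %s | reductases: %s | quinones: %s | pregrowth: %s\n",
              x$acceptor,
              if (length(x$reductases)) paste(x$reductases, collapse = ", ") else "none",
              if (length(x$quinones)) paste(x$quinones, collapse = ", ") else "none",
              x$condition$label))
  invisible(x)
}

# Instantaneous fluxes (uM/h) at a given state. Returns the category fluxes
# and the total PCA-oxidizing flux. `gate` in [0,1] scales cellular fluxes
# (transport-delay lag).
etc_fluxes <- function(model, PCA_red, Q_red, TEA, gate = 1) {
  p <- model$params
  sat <- if (TEA > 0) TEA / (TEA + p$K_TEA) else 0
  q <- model$quinones
  v2 <- setNames(numeric(length(q)), q)
  v_resp <- setNames(numeric(length(q)), q)
  for (s in q) {
    Q_ox <- max(p$Q_tot[[s]] - Q_red[[s]], 0)
    v2[s] <- gate * p$k2[[s]] * PCA_red * Q_ox
    if (length(model$reductases)) {
      cap <- sum(p$Vmax[model$reductases] * model$weights * model$compat[, s])
      v_resp[s] <- gate * cap * (max(Q_red[[s]], 0) / p$Q_tot[[s]]) * sat
    }
  }
  v1 <- 0
  if (length(model$reductases)) {
    v1 <- gate * sum(p$k1[model$reductases] * model$weights) * PCA_red * sat
  }
  v3 <- p$k3 * PCA_red * TEA
  v_red <- gate * p$k_reduce * max(p$PCA_red0 + p$PCA_ox0 - PCA_red, 0)
  list(v2 = v2, v_resp = v_resp, v1 = v1, v3 = v3, v_red = v_red,
       ox_total = sum(v2) + v1 + v3)
}

#' Simulate an assembled flux model
#'
#' Integrates the flux system with `deSolve::lsoda`. Mid-run additions of
#' terminal electron acceptor (`spikes`) are handled by piecewise
#' re-initialization at the spike times. With `clamp_pca = TRUE` the reduced
#' phenazine is held at its initial value, emulating a poised working
#' electrode that instantly re-reduces any oxidized phenazine (the
#' bioelectrochemical reactor configuration).
#'
#' @param model An [assemble_model()] result.
#' @param t_grid Increasing time grid in hours starting at 0.
#' @param spikes Optional data frame / tibble with columns `time` (h) and
#'   `amount` (uM TEA added), sorted by time.
#' @param clamp_pca Hold PCA_red constant (electrode mode).
#' @param rtol,atol Solver tolerances.
#' @return An `etc_trajectory` tibble: `time_h`, `PCA_red`, `PCA_ox`,
#'   `Q_red_*`/`Q_ox_*` per species, `TEA`, `product`, `cum_ox` (cumulative
#'   phenazine oxidized, uM), `electrons` (= 2 * cum_ox, uM electron
#'   equivalents) and `ox_flux` (instantaneous oxidation flux, uM/h).
#' @export
simulate_etc <- function(model, t_grid = seq(0, 48, by = 0.25), spikes = NULL,
                         clamp_pca = FALSE, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(model, "etc_model"))
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE)) {
    stop("`t_grid` must start at 0 and be strictly increasing", call. = FALSE)
  }
  p <- model$params
  q <- model$quinones
  state <- c(PCA_red = p$PCA_red0,
             setNames(p$q_red_frac0 * p$Q_tot[q], paste0("Qr_", q, recycle0 = TRUE)),
             TEA = p$TEA0, product = 0, cum_ox = 0)

  deriv <- function(t, y, parms) {
    Q_red <- setNames(y[paste0("Qr_", q, recycle0 = TRUE)], q)
    gate <- if (p$lag > 0) 1 / (1 + exp(-(t - p$lag) / max(p$lag * 0.02, 1e-3))) else 1
    fl <- etc_fluxes(model, y[["PCA_red"]], Q_red, y[["TEA"]], gate)
    tea_flux <- sum(fl$v_resp) + fl$v1 + fl$v3   # 2 e- per TEA, 1:1 quanta
    dPCA <- if (clamp_pca) 0 else -fl$ox_total + fl$v_red
    dQ <- fl$v2 - fl$v_resp
    list(c(dPCA, dQ, -tea_flux, tea_flux, fl$ox_total))
  }

  seg_bounds <- numeric(0)
  if (!is.null(spikes) && nrow(spikes) > 0) {
    if (is.unsorted(spikes$time)) stop("`spikes` must be sorted by time", call. = FALSE)
    seg_bounds <- spikes$time
  }
  bounds <- c(0, seg_bounds, max(t_grid))
  out_rows <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    times <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid <= t1], t1)))
    sol <- deSolve::lsoda(y = state, times = times, func = deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed (lsoda istate = ", attr(sol, "istate")[1],
           ") in segment [", t0, ", ", t1, "] h", call. = FALSE)
    }
    sol <- as.data.frame(sol)
    keep <- sol$time %in% t_grid & !(i > 1L & sol$time == t0)
    out_rows[[i]] <- sol[keep, , drop = FALSE]
    state <- unlist(sol[nrow(sol), -1, drop = TRUE])
    if (i <= length(seg_bounds)) state[["TEA"]] <- state[["TEA"]] + spikes$amount[i]
  }
  sol <- do.call(rbind, out_rows)

  Q_red_mat <- as.matrix(sol[, paste0("Qr_", q, recycle0 = TRUE), drop = FALSE])
  flux <- vapply(seq_len(nrow(sol)), function(i) {
    gate <- if (p$lag > 0) 1 / (1 + exp(-(sol$time[i] - p$lag) / max(p$lag * 0.02, 1e-3))) else 1
    etc_fluxes(model, sol$PCA_red[i], setNames(Q_red_mat[i, ], q), sol$TEA[i], gate)$ox_total
  }, numeric(1))

  out <- tibble(time_h = sol$time,
                PCA_red = sol$PCA_red,
                PCA_ox = p$PCA_red0 + p$PCA_ox0 - sol$PCA_red)
  for (s in QUINONE_SPECIES) {
    col <- paste0("Qr_", s)
    qr <- if (col %in% names(sol)) sol[[col]] else rep(0, nrow(sol))
    tot <- if (s %in% q) p$Q_tot[[s]] else 0
    out[[paste0("Q_red_", s)]] <- qr
    out[[paste0("Q_ox_", s)]] <- tot - qr
  }
  out$TEA <- sol$TEA
  out$product <- sol$product
  out$cum_ox <- sol$cum_ox
  out$electrons <- 2 * sol$cum_ox
  out$ox_flux <- flux
  attr(out, "model") <- model
  attr(out, "spikes") <- spikes
  class(out) <- c("etc_trajectory", class(out))
  out
}

#' Check conservation laws of a trajectory
#'
#' Verifies phenazine, quinone-pool and acceptor mass balances and the
#' two-electron bookkeeping (`2 * cum_ox = 2 * delta Q_red + 2 * product`,
#' phenazine being the sole electron donor to the chain).
#'
#' @param traj An `etc_trajectory`.
#' @return Named numeric vector of maximum relative violations.
#' @export
conservation_errors <- function(traj) {
  model <- attr(traj, "model")
  p <- model$params
  spikes <- attr(traj, "spikes")
  total_pca <- p$PCA_red0 + p$PCA_ox0
  scale_pca <- max(total_pca, 1)
  err_pca <- max(abs(traj$PCA_red + traj$PCA_ox - total_pca)) / scale_pca
  err_q <- 0
  for (s in model$quinones) {
    tot <- p$Q_tot[[s]]
    err_q <- max(err_q, max(abs(traj[[paste0("Q_red_", s)]] +
                                  traj[[paste0("Q_ox_", s)]] - tot)) / max(tot, 1e-9))
  }
  # the row recorded at a spike time precedes the addition
  added <- if (is.null(spikes)) rep(0, nrow(traj)) else
    vapply(traj$time_h, function(t) sum(spikes$amount[spikes$time < t]), numeric(1))
  scale_tea <- max(p$TEA0 + if (is.null(spikes)) 0 else sum(spikes$amount), 1)
  err_tea <- max(abs(traj$TEA + traj$product - p$TEA0 - added)) / scale_tea
  # electron ledger: 2 e- per phenazine into quinols (2 e- each) or product
  dq <- rep(0, nrow(traj))
  for (s in model$quinones) {
    dq <- dq + traj[[paste0("Q_red_", s)]] - traj[[paste0("Q_red_", s)]][1]
  }
  err_e <- max(abs(2 * traj$cum_ox - (2 * dq + 2 * traj$product))) /
    max(2 * max(traj$cum_ox), 1)
  c(phenazine = err_pca, quinone = err_q, acceptor = err_tea, electron = err_e)
}

#' Simulated knockout panel of maximum oxidation rates
#'
#' Simulates each genotype under shared parameters/condition/acceptor,
#' converts the reduced-phenazine trajectory to a fluorescence-like curve
#' (fluorescence is linear in PCA_red) and pipes it through the kinetic
#' feature extraction, returning one row per genotype.
#'
#' @param genotypes Named list of [genotype()] objects.
#' @param params,condition,acceptor,compat Shared model configuration.
#' @param t_grid Assay time grid (h).
#' @param fraction LOWESS window fraction for the metric extraction.
#' @param calibration Fluorescence units per uM reduced phenazine.
#' @return Tibble: `strain`, `max_rate` (fluorescence units/h), `t_at_max`,
#'   `t_half` (h, `NA` when the half-oxidation threshold is never reached),
#'   `detected`.
#' @export
knockout_panel <- function(genotypes, params = model_params(),
                           condition = pregrowth_condition("hypoxic"),
                           acceptor = "nitrate",
                           compat = default_compatibility(),
                           t_grid = seq(0, 48, by = 0.25),
                           fraction = 0.05, calibration = 1) {
  stopifnot(is.list(genotypes), length(genotypes) >= 1L)
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes)))) {
    stop("`genotypes` must be a named list", call. = FALSE)
  }
  rows <- lapply(names(genotypes), function(nm) {
    m <- assemble_model(genotypes[[nm]], params, condition, acceptor, compat)
    tr <- simulate_etc(m, t_grid)
    curve <- oxidation_curve(tr$time_h, calibration * tr$PCA_red)
    met <- extract_metrics(curve, fraction = fraction)
    tibble(strain = nm, max_rate = met$max_rate, t_at_max = met$t_at_max,
           t_half = met$t_half, detected = met$detected)
  })
  dplyr::bind_rows(rows)
}
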