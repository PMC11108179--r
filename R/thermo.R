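#' @importFrom tibble tibble as_tibble
#' @importFrom stats median pt qt rnorm sd setNames uniroot optimize
#' @importFrom utils head read.csv write.csv combn
NULL

# Physical constants (SI)
FARADAY <- 96485.33212    # C per mol electrons
GAS_CONSTANT <- 8.314462618  # J / mol / K

#' Define a redox half-reaction
#'
#' A half-reaction is one rung of the electron tower: a redox couple with a
#' midpoint potential at pH 7 (`E0_prime`, volts vs. the standard hydrogen
#' electrode) and its electron/proton stoichiometry. Phenazine and quinone
#' couples are two-electron, two-proton processes.
#'
#' @param name Short unique label, e.g. `"PCA"`.
#' @param E0_prime Midpoint potential in volts vs. SHE at pH 7. Must be finite
#'   and within +-2 V.
#' @param n_electrons Positive integer number of electrons transferred.
#' @param n_protons Non-negative integer number of protons transferred.
#' @param oxidized_label,reduced_label Species names for the two redox states.
#' @return An object of class `half_reaction`.
#' @examples
#' pca <- half_reaction("PCA", -0.24, 2, 2, "PCA_ox", "PCA_red")
#' @export
half_reaction <- function(name, E0_prime, n_electrons = 2L, n_protons = 2L,
                          oxidized_label = paste0(name, "_ox"),
                          reduced_label = paste0(name, "_red")) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(E0_prime) || length(E0_prime) != 1L || !is.finite(E0_prime) ||
      abs(E0_prime) >= 2) {
    stop("`E0_prime` must be a finite potential with |E0_prime| < 2 V", call. = FALSE)
  }
  n_electrons <- as.integer(n_electrons)
  n_protons <- as.integer(n_protons)
  if (is.na(n_electrons) || n_electrons < 1L) {
    stop("`n_electrons` must be a positive integer", call. = FALSE)
  }
  if (is.na(n_protons) || n_protons < 0L) {
    stop("`n_protons` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(name = name, E0_prime = E0_prime, n_electrons = n_electrons,
         n_protons = n_protons, oxidized_label = oxidized_label,
         reduced_label = reduced_label),
    class = "half_reaction"
  )
}

#' @export
print.half_reaction <- function(x, ...) {
  cat(sprintf("<half_reaction> %s: E0' = %+.3f V (%de-, %dH+)  %s/%s\n",
              x$name, x$E0_prime, x$n_electrons, x$n_protons,
              x$oxidized_label, x$reduced_label))
  invisible(x)
}

#' Assemble a potential table (electron tower)
#'
#' @param reactions A list of [half_reaction()] objects with unique names.
#' @param temperature Temperature in kelvin (default 298.15 K).
#' @param pH Reference pH (default 7).
#' @return A `potential_table`: a tibble with one row per half-reaction and
#'   `temperature` / `pH` attributes.
#' @export
potential_table <- function(reactions, temperature = 298.15, pH = 7) {
  stopifnot(is.list(reactions), length(reactions) >= 1L)
  ok <- vapply(reactions, inherits, logical(1), "half_reaction")
  if (!all(ok)) stop("all `reactions` must be half_reaction objects", call. = FALSE)
  nms <- vapply(reactions, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("half-reaction names must be unique: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  tbl <- tibble(
    name = nms,
    E0_prime = vapply(reactions, `[[`, numeric(1), "E0_prime"),
    n_electrons = vapply(reactions, `[[`, integer(1), "n_electrons"),
    n_protons = vapply(reactions, `[[`, integer(1), "n_protons"),
    oxidized_label = vapply(reactions, `[[`, character(1), "oxidized_label"),
    reduced_label = vapply(reactions, `[[`, character(1), "reduced_label")
  )
  attr(tbl, "temperature") <- temperature
  attr(tbl, "pH") <- pH
  class(tbl) <- c("potential_table", class(tbl))
  tbl
}

#' Default electron tower for phenazine oxidation
#'
#' Midpoint potentials (pH 7, vs. SHE) for the couples relevant to anaerobic
#' phenazine oxidation: the phenazines PCA and pyocyanin, the three quinones,
#' and the four respirable terminal electron acceptors. Values are standard
#' literature numbers (Thauer-style tabulations and the E. coli quinone
#' literature); pyocyanin's -0.040 V is its commonly cited half-wave
#' potential. All couples here are treated as two-electron transfers;
#' nitrate/nitrite and the N-/S-oxide couples are 2e-, the quinones and
#' phenazines additionally carry two protons.
#'
#' @return A [potential_table()].
#' @export
default_potential_table <- function() {
  potential_table(list(
    half_reaction("PCA", -0.240, 2L, 2L, "PCA_ox", "PCA_red"),
    half_reaction("pyocyanin", -0.040, 2L, 2L, "PYO_ox", "PYO_red"),
    half_reaction("menaquinone", -0.074, 2L, 2L, "MQ", "MQH2"),
    half_reaction("demethylmenaquinone", 0.036, 2L, 2L, "DMQ", "DMQH2"),
    half_reaction("ubiquinone", 0.100, 2L, 2L, "UQ", "UQH2"),
    half_reaction("fumarate", 0.033, 2L, 0L, "fumarate", "succinate"),
    half_reaction("TMAO", 0.130, 2L, 2L, "TMAO", "TMA"),
    half_reaction("DMSO", 0.160, 2L, 2L, "DMSO", "DMS"),
    half_reaction("nitrate", 0.433, 2L, 2L, "NO3-", "NO2-")
  ))
}

#' Read a potential table from CSV
#'
#' The file must have columns `name`, `E0_prime`, `n_electrons`, `n_protons`
#' and optionally `oxidized_label`, `reduced_label`.
#'
#' @param path Path to a CSV file (lines starting with `#` are ignored).
#' @param temperature,pH Context passed to [potential_table()].
#' @export
read_potential_table <- function(path, temperature = 298.15, pH = 7) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "E0_prime", "n_electrons", "n_protons")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$oxidized_label)) df$oxidized_label <- paste0(df$name, "_ox")
  if (is.null(df$reduced_label)) df$reduced_label <- paste0(df$name, "_red")
  rx <- lapply(seq_len(nrow(df)), function(i) {
    half_reaction(df$name[i], df$E0_prime[i], df$n_electrons[i], df$n_protons[i],
                  df$oxidized_label[i], df$reduced_label[i])
  })
  potential_table(rx, temperature = temperature, pH = pH)
}

get_half_reaction <- function(table, name) {
  i <- match(name, table$name)
  if (is.na(i)) {
    stop("half-reaction not in table: '", name, "'", call. = FALSE)
  }
  half_reaction(table$name[i], table$E0_prime[i], table$n_electrons[i],
                table$n_protons[i], table$oxidized_label[i], table$reduced_label[i])
}

#' Standard reaction potential of a redox coupling
#'
#' Couples the oxidation of `donor` to the reduction of `acceptor`. A
#' positive difference means the pairing is thermodynamically favorable at
#' standard conditions (a more positive acceptor couple below a more
#' negative donor couple on the tower).
#'
#' @param donor,acceptor [half_reaction()] objects sharing a temperature/pH
#'   context.
#' @return The reaction potential `acceptor$E0_prime - donor$E0_prime` in volts.
#' @export
reaction_potential <- function(donor, acceptor) {
  stopifnot(inherits(donor, "half_reaction"), inherits(acceptor, "half_reaction"))
  acceptor$E0_prime - donor$E0_prime
}

#' Gibbs free energy of an n-electron redox reaction
#'
#' `delta_G = -n F delta_E`; negative when the coupling is favorable.
#'
#' @param delta_E Reaction potential in volts.
#' @param n_electrons Number of electrons transferred (>= 1).
#' @return Free energy in joules per mole.
#' @export
gibbs_free_energy <- function(delta_E, n_electrons) {
  stopifnot(is.numeric(delta_E), is.numeric(n_electrons))
  if (any(n_electrons < 1)) stop("`n_electrons` must be >= 1", call. = FALSE)
  -n_electrons * FARADAY * delta_E
}

#' Nernst adjustment of a midpoint potential
#'
#' Moves a pH-7 midpoint potential to another pH and reduced:oxidized ratio:
#' `E = E0' - ln(10) R T (n_p/n_e F) (pH - 7) - (R T / n_e F) ln(ratio)`.
#' At pH 7 and ratio 1 the configured `E0_prime` is returned exactly.
#'
#' @param hr A [half_reaction()].
#' @param pH Solution pH in `[0, 14]`.
#' @param ratio_red_over_ox Activity ratio reduced/oxidized; must be > 0.
#' @param temperature Kelvin.
#' @return Adjusted potential in volts.
#' @export
nernst_adjust <- function(hr, pH = 7, ratio_red_over_ox = 1, temperature = 298.15) {
  stopifnot(inherits(hr, "half_reaction"))
  if (!is.numeric(ratio_red_over_ox) || any(ratio_red_over_ox <= 0)) {
    stop("`ratio_red_over_ox` must be positive", call. = FALSE)
  }
  if (pH < 0 || pH > 14) stop("`pH` must lie in [0, 14]", call. = FALSE)
  rt_f <- GAS_CONSTANT * temperature / FARADAY
  hr$E0_prime -
    log(10) * rt_f * hr$n_protons / hr$n_electrons * (pH - 7) -
    rt_f / hr$n_electrons * log(ratio_red_over_ox)
}

#' Thermodynamically favorable oxidants of a donor couple
#'
#' Screens every other couple in the table as a potential oxidant of `donor`
#' (donor oxidized, acceptor reduced) and keeps the strictly favorable
#' pairings (`delta_E > 0`; ties count as unfavorable).
#'
#' @param table A [potential_table()].
#' @param donor Name of the donor couple (must be in the table).
#' @return Tibble with columns `acceptor`, `delta_E`, sorted by descending
#'   `delta_E`; the donor itself is excluded.
#' @export
favorable_acceptors <- function(table, donor) {
  stopifnot(inherits(table, "potential_table"))
  d <- get_half_reaction(table, donor)
  others <- table[table$name != donor, , drop = FALSE]
  out <- tibble(acceptor = others$name, delta_E = others$E0_prime - d$E0_prime)
  out <- out[out$delta_E > 0, , drop = FALSE]
  out[order(-out$delta_E), , drop = FALSE]
}

# quinone species label -> default table couple name
QUINONE_COUPLES <- c(UQ = "ubiquinone", MQ = "menaquinone", DMQ = "demethylmenaquinone")

#' Route-aware screen of phenazine oxidants
#'
#' Predicts which quinones and which respirable terminal electron acceptors
#' (TEAs) can drive oxidation of a phenazine donor. Quinones are screened by
#' direct pairwise favorability (`delta_E(donor -> quinone) > 0`). A TEA is
#' predicted to work only if a full respiratory route exists: some quinone q
#' with (i) `delta_E(donor -> q) > 0`, (ii) `delta_E(q -> TEA) > 0`, and
#' (iii) a terminal reductase for that TEA that accepts electrons from q
#' (the quinone-reductase compatibility matrix). This is the electron-tower
#' argument for why a phenazine with a relatively positive midpoint
#' potential, such as pyocyanin, cannot be oxidized through menaquinone, and
#' hence not by fumarate respiration, even though the raw
#' pyocyanin/fumarate pair is downhill.
#'
#' @param table A [potential_table()] containing the donor, the quinone
#'   couples and the TEA couples.
#' @param donor Donor couple name (e.g. `"PCA"` or `"pyocyanin"`).
#' @param compat Quinone-reductase compatibility matrix, see
#'   [default_compatibility()].
#' @param acceptors TEA couple names to screen; defaults to the four
#'   respirable acceptors.
#' @return Tibble with one row per screened species: `species`, `type`
#'   (`"quinone"` or `"acceptor"`), `favorable`, `delta_E` (direct step for
#'   quinones; the limiting step of the best route for TEAs, `NA` when no
#'   route exists), and `route` (the mediating quinone, or `NA`).
#' @export
oxidant_screen <- function(table, donor, compat = default_compatibility(),
                           acceptors = c("nitrate", "fumarate", "DMSO", "TMAO")) {
  stopifnot(inherits(table, "potential_table"))
  d <- get_half_reaction(table, donor)
  q_names <- QUINONE_COUPLES[QUINONE_COUPLES %in% table$name]
  dE_q <- vapply(q_names, function(nm) {
    get_half_reaction(table, nm)$E0_prime - d$E0_prime
  }, numeric(1))
  rows_q <- tibble(species = unname(q_names), type = "quinone",
                   favorable = unname(dE_q) > 0, delta_E = unname(dE_q),
                   route = NA_character_)

  rows_a <- lapply(acceptors, function(a) {
    ea <- get_half_reaction(table, a)$E0_prime
    reds <- acceptor_reductases(a)
    best <- NA_real_; via <- NA_character_
    for (q in names(q_names)) {
      eq <- get_half_reaction(table, q_names[[q]])$E0_prime
      step1 <- eq - d$E0_prime   # donor -> quinone
      step2 <- ea - eq           # quinol -> TEA via a compatible reductase
      if (step1 > 0 && step2 > 0 && any(compat[reds, q])) {
        lim <- min(step1, step2)
        if (is.na(best) || lim > best) { best <- lim; via <- q_names[[q]] }
      }
    }
    tibble(species = a, type = "acceptor", favorable = !is.na(best),
           delta_E = best, route = unname(via))
  })
  dplyr::bind_rows(rows_q, dplyr::bind_rows(rows_a))
}
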