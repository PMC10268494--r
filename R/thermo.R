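R_GAS <- 8.314462618e-3   # kJ/mol/K
T_REF <- 298.15           # K, reference for the formation-energy table
RTLN10_REF <- R_GAS * T_REF * log(10)  # kJ/mol per pH unit per proton

#' Standard transformed Gibbs energies of formation
#'
#' Formation energies of the fermentation species, compiled from a
#' Thauer-style thermochemical table of standard (untransformed) values at
#' 298.15 K and converted to the transformed convention at pH 7 via
#' \eqn{\Delta_f G'^\circ = \Delta_f G^\circ + N_H \, RT \ln 10 \cdot pH}.
#' In the transformed convention the proton is absorbed: it contributes
#' neither to reaction sums nor to the reaction quotient.
#'
#' @param config optional path to a YAML file with a \code{thermo:} list of
#'   records (\code{name}, \code{dfG0_kJ}, optional \code{note}) replacing
#'   the built-in values (untransformed standard formation energies).
#' @param species species table (provides H counts for the transform).
#' @return data.frame with columns \code{name}, \code{dfG0_kJ}
#'   (untransformed), \code{dfG0prime_kJ} (transformed, pH 7),
#'   \code{note}; attributes \code{ref_temperature} (298.15 K) and
#'   \code{ref_pH} (7).
#' @export
thermo_table <- function(config = NULL, species = species_table()) {
  if (is.null(config)) {
    df <- data.frame(
      name = c("glucose", "butyrate", "acetate", "lactate", "formate",
               "CO2", "H2", "CH4", "H2O", "H+"),
      dfG0_kJ = c(-917.22, -352.63, -369.41, -517.18, -351.04,
                  -394.36, 0, -50.75, -237.18, 0),
      note = c(rep("Thauer-style compilation, aqueous, 298.15 K", 5),
               "gas", "gas", "gas", "liquid", "convention"),
      stringsAsFactors = FALSE
    )
  } else {
    cfg <- yaml::read_yaml(config)
    if (is.null(cfg$thermo)) stop("config has no 'thermo' entry", call. = FALSE)
    df <- do.call(rbind, lapply(cfg$thermo, function(s) {
      data.frame(name = s$name, dfG0_kJ = as.numeric(s$dfG0_kJ),
                 note = if (is.null(s$note)) "" else s$note,
                 stringsAsFactors = FALSE)
    }))
  }
  idx <- match(df$name, species$name)
  if (anyNA(idx)) {
    stop("thermo table names unknown to species table: ",
         paste(df$name[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  nH <- species$H[idx]
  df$dfG0prime_kJ <- df$dfG0_kJ + nH * RTLN10_REF * 7
  # the proton is absorbed by the transformed convention
  df$dfG0prime_kJ[df$name == "H+"] <- 0
  rownames(df) <- df$name
  structure(df, ref_temperature = T_REF, ref_pH = 7, class = "data.frame")
}

#' Reaction conditions for Gibbs energy evaluation
#'
#' Temperature, pH, solute concentrations and gas partial pressures at which
#' a fermentation balance is evaluated.  Defaults are literature-typical
#' physiological values for the colonic / culture environment: 37 C, pH 7,
#' glucose 10 mM, acetate 60 mM, butyrate 20 mM, lactate and formate 1 mM,
#' 0.2 atm CO2.  Water activity is fixed at 1.
#'
#' @param temperature Kelvin.
#' @param pH medium pH (handled through the transformed convention).
#' @param concentrations named mol/L vector for aqueous solutes.
#' @param pCO2_atm,pH2_atm,pCH4_atm gas partial pressures in atm.
#' @return object of class \code{fermentation_conditions}.
#' @export
fermentation_conditions <- function(temperature = 310.15, pH = 7,
                                    concentrations = c(glucose = 0.010,
                                                       acetate = 0.060,
                                                       butyrate = 0.020,
                                                       lactate = 0.001,
                                                       formate = 0.001),
                                    pCO2_atm = 0.2, pH2_atm = 0.01,
                                    pCH4_atm = 0.001) {
  stopifnot(temperature > 0, pH2_atm >= 0, pCO2_atm > 0)
  if (any(concentrations <= 0)) {
    stop("solute concentrations must be > 0", call. = FALSE)
  }
  structure(
    list(temperature = temperature, pH = pH,
         concentrations = concentrations,
         partial_pressures = c(CO2 = pCO2_atm, H2 = pH2_atm,
                               CH4 = pCH4_atm)),
    class = "fermentation_conditions"
  )
}

#' Standard transformed Gibbs energy of a balance
#'
#' \eqn{\Delta G'^\circ = \sum_i \nu_i \Delta_f G'^\circ_i}, the pure
#' formation-energy bookkeeping with no concentration terms.  At a pH other
#' than the table's reference the per-species transform is shifted by
#' \eqn{N_H \, RT\ln 10\,(pH - pH_{ref})}; the proton itself contributes
#' nothing.
#'
#' @param balance a \code{\link{fermentation_balance}}.
#' @param table a \code{\link{thermo_table}}.
#' @param pH evaluation pH (default: the table's reference pH).
#' @return kJ per mol reaction as written.
#' @export
delta_g_standard <- function(balance, table = thermo_table(),
                             pH = attr(table, "ref_pH")) {
  stopifnot(inherits(balance, "fermentation_balance"))
  cf <- balance$coefficients
  cf <- cf[names(cf) != "H+"]
  if (length(cf) == 0) return(0)
  idx <- match(names(cf), table$name)
  if (anyNA(idx)) {
    stop("species missing from thermo table: ",
         paste(names(cf)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sp <- balance$species
  nH <- sp$H[match(names(cf), sp$name)]
  g <- table$dfG0prime_kJ[idx] +
    nH * RTLN10_REF * (pH - attr(table, "ref_pH"))
  sum(cf * g)
}

#' Gibbs energy of a balance at given conditions
#'
#' \eqn{\Delta G = \Delta G'^\circ + RT \ln Q} with the reaction quotient
#' built from molar solute concentrations (1 M standard state) and gas
#' partial pressures in atm (1 atm standard state); water activity 1 and
#' protons absorbed into the transformed convention.
#'
#' @param balance a \code{\link{fermentation_balance}}.
#' @param table a \code{\link{thermo_table}}.
#' @param cond a \code{\link{fermentation_conditions}} object.
#' @return kJ per mol reaction as written.
#' @export
delta_g <- function(balance, table = thermo_table(),
                    cond = fermentation_conditions()) {
  stopifnot(inherits(cond, "fermentation_conditions"))
  cf <- balance$coefficients
  cf <- cf[!names(cf) %in% c("H+", "H2O")]
  cf <- cf[abs(cf) > 1e-12]
  dg0 <- delta_g_standard(balance, table, pH = cond$pH)
  if (length(cf) == 0) return(dg0)
  sp <- balance$species
  phase <- sp$phase[match(names(cf), sp$name)]
  act <- numeric(length(cf))
  for (i in seq_along(cf)) {
    nm <- names(cf)[i]
    if (phase[i] == "gas") {
      a <- cond$partial_pressures[nm]
      if (is.na(a)) stop("no partial pressure given for ", nm, call. = FALSE)
      if (a == 0) {
        stop("partial pressure of ", nm, " is zero while its coefficient ",
             "is nonzero: Gibbs energy is unboundedly favorable",
             call. = FALSE)
      }
    } else {
      a <- cond$concentrations[nm]
      if (is.na(a)) stop("no concentration given for ", nm, call. = FALSE)
      if (a <= 0) stop("non-positive concentration for ", nm, call. = FALSE)
    }
    act[i] <- a
  }
  dg0 + R_GAS * cond$temperature * sum(cf * log(act))
}

#' ATP-feasibility threshold
#'
#' Number of ATP whose synthesis a reaction's Gibbs energy can drive,
#' assuming a fixed energy per ADP phosphorylation (default +70 kJ/mol):
#' the largest integer \eqn{n \ge 0} with \eqn{\Delta G \le -n \,
#' \Delta G_{ATP}}.
#'
#' @param deltaG reaction Gibbs energy, kJ/mol (vectorized).
#' @param dG_atp energy per ATP formed, kJ/mol, > 0.
#' @return integer vector of feasible ATP counts.
#' @export
n_atp_feasible <- function(deltaG, dG_atp = 70) {
  stopifnot(dG_atp > 0)
  pmax(0L, as.integer(floor(-deltaG / dG_atp + 1e-12)))
}

#' Sweep Gibbs energy over butyrate yield and H2 partial pressure
#'
#' Evaluates \code{\link{delta_g}} of the balanced fermentation family on a
#' grid of butyrate yields and H2 partial pressures and annotates each point
#' with the number of ATP the energy could drive.  Because the family's H2
#' coefficient is 4 - 2b, curves for low butyrate yields rise steeply with
#' H2 while the b = 2 curve is flat.
#'
#' @param b_grid butyrate yields in [0, 2].
#' @param pH2_grid H2 partial pressures in atm, > 0.
#' @param table a \code{\link{thermo_table}}.
#' @param cond a \code{\link{fermentation_conditions}} object (its
#'   \code{pH2_atm} is overridden by the grid).
#' @param dG_atp ATP threshold energy, kJ/mol.
#' @param species species table.
#' @return data.frame of class \code{h2_sweep} with columns \code{b},
#'   \code{pH2_atm}, \code{deltaG_kJ_per_mol}, \code{n_atp_feasible}.
#' @export
sweep_h2 <- function(b_grid = seq(0, 2, by = 0.25),
                     pH2_grid = 10^seq(-6, 0, length.out = 50),
                     table = thermo_table(),
                     cond = fermentation_conditions(),
                     dG_atp = 70, species = species_table()) {
  stopifnot(length(b_grid) > 0, length(pH2_grid) > 0, all(pH2_grid > 0))
  rows <- vector("list", length(b_grid))
  for (i in seq_along(b_grid)) {
    bal <- build_balance_family(b_grid[i], species = species)
    dg <- vapply(pH2_grid, function(p) {
      ci <- cond
      ci$partial_pressures["H2"] <- p
      delta_g(bal, table, ci)
    }, numeric(1))
    rows[[i]] <- data.frame(b = b_grid[i], pH2_atm = pH2_grid,
                            deltaG_kJ_per_mol = dg,
                            n_atp_feasible = n_atp_feasible(dg, dG_atp))
  }
  out <- do.call(rbind, rows)
  attr(out, "dG_atp") <- dG_atp
  attr(out, "temperature") <- cond$temperature
  class(out) <- c("h2_sweep", "data.frame")
  out
}

#' @export
plot.h2_sweep <- function(x, ...) {
  bs <- sort(unique(x$b))
  cols <- grDevices::hcl.colors(length(bs), "viridis")
  graphics::plot(range(x$pH2_atm), range(x$deltaG_kJ_per_mol), type = "n",
                 log = "x", xlab = "pH2 (atm)",
                 ylab = expression(Delta * G ~ "(kJ/mol glucose)"), ...)
  for (i in seq_along(bs)) {
    s <- x[x$b == bs[i], ]
    graphics::lines(s$pH2_atm, s$deltaG_kJ_per_mol, col = cols[i])
  }
  dga <- attr(x, "dG_atp")
  nmax <- max(x$n_atp_feasible)
  if (nmax > 0) {
    graphics::abline(h = -dga * seq_len(nmax), lty = 3, col = "grey40")
  }
  graphics::legend("topleft", legend = sprintf("b = %g", bs), col = cols,
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' Dissolved H2 concentration from Henry's law
#'
#' Converts an H2 partial pressure to the equilibrium dissolved
#' concentration using a Henry solubility of 7.8e-4 mol/L/atm at 298.15 K
#' with a van 't Hoff temperature correction (d ln k / d(1/T) = 500 K),
#' constants from a standard solubility compilation.  At 310 K and 1 atm
#' this gives about 0.73 mmol/L.
#'
#' @param pH2 partial pressure, atm (vectorized).
#' @param temperature Kelvin.
#' @return dissolved H2, mmol/L.
#' @export
henry_dissolved_h2 <- function(pH2, temperature = 310.15) {
  stopifnot(all(pH2 >= 0), temperature > 0)
  kH <- 7.8e-4 * exp(500 * (1 / temperature - 1 / T_REF))  # mol/L/atm
  1000 * kH * pH2
}
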