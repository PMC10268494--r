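#' Branch fractions of the butyrogen fermentation network
#'
#' Parameters of the branched network: the fraction of pyruvate reduced to
#' lactate by LDH, the fraction of the remaining (acetyl-CoA-forming)
#' pyruvate cleaved by PFL (the remainder is oxidized by PFOR), the fraction
#' of acetyl-CoA entering the butyrate branch, the ATP conserved per reduced
#' ferredoxin pair oxidized by the Rnf complex, and whether a generic
#' NADH-to-H2 disposal route is available.
#'
#' @param lactate_fraction fraction of pyruvate to LDH, in [0, 1].
#' @param pfl_fraction fraction of acetyl-CoA-forming pyruvate via PFL, in
#'   [0, 1].
#' @param butyrate_fraction fraction of acetyl-CoA entering the butyrate
#'   branch, in [0, 1].
#' @param rnf_atp_per_fd ATP per reduced-ferredoxin pair oxidized by Rnf
#'   (chemiosmotic; default 0.5, i.e. 2 translocated ions per ferredoxin
#'   pair at 4 ions per ATP).
#' @param allow_nadh_to_h2 enable a generic NADH -> H2 disposal route.  The
#'   strict network (ferredoxin hydrogenase only) cannot reoxidize excess
#'   NADH when little pyruvate is reduced to lactate and little acetyl-CoA
#'   enters the butyrate branch; with this flag off such parameter choices
#'   are reported as infeasible rather than silently patched.
#' @return object of class \code{branch_params}.
#' @export
branch_params <- function(lactate_fraction = 0, pfl_fraction = 0,
                          butyrate_fraction = 1, rnf_atp_per_fd = 0.5,
                          allow_nadh_to_h2 = FALSE) {
  frac <- c(lactate_fraction = lactate_fraction,
            pfl_fraction = pfl_fraction,
            butyrate_fraction = butyrate_fraction)
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1)) {
    stop("branch fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(rnf_atp_per_fd) || rnf_atp_per_fd < 0) {
    stop("rnf_atp_per_fd must be >= 0", call. = FALSE)
  }
  structure(
    list(lactate_fraction = lactate_fraction,
         pfl_fraction = pfl_fraction,
         butyrate_fraction = butyrate_fraction,
         rnf_atp_per_fd = rnf_atp_per_fd,
         allow_nadh_to_h2 = isTRUE(allow_nadh_to_h2)),
    class = "branch_params"
  )
}

#' Internal stoichiometry of the branched network
#'
#' Stoichiometric matrix of the internal (balanced) metabolites over the
#' network's reactions, per unit flux.  Reduced ferredoxin is counted in
#' two-electron pairs.  A feasible flux vector multiplied by this matrix is
#' zero on every row.
#'
#' @return numeric matrix, rows internal metabolites, columns reactions.
#' @export
flux_stoichiometry <- function() {
  rx <- c("glycolysis", "ldh", "pfor", "pfl", "pta", "ack",
          "butyrate_branch", "but_transferase", "hydrogenase", "rnf",
          "nadh_to_h2")
  met <- c("pyruvate", "acetyl_coa", "acetyl_p", "nadh", "fd_red",
           "butyryl_coa")
  S <- matrix(0, length(met), length(rx), dimnames = list(met, rx))
  S["pyruvate", "glycolysis"] <- 2
  S["nadh", "glycolysis"] <- 2
  S["pyruvate", "ldh"] <- -1
  S["nadh", "ldh"] <- -1
  S["pyruvate", "pfor"] <- -1
  S["acetyl_coa", "pfor"] <- 1
  S["fd_red", "pfor"] <- 1
  S["pyruvate", "pfl"] <- -1
  S["acetyl_coa", "pfl"] <- 1
  S["acetyl_coa", "pta"] <- -1
  S["acetyl_p", "pta"] <- 1
  S["acetyl_p", "ack"] <- -1
  # per butyryl-CoA: 2 acetyl-CoA condensed; Bhbd reoxidizes 1 NADH and
  # Bcd-Etf bifurcates 2 NADH into crotonyl-CoA reduction + 1 Fd pair
  S["acetyl_coa", "butyrate_branch"] <- -2
  S["nadh", "butyrate_branch"] <- -3
  S["fd_red", "butyrate_branch"] <- 1
  S["butyryl_coa", "butyrate_branch"] <- 1
  # But transferase: butyryl-CoA + free acetate -> butyrate + acetyl-CoA
  S["butyryl_coa", "but_transferase"] <- -1
  S["acetyl_coa", "but_transferase"] <- 1
  S["fd_red", "hydrogenase"] <- -1
  S["fd_red", "rnf"] <- -1
  S["nadh", "rnf"] <- 1
  S["nadh", "nadh_to_h2"] <- -1
  S
}

#' Solve the redox-balanced flux distribution of the network
#'
#' Per mole of glucose: glycolysis forms 2 pyruvate, 2 ATP and 2 NADH.  A
#' fraction of pyruvate is reduced to lactate (LDH); the rest forms
#' acetyl-CoA via PFL (releasing formate) or PFOR (releasing CO2 and
#' reducing ferredoxin).  Acetyl-CoA splits between acetate production
#' (acetyl-P, then acetate kinase with 1 ATP each) and the butyrate branch
#' (2 acetyl-CoA per butyryl-CoA; 3 NADH reoxidized and 1 ferredoxin pair
#' reduced per butyrate via Bhbd and the electron-bifurcating Bcd-Etf).
#' Butyrate release by the CoA transferase consumes one free acetate and
#' returns one acetyl-CoA, which flows to acetate kinase.  The Rnf flux is
#' chosen to close the NADH balance and the ferredoxin hydrogenase flux to
#' close the ferredoxin balance; if closing NADH would require a negative
#' Rnf flux the solution is infeasible unless the NADH-to-H2 route is
#' enabled.
#'
#' @param params a \code{\link{branch_params}} object.
#' @param species species table used for the net balance.
#' @return object of class \code{flux_solution} with elements \code{fluxes}
#'   (named, per mol glucose), \code{atp_yield}, \code{atp_glycolysis},
#'   \code{nadh_glycolysis}, \code{net_balance} (a
#'   \code{\link{fermentation_balance}}), \code{feasible} and, when
#'   infeasible, \code{violated} naming the balance that cannot close.
#' @examples
#' solve_fluxes(branch_params(lactate_fraction = 1))          # homolactate
#' solve_fluxes(branch_params(butyrate_fraction = 1))         # pure butyrate
#' @export
solve_fluxes <- function(params, species = species_table()) {
  stopifnot(inherits(params, "branch_params"))
  lam <- params$lactate_fraction
  phi <- params$pfl_fraction
  beta <- params$butyrate_fraction
  eta <- params$rnf_atp_per_fd

  A <- 2 * (1 - lam)            # acetyl-CoA formed from pyruvate
  B <- A * beta / 2             # butyrate formed
  ldh <- 2 * lam
  pfor <- (1 - phi) * A
  pfl <- phi * A
  ack <- A * (1 - beta) + B     # includes acetyl-CoA recycled by But

  # NADH: 2 (glycolysis) + rnf + nadh_route_reversal = ldh + 3 B
  rnf_raw <- ldh + 3 * B - 2
  if (rnf_raw < -1e-12 && !params$allow_nadh_to_h2) {
    sol <- list(fluxes = NULL, atp_yield = NA_real_,
                atp_glycolysis = 2, nadh_glycolysis = 2,
                net_balance = NULL, params = params,
                feasible = FALSE, violated = "NADH",
                message = sprintf(
                  "NADH balance cannot close: %.3f mol NADH per glucose has no sink (enable allow_nadh_to_h2 or raise lactate/butyrate flux)",
                  -rnf_raw))
    return(structure(sol, class = "flux_solution"))
  }
  rnf <- max(rnf_raw, 0)
  nadh_h2 <- max(-rnf_raw, 0)
  hyd <- pfor + B - rnf
  if (hyd < -1e-9) {
    sol <- list(fluxes = NULL, atp_yield = NA_real_,
                atp_glycolysis = 2, nadh_glycolysis = 2,
                net_balance = NULL, params = params,
                feasible = FALSE, violated = "ferredoxin",
                message = "ferredoxin balance cannot close")
    return(structure(sol, class = "flux_solution"))
  }
  hyd <- max(hyd, 0)

  fluxes <- c(glycolysis = 1, ldh = ldh, pfor = pfor, pfl = pfl,
              pta = ack, ack = ack, butyrate_branch = B,
              but_transferase = B, hydrogenase = hyd, rnf = rnf,
              nadh_to_h2 = nadh_h2)
  atp <- 2 + ack + eta * rnf

  net <- c(glucose = -1, lactate = ldh, formate = pfl, CO2 = pfor,
           acetate = A * (1 - beta), butyrate = B, H2 = hyd + nadh_h2)
  net <- close_water_protons(net, species)
  bal <- fermentation_balance(net, label = "net fermentation",
                              species = species)

  structure(
    list(fluxes = fluxes, atp_yield = atp, atp_glycolysis = 2,
         nadh_glycolysis = 2, net_balance = bal, params = params,
         feasible = TRUE, violated = NULL),
    class = "flux_solution"
  )
}

# Solve the H2O and H+ coefficients that close a reaction whose C and
# electron balances already hold; errors if no exact closure exists.
close_water_protons <- function(coefs, species = species_table()) {
  coefs <- coefs[!names(coefs) %in% c("H2O", "H+")]
  M <- elemental_matrix(species, names(coefs))
  Mw <- elemental_matrix(species, c("H2O", "H+"))
  rows <- c("H", "O", "charge")
  sol <- qr.solve(Mw[rows, , drop = FALSE], -as.vector(M[rows, ] %*% coefs))
  out <- c(coefs, setNames(sol, c("H2O", "H+")))
  resid <- elemental_matrix(species, names(out)) %*% out
  if (max(abs(resid)) > 1e-9) {
    stop("reaction cannot be closed with water and protons alone ",
         "(carbon or electron balance violated)", call. = FALSE)
  }
  out
}

#' @export
print.flux_solution <- function(x, digits = 4, ...) {
  if (!x$feasible) {
    cat("infeasible flux solution: ", x$violated, " balance violated\n",
        x$message, "\n", sep = "")
    return(invisible(x))
  }
  cat("flux solution (per mol glucose):\n")
  print(round(x$fluxes, digits))
  cat("ATP yield:", format(signif(x$atp_yield, digits)),
      "(glycolysis", x$atp_glycolysis, "+ SLP + Rnf)\n")
  cat("net: ", reaction_string(x$net_balance), "\n", sep = "")
  invisible(x)
}

#' @export
summary.flux_solution <- function(object, ...) {
  if (!object$feasible) return(print(object))
  cat("branch fractions: lactate", object$params$lactate_fraction,
      "| PFL", object$params$pfl_fraction,
      "| butyrate", object$params$butyrate_fraction,
      "| eta(Rnf)", object$params$rnf_atp_per_fd, "\n")
  print(object)
  cat("net acetate:", net_acetate_sign(object), "\n")
  invisible(object)
}

#' @export
coef.flux_solution <- function(object, ...) object$fluxes

#' Sign of net acetate in a fermentation
#'
#' Acetate is a net product when butyrate yield is below 1 mol per mol
#' glucose, zero at exactly 1, and a net substrate above it (the CoA
#' transferase then consumes more acetate than acetate kinase releases).
#'
#' @param x a \code{\link{solve_fluxes}} solution or a
#'   \code{\link{fermentation_balance}}.
#' @param tol tolerance for calling the coefficient zero.
#' @return one of \code{"product"}, \code{"zero"}, \code{"substrate"}.
#' @export
net_acetate_sign <- function(x, tol = 1e-9) {
  if (inherits(x, "flux_solution")) {
    if (!x$feasible) stop("flux solution is infeasible", call. = FALSE)
    x <- x$net_balance
  }
  stopifnot(inherits(x, "fermentation_balance"))
  a <- x$coefficients["acetate"]
  if (is.na(a)) a <- 0
  if (abs(a) <= tol) "zero" else if (a > 0) "product" else "substrate"
}
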