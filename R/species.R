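#' Parse an elemental formula string
#'
#' Converts a Hill-style formula such as \code{"C4H7O2"} into a named count
#' vector over the elements C, H and O.  Elements absent from the formula get
#' a count of zero; an element letter without a number means a count of one.
#'
#' @param formula a single character string, e.g. \code{"C6H12O6"},
#'   \code{"H2"}, \code{"CO2"}.
#' @return named integer vector with elements \code{C}, \code{H}, \code{O}.
#' @examples
#' parse_formula("C4H7O2")   # butyrate anion skeleton
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  body <- gsub("\\s", "", formula)
  out <- c(C = 0, H = 0, O = 0)
  if (body == "" || body == "0") {
    return(out)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", body)[[1]]
  parts <- regmatches(body, gregexpr("([A-Z][a-z]?)([0-9]*)", body))[[1]]
  if (sum(attr(m, "match.length")) != nchar(body)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[A-Za-z]", "", p)
    n <- if (n == "") 1L else as.integer(n)
    if (!el %in% names(out)) {
      stop("unsupported element '", el, "' in formula ", formula, call. = FALSE)
    }
    out[el] <- out[el] + n
  }
  out
}

#' Built-in species table for butyrogen fermentation
#'
#' The metabolites of the branched butyrogen fermentation network: glucose,
#' the organic acid end products (as the anions dominant at pH 7), the gases
#' H2, CO2 and CH4, water and the proton.  Each species carries its elemental
#' composition, charge and phase, from which the degree of reduction used in
#' electron balancing is derived.
#'
#' @param config optional path to a YAML file with a \code{species:} list of
#'   records (\code{name}, \code{formula}, \code{charge}, \code{phase}) that
#'   replaces the built-in table.
#' @return data.frame with columns \code{name}, \code{formula}, \code{C},
#'   \code{H}, \code{O}, \code{charge}, \code{phase} and \code{gamma}
#'   (degree of reduction).
#' @export
species_table <- function(config = NULL) {
  if (is.null(config)) {
    df <- data.frame(
      name = c("glucose", "butyrate", "acetate", "lactate", "formate",
               "CO2", "H2", "CH4", "H2O", "H+"),
      formula = c("C6H12O6", "C4H7O2", "C2H3O2", "C3H5O3", "CHO2",
                  "CO2", "H2", "CH4", "H2O", "H"),
      charge = c(0L, -1L, -1L, -1L, -1L, 0L, 0L, 0L, 0L, 1L),
      phase = c("aqueous", "aqueous", "aqueous", "aqueous", "aqueous",
                "gas", "gas", "gas", "aqueous", "aqueous"),
      stringsAsFactors = FALSE
    )
  } else {
    cfg <- yaml::read_yaml(config)
    if (is.null(cfg$species)) stop("config has no 'species' entry", call. = FALSE)
    df <- do.call(rbind, lapply(cfg$species, function(s) {
      data.frame(name = s$name, formula = s$formula,
                 charge = as.integer(s$charge), phase = s$phase,
                 stringsAsFactors = FALSE)
    }))
  }
  counts <- t(vapply(df$formula, parse_formula, numeric(3)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("formula counts must be non-negative integers", call. = FALSE)
  }
  df$C <- counts[, "C"]
  df$H <- counts[, "H"]
  df$O <- counts[, "O"]
  df$gamma <- degree_of_reduction(df$C, df$H, df$O, df$charge)
  rownames(df) <- df$name
  df[, c("name", "formula", "C", "H", "O", "charge", "phase", "gamma")]
}

#' Degree of reduction of a species
#'
#' Available-electron count relative to the CO2 / H2O / H+ reference state:
#' \eqn{\gamma = 4C + H - 2O - z} where \eqn{z} is the charge.  Under this
#' convention CO2, H2O and H+ all have \eqn{\gamma = 0}, H2 has 2, glucose 24,
#' butyrate (anion) 20.
#'
#' @param C,H,O elemental counts.
#' @param charge ionic charge.
#' @return numeric degree of reduction.
#' @export
degree_of_reduction <- function(C, H, O, charge = 0) {
  4 * C + H - 2 * O - charge
}
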