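#' Construct a fermentation balance
#'
#' A fermentation balance is an overall reaction over the species of
#' \code{\link{species_table}}, stored as a named coefficient vector with
#' negative coefficients for consumed species and positive for produced.
#' Balances produced by \code{\link{build_balance_family}} are normalized to
#' 1 mol glucose consumed.
#'
#' @param coefficients named numeric vector (names are species).
#' @param label short text label for the reaction.
#' @param species species table (see \code{\link{species_table}}).
#' @return object of class \code{fermentation_balance}.
#' @export
fermentation_balance <- function(coefficients, label = "",
                                 species = species_table()) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  unknown <- setdiff(names(coefficients), species$name)
  if (length(unknown) > 0) {
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  coefficients <- coefficients[abs(coefficients) > 0 | names(coefficients) == "glucose"]
  structure(
    list(coefficients = coefficients, label = label, species = species),
    class = "fermentation_balance"
  )
}

# elemental/charge/electron matrix for a set of species (columns) with rows
# C, H, O, charge, gamma
elemental_matrix <- function(species, names) {
  idx <- match(names, species$name)
  if (anyNA(idx)) {
    stop("unknown species: ", paste(names[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  m <- rbind(
    C = species$C[idx],
    H = species$H[idx],
    O = species$O[idx],
    charge = species$charge[idx],
    electron = species$gamma[idx]
  )
  colnames(m) <- names
  m
}

#' Balanced glucose fermentation as a function of butyrate yield
#'
#' Generates the one-parameter family of overall glucose fermentations to
#' butyrate, acetate, H2 and CO2.  Fixing glucose at -1, the butyrate
#' coefficient at \code{b} and CO2 at 2 (both pyruvate carbons decarboxylated
#' via the oxidative route; no lactate or formate in this family), the
#' remaining coefficients (acetate, H2, water, protons) are obtained by a
#' linear solve of the C, H, O and charge balances.  The solution reproduces
#' acetate = 2 - 2b and H2 = 4 - 2b: below one butyrate per glucose acetate is
#' a net product, above it a net substrate.
#'
#' @param b butyrate yield, mol per mol glucose, in [0, 2].
#' @param species species table.
#' @return a \code{\link{fermentation_balance}}.
#' @examples
#' build_balance_family(1)    # glucose -> butyrate + 2 CO2 + 2 H2 + H+
#' build_balance_family(0)    # homoacetate: 2 acetate + 2 CO2 + 4 H2
#' @export
build_balance_family <- function(b, species = species_table()) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  if (b < 0 || b > 2) {
    stop("butyrate yield b must lie in [0, 2]; b = ", b,
         " would require a negative H2 or CO2 coefficient", call. = FALSE)
  }
  fixed <- c(glucose = -1, butyrate = b, CO2 = 2)
  free <- c("acetate", "H2", "H2O", "H+")
  M <- elemental_matrix(species, c(names(fixed), free))
  rows <- c("C", "H", "O", "charge")
  A <- M[rows, free, drop = FALSE]
  rhs <- -as.vector(M[rows, names(fixed), drop = FALSE] %*% fixed)
  x <- solve(A, rhs)
  names(x) <- free
  coefs <- c(fixed, x)
  # electron closure is implied by C/H/O/charge; assert rather than assume
  resid <- as.vector(elemental_matrix(species, names(coefs)) %*% coefs)
  if (max(abs(resid)) > 1e-9) {
    stop("internal error: balance did not close (residual ",
         max(abs(resid)), ")", call. = FALSE)
  }
  fermentation_balance(coefs, label = sprintf("family b=%g", b),
                       species = species)
}

#' Check elemental, charge and electron closure of a balance
#'
#' Computes the per-element residuals (C, H, O), the charge residual and the
#' degree-of-reduction (electron) residual of a reaction.  All residuals are
#' zero, within tolerance, for a valid fermentation balance.
#'
#' @param balance a \code{\link{fermentation_balance}}.
#' @param tol absolute tolerance below which a residual counts as zero.
#' @return object of class \code{balance_report}: named residual vector with
#'   attributes \code{ok} and \code{tol}.
#' @export
balance_check <- function(balance, tol = 1e-9) {
  stopifnot(inherits(balance, "fermentation_balance"))
  cf <- balance$coefficients
  M <- elemental_matrix(balance$species, names(cf))
  resid <- as.vector(M %*% cf)
  names(resid) <- rownames(M)
  structure(resid, ok = all(abs(resid) <= tol), tol = tol,
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("balance residuals (tol ", format(attr(x, "tol")), "):\n", sep = "")
  print(unclass(x)[seq_along(x)])
  cat(if (isTRUE(attr(x, "ok"))) "balanced\n" else "NOT balanced\n")
  invisible(x)
}

#' Format a balance as a human-readable reaction string
#'
#' @param balance a \code{\link{fermentation_balance}}.
#' @param digits significant digits for coefficients.
#' @param tol coefficients smaller than this in absolute value are dropped.
#' @return character reaction string, consumed species on the left.
#' @export
reaction_string <- function(balance, digits = 4, tol = 1e-9) {
  cf <- balance$coefficients
  cf <- cf[abs(cf) > tol]
  fmt <- function(v, nm) {
    a <- signif(abs(v), digits)
    ifelse(abs(a - 1) < tol, nm, paste(format(a, trim = TRUE), nm))
  }
  lhs <- cf[cf < 0]
  rhs <- cf[cf > 0]
  paste(
    paste(fmt(lhs, names(lhs)), collapse = " + "),
    "->",
    paste(fmt(rhs, names(rhs)), collapse = " + ")
  )
}

#' @export
print.fermentation_balance <- function(x, ...) {
  if (nzchar(x$label)) cat(x$label, ": ", sep = "")
  cat(reaction_string(x), "\n")
  invisible(x)
}

#' @export
coef.fermentation_balance <- function(object, ...) object$coefficients

#' @export
as.data.frame.fermentation_balance <- function(x, ...) {
  data.frame(species = names(x$coefficients),
             coefficient = unname(x$coefficients),
             stringsAsFactors = FALSE)
}

#' @export
`+.fermentation_balance` <- function(e1, e2) {
  nm <- union(names(e1$coefficients), names(e2$coefficients))
  cf <- setNames(numeric(length(nm)), nm)
  cf[names(e1$coefficients)] <- cf[names(e1$coefficients)] + e1$coefficients
  cf[names(e2$coefficients)] <- cf[names(e2$coefficients)] + e2$coefficients
  fermentation_balance(cf, label = paste(e1$label, "+", e2$label),
                       species = e1$species)
}

#' Write / read a balance as a plain species-coefficient table
#'
#' @param balance a \code{\link{fermentation_balance}}.
#' @param path file path.
#' @rdname balance_io
#' @export
write_balance <- function(balance, path) {
  utils::write.csv(as.data.frame(balance), path, row.names = FALSE)
  invisible(path)
}

#' @param label label for the re-read balance.
#' @param species species table.
#' @rdname balance_io
#' @export
read_balance <- function(path, label = "", species = species_table()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fermentation_balance(setNames(df$coefficient, df$species),
                       label = label, species = species)
}
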