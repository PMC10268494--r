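PRODUCT_CARBONS <- c(acetate = 2, butyrate = 4, lactate = 3, formate = 1,
                     propionate = 3, succinate = 4)

# endpoint - blank for one analyte of a single culture record (list or
# one-row data.frame); missing blank column means a blank of zero
production <- function(rec, analyte) {
  end <- rec[[analyte]]
  blank <- rec[[paste0("blank_", analyte)]]
  if (is.null(blank) || is.na(blank)) blank <- 0
  if (is.null(end) || is.na(end)) return(NA_real_)
  end - blank
}

#' Carbon-share accounting for a monoculture record
#'
#' Expresses fermentation products as the percent of total fermented carbon.
#' Because butyrate release by the CoA transferase consumes one free acetate
#' per butyrate, a theoretical acetate consumption equal to the butyrate
#' produced is assumed; total fermented carbon is the carbon of the consumed
#' glucose plus the carbon of that theoretically consumed acetate, and total
#' acetate produced is the theoretical consumption plus the measured
#' endpoint-minus-blank change (which may be negative when acetate is a net
#' substrate).  Butyrate, lactate and formate are absent from the medium, so
#' their production is their endpoint concentration; small negative measured
#' productions are clipped to zero with a warning.
#'
#' @param rec a single culture record: a list or one-row data.frame with
#'   endpoint concentrations (mM) named \code{glucose}, \code{acetate},
#'   \code{butyrate}, \code{lactate}, \code{formate} and blanks named
#'   \code{blank_<analyte>} (missing blanks are taken as 0).
#' @return object of class \code{carbon_shares}: list with
#'   \code{glucose_consumed_mM}, \code{theoretical_acetate_consumed_mM},
#'   \code{total_fermented_C_mM}, \code{total_acetate_produced_mM},
#'   \code{shares_pct} (named: acetate, butyrate, lactate, formate) and
#'   \code{flagged} (TRUE when total acetate produced is negative,
#'   violating the accounting assumption).
#' @examples
#' rec <- list(glucose = 12, blank_glucose = 22, acetate = 28,
#'             blank_acetate = 30, butyrate = 5, lactate = 0, formate = 1)
#' monoculture_shares(rec)
#' @export
monoculture_shares <- function(rec) {
  glu_cons <- -production(rec, "glucose")
  if (is.na(glu_cons) || glu_cons < 0) {
    stop("glucose consumed (blank - endpoint) must be >= 0", call. = FALSE)
  }
  if (glu_cons == 0) {
    stop("carbon shares are undefined when no glucose was consumed",
         call. = FALSE)
  }
  prod <- vapply(c("butyrate", "lactate", "formate"), production,
                 numeric(1), rec = rec)
  prod[is.na(prod)] <- 0
  if (any(prod < 0)) {
    warning("negative measured production of ",
            paste(names(prod)[prod < 0], collapse = ", "),
            " clipped to 0 (not expected in the medium or consumed)",
            call. = FALSE)
    prod <- pmax(prod, 0)
  }
  d_ace <- production(rec, "acetate")
  if (is.na(d_ace)) d_ace <- 0
  theo_ace <- prod[["butyrate"]]
  total_C <- 6 * glu_cons + 2 * theo_ace
  total_ace <- theo_ace + d_ace
  flagged <- total_ace < 0
  if (flagged) {
    warning("total acetate produced is negative (", signif(total_ace, 4),
            " mM): measured acetate consumption exceeds the theoretical ",
            "transferase demand; accounting assumption violated",
            call. = FALSE)
  }
  shares <- c(
    acetate = 100 * PRODUCT_CARBONS[["acetate"]] * total_ace / total_C,
    butyrate = 100 * PRODUCT_CARBONS[["butyrate"]] * prod[["butyrate"]] / total_C,
    lactate = 100 * PRODUCT_CARBONS[["lactate"]] * prod[["lactate"]] / total_C,
    formate = 100 * PRODUCT_CARBONS[["formate"]] * prod[["formate"]] / total_C
  )
  structure(
    list(glucose_consumed_mM = glu_cons,
         theoretical_acetate_consumed_mM = theo_ace,
         total_fermented_C_mM = total_C,
         total_acetate_produced_mM = total_ace,
         shares_pct = shares, flagged = flagged),
    class = "carbon_shares"
  )
}

#' @export
print.carbon_shares <- function(x, digits = 4, ...) {
  cat("total fermented carbon:", signif(x$total_fermented_C_mM, digits),
      "mM C  (glucose consumed", signif(x$glucose_consumed_mM, digits),
      "mM; theoretical acetate consumed",
      signif(x$theoretical_acetate_consumed_mM, digits), "mM)\n")
  cat("percent of total fermented carbon:\n")
  print(round(x$shares_pct, 3))
  if (x$flagged) cat("FLAGGED: total acetate produced is negative\n")
  invisible(x)
}

#' Community product yields per substrate consumed
#'
#' For synthetic-community cultures the per-strain carbon bookkeeping is not
#' identifiable, so each product is expressed as its molar change
#' (endpoint minus blank) divided by the total moles of substrate (glucose
#' plus fructose) consumed.  Acetate may legitimately be negative.
#'
#' @param rec a single culture record as in
#'   \code{\link{monoculture_shares}}, optionally with \code{fructose} /
#'   \code{blank_fructose} columns.
#' @param products analytes to report.
#' @return named numeric vector, mol product per mol substrate consumed.
#' @export
community_yields <- function(rec, products = c("acetate", "butyrate",
                                               "lactate", "formate",
                                               "propionate", "succinate")) {
  glu <- -production(rec, "glucose")
  fru <- -production(rec, "fructose")
  if (is.na(glu)) glu <- 0
  if (is.na(fru)) fru <- 0
  subs <- glu + fru
  if (subs <= 0) {
    stop("yields are undefined when no substrate was consumed", call. = FALSE)
  }
  deltas <- vapply(products, production, numeric(1), rec = rec)
  deltas / subs
}

#' Per-product contrast between two culture condition groups
#'
#' Computes a per-product metric (community yields or a single analyte's
#' production) for every record, then compares two condition groups with
#' two-sided two-sample Student's t-tests, reporting group means, SEM, t,
#' degrees of freedom, p and significance stars (* p < 0.05, ** p < 0.01,
#' *** p < 0.001).
#'
#' @param records data.frame of culture records with a \code{condition}
#'   column, one row per culture.
#' @param group_a,group_b condition labels to contrast.
#' @param metric \code{"yields"} (mol per mol substrate,
#'   \code{\link{community_yields}}) or \code{"production"} (endpoint minus
#'   blank, mM).
#' @param products analytes to compare.
#' @param var_equal pooled-variance Student's test (TRUE, default) or Welch.
#' @return data.frame: product, n and mean and SEM per group, t, df, p,
#'   stars.
#' @export
condition_contrast <- function(records, group_a, group_b,
                               metric = c("yields", "production"),
                               products = c("acetate", "butyrate",
                                            "lactate", "formate"),
                               var_equal = TRUE) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(records), "condition" %in% names(records))
  split_vals <- function(group) {
    rows <- which(records$condition == group)
    if (length(rows) < 2) {
      stop("need >= 2 replicates in group '", group, "'", call. = FALSE)
    }
    t(vapply(rows, function(i) {
      rec <- records[i, , drop = FALSE]
      if (metric == "yields") {
        community_yields(rec, products)
      } else {
        vapply(products, production, numeric(1), rec = rec)
      }
    }, numeric(length(products))))
  }
  va <- split_vals(group_a)
  vb <- split_vals(group_b)
  out <- lapply(seq_along(products), function(j) {
    a <- va[, j]
    b <- vb[, j]
    tt <- safe_t_test(a, b, var_equal = var_equal)
    data.frame(product = products[j],
               n_a = length(a), mean_a = mean(a),
               sem_a = stats::sd(a) / sqrt(length(a)),
               n_b = length(b), mean_b = mean(b),
               sem_b = stats::sd(b) / sqrt(length(b)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stars = p_stars(tt$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# two-sided two-sample t-test that degrades gracefully when both groups are
# constant (t.test refuses essentially-constant data): equal constants give
# t = 0, p = 1; distinct constants an infinite t with p = 0
safe_t_test <- function(a, b, var_equal = TRUE) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    df <- length(a) + length(b) - 2
    if (mean(a) == mean(b)) {
      return(list(statistic = c(t = 0), parameter = c(df = df), p.value = 1))
    }
    return(list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
                parameter = c(df = df), p.value = 0))
  }
  stats::t.test(a, b, var.equal = var_equal)
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}
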