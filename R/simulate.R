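#' Strain fermentation profile for culture simulation
#'
#' A strain is described by its baseline product yields (mol per mol
#' glucose) for butyrate, lactate and formate and by multiplicative effect
#' factors applied to those yields under a high-H2 (or CO, a hydrogenase
#' inhibitor) atmosphere.  Acetate, CO2 and H2 yields are not free: they are
#' closed through the redox-balanced flux model, so every generated yield
#' set is elementally balanced before noise.  A strain without a hydrogenase
#' cannot sense H2 or CO, so all its effect factors must be 1.
#'
#' @param name strain label.
#' @param has_hydrogenase logical.
#' @param butyrate,lactate,formate baseline yields, mol per mol glucose.
#'   Constraints: \code{lactate <= 2}, \code{butyrate <= (2 - lactate)/2},
#'   \code{formate <= 2 - lactate}.
#' @param h2_effects named multiplicative factors (subset of butyrate,
#'   lactate, formate) applied under high-H2/CO conditions.
#' @param noise_sd relative measurement noise (log-normal sdlog).
#' @return object of class \code{strain_profile}.
#' @export
strain_profile <- function(name, has_hydrogenase = TRUE,
                           butyrate = 0.6, lactate = 0.01, formate = 0.1,
                           h2_effects = c(butyrate = 1, lactate = 1,
                                          formate = 1),
                           noise_sd = 0.05) {
  yields <- c(butyrate = butyrate, lactate = lactate, formate = formate)
  if (any(yields < 0)) stop("yields must be >= 0", call. = FALSE)
  eff <- c(butyrate = 1, lactate = 1, formate = 1)
  eff[names(h2_effects)] <- h2_effects
  if (!has_hydrogenase && any(eff != 1)) {
    stop("a strain without a hydrogenase cannot respond to H2/CO: ",
         "all effect factors must be 1", call. = FALSE)
  }
  check_yield_set(yields)
  check_yield_set(yields * eff)
  structure(list(name = name, has_hydrogenase = has_hydrogenase,
                 yields = yields, h2_effects = eff, noise_sd = noise_sd),
            class = "strain_profile")
}

check_yield_set <- function(y) {
  lam <- y[["lactate"]] / 2
  A <- 2 - y[["lactate"]]
  if (lam > 1) stop("lactate yield cannot exceed 2 per glucose", call. = FALSE)
  if (A > 0) {
    if (2 * y[["butyrate"]] / A > 1 + 1e-9) {
      stop("butyrate yield exceeds available acetyl-CoA", call. = FALSE)
    }
    if (y[["formate"]] / A > 1 + 1e-9) {
      stop("formate yield exceeds available pyruvate", call. = FALSE)
    }
  } else if (y[["butyrate"]] > 0 || y[["formate"]] > 0) {
    stop("homolactate profile cannot also form butyrate/formate",
         call. = FALSE)
  }
  invisible(y)
}

#' Balanced product yields from butyrate/lactate/formate targets
#'
#' Maps target yields to branch fractions, solves the flux model (with the
#' NADH-to-H2 route enabled so any physically consistent target closes),
#' and returns the full net yield vector including the dependent acetate,
#' H2 and CO2 coefficients.  The result always passes
#' \code{\link{balance_check}}.
#'
#' @param butyrate,lactate,formate target yields, mol per mol glucose.
#' @return list with \code{yields} (named: acetate, butyrate, lactate,
#'   formate, H2, CO2; acetate may be negative) and \code{balance}
#'   (the \code{\link{fermentation_balance}}).
#' @export
yields_to_balance <- function(butyrate, lactate = 0, formate = 0) {
  y <- c(butyrate = butyrate, lactate = lactate, formate = formate)
  check_yield_set(y)
  lam <- lactate / 2
  A <- 2 - lactate
  phi <- if (A > 0) formate / A else 0
  beta <- if (A > 0) min(2 * butyrate / A, 1) else 0
  sol <- solve_fluxes(branch_params(lactate_fraction = lam,
                                    pfl_fraction = phi,
                                    butyrate_fraction = beta,
                                    allow_nadh_to_h2 = TRUE))
  cf <- sol$net_balance$coefficients
  get <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else 0
  list(yields = c(acetate = get("acetate"), butyrate = get("butyrate"),
                  lactate = get("lactate"), formate = get("formate"),
                  H2 = get("H2"), CO2 = get("CO2")),
       balance = sol$net_balance)
}

#' Default strain profiles
#'
#' Three illustrative profiles mirroring the qualitative response patterns
#' of well-studied gut butyrogens: a strain that diverts reducing power to
#' butyrate and formate under high H2 (R. intestinalis-like), one that
#' diverts it mainly to lactate (E. rectale-like), and a hydrogenase-free
#' strain that does not respond (F. prausnitzii-like, with an all-PFL,
#' all-butyrate baseline that emits no H2).  Effect sizes are illustrative
#' directions, not measured values.
#'
#' @return named list of \code{\link{strain_profile}} objects.
#' @export
default_strain_profiles <- function() {
  list(
    butyrate_responder = strain_profile(
      "butyrate_responder", has_hydrogenase = TRUE,
      butyrate = 0.6, lactate = 0.005, formate = 0.10,
      h2_effects = c(butyrate = 1.5, lactate = 3, formate = 2.5)),
    lactate_responder = strain_profile(
      "lactate_responder", has_hydrogenase = TRUE,
      butyrate = 0.5, lactate = 0.05, formate = 0.15,
      h2_effects = c(butyrate = 1, lactate = 8, formate = 1.8)),
    no_hydrogenase = strain_profile(
      "no_hydrogenase", has_hydrogenase = FALSE,
      butyrate = 1, lactate = 0, formate = 2,
      h2_effects = c(butyrate = 1, lactate = 1, formate = 1))
  )
}

#' Simulate monoculture endpoint records
#'
#' Draws endpoint culture records for each strain profile under each
#' condition.  High-H2/CO conditions apply the profile's effect factors to
#' its target yields; the dependent acetate/H2/CO2 yields are re-closed
#' through the flux model so pre-noise yields are always elementally
#' balanced.  Concentrations then get multiplicative log-normal noise
#' (HPLC-style error roughly proportional to the signal); set
#' \code{noise_model = "additive"} for Gaussian noise instead.
#'
#' @param profiles list of \code{\link{strain_profile}} objects.
#' @param conditions condition labels; those in \code{high_h2_conditions}
#'   apply the effect factors.
#' @param replicates biological replicates per strain and condition (>= 2).
#' @param seed integer RNG seed.
#' @param glucose_consumed_mM mean glucose consumption.
#' @param blank_glucose_mM,blank_acetate_mM medium (blank) composition; the
#'   medium contains abundant acetate and no butyrate, lactate or formate.
#' @param high_h2_conditions labels treated as high-H2/CO.
#' @param noise_model \code{"lognormal"} (default) or \code{"additive"}.
#' @return data.frame of culture records in the accounting schema
#'   (endpoint and \code{blank_*} concentrations, mM) plus hidden truth
#'   columns prefixed with \code{"."}.
#' @export
gen_cultures <- function(profiles = default_strain_profiles(),
                         conditions = c("N2", "H2"),
                         replicates = 5, seed = 1,
                         glucose_consumed_mM = 20,
                         blank_glucose_mM = 22, blank_acetate_mM = 30,
                         high_h2_conditions = c("H2", "CO"),
                         noise_model = c("lognormal", "additive")) {
  noise_model <- match.arg(noise_model)
  stopifnot(replicates >= 2)
  for (p in profiles) stopifnot(inherits(p, "strain_profile"))
  set.seed(as.integer(seed))
  rows <- list()
  for (p in profiles) {
    for (cond in conditions) {
      eff <- if (cond %in% high_h2_conditions) p$h2_effects else
        c(butyrate = 1, lactate = 1, formate = 1)
      y <- p$yields * eff
      closed <- yields_to_balance(y[["butyrate"]], y[["lactate"]],
                                  y[["formate"]])$yields
      for (r in seq_len(replicates)) {
        glu <- glucose_consumed_mM
        conc <- c(
          glucose = blank_glucose_mM - glu,
          acetate = blank_acetate_mM + closed[["acetate"]] * glu,
          butyrate = closed[["butyrate"]] * glu,
          lactate = closed[["lactate"]] * glu,
          formate = closed[["formate"]] * glu
        )
        noisy <- apply_noise(conc, p$noise_sd, noise_model)
        rows[[length(rows) + 1]] <- data.frame(
          culture_id = sprintf("%s_%s_r%d", p$name, cond, r),
          strain = p$name, condition = cond,
          glucose = noisy[["glucose"]], acetate = noisy[["acetate"]],
          butyrate = noisy[["butyrate"]], lactate = noisy[["lactate"]],
          formate = noisy[["formate"]],
          blank_glucose = blank_glucose_mM,
          blank_acetate = blank_acetate_mM,
          blank_butyrate = 0, blank_lactate = 0, blank_formate = 0,
          headspace_h2_yield = closed[["H2"]],
          .yield_butyrate = unname(y[["butyrate"]]),
          .yield_lactate = unname(y[["lactate"]]),
          .yield_formate = unname(y[["formate"]]),
          .yield_acetate = closed[["acetate"]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

apply_noise <- function(x, sd, model) {
  if (sd == 0) return(x)
  if (model == "lognormal") {
    x * exp(stats::rnorm(length(x), -sd^2 / 2, sd))
  } else {
    x + stats::rnorm(length(x), 0, sd * pmax(abs(x), 1e-6))
  }
}

#' Simulation parameters for a synthetic human cohort
#'
#' Describes a cohort with a methanogenic (MG) subpopulation sampled before
#' and during a fermentable-starch supplement.  Per metric and group the
#' generator draws a subject-level mean (between-subject SD) and then
#' per-sample values (within-subject SD).  By default the MG deficits in
#' breath H2 and fecal butyrate are applied only in the during period,
#' matching the study design the pipeline is meant to recover; the before
#' period is a true null.
#'
#' @param n_subjects total subjects (>= 4).
#' @param fraction_mg fraction methanogenic, in [0, 1].
#' @param n_breath,n_fecal samples per subject per period.
#' @param h2,ch4,butyrate lists with \code{before}/\code{during} elements,
#'   each a list of \code{mg} and \code{non} means, plus \code{between_sd}
#'   and \code{within_sd}.
#' @param outlier_rate per-sample probability of injecting an outlier.
#' @param outlier_sd outlier magnitude in within-subject SD units.
#' @param seed integer RNG seed.
#' @return object of class \code{cohort_sim_params}.
#' @export
cohort_sim_params <- function(n_subjects = 40, fraction_mg = 0.5,
                              n_breath = 3, n_fecal = 3,
                              h2 = list(before = list(mg = 8, non = 8),
                                        during = list(mg = 10, non = 20),
                                        between_sd = 5, within_sd = 3),
                              ch4 = list(before = list(mg = 20, non = 0.8),
                                         during = list(mg = 20, non = 0.8),
                                         between_sd = 5, within_sd = 2),
                              butyrate = list(before = list(mg = 8, non = 8),
                                              during = list(mg = 8, non = 12),
                                              between_sd = 2.5,
                                              within_sd = 1.5),
                              outlier_rate = 0, outlier_sd = 10, seed = 1) {
  stopifnot(n_subjects >= 4, fraction_mg >= 0, fraction_mg <= 1,
            n_breath >= 1, n_fecal >= 1, outlier_rate >= 0,
            outlier_rate <= 1)
  structure(list(n_subjects = n_subjects, fraction_mg = fraction_mg,
                 n_breath = n_breath, n_fecal = n_fecal,
                 h2 = h2, ch4 = ch4, butyrate = butyrate,
                 outlier_rate = outlier_rate, outlier_sd = outlier_sd,
                 seed = seed),
            class = "cohort_sim_params")
}

#' Simulate breath and fecal tables for a synthetic cohort
#'
#' Generates a breath table (subject, period, semester, raw H2/CH4 ppm, CO2
#' percent) and a fecal table (subject, period, butyrate per g wet weight).
#' CO2 varies between samples so raw readings must be renormalized by the
#' analysis; the programmed gas values are the normalized ones (raw values
#' are back-computed as \code{value * co2 / 3.5}).  Methanogenic subjects
#' are guaranteed at least one CH4 reading above the classification
#' threshold per period and non-methanogenic subjects never exceed it.
#' Injected outliers are marked in the hidden \code{.outlier} truth column.
#'
#' @param params a \code{\link{cohort_sim_params}} object.
#' @param threshold CH4 classification threshold the guarantees refer to.
#' @return list with \code{breath}, \code{fecal} and \code{subjects}
#'   (truth: subject, methanogenic) data.frames.
#' @export
gen_cohort <- function(params = cohort_sim_params(), threshold = 4) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(as.integer(params$seed))
  n <- params$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  is_mg <- seq_len(n) <= round(n * params$fraction_mg)
  breath <- list()
  fecal <- list()
  for (i in seq_len(n)) {
    grp <- if (is_mg[i]) "mg" else "non"
    for (per in c("before", "during")) {
      h2_mu <- params$h2[[per]][[grp]] +
        stats::rnorm(1, 0, params$h2$between_sd)
      ch4_mu <- params$ch4[[per]][[grp]] +
        stats::rnorm(1, 0, params$ch4$between_sd)
      bu_mu <- params$butyrate[[per]][[grp]] +
        stats::rnorm(1, 0, params$butyrate$between_sd)
      h2 <- pmax(h2_mu + stats::rnorm(params$n_breath, 0,
                                      params$h2$within_sd), 0)
      ch4 <- pmax(ch4_mu + stats::rnorm(params$n_breath, 0,
                                        params$ch4$within_sd), 0)
      if (is_mg[i] && max(ch4) <= threshold) {
        ch4[which.max(ch4)] <- threshold + 1 + abs(stats::rnorm(1))
      }
      if (!is_mg[i]) ch4 <- pmin(ch4, threshold - 0.5)
      # outliers are upward spikes (instrument carry-over / contamination);
      # a downward 10-SD excursion would clamp at zero and be undetectable
      out_h2 <- stats::runif(params$n_breath) < params$outlier_rate
      h2[out_h2] <- h2[out_h2] + params$outlier_sd * params$h2$within_sd
      h2 <- pmax(h2, 0)
      co2 <- pmin(pmax(stats::rnorm(params$n_breath, 4, 0.8), 2), 6)
      breath[[length(breath) + 1]] <- data.frame(
        subject = ids[i], period = per, semester = "SIM",
        h2_ppm = h2 * co2 / 3.5, ch4_ppm = ch4 * co2 / 3.5,
        co2_pct = co2, .outlier = out_h2, stringsAsFactors = FALSE)
      bu <- pmax(bu_mu + stats::rnorm(params$n_fecal, 0,
                                      params$butyrate$within_sd), 0)
      out_bu <- stats::runif(params$n_fecal) < params$outlier_rate
      bu[out_bu] <- bu[out_bu] + params$outlier_sd *
        params$butyrate$within_sd
      bu <- pmax(bu, 0)
      fecal[[length(fecal) + 1]] <- data.frame(
        subject = ids[i], period = per, butyrate_umol_g = bu,
        .outlier = out_bu, stringsAsFactors = FALSE)
    }
  }
  list(breath = do.call(rbind, breath),
       fecal = do.call(rbind, fecal),
       subjects = data.frame(subject = ids, methanogenic = is_mg,
                             stringsAsFactors = FALSE))
}
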