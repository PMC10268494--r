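#' Read a delimited table (comma or tab autodetected)
#'
#' Single tabular dialect for culture and cohort tables: UTF-8 plain text,
#' one header row, comma or tab separated (detected from the header), lines
#' starting with \code{#} ignored.  Hidden truth columns written by the
#' simulators (names starting with \code{.}) are dropped on read.
#'
#' @param path file path.
#' @param keep_truth keep columns whose names start with \code{.}.
#' @return data.frame.
#' @export
read_tabular <- function(path, keep_truth = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 50L, warn = FALSE)
  header <- lines[!startsWith(lines, "#")][1]
  if (is.na(header)) stop("no header row in ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!keep_truth) df <- df[, !startsWith(names(df), "."), drop = FALSE]
  df
}

#' Write a result table with a provenance header
#'
#' Writes comma-separated UTF-8 text with comment lines recording the
#' package version and, when a configuration list is supplied, an MD5 hash
#' of its serialized content, so identical configurations yield
#' byte-identical outputs.
#'
#' @param df data.frame.
#' @param path output path.
#' @param config optional configuration list to hash into the header.
#' @return the path, invisibly.
#' @export
write_tabular <- function(df, path, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("butyrogen")),
                  error = function(e) "dev")
  writeLines(sprintf("# butyrogen %s", ver), con)
  if (!is.null(config)) {
    writeLines(sprintf("# config_hash %s", config_hash(config)), con)
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config, file = tmp, control = c("digits17", "niceNames"))
  unname(tools::md5sum(tmp))
}

#' Read a run configuration file
#'
#' YAML configuration with optional blocks \code{species:}, \code{thermo:},
#' \code{conditions:} and scalar module options (\code{rnf_atp_per_fd},
#' \code{allow_nadh_to_h2}, \code{tukey_k}, \code{ch4_threshold_ppm},
#' \code{baseline_semesters}, \code{baseline_ppm}, \code{quantile_type},
#' \code{dG_atp}, \code{seed}).  Options are validated against their
#' documented ranges and merged over the defaults.
#'
#' @param path YAML file path, or NULL for all defaults.
#' @return named list of options.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(rnf_atp_per_fd = 0.5, allow_nadh_to_h2 = FALSE,
                   tukey_k = 3, ch4_threshold_ppm = 4,
                   baseline_semesters = character(), baseline_ppm = 1,
                   quantile_type = 7, dG_atp = 70, seed = 1,
                   b_grid = seq(0, 2, by = 0.25),
                   pH2_grid = 10^seq(-6, 0, length.out = 50))
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(defaults, cfg[setdiff(names(cfg),
                                                 c("species", "thermo",
                                                   "conditions"))])
  out$species_block <- cfg$species
  out$thermo_block <- cfg$thermo
  out$conditions_block <- cfg$conditions
  with(out, {
    stopifnot(rnf_atp_per_fd >= 0, tukey_k > 0, ch4_threshold_ppm >= 0,
              baseline_ppm >= 0, quantile_type %in% 1:9, dG_atp > 0)
  })
  out
}
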