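#' Render a measurement table for display
#'
#' Formats a compensation table (`style = "table2"`) or a switcher table
#' (`style = "table4"`) the way such tables are conventionally printed:
#' currency rounded to whole units with an explicit sign, predictive
#' ratios to two decimals, reductions as negative percentages, stars for
#' significance (`**` at 0.01, `*` at 0.05 in table2; `*` at 0.05 in
#' table4), and unavailable estimates (fewer than two switchers) as an
#' en dash with the count shown. Rounding applies to the rendered view
#' only; CSV outputs keep full precision.
#'
#' @param rows A `compensation_row` table for `"table2"`, or a
#'   `switcher_estimates` table for `"table4"`.
#' @param style `"table2"` or `"table4"`.
#' @param format `"markdown"` (character vector of lines) or `"csv"`
#'   (data.frame of the rendered columns).
#' @return Character vector of Markdown lines, or a data.frame.
#' @export
render_table <- function(rows, style = c("table2", "table4"),
                         format = c("markdown", "csv")) {
  style <- match.arg(style)
  format <- match.arg(format)
  if (nrow(rows) == 0L) stop("no rows to render", call. = FALSE)
  fmt_eur <- function(x) ifelse(is.na(x), "–",
                                sprintf("%+.0f", x))
  if (style == "table2") {
    stars <- ifelse(rows$sig_01, "**", ifelse(rows$sig_05, "*", ""))
    out <- data.frame(
      group = rows$group,
      share_pct = sprintf("%.1f %%", 100 * rows$population_share),
      overcompensation = paste0(fmt_eur(rows$mean_overcompensation),
                                stars),
      predictive_ratio = sprintf("%.2f", rows$predictive_ratio),
      reduction = ifelse(is.na(rows$reduction_vs_no_equalization), "–",
                         sprintf("−%.0f %%",
                                 100 * rows$reduction_vs_no_equalization)),
      check.names = FALSE)
  } else {
    cell <- function(est, sig, n) ifelse(
      is.na(est), sprintf("– (n=%d)", n),
      paste0(sprintf("%+.0f", est), ifelse(sig, "*", "")))
    out <- data.frame(
      insurer = rows$insurer_id,
      n_inflow = rows$n_inflow,
      inflow_overcompensation = cell(rows$inflow_overcompensation,
                                     rows$inflow_sig_05, rows$n_inflow),
      n_outflow = rows$n_outflow,
      outflow_overcompensation = cell(rows$outflow_overcompensation,
                                      rows$outflow_sig_05, rows$n_outflow),
      check.names = FALSE)
  }
  if (format == "csv") return(out)
  header <- paste0("| ", paste(names(out), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(out)), collapse = "|"), "|")
  body <- apply(out, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, unname(body))
}

# Polynomial rolling hash over the serialized object (mod 2^31 - 1);
# a stable fingerprint for manifests, not a cryptographic digest.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 3)
  h <- 0
  for (b in as.integer(bytes)) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Run manifest
#'
#' Metadata tying a set of output files to the run that produced them:
#' configuration hash, seed, package version, scenario tag, output paths,
#' wall-clock timestamp and exclusion tallies (persons present in one
#' panel year only, etc.). The timestamp records when the run happened and
#' is the only non-deterministic field.
#'
#' @param config The `market_config` of the run.
#' @param paths Character vector of output file names.
#' @param exclusions Named integer vector of exclusion tallies.
#' @return A list of class `run_manifest`.
#' @export
make_manifest <- function(config, paths = character(0),
                          exclusions = NULL) {
  structure(list(
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    scenario = attr(config, "scenario"),
    package_version =
      as.character(utils::packageVersion("riskselect")),
    paths = paths,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    exclusions = as.list(exclusions)
  ), class = "run_manifest")
}
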