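#' Read and write person-year panels as CSV
#'
#' One row per person-year with header `person_id`, `year`, `insurer_id`,
#' one column per adjuster, optionally `unpriced_effect` (the simulator's
#' hidden truth, emitted only on request), and `expenses`.
#'
#' @param panel A person-year data.frame.
#' @param path File path.
#' @param emit_truth Include the `unpriced_effect` column (default
#'   `FALSE`: estimators never see it).
#' @return `write_panel_csv()` returns `path` invisibly;
#'   `read_panel_csv()` returns the panel with adjuster columns as factors
#'   and the adjuster names in attribute `adjusters`.
#' @export
write_panel_csv <- function(panel, path, emit_truth = FALSE) {
  out <- panel
  if (!emit_truth) out$unpriced_effect <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @param adjusters Adjuster column names; by default every column other
#'   than the reserved ones.
#' @export
read_panel_csv <- function(path, adjusters = NULL) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  reserved <- c("person_id", "year", "insurer_id", "unpriced_effect",
                "expenses")
  if (is.null(adjusters)) adjusters <- setdiff(names(panel), reserved)
  for (a in adjusters) panel[[a]] <- factor(panel[[a]])
  attr(panel, "adjusters") <- adjusters
  panel
}

#' Read and write simulator ground truth as JSON
#'
#' The JSON object is keyed by insurer id; each entry carries the
#' insurer's efficiency multiplier and the realized inflow/outflow mean
#' unpriced effect and implied true overcompensation.
#'
#' @param ground_truth A `ground_truth` data.frame.
#' @param path File path.
#' @return `write_ground_truth_json()` returns `path` invisibly;
#'   `read_ground_truth_json()` returns the `ground_truth` data.frame.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  rows <- lapply(seq_len(nrow(ground_truth)), function(i)
    as.list(ground_truth[i, setdiff(names(ground_truth), "insurer_id")]))
  names(rows) <- as.character(ground_truth$insurer_id)
  obj <- list(population_mean_unpriced =
                attr(ground_truth, "population_mean_unpriced"),
              insurers = rows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- obj$insurers
  gt <- do.call(rbind, lapply(names(rows), function(k)
    data.frame(insurer_id = as.integer(k),
               as.data.frame(lapply(rows[[k]], function(v)
                 if (is.null(v)) NA else v)))))
  gt <- gt[order(gt$insurer_id), ]
  rownames(gt) <- NULL
  attr(gt, "population_mean_unpriced") <- obj$population_mean_unpriced
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

#' Read a market configuration from YAML
#'
#' Accepts any subset of the [market_config()] arguments as YAML keys;
#' omitted keys take the package defaults. The configuration is validated
#' on construction.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file contents (e.g. `seed`).
#' @return A `market_config`.
#' @export
read_market_config <- function(path, ...) {
  obj <- yaml::read_yaml(path)
  dots <- list(...)
  obj[names(dots)] <- dots
  known <- names(formals(market_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(market_config, obj)
}

# Full-precision CSV for report tables: numeric fields survive a
# write/read round trip bit-exactly.
write_report_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

read_report_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
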