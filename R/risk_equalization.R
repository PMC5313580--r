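#' Construct an equalization model from fixed coefficients
#'
#' A risk-equalization model maps a person's risk-adjuster levels to
#' predicted annual expenses via an intercept plus one coefficient per
#' non-reference dummy-encoded adjuster level. Models are normally fitted
#' with [fit_equalization_model()], but a regulator-supplied model (fixed
#' coefficients estimated elsewhere) can be constructed directly and
#' applied without refitting — this is what makes the efficiency-invariance
#' property of the switcher estimator testable under common random numbers.
#'
#' @param coefficients Named numeric vector: `"(Intercept)"` plus entries
#'   named `"adjuster=level"` (currency units).
#' @param adjusters Character vector of adjuster column names.
#' @param levels Named list: for each adjuster, its levels with the
#'   reference level first.
#' @param p_share Payment parameter p in percent, in `[0, 100]`: the
#'   equalization payment is predicted expenses minus p% of the overall
#'   mean expenses (p = 0 in Israel, 50 in the Netherlands, 100 in
#'   Switzerland).
#' @param overall_mean Mean actual expenses per person in the fit year
#'   (currency), the `m` of the payment formula.
#' @param fit_year Year the coefficients refer to (`NA` for supplied
#'   models).
#' @return An object of class `equalization_model`.
#' @export
equalization_model <- function(coefficients, adjusters, levels,
                               p_share = 50, overall_mean, fit_year = NA) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            "(Intercept)" %in% names(coefficients))
  if (p_share < 0 || p_share > 100)
    stop("`p_share` must lie in [0, 100]", call. = FALSE)
  if (!is.numeric(overall_mean) || length(overall_mean) != 1L ||
      overall_mean < 0)
    stop("`overall_mean` must be a non-negative scalar", call. = FALSE)
  stopifnot(all(adjusters %in% names(levels)))
  expected <- unlist(lapply(adjusters, function(a)
    paste0(a, "=", levels[[a]][-1])))
  missing <- setdiff(expected, names(coefficients))
  if (length(missing))
    stop("coefficients missing for levels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(coefficients = coefficients,
                 adjusters = adjusters,
                 levels = levels[adjusters],
                 p_share = as.numeric(p_share),
                 overall_mean = as.numeric(overall_mean),
                 fit_year = fit_year),
            class = "equalization_model")
}

#' Fit the risk-equalization formula by OLS
#'
#' Ordinary least squares of actual annual expenses on dummy-encoded risk
#' adjusters with an intercept, fitted on the rows of one calendar year.
#' The fit deliberately excludes the unpriced health component, so groups
#' defined by it are under- or overcompensated by construction. Declared
#' adjuster levels without observations in the fit year are dropped with a
#' warning; exact collinearity among the remaining dummies is an error
#' naming the offending columns.
#'
#' @param panel A person-year data.frame with `year`, `expenses` and the
#'   adjuster columns.
#' @param adjusters Character vector of adjuster column names to include.
#' @param fit_year Calendar year whose rows are used for estimation.
#' @param p_share Payment parameter p (percent), stored on the model.
#' @return An `equalization_model` whose `overall_mean` is the fit-year
#'   mean of actual expenses.
#' @examples
#' sim <- simulate_market(market_config(n_persons = 2000, n_insurers = 5,
#'                                      seed = 1))
#' mod <- fit_equalization_model(sim$panel, attr(sim$panel, "adjusters"),
#'                               fit_year = 2008)
#' mod
#' @export
fit_equalization_model <- function(panel, adjusters, fit_year,
                                   p_share = 50) {
  if (!all(adjusters %in% names(panel)))
    stop("panel is missing adjuster column(s): ",
         paste(setdiff(adjusters, names(panel)), collapse = ", "),
         call. = FALSE)
  rows <- panel$year == fit_year
  if (!any(rows))
    stop("no panel rows for fit year ", fit_year, call. = FALSE)
  sub <- panel[rows, , drop = FALSE]
  y <- sub$expenses
  n <- length(y)
  lev <- list()
  cols <- list(`(Intercept)` = rep(1, n))
  for (a in adjusters) {
    f <- sub[[a]]
    if (!is.factor(f)) f <- factor(f)
    present <- levels(f)[tabulate(f, nlevels(f)) > 0L]
    dropped <- setdiff(levels(f), present)
    if (length(dropped))
      warning("adjuster '", a, "': dropping level(s) without fit-year ",
              "observations: ", paste(dropped, collapse = ", "),
              call. = FALSE)
    lev[[a]] <- present
    ch <- as.character(f)
    for (l in present[-1]) cols[[paste0(a, "=", l)]] <- as.numeric(ch == l)
  }
  X <- do.call(cbind, cols)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    collinear <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(collinear, collapse = ", "), call. = FALSE)
  }
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  equalization_model(beta, adjusters, lev, p_share = p_share,
                     overall_mean = mean(y), fit_year = fit_year)
}

#' @export
print.equalization_model <- function(x, ...) {
  cat("Risk-equalization model",
      if (!is.na(x$fit_year)) sprintf("(fitted on year %s)", x$fit_year)
      else "(supplied coefficients)", "\n")
  cat(sprintf("  adjusters: %s\n", paste(x$adjusters, collapse = ", ")))
  cat(sprintf("  p = %g%%, overall mean expenses m = %.2f\n",
              x$p_share, x$overall_mean))
  cat(sprintf("  %d coefficients (intercept %.2f)\n",
              length(x$coefficients), x$coefficients[["(Intercept)"]]))
  invisible(x)
}

#' Predicted expenses under an equalization model
#'
#' @param object An `equalization_model`.
#' @param newdata A data.frame with the model's adjuster columns.
#' @param ... Unused.
#' @return Numeric vector of predicted annual expenses. Adjuster levels
#'   unseen at fit time are mapped to the reference level; their count is
#'   attached as attribute `n_unseen` and reported via a warning.
#' @export
predict.equalization_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$adjusters, names(newdata))
  if (length(missing_cols))
    stop("newdata is missing adjuster column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  pred <- rep(object$coefficients[["(Intercept)"]], nrow(newdata))
  n_unseen <- 0L
  for (a in object$adjusters) {
    lv <- object$levels[[a]]
    coefs <- c(0, object$coefficients[paste0(a, "=", lv[-1])])
    idx <- match(as.character(newdata[[a]]), lv)
    n_unseen <- n_unseen + sum(is.na(idx))
    idx[is.na(idx)] <- 1L   # unseen level -> reference
    pred <- pred + coefs[idx]
  }
  if (n_unseen > 0L)
    warning(n_unseen, " observation(s) carried adjuster levels unseen at ",
            "fit time; mapped to the reference level", call. = FALSE)
  attr(pred, "n_unseen") <- n_unseen
  pred
}

#' Residual expenses, overcompensation and equalization payments
#'
#' For each person-year of the target year(s), computes predicted expenses
#' under the model, the residual (actual minus predicted), the
#' overcompensation (predicted minus actual; negative values are
#' undercompensation) and the equalization payment
#' (predicted minus p% of the overall mean expenses).
#'
#' @param panel Person-year data.frame with `person_id`, `year`,
#'   `insurer_id`, `expenses` and the model's adjuster columns.
#' @param model An `equalization_model`.
#' @param target_year Year(s) to residualize; defaults to all years in the
#'   panel.
#' @return A data.frame with columns `person_id`, `year`, `insurer_id`,
#'   `actual`, `predicted`, `residual`, `overcompensation`, `payment`.
#' @export
residualize <- function(panel, model, target_year = NULL) {
  if (is.null(target_year)) target_year <- sort(unique(panel$year))
  rows <- panel$year %in% target_year
  if (!any(rows))
    stop("no panel rows for target year(s) ",
         paste(target_year, collapse = ", "), call. = FALSE)
  sub <- panel[rows, , drop = FALSE]
  pred <- predict(model, sub)
  out <- data.frame(person_id = sub$person_id,
                    year = sub$year,
                    insurer_id = sub$insurer_id,
                    actual = sub$expenses,
                    predicted = as.numeric(pred))
  out$residual <- out$actual - out$predicted
  out$overcompensation <- -out$residual
  out$payment <- equalization_payment(out$predicted, model)
  attr(out, "n_unseen") <- attr(pred, "n_unseen")
  out
}

#' Equalization payment per insured
#'
#' The payment the insurer receives from (if positive) or pays to (if
#' negative) the equalization fund: predicted expenses minus p% of the
#' overall average expenses per person.
#'
#' @param predicted Predicted annual expenses (currency).
#' @param model An `equalization_model` carrying `p_share` and
#'   `overall_mean`.
#' @return Numeric vector of payments (may be negative).
#' @examples
#' m <- equalization_model(c("(Intercept)" = 1570), character(0), list(),
#'                         p_share = 50, overall_mean = 1570)
#' equalization_payment(2000, m)  # 2000 - 0.5 * 1570 = 1215
#' @export
equalization_payment <- function(predicted, model) {
  predicted - model$p_share / 100 * model$overall_mean
}

#' Read or write an equalization model as JSON
#'
#' The JSON carries the adjuster list, the per-adjuster level order
#' (reference first), the named coefficient map, `p_share`,
#' `overall_mean` and `fit_year`, so a model estimated elsewhere can be
#' supplied and applied without refitting.
#'
#' @param model An `equalization_model`.
#' @param path File path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns the `equalization_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "equalization_model"))
  obj <- list(adjusters = model$adjusters,
              levels = model$levels,
              coefficients = as.list(model$coefficients),
              p_share = model$p_share,
              overall_mean = model$overall_mean,
              fit_year = model$fit_year)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  equalization_model(unlist(obj$coefficients),
                     adjusters = obj$adjusters,
                     levels = as.list(obj$levels),
                     p_share = obj$p_share,
                     overall_mean = obj$overall_mean,
                     fit_year = if (is.null(obj$fit_year)) NA
                                else obj$fit_year)
}
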