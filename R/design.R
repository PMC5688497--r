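#' Build the regression design for one risk category
#'
#' Extracts, from a table of survey aggregates, the modelling rows for one
#' `(dimension, label)` category: the natural log of the observed category
#' percent as response, with mCPR and the two method-mix shares as covariates
#' and the country identifier for the random intercept.
#'
#' Surveys with no births in the window (`n_births_window == 0`, category
#' percent `NA`) are dropped. A survey with a zero observed percent is handled
#' by `zero_rule`: `"continuity"` (default) substitutes the percent
#' `100 * 0.5 / n_births_window` — half a birth — before taking logs;
#' `"drop"` removes the row; `"error"` stops.
#'
#' @param aggregates Survey-aggregate data frame (see [aggregate_surveys()]).
#' @param dimension,label The category, e.g. `"parity"`, `"5+"`.
#' @param zero_rule One of `"continuity"`, `"drop"`, `"error"`.
#' @return Data frame with columns `y`, `mcpr_pct`, `pct_permanent`,
#'   `pct_larc`, `country_id`, `survey_id`.
#' @export
build_design <- function(aggregates, dimension, label,
                         zero_rule = c("continuity", "drop", "error")) {
  zero_rule <- match.arg(zero_rule)
  col <- paste0(dimension, "__", label)
  if (!col %in% names(aggregates))
    stop("no category column '", col, "' in aggregates")
  pct <- aggregates[[col]]
  keep <- !is.na(pct) &
    (is.null(aggregates$n_births_window) | aggregates$n_births_window > 0)
  agg <- aggregates[keep, , drop = FALSE]
  pct <- pct[keep]
  if (nrow(agg) == 0L || all(pct == 0))
    stop("category ", col, " has no nonzero observations across surveys")
  zero <- pct == 0
  if (any(zero)) {
    if (zero_rule == "error")
      stop("zero percent in category ", col, " for survey ",
           agg$survey_id[which(zero)[1L]])
    if (zero_rule == "drop") {
      agg <- agg[!zero, , drop = FALSE]; pct <- pct[!zero]
    } else {
      if (is.null(agg$n_births_window))
        stop("continuity zero rule needs an n_births_window column")
      pct[zero] <- 100 * 0.5 / agg$n_births_window[zero]
    }
  }
  data.frame(y = log(pct),
             mcpr_pct = agg$mcpr_pct,
             pct_permanent = agg$pct_permanent,
             pct_larc = agg$pct_larc,
             country_id = as.character(agg$country_id),
             survey_id = as.character(agg$survey_id),
             stringsAsFactors = FALSE)
}
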