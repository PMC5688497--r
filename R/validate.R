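# Schema validation for the two individual-level input tables.
# Errors name the offending field and the first bad row index.

.bad_rows <- function(cond) which(cond)[1L]

#' Validate a women table
#'
#' Checks the `women.csv` schema invariants: ages within 10-60 completed
#' years, method codes drawn from the recognised enumeration, logical union
#' status, and nonnegative sample weights (a missing `sample_weight` column is
#' filled with 1).
#'
#' @param women Data frame with columns `woman_id`, `survey_id`, `age_years`,
#'   `in_union`, `method_code` and optionally `sample_weight`.
#' @return The validated (possibly weight-augmented) data frame, invisibly
#'   usable; errors on the first violated invariant, naming field and row.
#' @export
validate_women <- function(women) {
  need <- c("woman_id", "survey_id", "age_years", "in_union", "method_code")
  miss <- setdiff(need, names(women))
  if (length(miss))
    stop("women table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(women$sample_weight)) women$sample_weight <- 1
  if (anyNA(women$age_years) || any(women$age_years < 10 | women$age_years > 60))
    stop("invalid field 'age_years' (must be in [10, 60]) at row ",
         .bad_rows(is.na(women$age_years) | women$age_years < 10 |
                     women$age_years > 60))
  if (!all(women$method_code %in% METHOD_CODES))
    stop("invalid field 'method_code' at row ",
         .bad_rows(!(women$method_code %in% METHOD_CODES)))
  if (!is.logical(women$in_union)) {
    if (all(women$in_union %in% c(0, 1))) women$in_union <- women$in_union == 1
    else stop("invalid field 'in_union' (must be logical or 0/1)")
  }
  if (any(is.na(women$sample_weight) | women$sample_weight < 0))
    stop("invalid field 'sample_weight' (must be nonnegative) at row ",
         .bad_rows(is.na(women$sample_weight) | women$sample_weight < 0))
  women
}

#' Validate a births table
#'
#' Checks the `births.csv` schema invariants: positive birth orders, a
#' preceding interval present exactly when the order is 2 or more, and (when
#' identifiers are present) strictly increasing birth dates with birth order
#' within each woman.
#'
#' @param births Data frame with columns `birth_order`,
#'   `mother_age_at_birth_years`, `preceding_interval_months`, and (unless
#'   `require_ids = FALSE`) `woman_id`, `survey_id`, `birth_cmc`.
#' @param require_ids Require the identifier and date columns (default `TRUE`).
#' @return The validated data frame; errors name the violated field.
#' @export
validate_births <- function(births, require_ids = TRUE) {
  need <- c("birth_order", "mother_age_at_birth_years",
            "preceding_interval_months")
  if (require_ids) need <- c("woman_id", "survey_id", "birth_cmc", need)
  miss <- setdiff(need, names(births))
  if (length(miss))
    stop("births table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(births) == 0L) return(births)
  if (anyNA(births$birth_order) || any(births$birth_order < 1))
    stop("invalid field 'birth_order' (must be a positive integer) at row ",
         .bad_rows(is.na(births$birth_order) | births$birth_order < 1))
  first <- births$birth_order == 1L
  has_int <- !is.na(births$preceding_interval_months)
  if (any(first & has_int))
    stop("invalid field 'preceding_interval_months': present on a first ",
         "birth at row ", .bad_rows(first & has_int))
  if (any(!first & !has_int))
    stop("invalid field 'preceding_interval_months': absent on a birth of ",
         "order >= 2 at row ", .bad_rows(!first & !has_int))
  if (any(has_int & births$preceding_interval_months <= 0))
    stop("invalid field 'preceding_interval_months' (must be positive) at row ",
         .bad_rows(has_int & births$preceding_interval_months <= 0))
  if (require_ids) {
    o <- order(births$woman_id, births$birth_order)
    b <- births[o, ]
    same <- duplicated(b$woman_id)
    if (any(same & diff(c(NA, b$birth_cmc))[seq_len(nrow(b))] <= 0, na.rm = TRUE)) {
      bad <- which(same & c(NA, diff(b$birth_cmc)) <= 0)[1L]
      stop("invalid field 'birth_cmc': not strictly increasing with ",
           "birth_order for woman_id ", b$woman_id[bad])
    }
  }
  births
}
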