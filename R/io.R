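case_table_columns <- c("case_id", "x_birth", "y_birth", "birth_date", "diagnosis_date")

#' Write a case table to CSV
#'
#' Column order: `case_id`, `x_birth`, `y_birth` (meters, floats),
#' `birth_date`, `diagnosis_date` (ISO-8601), then all remaining columns.
#'
#' @param cases a case table.
#' @param path CSV file path.
#' @export
write_case_table <- function(cases, path) {
  extra <- setdiff(names(cases), case_table_columns)
  out <- cases[, c(case_table_columns, extra)]
  out$birth_date <- format(as.Date(out$birth_date))
  out$diagnosis_date <- format(as.Date(out$diagnosis_date))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a case table from CSV
#'
#' Mandatory columns: `case_id`, `x_birth`, `y_birth`, `birth_date`,
#' `diagnosis_date` (ISO-8601 dates). Rows violating the record invariants --
#' non-finite coordinates, unparseable dates, diagnosis before birth, or
#' diagnosis at age 16 years or older -- are dropped and reported in the
#' `"rejected"` attribute (data frame with `row`, `case_id`, `reason`).
#'
#' @param path CSV file path.
#' @return The validated case table; inspect `attr(x, "rejected")`.
#' @export
read_case_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(case_table_columns, names(raw))
  if (length(missing_cols)) {
    stop("case CSV is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$birth_date <- as.Date(raw$birth_date)
  raw$diagnosis_date <- as.Date(raw$diagnosis_date)
  # documented optional columns keep stable types even when entirely missing
  if ("truth_cluster_id" %in% names(raw)) raw$truth_cluster_id <- as.integer(raw$truth_cluster_id)
  if ("sibling_group" %in% names(raw)) raw$sibling_group <- as.character(raw$sibling_group)
  reasons <- character(nrow(raw))
  bad_coord <- !is.finite(raw$x_birth) | !is.finite(raw$y_birth)
  reasons[bad_coord] <- "missing or non-finite birth coordinates"
  bad_date <- is.na(raw$birth_date) | is.na(raw$diagnosis_date)
  reasons[bad_date & reasons == ""] <- "unparseable birth or diagnosis date"
  ok_date <- !bad_date
  diag_before <- ok_date & (raw$diagnosis_date < raw$birth_date)
  reasons[diag_before & reasons == ""] <- "diagnosis before birth"
  too_old <- ok_date &
    (as.numeric(raw$diagnosis_date - raw$birth_date) / 365.25 >= 16)
  reasons[too_old & reasons == ""] <- "diagnosed at age >= 16 years"
  keep <- reasons == ""
  rejected <- data.frame(row = which(!keep),
                         case_id = raw$case_id[!keep],
                         reason = reasons[!keep], row.names = NULL)
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Exclude sibling cases
#'
#' From every `sibling_group`, exactly one case is retained: the earliest born,
#' with ties broken by the lowest `case_id`. Cases born less than
#' `distance_m` apart that do NOT share a sibling group are retained but
#' listed in the `"review"` attribute so they can be inspected for
#' unrecognized sibling relationships.
#'
#' @param cases a case table with a `sibling_group` column (NA = no sibling).
#' @param distance_m review radius in meters (default 50).
#' @return The case table without excluded siblings; `attr(x, "excluded")`
#'   lists removed case ids, `attr(x, "review")` the close non-sibling pairs.
#' @export
exclude_siblings <- function(cases, distance_m = 50) {
  if (!"sibling_group" %in% names(cases)) {
    stop("'sibling_group' column is required (use NA for non-siblings)", call. = FALSE)
  }
  grp <- cases$sibling_group
  drop <- logical(nrow(cases))
  for (g in unique(grp[!is.na(grp)])) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    keep <- idx[order(cases$birth_date[idx], cases$case_id[idx])][1]
    drop[setdiff(idx, keep)] <- TRUE
  }
  # close non-sibling pairs flagged for manual review
  d2 <- (outer(cases$x_birth, cases$x_birth, "-"))^2 +
    (outer(cases$y_birth, cases$y_birth, "-"))^2
  close <- which(d2 < distance_m^2 & upper.tri(d2), arr.ind = TRUE)
  same_grp <- !is.na(grp[close[, 1]]) & !is.na(grp[close[, 2]]) &
    grp[close[, 1]] == grp[close[, 2]]
  review <- data.frame(case_id_1 = cases$case_id[close[!same_grp, 1]],
                       case_id_2 = cases$case_id[close[!same_grp, 2]],
                       distance_m = sqrt(d2[close[!same_grp, , drop = FALSE]]),
                       row.names = NULL)
  out <- cases[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- cases$case_id[drop]
  attr(out, "review") <- review
  out
}
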