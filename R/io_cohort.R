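COHORT_SCHEMA <- c("id", "sex", "age", "edu", "mmse_total",
                   names(DOMAIN_MAX))

#' Read and validate a cohort table
#'
#' Expects the CSV schema
#' `id,sex,age,edu,mmse_total,ot,op,rg,ac,rc,lg,vc,dm` with sex coded 1 for
#' female and 0 for male. Row-level problems (unknown sex code, MMSE total
#' outside [0, 30], non-integer totals) are collected and reported together
#' in a single error; domain scores that do not sum to the total raise a
#' consistency warning listing the offending rows. Cognitive stages are
#' assigned from the fixed MMSE cut points.
#'
#' @param path CSV file path.
#' @return A validated `cohort_table` with a `stage` column.
#' @export
read_cohort <- function(path) {
  d <- read.csv(path)
  missing_cols <- setdiff(COHORT_SCHEMA, names(d))
  if (length(missing_cols))
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$id))
    stop("duplicate subject ids: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "), call. = FALSE)
  errs <- character()
  bad_sex <- which(!d$sex %in% c(0, 1))
  if (length(bad_sex))
    errs <- c(errs, paste0("unknown sex code in row(s) ",
                           paste(bad_sex, collapse = ", ")))
  bad_mmse <- which(!is.finite(d$mmse_total) | d$mmse_total < 0 |
                      d$mmse_total > 30 | d$mmse_total != round(d$mmse_total))
  if (length(bad_mmse))
    errs <- c(errs, paste0("MMSE total out of range in row(s) ",
                           paste(bad_mmse, collapse = ", ")))
  if (length(errs))
    stop("invalid cohort rows:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  dom_sum <- rowSums(d[, names(DOMAIN_MAX)])
  mismatch <- which(dom_sum != d$mmse_total)
  if (length(mismatch))
    warning("domain scores do not sum to the MMSE total in row(s) ",
            paste(mismatch, collapse = ", "))
  d$stage <- assign_stage(d$mmse_total)
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Write a cohort table as CSV
#'
#' Writes the canonical schema columns (plus biomarkers when present);
#' generator-internal columns are dropped.
#'
#' @param cohort a `cohort_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  d <- as.data.frame(cohort)
  keep <- intersect(c(COHORT_SCHEMA, "mdf", "pf", "atr", "stage"), names(d))
  write.csv(d[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Write a per-subject biomarker table as CSV
#'
#' @param biomarkers a list of `biomarker_set` objects or the data frame
#'   produced by flattening them.
#' @param path output file path.
#' @return The flattened data frame, invisibly.
#' @export
write_biomarkers <- function(biomarkers, path) {
  d <- if (is.data.frame(biomarkers)) biomarkers
       else do.call(rbind, lapply(biomarkers, as.data.frame))
  write.csv(d, path, row.names = FALSE)
  invisible(d)
}
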