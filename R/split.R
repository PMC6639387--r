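# allocate a total of `target` test slots across strata: per-stratum floor
# of the proportional quota, remaining slots to the largest fractional
# remainders (ties to the larger stratum)
allocate_counts <- function(sizes, fraction, target = round(sum(sizes) * fraction)) {
  quota <- sizes * fraction
  base <- floor(quota)
  rem <- target - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, sizes, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(quota - base, -sizes)
    take <- head(ord[base[ord] > 0], -rem)
    base[take] <- base[take] - 1
  }
  pmin(base, sizes)
}

#' Stage-stratified train/test split
#'
#' Randomly assigns the stated fraction of each cognitive stage to the test
#' set (per-stratum proportional allocation with largest-remainder
#' rounding), so train and test have approximately the stage distribution
#' of the full cohort. Reproducible under `seed`.
#'
#' @param cohort a cohort table with a `stage` column.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed or `NULL`.
#' @return `list(train, test, counts)` where `counts` is a per-stage table
#'   of test allocations.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_sim_params(n_subjects = 100, seed = 1))
#' sp <- stratified_split(coh, seed = 2)
#' nrow(sp$test)
stratified_split <- function(cohort, test_fraction = 0.2, seed = NULL) {
  d <- as.data.frame(cohort)
  if (is.null(d$stage)) stop("cohort lacks a 'stage' column", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("'test_fraction' must be in (0, 1)", call. = FALSE)
  sizes <- table(d$stage)
  if (any(sizes < 5))
    stop("every stage needs at least 5 subjects", call. = FALSE)
  n_test <- allocate_counts(as.numeric(sizes), test_fraction)
  test_idx <- with_seed(seed, {
    unlist(lapply(seq_along(sizes), function(i) {
      idx <- which(d$stage == names(sizes)[i])
      sample(idx, n_test[i])
    }))
  })
  list(train = cohort[-test_idx, , drop = FALSE],
       test = cohort[test_idx, , drop = FALSE],
       counts = stats::setNames(n_test, names(sizes)))
}

# stage-stratified k-fold assignment; returns integer fold id per row
stratified_folds <- function(stage, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(stage))
    for (s in unique(stage)) {
      idx <- which(stage == s)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}
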