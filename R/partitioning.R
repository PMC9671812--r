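# Spatially nested cross-validation: one fold per recruitment center.

#' Build the spatial cross-validation plan
#'
#' One fold per center: the fold's test set is every participant of that
#' center; the remaining centers are pooled and a uniform random
#' `valid_fraction` (floor rounding) is set aside for validation, the rest is
#' the training set. Unstratified by default.
#'
#' @param cohort cohort table with a `center_id` column.
#' @param valid_fraction fraction of the pooled non-test rows used for
#'   validation (default 0.10).
#' @param seed RNG seed; the plan is reproducible from it.
#' @return object of class `partition_plan`: list of folds, each with
#'   `test_center_id`, `train_ids`, `valid_ids`, `test_ids` (participant ids).
#' @export
make_partitions <- function(cohort, valid_fraction = 0.10, seed = 1L) {
  centers <- sort(unique(cohort$center_id))
  if (length(centers) < 2L) stop("need at least 2 distinct centers")
  if (valid_fraction <= 0 || valid_fraction >= 1)
    stop("valid_fraction must be in (0, 1)")
  set.seed(seed)
  ids <- cohort$participant_id
  folds <- lapply(centers, function(ct) {
    test <- ids[cohort$center_id == ct]
    pool <- ids[cohort$center_id != ct]
    nv <- floor(valid_fraction * length(pool))
    valid <- sample(pool, nv)
    list(test_center_id = ct,
         train_ids = setdiff(pool, valid),
         valid_ids = valid,
         test_ids = test)
  })
  plan <- structure(list(folds = folds, valid_fraction = valid_fraction,
                         seed = seed, n_participants = length(ids)),
                    class = "partition_plan")
  audit_partitions(plan, ids)
  plan
}

#' Assert the leakage invariants of a partition plan
#'
#' Checks, for every fold, that train/valid/test are pairwise disjoint, and
#' that the union of test sets over folds is exactly the cohort with every
#' participant in exactly one fold's test set. Errors on violation.
#'
#' @param plan a `partition_plan`.
#' @param all_ids participant ids of the cohort the plan was built for.
#' @return `TRUE`, invisibly.
#' @export
audit_partitions <- function(plan, all_ids) {
  stopifnot(inherits(plan, "partition_plan"))
  test_union <- character()
  for (f in plan$folds) {
    if (length(intersect(f$train_ids, f$test_ids)) ||
        length(intersect(f$valid_ids, f$test_ids)) ||
        length(intersect(f$train_ids, f$valid_ids)))
      stop("partition audit failed: overlapping train/valid/test in fold of center ",
           f$test_center_id)
    if (length(union(union(f$train_ids, f$valid_ids), f$test_ids)) !=
        length(all_ids))
      stop("partition audit failed: fold of center ", f$test_center_id,
           " does not cover the cohort")
    test_union <- c(test_union, f$test_ids)
  }
  if (anyDuplicated(test_union))
    stop("partition audit failed: participant in more than one test set")
  if (!setequal(test_union, all_ids))
    stop("partition audit failed: test sets do not cover the cohort")
  invisible(TRUE)
}

#' Serialize a partition plan to JSON
#' @param plan a `partition_plan`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition_plan <- function(plan, path) {
  jsonlite::write_json(
    list(valid_fraction = plan$valid_fraction, seed = plan$seed,
         folds = lapply(plan$folds, function(f)
           list(test_center_id = f$test_center_id, train_ids = f$train_ids,
                valid_ids = f$valid_ids, test_ids = f$test_ids))),
    path, auto_unbox = TRUE)
  invisible(path)
}
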