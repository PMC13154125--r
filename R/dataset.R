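# Dataset curation: polymorph handling (one-polymorph and
# all-unique-space-group variants), balanced subsets over the most frequent
# space groups, and train/validation/test splitting (optionally stratified
# with largest-remainder rounding).

#' Keep one polymorph per molecule family
#'
#' Retains, per `family_id`, the record with the lowest deposition rank (the
#' first deposited structure).
#'
#' @param records list of `xtal_record` objects.
#' @return Filtered record list (one record per family), input order
#'   preserved.
#' @export
first_polymorph_only <- function(records) {
  tab <- record_table(records)
  keep <- logical(length(records))
  best <- tapply(tab$deposition_rank, tab$family_id, min)
  keep <- tab$deposition_rank == best[tab$family_id]
  # guard against duplicated ranks: keep the first occurrence only
  keep[keep] <- !duplicated(tab$family_id[keep])
  records[keep]
}

#' Keep all polymorphs with unique space groups
#'
#' Per family, one record per distinct space-group label (the lowest
#' deposition rank among duplicates).
#'
#' @inheritParams first_polymorph_only
#' @return Filtered record list, input order preserved.
#' @export
unique_space_group_polymorphs <- function(records) {
  tab <- record_table(records)
  key <- paste(tab$family_id, tab$space_group)
  ord <- order(tab$deposition_rank)
  first_of_key <- !duplicated(key[ord])
  keep <- logical(length(records))
  keep[ord] <- first_of_key
  records[keep]
}

#' Balanced subset over the k most frequent space groups
#'
#' Restricts to the `k_groups` most frequent labels (frequency ties broken
#' by lower space-group number), then samples, per retained label, `m`
#' records uniformly without replacement, where `m` is the count of the
#' least frequent retained label. The output has exactly `k_groups * m`
#' records with a uniform label histogram.
#'
#' @inheritParams first_polymorph_only
#' @param k_groups number of space groups to retain.
#' @param seed integer seed for the per-label subsampling.
#' @return Balanced record list.
#' @export
balanced_subset <- function(records, k_groups, seed = 1L) {
  tab <- record_table(records)
  cnt <- table(tab$space_group)
  if (k_groups > length(cnt)) {
    stop("k_groups (", k_groups, ") exceeds the ", length(cnt),
         " distinct labels present")
  }
  cnt_df <- data.frame(sg = as.integer(names(cnt)), n = as.integer(cnt))
  cnt_df <- cnt_df[order(-cnt_df$n, cnt_df$sg), ]
  keep_sg <- cnt_df$sg[seq_len(k_groups)]
  m <- min(cnt_df$n[seq_len(k_groups)])
  set.seed(seed)
  idx <- integer()
  for (sg in sort(keep_sg)) {
    pool <- which(tab$space_group == sg)
    idx <- c(idx, if (length(pool) == m) pool else sort(sample(pool, m)))
  }
  records[sort(idx)]
}

#' Train/validation/test split
#'
#' Unstratified: a seeded random partition with sizes from largest-remainder
#' rounding of the fractions. Stratified: the same largest-remainder
#' assignment per label, so per-label proportions deviate from the target by
#' less than one record; strata smaller than 3 go entirely to the training
#' set with a warning.
#'
#' @inheritParams first_polymorph_only
#' @param fractions three nonnegative fractions (train, validation, test)
#'   summing to 1 within 1e-9.
#' @param stratified logical; stratify the partition by space-group label.
#' @param seed integer seed.
#' @return Object of class `xtal_split`: `train_ids`, `val_ids`, `test_ids`
#'   (disjoint record-id sets partitioning the input), plus the fractions,
#'   seed and stratification flag.
#' @export
split_records <- function(records, fractions = c(0.95, 0.025, 0.025),
                          stratified = FALSE, seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three nonnegative values summing to 1")
  }
  tab <- record_table(records)
  set.seed(seed)

  largest_remainder <- function(n) {
    raw <- n * fractions
    base <- floor(raw)
    rem <- raw - base
    short <- n - sum(base)
    if (short > 0) {
      add <- order(-rem)[seq_len(short)]
      base[add] <- base[add] + 1
    }
    as.integer(base)
  }
  assign_ids <- function(ids) {
    n <- length(ids)
    sizes <- largest_remainder(n)
    perm <- sample(ids)
    list(train = perm[seq_len(sizes[1])],
         val = perm[sizes[1] + seq_len(sizes[2])],
         test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }

  if (!stratified) {
    parts <- assign_ids(tab$record_id)
  } else {
    parts <- list(train = character(), val = character(), test = character())
    small <- integer()
    for (sg in sort(unique(tab$space_group))) {
      ids <- tab$record_id[tab$space_group == sg]
      if (length(ids) < 3L) {
        small <- c(small, sg)
        parts$train <- c(parts$train, ids)
        next
      }
      p <- assign_ids(ids)
      parts$train <- c(parts$train, p$train)
      parts$val <- c(parts$val, p$val)
      parts$test <- c(parts$test, p$test)
    }
    if (length(small)) {
      warning("strata smaller than 3 records assigned entirely to train: SG ",
              paste(small, collapse = ", "))
    }
  }
  structure(list(train_ids = parts$train, val_ids = parts$val,
                 test_ids = parts$test, fractions = fractions,
                 seed = as.integer(seed), stratified = stratified),
            class = "xtal_split")
}

#' @export
print.xtal_split <- function(x, ...) {
  cat(sprintf("<xtal_split %d/%d/%d (%s%s)>\n", length(x$train_ids),
              length(x$val_ids), length(x$test_ids),
              paste(x$fractions, collapse = "/"),
              if (x$stratified) ", stratified" else ""))
  invisible(x)
}

#' Subset records by id
#'
#' @param records list of `xtal_record` objects.
#' @param ids character vector of record ids.
#' @return Records with the given ids, in `ids` order.
#' @export
records_by_id <- function(records, ids) {
  all_ids <- vapply(records, `[[`, "", "record_id")
  i <- match(ids, all_ids)
  if (anyNA(i)) stop("unknown record id(s): ",
                     paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
  records[i]
}
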