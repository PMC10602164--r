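# Corpus ingestion, PCL-5 scoring, labeling, filtering, balancing, splitting.

pcl5_cols <- function() sprintf("pcl5_%02d", 1:20)

#' Score a PCL-5 response
#'
#' Sums the 20 item severities (each 0-4). Missing items contribute 0, the
#' convention used when a respondent skips items. The total ranges 0-80.
#'
#' @param items Numeric vector of exactly 20 entries; each entry an integer in
#'   0-4 or `NA` for a missing item.
#' @return Integer total in 0-80.
#' @export
#' @examples
#' score_pcl5(rep(2, 20))
#' score_pcl5(c(rep(1, 19), NA))
score_pcl5 <- function(items) {
  if (length(items) != 20L) {
    stop("a PCL-5 response must have exactly 20 items, got ", length(items))
  }
  present <- items[!is.na(items)]
  if (length(present) && (any(present %% 1 != 0) || any(present < 0) || any(present > 4))) {
    stop("PCL-5 item values must be integers in 0-4")
  }
  as.integer(sum(present))
}

#' Assign the screening class from a PCL-5 total
#'
#' A total at or above the cutoff (default 31) marks the positive class
#' (probable CB-PTSD, class 1); below it, class 0.
#'
#' @param total Integer vector of PCL-5 totals in 0-80.
#' @param cutoff Integer cutoff in 0-80; default 31.
#' @return Integer vector of class labels in \{0, 1\}.
#' @export
#' @examples
#' assign_class(c(30, 31, 80))
assign_class <- function(total, cutoff = 31L) {
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 0 || cutoff > 80) {
    stop("cutoff must be a single integer in 0-80")
  }
  if (any(is.na(total)) || any(total < 0) || any(total > 80)) {
    stop("totals must be in 0-80")
  }
  as.integer(total >= cutoff)
}

#' Read a survey table
#'
#' Reads a UTF-8 delimited file with columns `record_id`, `text` and
#' `pcl5_01` ... `pcl5_20` (blank cells are missing items).
#'
#' @param path File path.
#' @param sep Field delimiter; default tab.
#' @return A data frame with one row per record.
#' @export
read_survey <- function(path, sep = "\t") {
  df <- utils::read.table(
    path, sep = sep, header = TRUE, quote = "\"",
    na.strings = c("", "NA"), stringsAsFactors = FALSE,
    fileEncoding = "UTF-8", check.names = FALSE, comment.char = ""
  )
  need <- c("record_id", "text", pcl5_cols())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("survey table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$record_id <- as.character(df$record_id)
  df$text <- ifelse(is.na(df$text), "", as.character(df$text))
  for (cl in pcl5_cols()) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Label survey records
#'
#' Computes derived columns for each record: `pcl5_total` (missing items
#' coded 0), `label` (1 if total at or above `cutoff`), and `word_count`
#' (whitespace tokenizer, see [count_words()]). Records with all 20 items
#' missing are scored 0 and reported via a message.
#'
#' @param df Data frame with columns `record_id`, `text`, `pcl5_01`..`pcl5_20`.
#' @param cutoff PCL-5 cutoff for the positive class; default 31.
#' @return The input data frame with `pcl5_total`, `label`, `word_count` added.
#' @export
label_records <- function(df, cutoff = 31L) {
  need <- c("record_id", "text", pcl5_cols())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(df$record_id)
  if (anyDuplicated(ids)) {
    stop("duplicate record_id values: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  items <- as.matrix(df[, pcl5_cols()])
  storage.mode(items) <- "numeric"
  totals <- vapply(seq_len(nrow(df)), function(i) score_pcl5(items[i, ]), integer(1L))
  all_missing <- rowSums(!is.na(items)) == 0L
  if (any(all_missing)) {
    message(sum(all_missing), " record(s) with all PCL-5 items missing scored 0: ",
            paste(ids[all_missing], collapse = ", "))
  }
  df$record_id <- ids
  df$pcl5_total <- totals
  df$label <- assign_class(totals, cutoff = cutoff)
  df$word_count <- count_words(df$text)
  df
}

#' Filter narratives by minimum word count
#'
#' Keeps records whose narrative has at least `min_words` words (default 30,
#' the minimum length considered analyzable). Input order is preserved and
#' the operation is idempotent.
#'
#' @param records Labeled data frame (see [label_records()]).
#' @param min_words Minimum word count; default 30.
#' @return The retained subset of `records`.
#' @export
filter_by_word_count <- function(records, min_words = 30L) {
  if (!"word_count" %in% names(records)) {
    records$word_count <- count_words(records$text)
  }
  records[records$word_count >= min_words, , drop = FALSE]
}

#' Balance classes by down-sampling the majority class
#'
#' Randomly discards majority-class records until both classes have the
#' minority-class size. The minority class is untouched; the sampled subset is
#' reproducible from `seed`; input row order is preserved among survivors.
#'
#' @param records Labeled data frame with a `label` column in \{0, 1\}.
#' @param seed Integer RNG seed for the down-sampling draw.
#' @return A balanced subset of `records`.
#' @export
balance_downsample <- function(records, seed) {
  n1 <- sum(records$label == 1L)
  n0 <- sum(records$label == 0L)
  if (n1 == 0L) stop("class 1 is empty; cannot balance")
  if (n0 == 0L) stop("class 0 is empty; cannot balance")
  n_min <- min(n0, n1)
  keep <- rep(TRUE, nrow(records))
  if (n0 != n1) {
    major <- if (n0 > n1) 0L else 1L
    major_idx <- which(records$label == major)
    kept_major <- withr::with_seed(as.integer(seed), sample(major_idx, n_min))
    keep[setdiff(major_idx, kept_major)] <- FALSE
  }
  records[keep, , drop = FALSE]
}

#' Split balanced records into train and test sets per class
#'
#' Samples `train_per_class` record ids per class without replacement; the
#' remainder of each class forms the test set. The draw is reproducible from
#' `seed + repeat_index`, so a sequence of repeats re-draws independent splits.
#'
#' @param records Balanced labeled data frame.
#' @param train_per_class Training narratives per class; default 170.
#' @param seed Base integer seed.
#' @param repeat_index Zero-based repeat number; default 0.
#' @return A `split_plan` object: lists of train and test ids per class.
#' @export
split_train_test <- function(records, train_per_class = 170L, seed = 1L,
                             repeat_index = 0L) {
  ids0 <- records$record_id[records$label == 0L]
  ids1 <- records$record_id[records$label == 1L]
  for (ids in list(`0` = ids0, `1` = ids1)) {
    if (length(ids) < train_per_class) {
      stop("train_per_class (", train_per_class, ") exceeds a class size (",
           length(ids), ")")
    }
  }
  drawn <- withr::with_seed(as.integer(seed) + as.integer(repeat_index), {
    t0 <- sample(ids0, train_per_class)
    t1 <- sample(ids1, train_per_class)
    list(t0 = t0, t1 = t1)
  })
  plan <- list(
    repeat_index = as.integer(repeat_index),
    seed = as.integer(seed),
    train_ids = list(`0` = sort(drawn$t0), `1` = sort(drawn$t1)),
    test_ids = list(`0` = sort(setdiff(ids0, drawn$t0)),
                    `1` = sort(setdiff(ids1, drawn$t1)))
  )
  structure(plan, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan (repeat ", x$repeat_index, ", seed ", x$seed, ")\n",
      "  train: ", length(x$train_ids$`0`), " / ", length(x$train_ids$`1`),
      " per class (0/1)\n",
      "  test:  ", length(x$test_ids$`0`), " / ", length(x$test_ids$`1`),
      " per class (0/1)\n", sep = "")
  invisible(x)
}

#' Cronbach's alpha for an item matrix
#'
#' Internal-consistency reliability
#' \eqn{\alpha = \frac{k}{k-1}\left(1 - \sum_i s_i^2 / s_T^2\right)} where
#' \eqn{s_i^2} are sample item variances and \eqn{s_T^2} the variance of the
#' row totals. Missing items are coded 0 first, matching the scoring rule.
#'
#' @param item_matrix Numeric matrix or data frame, records by items.
#' @return Alpha as a single numeric value.
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  storage.mode(x) <- "numeric"
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("cronbach_alpha needs at least 2 records and 2 items")
  }
  x[is.na(x)] <- 0
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) stop("total-score variance is zero; alpha undefined")
  item_var <- sum(apply(x, 2L, stats::var))
  (k / (k - 1)) * (1 - item_var / total_var)
}
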