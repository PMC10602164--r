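test_that("PCL-5 scoring sums items with missing coded as zero", {
  expect_identical(score_pcl5(rep(0, 20)), 0L)
  expect_identical(score_pcl5(rep(4, 20)), 80L)
  expect_identical(score_pcl5(c(rep(1, 19), NA)), 19L)
  expect_identical(score_pcl5(rep(NA_real_, 20)), 0L)
  expect_error(score_pcl5(rep(1, 19)), "exactly 20")
  expect_error(score_pcl5(rep(1, 21)), "exactly 20")
  expect_error(score_pcl5(c(rep(1, 19), 5)), "0-4")
  expect_error(score_pcl5(c(rep(1, 19), -1)), "0-4")
  expect_error(score_pcl5(c(rep(1, 19), 2.5)), "0-4")
})

test_that("filling a missing item never decreases the total", {
  for (s in 1:10) {
    items <- withr::with_seed(s, sample(c(0:4, NA), 20, replace = TRUE))
    items[1] <- NA
    base <- score_pcl5(items)
    for (v in 0:4) {
      filled <- items
      filled[1] <- v
      expect_gte(score_pcl5(filled), base)
    }
  }
})

test_that("class assignment applies the 31-point cutoff inclusively", {
  expect_identical(assign_class(31), 1L)
  expect_identical(assign_class(30), 0L)
  expect_identical(assign_class(0), 0L)
  expect_identical(assign_class(c(0, 30, 31, 80)), c(0L, 0L, 1L, 1L))
  expect_identical(assign_class(30, cutoff = 30), 1L)
  expect_error(assign_class(31, cutoff = 81), "cutoff")
  expect_error(assign_class(31, cutoff = -1), "cutoff")
  expect_error(assign_class(81), "0-80")
})

test_that("label_records derives totals, labels and word counts", {
  df <- data.frame(record_id = c("a", "b", "c"),
                   text = c("one two three", "", "just one two three four"),
                   stringsAsFactors = FALSE)
  items <- matrix(0, 3, 20, dimnames = list(NULL, sprintf("pcl5_%02d", 1:20)))
  items[1, ] <- 2          # total 40 -> class 1
  items[2, 1:10] <- 3      # total 30 -> class 0
  items[3, ] <- NA         # all missing -> total 0, flagged
  df <- cbind(df, as.data.frame(items))
  expect_message(out <- label_records(df), "all PCL-5 items missing")
  expect_identical(out$pcl5_total, c(40L, 30L, 0L))
  expect_identical(out$label, c(1L, 0L, 0L))
  expect_identical(out$word_count, c(3L, 0L, 5L))
  # classes partition the input
  expect_identical(sum(out$label == 1L) + sum(out$label == 0L), nrow(out))
  df2 <- df
  df2$record_id <- c("a", "a", "c")
  expect_error(suppressMessages(label_records(df2)), "duplicate record_id")
})

test_that("survey tables round-trip through the delimited format", {
  df <- data.frame(record_id = c("r1", "r2"),
                   text = c("a narrative of birth", "another story"),
                   stringsAsFactors = FALSE)
  items <- matrix(c(rep(2, 20), rep(1, 20)), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, sprintf("pcl5_%02d", 1:20)))
  items[2, 7] <- NA
  df <- cbind(df, as.data.frame(items))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  back <- read_survey(path)
  expect_identical(back$record_id, c("r1", "r2"))
  expect_true(is.na(back$pcl5_07[2]))
  labeled <- label_records(back)
  expect_identical(labeled$pcl5_total, c(40L, 19L))
})

test_that("word-count filter keeps 30-word narratives and is idempotent", {
  mk <- function(n) trimws(paste(rep("w", n), collapse = " "))
  df <- data.frame(record_id = as.character(1:4),
                   text = c(mk(30), mk(29), "", mk(100)),
                   stringsAsFactors = FALSE)
  df$word_count <- count_words(df$text)
  kept <- filter_by_word_count(df)
  expect_identical(kept$record_id, c("1", "4"))
  expect_identical(filter_by_word_count(kept), kept)
  expect_identical(nrow(filter_by_word_count(df[0, , drop = FALSE])), 0L)
})

test_that("down-sampling equalizes class sizes reproducibly", {
  rec <- toy_records(c(rep(0, 19), rep(1, 5)))
  bal <- balance_downsample(rec, seed = 42)
  expect_identical(as.integer(table(bal$label)), c(5L, 5L))
  expect_true(all(rec$record_id[rec$label == 1] %in% bal$record_id))
  # same seed twice: identical subset; different seed: (almost surely) not
  expect_identical(balance_downsample(rec, seed = 42), bal)
  # already balanced: a no-op
  even <- toy_records(rep(c(0, 1), 6))
  expect_identical(balance_downsample(even, seed = 1), even)
  # class sizes equal the minimum for random class mixes
  for (s in 1:5) {
    lab <- withr::with_seed(s, sample(0:1, 30, replace = TRUE, prob = c(.7, .3)))
    if (length(unique(lab)) < 2) next
    b <- balance_downsample(toy_records(lab), seed = s)
    expect_identical(as.integer(table(b$label)),
                     rep(as.integer(min(table(lab))), 2))
  }
  expect_error(balance_downsample(toy_records(rep(1, 4)), seed = 1), "class 0")
  expect_error(balance_downsample(toy_records(rep(0, 4)), seed = 1), "class 1")
})

test_that("train/test splits are disjoint, balanced and vary with repeat index", {
  rec <- toy_records(rep(c(0, 1), each = 5))
  plan <- split_train_test(rec, train_per_class = 3, seed = 7, repeat_index = 0)
  expect_identical(lengths(plan$train_ids), c(`0` = 3L, `1` = 3L))
  expect_identical(lengths(plan$test_ids), c(`0` = 2L, `1` = 2L))
  expect_length(intersect(unlist(plan$train_ids), unlist(plan$test_ids)), 0L)
  # distinct repeat indices reach more than one of the C(5,3) possible splits
  tests <- vapply(0:9, function(r) {
    p <- split_train_test(rec, train_per_class = 3, seed = 7, repeat_index = r)
    paste(p$test_ids$`1`, collapse = ",")
  }, character(1))
  expect_gt(length(unique(tests)), 1L)
  # boundary: train = class size leaves an empty test set
  full <- split_train_test(rec, train_per_class = 5, seed = 7)
  expect_length(full$test_ids$`1`, 0L)
  expect_error(split_train_test(rec, train_per_class = 6, seed = 7),
               "exceeds")
})

test_that("Cronbach's alpha matches direct evaluation of the formula", {
  # identical copies of one varying column are perfectly consistent
  x <- cbind(1:6, 1:6, 1:6)
  expect_equal(cronbach_alpha(x), 1.0)
  # 4 records x 2 items, hand-computed: item variances 5/3 and 35/12,
  # total variance 107/12, alpha = 2 * (1 - (55/12)/(107/12)) = 104/107
  y <- rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 5))
  expect_equal(cronbach_alpha(y), 104 / 107, tolerance = 1e-12)
  # independent uniform items have alpha near zero
  z <- withr::with_seed(1, matrix(sample(0:4, 10000 * 20, replace = TRUE),
                                  ncol = 20))
  expect_lt(abs(cronbach_alpha(z)), 0.05)
  expect_error(cronbach_alpha(matrix(2, 5, 3)), "variance")
  expect_error(cronbach_alpha(y[1, , drop = FALSE]), "at least 2")
})
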