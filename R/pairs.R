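# Pairwise data augmentation: within-class and cross-class narrative pairs
# with Hadamard-product embedding features.
#
# With k training narratives per class the augmentation yields
#   |Set 1| = |Set 2| = C(k, 2)   within-class ("similar", label 1)
#   |Set 3| = 2 * C(k, 2)         cross-class ("dissimilar", label 0)
# for a total of 4 * C(k, 2) balanced examples (57460 at k = 170).

#' All unordered pairs within one class
#'
#' @param ids Character vector of at least two distinct record ids.
#' @return Data frame with columns `id_a`, `id_b`, canonical `id_a < id_b`;
#'   exactly `choose(length(ids), 2)` rows.
#' @export
within_class_pairs <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids must be distinct")
  if (length(ids) < 2L) stop("need at least 2 ids to form pairs")
  ids <- sort(ids)
  idx <- utils::combn(length(ids), 2L)
  data.frame(id_a = ids[idx[1L, ]], id_b = ids[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Randomly sampled cross-class pairs
#'
#' Samples `count` pairs with one member from each class. When `count` does
#' not exceed the size of the full cross grid the draw is without replacement
#' (no duplicate pairs); otherwise with replacement. Reproducible from `seed`.
#'
#' @param ids0,ids1 Character vectors of record ids for class 0 and class 1.
#' @param count Number of pairs to draw.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `id_a`, `id_b` (canonical order).
#' @export
cross_class_pairs <- function(ids0, ids1, count, seed) {
  ids0 <- as.character(ids0); ids1 <- as.character(ids1)
  if (!length(ids0)) stop("class 0 id set is empty")
  if (!length(ids1)) stop("class 1 id set is empty")
  if (count < 1L) stop("count must be >= 1")
  grid_n <- length(ids0) * length(ids1)
  cells <- withr::with_seed(as.integer(seed), {
    if (count <= grid_n) sample.int(grid_n, count)
    else sample.int(grid_n, count, replace = TRUE)
  })
  i0 <- ((cells - 1L) %% length(ids0)) + 1L
  i1 <- ((cells - 1L) %/% length(ids0)) + 1L
  a <- ids0[i0]; b <- ids1[i1]
  swap <- a > b
  data.frame(id_a = ifelse(swap, b, a), id_b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

#' Hadamard-product pair feature
#'
#' Elementwise product `z[i] = u[i] * v[i]` of two embedding vectors; the
#' feature is symmetric in its arguments.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Numeric vector `z` of the same length.
#' @export
#' @examples
#' hadamard_feature(c(1, 2, 3), c(1, 1, 1))
hadamard_feature <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors differ in length (", length(u), " vs ", length(v), ")")
  }
  as.numeric(u) * as.numeric(v)
}

#' Build the augmented pairwise training set for one split
#'
#' Assembles Set 1 (all within-class-1 pairs), Set 2 (all within-class-0
#' pairs) and Set 3 (randomly sampled cross-class pairs, `neg_ratio` times
#' one within-class set), labels them similar (1) / dissimilar (0), and
#' computes the Hadamard feature for every pair from the embedding store.
#'
#' @param split A `split_plan` from [split_train_test()].
#' @param store An `embedding_store` holding vectors for every train id.
#' @param seed Integer seed for the cross-class draw.
#' @param neg_ratio Cross-class pairs per within-class pair count; default 2
#'   (negatives equal positives since there are two within-class sets).
#' @return List with `pairs` (data frame: `id_a`, `id_b`, `set_tag`, `label`)
#'   and `features` (numeric matrix, one row per pair).
#' @export
build_training_set <- function(split, store, seed, neg_ratio = 2) {
  stopifnot(inherits(split, "split_plan"))
  ids0 <- split$train_ids$`0`
  ids1 <- split$train_ids$`1`
  if (length(ids0) != length(ids1)) {
    stop("train classes are not balanced (", length(ids0), " vs ",
         length(ids1), ")")
  }
  set1 <- within_class_pairs(ids1)
  set1$set_tag <- "within_class1"
  set2 <- within_class_pairs(ids0)
  set2$set_tag <- "within_class0"
  n_neg <- round(neg_ratio * nrow(set1))
  set3 <- cross_class_pairs(ids0, ids1, count = n_neg, seed = seed)
  set3$set_tag <- "cross_class"
  pairs <- rbind(set1, set2, set3)
  pairs$label <- as.integer(pairs$set_tag != "cross_class")
  emb <- store_vectors(store, c(ids0, ids1))
  features <- emb[pairs$id_a, , drop = FALSE] * emb[pairs$id_b, , drop = FALSE]
  dimnames(features) <- NULL
  rownames(pairs) <- NULL
  list(pairs = pairs, features = features)
}
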