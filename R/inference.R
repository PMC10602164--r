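# Anchor-based classification of a single unseen narrative.
#
# The trained network scores pair similarity, not class membership. To label
# one test narrative we compare it against the train-split narratives of each
# class (the "anchors"): the mean predicted similarity of the test vector to
# the class-1 anchors versus the class-0 anchors decides the label, with ties
# going to class 0 (the specificity-favoring choice for a screening tool).

#' Construct an anchor set
#'
#' @param class_label 0 or 1.
#' @param ids Character record ids (train-split members of that class).
#' @param vectors Numeric matrix of their embeddings, one row per id.
#' @return An `anchor_set` object.
#' @export
anchor_set <- function(class_label, ids, vectors) {
  stopifnot(class_label %in% c(0L, 1L))
  vectors <- as.matrix(vectors)
  if (length(ids) == 0L || nrow(vectors) == 0L) {
    stop("anchor set for class ", class_label, " is empty")
  }
  if (nrow(vectors) != length(ids)) {
    stop("ids and vectors disagree in length")
  }
  structure(list(class_label = as.integer(class_label),
                 ids = as.character(ids), vectors = vectors),
            class = "anchor_set")
}

anchor_score <- function(test_vector, model, anchors) {
  feats <- anchors$vectors *
    matrix(test_vector, nrow(anchors$vectors), length(test_vector),
           byrow = TRUE)
  mean(predict_similarity(model, feats))
}

#' Classify one narrative against class anchor sets
#'
#' Computes the mean predicted similarity of the test embedding to every
#' anchor of each class (Hadamard feature per anchor pair) and predicts the
#' class with the larger mean; a tie predicts class 0.
#'
#' @param test_vector Numeric embedding of the narrative to classify.
#' @param model A trained `similarity_model`.
#' @param anchors0,anchors1 `anchor_set` objects for classes 0 and 1.
#' @return A one-row data frame: `score_class0`, `score_class1`, `predicted`.
#' @export
classify_narrative <- function(test_vector, model, anchors0, anchors1) {
  stopifnot(inherits(anchors0, "anchor_set"), inherits(anchors1, "anchor_set"))
  if (anchors0$class_label != 0L || anchors1$class_label != 1L) {
    stop("anchor sets must be given as (class 0, class 1)")
  }
  if (ncol(anchors0$vectors) != length(test_vector) ||
      ncol(anchors1$vectors) != length(test_vector)) {
    stop("anchor and test vector dimensions disagree")
  }
  s0 <- anchor_score(test_vector, model, anchors0)
  s1 <- anchor_score(test_vector, model, anchors1)
  data.frame(score_class0 = s0, score_class1 = s1,
             predicted = as.integer(s1 > s0))
}

#' Classify every test narrative of a split
#'
#' Uses the split's train ids per class as anchor sets and classifies each
#' test id's embedding with [classify_narrative()].
#'
#' @param split A `split_plan`.
#' @param model A trained `similarity_model`.
#' @param store An `embedding_store` holding vectors for all train and test
#'   ids of the split.
#' @return Data frame: `record_id`, `true_label`, `score_class0`,
#'   `score_class1`, `predicted`; one row per test narrative.
#' @export
classify_test_set <- function(split, model, store) {
  stopifnot(inherits(split, "split_plan"))
  test0 <- split$test_ids$`0`
  test1 <- split$test_ids$`1`
  if (length(test0) + length(test1) == 0L) stop("split has an empty test set")
  a0 <- anchor_set(0L, split$train_ids$`0`,
                   store_vectors(store, split$train_ids$`0`))
  a1 <- anchor_set(1L, split$train_ids$`1`,
                   store_vectors(store, split$train_ids$`1`))
  ids <- c(test0, test1)
  truth <- c(rep(0L, length(test0)), rep(1L, length(test1)))
  vecs <- store_vectors(store, ids)
  rows <- lapply(seq_along(ids), function(i) {
    classify_narrative(vecs[i, ], model, a0, a1)
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(record_id = ids, true_label = truth,
                   stringsAsFactors = FALSE),
        out)
}
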