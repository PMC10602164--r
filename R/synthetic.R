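# Synthetic survey generator.
#
# Emulates the statistical structure the pipeline assumes, so every stage is
# exercisable offline: class-conditional embedding clusters of controllable
# separation, class-conditional PCL-5 item responses whose totals straddle
# the cutoff, and template narratives with class-conditional word-count
# distributions (right-skewed, matching the reported class means/medians).
# Embeddings are generated directly from class labels rather than from the
# synthetic text: the production text-to-vector map is an external black box,
# and the text generator exists to exercise filtering, I/O and prompt
# plumbing. The two meet only through the record id.

#' Configuration for the synthetic survey generator
#'
#' Defaults mirror the study's shape: 190 records per class (so the default
#' 170-per-class training split leaves 20 test narratives per class),
#' 1536-dimensional embeddings, and word-count distributions with class means
#' 194.67 / 155.39 and median/mean skew matched by negative-binomial
#' dispersions.
#'
#' @param n_per_class Records per class.
#' @param dim Embedding dimension.
#' @param separation Distance between the two class centroids before vectors
#'   are renormalized; 0 removes all class signal.
#' @param noise_sd Isotropic noise standard deviation around each centroid.
#' @param word_count_params Per-class list of `c(mean = , size = )`
#'   negative-binomial word-count parameters (`size = Inf` gives constant
#'   counts).
#' @param pcl5_severity Per-class list of `c(p = , sd = )`: each record's 20
#'   items are Binomial(4, p_i) with `qlogis(p_i) ~ N(qlogis(p), sd)`,
#'   inducing the within-respondent item correlation of a severity scale.
#' @param missing_rate Per-item probability of a missing response.
#' @param fraction_below_min Fraction of narratives drawn short (< 30 words)
#'   to exercise the length filter.
#' @param inject_markers If `TRUE`, prepend a class marker token to each
#'   narrative (for scripted prompt-backend mocks).
#' @param seed Integer base seed; every generator draw derives from it.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_per_class = 190L, dim = 1536L, separation = 2,
                             noise_sd = 0.3,
                             word_count_params = list(
                               class1 = c(mean = 194.67, size = 1.7),
                               class0 = c(mean = 155.39, size = 1.0)
                             ),
                             pcl5_severity = list(
                               class1 = c(p = 0.60, sd = 0.4),
                               class0 = c(p = 0.12, sd = 0.4)
                             ),
                             missing_rate = 0.005,
                             fraction_below_min = 0,
                             inject_markers = FALSE,
                             seed = 1L) {
  stopifnot(n_per_class >= 1, dim >= 1, separation >= 0, noise_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            fraction_below_min >= 0, fraction_below_min < 1)
  structure(
    list(n_per_class = as.integer(n_per_class), dim = as.integer(dim),
         separation = separation, noise_sd = noise_sd,
         word_count_params = word_count_params,
         pcl5_severity = pcl5_severity,
         missing_rate = missing_rate,
         fraction_below_min = fraction_below_min,
         inject_markers = isTRUE(inject_markers),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

class_marker_tokens <- c(class0 = "steadybirth", class1 = "stormbirth")

wc_param <- function(cfg, label) {
  cfg$word_count_params[[if (label == 1L) "class1" else "class0"]]
}

sev_param <- function(cfg, label) {
  cfg$pcl5_severity[[if (label == 1L) "class1" else "class0"]]
}

#' Generate class-conditional embedding vectors
#'
#' Places two centroids at distance `separation` along a random unit
#' direction, adds isotropic Gaussian noise (`noise_sd`) per vector, and
#' renormalizes each vector to unit length. Reproducible from `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param labels Integer 0/1 vector, one per vector to generate; defaults to
#'   `n_per_class` of each class.
#' @return List: `vectors` (matrix, rows in `labels` order) and `labels`.
#' @export
generate_embeddings <- function(cfg, labels = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(labels)) labels <- rep(c(0L, 1L), each = cfg$n_per_class)
  stopifnot(all(labels %in% c(0L, 1L)))
  withr::with_seed(cfg$seed + 303L, {
    dir <- stats::rnorm(cfg$dim)
    dir <- dir / sqrt(sum(dir^2))
    centroids <- rbind(`0` = -dir * cfg$separation / 2,
                       `1` = dir * cfg$separation / 2)
    noise <- matrix(stats::rnorm(length(labels) * cfg$dim, sd = cfg$noise_sd),
                    nrow = length(labels))
    v <- centroids[as.character(labels), , drop = FALSE] + noise
    v <- v / sqrt(rowSums(v^2))
    dimnames(v) <- NULL
    list(vectors = v, labels = as.integer(labels))
  })
}

#' Generate class-conditional PCL-5 responses
#'
#' Each record draws an item propensity `p_i` on the logit scale around its
#' class's severity parameter, then 20 Binomial(4, p_i) items; items go
#' missing independently at `missing_rate`. Under the default parameters
#' class-1 totals reach the 31 cutoff with probability at least 0.95.
#'
#' @param cfg A [synthetic_config()].
#' @param classes Integer 0/1 vector of intended classes; defaults to
#'   `n_per_class` of each.
#' @return List: `items` (matrix n x 20, `NA` = missing) and `intended`
#'   (the class each record was drawn from).
#' @export
generate_pcl5 <- function(cfg, classes = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(classes)) classes <- rep(c(0L, 1L), each = cfg$n_per_class)
  stopifnot(all(classes %in% c(0L, 1L)))
  withr::with_seed(cfg$seed + 101L, {
    items <- t(vapply(classes, function(cl) draw_pcl5_items(cfg, cl),
                      numeric(20L)))
    if (cfg$missing_rate > 0) {
      miss <- matrix(stats::runif(length(items)) < cfg$missing_rate,
                     nrow = nrow(items))
      items[miss] <- NA_real_
    }
    list(items = items, intended = as.integer(classes))
  })
}

draw_pcl5_items <- function(cfg, class_label) {
  par <- sev_param(cfg, class_label)
  p_i <- stats::plogis(stats::qlogis(par[["p"]]) +
                         stats::rnorm(1L, sd = par[["sd"]]))
  stats::rbinom(20L, 4L, p_i)
}

# filler vocabulary for template narratives (no attempt at realistic prose)
narrative_vocab <- c(
  "labor", "hospital", "midwife", "nurse", "doctor", "contractions",
  "epidural", "delivery", "baby", "partner", "night", "hours", "room",
  "monitor", "pushing", "breathing", "waiting", "arrived", "finally",
  "suddenly", "quietly", "holding", "crying", "relieved", "exhausted",
  "overwhelmed", "calm", "afraid", "safe", "unexpected"
)

#' Generate template narratives with controlled word counts
#'
#' Word counts are drawn per class from the configured negative-binomial
#' distribution, conditioned to be at least 30 words, except for a
#' `fraction_below_min` subset drawn uniformly in 1-29 words to exercise the
#' length filter. Texts are filler words from a small vocabulary; with
#' `inject_markers` a class marker token is prepended (so scripted prompt
#' backends can key on it).
#'
#' @param cfg A [synthetic_config()].
#' @param classes Integer 0/1 vector; defaults to `n_per_class` of each.
#' @return Character vector of narratives, one per entry of `classes`.
#' @export
generate_narratives <- function(cfg, classes = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(classes)) classes <- rep(c(0L, 1L), each = cfg$n_per_class)
  withr::with_seed(cfg$seed + 202L, {
    n <- length(classes)
    short <- stats::runif(n) < cfg$fraction_below_min
    wc <- integer(n)
    for (i in seq_len(n)) {
      if (short[i]) {
        wc[i] <- sample(1:29, 1L)
      } else {
        par <- wc_param(cfg, classes[i])
        wc[i] <- if (is.infinite(par[["size"]])) {
          max(30L, as.integer(round(par[["mean"]])))
        } else {
          draw_wc_at_least(par[["mean"]], par[["size"]], 30L)
        }
      }
    }
    vapply(seq_len(n), function(i) {
      k <- wc[i]
      words <- sample(narrative_vocab, k, replace = TRUE)
      if (cfg$inject_markers) {
        words[1L] <- class_marker_tokens[[paste0("class", classes[i])]]
      }
      paste(words, collapse = " ")
    }, character(1L))
  })
}

draw_wc_at_least <- function(mean, size, min_wc) {
  for (i in 1:50) {
    w <- stats::rnbinom(1L, mu = mean, size = size)
    if (w >= min_wc) return(as.integer(w))
  }
  as.integer(min_wc)
}

#' Generate a complete synthetic survey
#'
#' Produces everything the pipeline ingests: the survey table (`record_id`,
#' `text`, `pcl5_01`..`pcl5_20`), the labeled record table, and an embedding
#' store keyed by record id. Ground-truth class is defined by the scored
#' PCL-5 total against the cutoff, so labeling always agrees with
#' `assign_class(score_pcl5(items))`; with `force_class = TRUE` (default)
#' items are redrawn until each record's realized class matches its intended
#' class, giving exact class sizes.
#'
#' @param cfg A [synthetic_config()].
#' @param n_class1,n_class0 Records per class; default `cfg$n_per_class`.
#' @param cutoff PCL-5 cutoff; default 31.
#' @param force_class Redraw items until realized class matches intended.
#' @return List: `survey` (raw table), `records` (labeled via
#'   [label_records()]), `store` (embedding store), `intended` (class each
#'   record was drawn from).
#' @export
generate_survey <- function(cfg, n_class1 = cfg$n_per_class,
                            n_class0 = cfg$n_per_class, cutoff = 31L,
                            force_class = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  classes <- rep(c(1L, 0L), times = c(n_class1, n_class0))
  n <- length(classes)
  ids <- sprintf("R%05d", seq_len(n))

  pcl <- generate_pcl5(cfg, classes)
  items <- pcl$items
  if (force_class) {
    items <- withr::with_seed(cfg$seed + 404L, {
      for (i in seq_len(n)) {
        tries <- 0L
        while (assign_class(score_pcl5(items[i, ]), cutoff) != classes[i] &&
               tries < 100L) {
          row <- draw_pcl5_items(cfg, classes[i])
          if (cfg$missing_rate > 0) {
            row[stats::runif(20L) < cfg$missing_rate] <- NA_real_
          }
          items[i, ] <- row
          tries <- tries + 1L
        }
        if (assign_class(score_pcl5(items[i, ]), cutoff) != classes[i]) {
          # deterministic fallback: minimal response pattern on the right side
          items[i, ] <- if (classes[i] == 1L) rep(2, 20) else rep(0, 20)
        }
      }
      items
    })
  }
  totals <- vapply(seq_len(n), function(i) score_pcl5(items[i, ]), integer(1L))
  realized <- assign_class(totals, cutoff)

  texts <- generate_narratives(cfg, realized)
  emb <- generate_embeddings(cfg, realized)

  survey <- data.frame(record_id = ids, text = texts,
                       stringsAsFactors = FALSE)
  item_df <- as.data.frame(items)
  names(item_df) <- pcl5_cols()
  survey <- cbind(survey, item_df)

  store <- embedding_store()
  hashes <- text_hash(texts)
  for (i in seq_len(n)) store_set(store, ids[i], emb$vectors[i, ], hashes[i])

  records <- suppressMessages(label_records(survey, cutoff = cutoff))
  list(survey = survey, records = records, store = store,
       intended = as.integer(classes))
}
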