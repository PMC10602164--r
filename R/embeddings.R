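# Embedding backend contract, deterministic offline backend, and cache.
#
# A backend maps one narrative to a fixed-length numeric vector. Downstream
# stages never hard-code the dimension; they read it from the backend (or the
# store it filled), so providers with other dimensions plug in unchanged.

#' Construct an embedding backend
#'
#' A backend bundles a name, an output dimension, and a function mapping a
#' single text to a numeric vector of that dimension. Remote providers are
#' wrapped the same way; tests use offline or mock backends so nothing
#' touches a network.
#'
#' @param name Identifier for the backend.
#' @param dim Output dimension (positive integer).
#' @param embed_fn Function taking one character string and returning a
#'   numeric vector of length `dim`.
#' @param deterministic Logical; `TRUE` if the same text always yields the
#'   same vector.
#' @return An `embedding_backend` object.
#' @export
embedding_backend <- function(name, dim, embed_fn, deterministic = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(dim), length(dim) == 1L, dim >= 1,
            is.function(embed_fn))
  structure(
    list(name = name, dim = as.integer(dim), embed_fn = embed_fn,
         deterministic = isTRUE(deterministic)),
    class = "embedding_backend"
  )
}

#' Deterministic offline embedding backend
#'
#' Maps each text to a pseudo-random unit vector whose RNG seed is derived
#' from a stable hash of the text's UTF-8 bytes plus `seed`. The same text
#' therefore yields the same vector in any process. Vectors carry no semantic
#' signal; this backend exists to exercise the pipeline's plumbing with the
#' dimension contract of the production provider (1536 by default).
#'
#' @param dim Output dimension; default 1536.
#' @param seed Integer offset mixed into every per-text seed.
#' @return An `embedding_backend`.
#' @export
offline_backend <- function(dim = 1536L, seed = 0L) {
  dim <- as.integer(dim)
  seed <- as.integer(seed)
  embedding_backend(
    name = sprintf("offline-hash-%d", dim),
    dim = dim,
    embed_fn = function(text) {
      h <- text_hash(text)
      withr::with_seed((seed + h) %% 2147483647L, {
        v <- stats::rnorm(dim)
        v / sqrt(sum(v^2))
      })
    },
    deterministic = TRUE
  )
}

#' Embed a sequence of texts
#'
#' Applies the backend to each text, preserving order. Any backend failure
#' aborts the whole call with the failing text index; there is no partial
#' silent output.
#'
#' @param texts Nonempty character vector.
#' @param backend An `embedding_backend`.
#' @return Numeric matrix, one row per text, `backend$dim` columns.
#' @export
embed_texts <- function(texts, backend) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (!is.character(texts) || length(texts) == 0L) {
    stop("texts must be a nonempty character vector")
  }
  out <- matrix(NA_real_, nrow = length(texts), ncol = backend$dim)
  for (i in seq_along(texts)) {
    v <- tryCatch(backend$embed_fn(texts[[i]]), error = function(e) {
      stop("embedding backend '", backend$name, "' failed at text index ", i,
           ": ", conditionMessage(e), call. = FALSE)
    })
    if (length(v) != backend$dim || any(!is.finite(v))) {
      stop("backend '", backend$name, "' returned an invalid vector at text index ",
           i, " (length ", length(v), ", expected ", backend$dim, ")")
    }
    out[i, ] <- v
  }
  out
}

#' Create an empty embedding store
#'
#' A mutable keyed store mapping record ids to embedding vectors. Each entry
#' remembers a hash of the source text so an id reused with different text is
#' caught as an error.
#'
#' @return An `embedding_store` object.
#' @export
embedding_store <- function() {
  structure(
    list(vectors = new.env(parent = emptyenv()),
         hashes = new.env(parent = emptyenv()),
         meta = new.env(parent = emptyenv())),
    class = "embedding_store"
  )
}

#' @export
print.embedding_store <- function(x, ...) {
  n <- length(ls(x$vectors))
  dim <- get0("dim", envir = x$meta, ifnotfound = NA_integer_)
  cat("embedding_store: ", n, " vector(s), dim ", dim, "\n", sep = "")
  invisible(x)
}

store_ids <- function(store) ls(store$vectors)

store_set <- function(store, id, vector, hash = NA_integer_) {
  assign(id, vector, envir = store$vectors)
  assign(id, hash, envir = store$hashes)
  if (is.null(get0("dim", envir = store$meta))) {
    assign("dim", length(vector), envir = store$meta)
  }
  invisible(store)
}

#' Fetch vectors for a set of ids
#'
#' @param store An `embedding_store`.
#' @param ids Character vector of record ids.
#' @return Numeric matrix with rownames `ids`.
#' @export
store_vectors <- function(store, ids) {
  stopifnot(inherits(store, "embedding_store"))
  missing_ids <- ids[!vapply(ids, exists, logical(1L), envir = store$vectors,
                             inherits = FALSE)]
  if (length(missing_ids)) {
    stop("no embedding cached for record id(s): ",
         paste(missing_ids, collapse = ", "))
  }
  out <- t(vapply(ids, get, numeric(get("dim", envir = store$meta)),
                  envir = store$vectors))
  rownames(out) <- ids
  out
}

#' Cache embeddings for records
#'
#' Embeds each record's text and stores the vector under its id. Ids already
#' in the store are skipped (after checking the stored text hash matches), so
#' re-running is a no-op.
#'
#' @param records Data frame with `record_id` and `text` columns, ids unique.
#' @param backend An `embedding_backend`.
#' @param store An `embedding_store` (mutated in place).
#' @return The store, invisibly, with attribute `n_new` = vectors computed.
#' @export
cache_embeddings <- function(records, backend, store) {
  stopifnot(inherits(store, "embedding_store"))
  ids <- as.character(records$record_id)
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate record_id values: ", paste(dups, collapse = ", "))
  }
  hashes <- text_hash(records$text)
  n_new <- 0L
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    if (exists(id, envir = store$vectors, inherits = FALSE)) {
      old <- get(id, envir = store$hashes)
      if (!is.na(old) && old != hashes[[i]]) {
        stop("record id '", id, "' already cached with different text")
      }
      next
    }
    v <- embed_texts(records$text[[i]], backend)[1L, ]
    store_set(store, id, v, hashes[[i]])
    n_new <- n_new + 1L
  }
  attr(store, "n_new") <- n_new
  invisible(store)
}

store_format_version <- "cbscreen-embeddings-v1"

#' Write an embedding store to a TSV file
#'
#' Plain-text format: a version header line, then one row per id with the
#' vector values tab-separated.
#'
#' @param store An `embedding_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_store <- function(store, path) {
  ids <- sort(store_ids(store))
  if (!length(ids)) stop("store is empty")
  m <- store_vectors(store, ids)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#%s dim=%d", store_format_version, ncol(m)), con)
  utils::write.table(
    data.frame(record_id = ids, m, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read an embedding store from a TSV file written by [save_store()]
#'
#' @param path File path.
#' @return An `embedding_store`.
#' @export
load_store <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!startsWith(header, paste0("#", store_format_version))) {
    stop("unsupported embedding store format: expected '",
         store_format_version, "', file says '", sub("^#", "", header), "'")
  }
  df <- utils::read.table(path, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE, comment.char = "")
  store <- embedding_store()
  for (i in seq_len(nrow(df))) {
    store_set(store, as.character(df[i, 1L]), as.numeric(df[i, -1L]))
  }
  store
}
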