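# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count words in a narrative
#'
#' Words are maximal runs of non-whitespace characters after trimming leading
#' and trailing whitespace; an empty or all-whitespace text has zero words.
#' This is the tokenizer used for the minimum-length narrative filter.
#'
#' @param text Character vector of narratives.
#' @return Integer vector of word counts.
#' @export
#' @examples
#' count_words(c("a short story", "", "  one  two  "))
count_words <- function(text) {
  stopifnot(is.character(text))
  trimmed <- trimws(text)
  n <- integer(length(text))
  has <- nzchar(trimmed)
  n[has] <- lengths(strsplit(trimmed[has], "\\s+"))
  n
}

# Stable 31-bit polynomial hash of the UTF-8 bytes of each string.
# Used to derive per-text RNG seeds; must be identical across processes.
text_hash <- function(x) {
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
  }, integer(1L), USE.NAMES = FALSE)
}

# Condition constructor for strict-parse failures (prompt module).
parse_error <- function(msg, raw) {
  structure(
    class = c("cbscreen_parse_error", "error", "condition"),
    list(message = msg, call = NULL, raw = raw)
  )
}
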