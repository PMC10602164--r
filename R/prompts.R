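# Zero- and few-shot prompt classification with a temperature-0 chat-backend
# contract, strict 0/1 response parsing, and a mock backend for offline use.
#
# Templates live as text assets under inst/extdata/prompts/ with `{text}` and
# `{examples}` placeholder markers.

example_slot_template <- "<Text>: “{etext}” <Label>: {elabel}"

#' Load a prompt template
#'
#' @param mode `"zero_shot"` (no labeled examples) or `"few_shot"` (labeled
#'   examples embedded in the prompt).
#' @return A `prompt_template` object carrying the template text.
#' @export
prompt_template <- function(mode = c("zero_shot", "few_shot")) {
  mode <- match.arg(mode)
  path <- system.file("extdata", "prompts", paste0(mode, ".txt"),
                      package = "cbscreen", mustWork = TRUE)
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  structure(list(mode = mode, text = text), class = "prompt_template")
}

#' Render a prompt for one narrative
#'
#' Substitutes the narrative (and, in few-shot mode, the labeled examples)
#' into the template verbatim. Zero-shot mode forbids examples; few-shot
#' requires at least two.
#'
#' @param template A [prompt_template()].
#' @param narrative The narrative text to classify.
#' @param examples For few-shot mode, a list of `list(text = , label = )`
#'   entries (labels 0/1); `NULL` otherwise.
#' @return The rendered prompt string.
#' @export
render_prompt <- function(template, narrative, examples = NULL) {
  stopifnot(inherits(template, "prompt_template"),
            is.character(narrative), length(narrative) == 1L)
  if (template$mode == "zero_shot") {
    if (!is.null(examples) && length(examples)) {
      stop("zero-shot prompts take no labeled examples")
    }
    return(gsub("{text}", narrative, template$text, fixed = TRUE))
  }
  if (is.null(examples) || length(examples) < 2L) {
    stop("few-shot prompts require at least 2 labeled examples")
  }
  blocks <- vapply(examples, function(ex) {
    if (is.null(ex$text) || is.null(ex$label) || !ex$label %in% c(0, 1)) {
      stop("each example needs $text and a 0/1 $label")
    }
    out <- gsub("{etext}", ex$text, example_slot_template, fixed = TRUE)
    gsub("{elabel}", as.integer(ex$label), out, fixed = TRUE)
  }, character(1L))
  out <- gsub("{examples}", paste(blocks, collapse = " ### "),
              template$text, fixed = TRUE)
  gsub("{text}", narrative, out, fixed = TRUE)
}

#' Strictly parse a chat response as a 0/1 label
#'
#' Accepts only a bare `"0"` or `"1"` after trimming whitespace and
#' surrounding quote characters; anything else raises a parse error carrying
#' the raw text. No digits are salvaged from verbose answers: the prompt
#' forbids them, and silent coercion would corrupt evaluation.
#'
#' @param raw Raw response string.
#' @return `0L` or `1L`.
#' @export
parse_response <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop(parse_error("response is not a single string", raw))
  }
  t <- trimws(raw)
  t <- gsub("^[\"'‘’“”]+|[\"'‘’“”]+$",
            "", t)
  t <- trimws(t)
  if (identical(t, "1")) return(1L)
  if (identical(t, "0")) return(0L)
  stop(parse_error(sprintf("response is not a bare '0' or '1': %s",
                           deparse(substr(raw, 1L, 80L))), raw))
}

#' Construct a mock chat backend
#'
#' Wraps a pure responder function as a temperature-0 chat backend, so prompt
#' classification is testable with no external service. The contract requires
#' determinism: the same prompt must always yield the same response.
#'
#' @param responder Function taking the rendered prompt string and returning
#'   the raw response string.
#' @param name Backend identifier.
#' @param max_context_tokens Advisory context budget; default 16384.
#' @return A `chat_backend` object.
#' @export
mock_chat_backend <- function(responder, name = "mock",
                              max_context_tokens = 16384L) {
  stopifnot(is.function(responder))
  structure(
    list(name = name, temperature = 0, max_context_tokens = max_context_tokens,
         complete = responder),
    class = "chat_backend"
  )
}

#' Classify records with a prompt template and chat backend
#'
#' Renders one prompt per record, queries the backend (retrying transient
#' backend errors), and strictly parses each response. Records whose response
#' fails to parse (or whose backend call keeps failing) are excluded from the
#' predictions and listed in the failure log, never defaulted to a class.
#'
#' @param records Data frame with `record_id` and `text` columns.
#' @param template A [prompt_template()].
#' @param backend A `chat_backend` (see [mock_chat_backend()]).
#' @param examples Labeled examples for few-shot mode; `NULL` for zero-shot.
#' @param retries Attempts per record on backend error; default 2.
#' @return List with `predictions` (data frame `record_id`, `label`) and
#'   `failures` (data frame `record_id`, `reason`).
#' @export
classify_with_prompts <- function(records, template, backend, examples = NULL,
                                  retries = 2L) {
  stopifnot(inherits(backend, "chat_backend"))
  preds <- list()
  fails <- list()
  for (i in seq_len(nrow(records))) {
    id <- as.character(records$record_id[[i]])
    prompt <- render_prompt(template, records$text[[i]], examples)
    raw <- NULL
    last_err <- NULL
    for (attempt in seq_len(max(1L, retries))) {
      raw <- tryCatch(backend$complete(prompt), error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
      if (!is.null(raw)) break
    }
    if (is.null(raw)) {
      fails[[length(fails) + 1L]] <-
        data.frame(record_id = id,
                   reason = paste("backend error:", last_err),
                   stringsAsFactors = FALSE)
      next
    }
    label <- tryCatch(parse_response(raw), cbscreen_parse_error = function(e) {
      fails[[length(fails) + 1L]] <<-
        data.frame(record_id = id,
                   reason = paste("parse error:", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      NULL
    })
    if (!is.null(label)) {
      preds[[length(preds) + 1L]] <-
        data.frame(record_id = id, label = label, stringsAsFactors = FALSE)
    }
  }
  empty_pred <- data.frame(record_id = character(), label = integer(),
                           stringsAsFactors = FALSE)
  empty_fail <- data.frame(record_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  list(
    predictions = if (length(preds)) do.call(rbind, preds) else empty_pred,
    failures = if (length(fails)) do.call(rbind, fails) else empty_fail
  )
}

#' Pick few-shot examples from labeled records
#'
#' Selects one class-1 and one class-0 narrative (in that order) uniformly at
#' random, reproducibly from `seed`.
#'
#' @param records Labeled data frame with `text` and `label` columns.
#' @param seed Integer RNG seed.
#' @return A two-element list of `list(text = , label = )` entries.
#' @export
select_prompt_examples <- function(records, seed = 1L) {
  idx1 <- which(records$label == 1L)
  idx0 <- which(records$label == 0L)
  if (!length(idx1) || !length(idx0)) {
    stop("need at least one record of each class")
  }
  picks <- withr::with_seed(as.integer(seed), {
    c(if (length(idx1) == 1L) idx1 else sample(idx1, 1L),
      if (length(idx0) == 1L) idx0 else sample(idx0, 1L))
  })
  list(list(text = records$text[[picks[1L]]], label = 1L),
       list(text = records$text[[picks[2L]]], label = 0L))
}
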