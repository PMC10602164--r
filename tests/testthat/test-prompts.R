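zero_expected <- paste0(
  "You are a psychiatrist specialized in diagnosing and treating ",
  "Post-Traumatic Stress Disorder (PTSD). I will provide you with a ",
  "narrative written by a woman describing her birth experience. Your task ",
  "is to decide whether this woman is at high risk of PTSD (Label 1) or ",
  "lower risk of PTSD (Label 0). Do not write anything but ‘1’ or ",
  "‘0’. ### <Text>: “X”"
)

few_expected <- paste0(
  "You are a psychiatrist specialized in diagnosing and treating ",
  "Post-Traumatic Stress Disorder (PTSD). I will provide you with a ",
  "narrative written by a woman describing her birth experience. Your task ",
  "is to decide whether this woman is at high risk of PTSD (Label 1), or ",
  "lower risk of PTSD (Label 0). Do not write anything but ‘1’ or ",
  "‘0’. Here are a few examples of text with their associated ",
  "class labels as ‘1’ (PTSD) or ‘0’ (No-PTSD). ",
  "<Text>: “S” <Label>: 1 ### <Text>: “H” <Label>: 0 ",
  "### <Text>: “X”"
)

test_that("rendered prompts match the published templates byte for byte", {
  zs <- prompt_template("zero_shot")
  expect_identical(render_prompt(zs, "X"), zero_expected)
  fs <- prompt_template("few_shot")
  ex <- list(list(text = "S", label = 1L), list(text = "H", label = 0L))
  expect_identical(render_prompt(fs, "X", ex), few_expected)
})

test_that("the narrative is inserted verbatim inside the quoted slot", {
  zs <- prompt_template("zero_shot")
  narrative <- "It was a long night; the moniters beeped, then (finally) calm."
  out <- render_prompt(zs, narrative)
  expect_true(grepl(paste0("“", narrative, "”"), out, fixed = TRUE))
})

test_that("example slots are enforced per mode, up to four examples", {
  zs <- prompt_template("zero_shot")
  fs <- prompt_template("few_shot")
  ex2 <- list(list(text = "S", label = 1L), list(text = "H", label = 0L))
  expect_error(render_prompt(zs, "X", ex2), "no labeled examples")
  expect_error(render_prompt(fs, "X"), "at least 2")
  expect_error(render_prompt(fs, "X", ex2[1]), "at least 2")
  ex4 <- c(ex2, list(list(text = "S2", label = 1L),
                     list(text = "H2", label = 0L)))
  out4 <- render_prompt(fs, "X", ex4)
  expect_identical(lengths(regmatches(out4, gregexpr("<Label>:", out4))), 4L)
  # zero-shot rendering contains no labeled-example block
  expect_false(grepl("<Label>:", render_prompt(zs, "X")))
})

test_that("responses parse strictly as a bare 0 or 1", {
  expect_identical(parse_response("1"), 1L)
  expect_identical(parse_response(" 0\n"), 0L)
  expect_identical(parse_response("'1'"), 1L)
  expect_identical(parse_response("“0”"), 0L)
  err <- tryCatch(parse_response("Label: 1, because the narrative..."),
                  cbscreen_parse_error = identity)
  expect_s3_class(err, "cbscreen_parse_error")
  expect_match(err$raw, "because")
  expect_error(parse_response("10"), class = "cbscreen_parse_error")
  expect_error(parse_response(""), class = "cbscreen_parse_error")
  expect_error(parse_response("yes"), class = "cbscreen_parse_error")
})

test_that("scripted mock backends classify records deterministically", {
  sv <- generate_survey(synthetic_config(n_per_class = 10, dim = 4,
                                         inject_markers = TRUE, seed = 2))
  zs <- prompt_template("zero_shot")
  # responder keys on the class-1 marker token inside the quoted narrative
  backend <- mock_chat_backend(function(prompt) {
    if (grepl("stormbirth", prompt)) "1" else "0"
  })
  out <- classify_with_prompts(sv$records, zs, backend)
  expect_identical(nrow(out$failures), 0L)
  truth <- sv$records$label[match(out$predictions$record_id,
                                  sv$records$record_id)]
  expect_identical(out$predictions$label, truth)
  # temperature-0 contract: identical output on a second run
  out2 <- classify_with_prompts(sv$records, zs, backend)
  expect_identical(out, out2)
})

test_that("unparseable responses are logged, not coerced", {
  recs <- data.frame(record_id = c("a", "b", "c"),
                     text = c("fine", "garbled", "fine too"),
                     stringsAsFactors = FALSE)
  zs <- prompt_template("zero_shot")
  backend <- mock_chat_backend(function(prompt) {
    if (grepl("garbled", prompt)) "I think the label is 1" else "0"
  })
  out <- classify_with_prompts(recs, zs, backend)
  expect_identical(out$predictions$record_id, c("a", "c"))
  expect_identical(out$failures$record_id, "b")
  expect_match(out$failures$reason, "parse error")
})

test_that("backend errors are retried and then logged", {
  attempts <- 0L
  flaky <- mock_chat_backend(function(prompt) {
    attempts <<- attempts + 1L
    if (attempts == 1L) stop("transient outage")
    "1"
  })
  recs <- data.frame(record_id = "a", text = "x", stringsAsFactors = FALSE)
  zs <- prompt_template("zero_shot")
  out <- classify_with_prompts(recs, zs, flaky, retries = 2)
  expect_identical(out$predictions$label, 1L)
  dead <- mock_chat_backend(function(prompt) stop("down"))
  out2 <- classify_with_prompts(recs, zs, dead, retries = 2)
  expect_identical(nrow(out2$predictions), 0L)
  expect_match(out2$failures$reason, "backend error")
})

test_that("prompt-model hard labels feed the stepped-ROC evaluation", {
  # a mock constructed to answer 1 for 6 of 25 positives (sensitivity 0.24)
  # and 1 for 1 of 25 negatives (specificity 0.96)
  truth <- c(rep(1, 25), rep(0, 25))
  answers <- c(rep("1", 6), rep("0", 19), rep("1", 1), rep("0", 24))
  recs <- data.frame(record_id = sprintf("r%02d", 1:50),
                     text = sprintf("narrative number %02d", 1:50),
                     stringsAsFactors = FALSE)
  lookup <- setNames(answers, recs$text)
  backend <- mock_chat_backend(function(prompt) {
    hit <- vapply(recs$text, function(t) grepl(t, prompt, fixed = TRUE),
                  logical(1))
    lookup[[which(hit)[1]]]
  })
  out <- classify_with_prompts(recs, prompt_template("zero_shot"), backend)
  m <- confusion_metrics(truth, out$predictions$label)
  expect_equal(m$sensitivity, 0.24)
  expect_equal(m$specificity, 0.96)
  expect_equal(binary_auc(m$sensitivity, m$specificity), 0.60)
})

test_that("few-shot example selection picks one narrative per class", {
  sv <- generate_survey(synthetic_config(n_per_class = 6, dim = 4, seed = 3))
  ex <- select_prompt_examples(sv$records, seed = 1)
  expect_identical(vapply(ex, `[[`, integer(1), "label"), c(1L, 0L))
  expect_identical(select_prompt_examples(sv$records, seed = 1), ex)
  texts1 <- sv$records$text[sv$records$label == 1L]
  expect_true(ex[[1]]$text %in% texts1)
})
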