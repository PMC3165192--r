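test_that("a leftward subject link learns the S- substance rule", {
  g <- parse_graph("fig4", c("tolfenamic", "acid", "induces", "degradation"),
                   data.frame(left = c(0, 1, 2), right = c(1, 2, 3),
                              full_label = c("AN", "Ss", "Os")))
  ts <- tagged_sentence(g, 2L, data.frame(start = 0L, end = 1L,
                                          placeholder = "@SUBSTANCE"))
  rules <- learn_rules(ts)
  expect_length(rules, 1)
  expect_equal(format(rules[[1]]), "induc :: S- @SUBSTANCE")
})

test_that("two-edge paths record the intermediate node stem", {
  # effect --M--> "of" --J--> concept
  g <- parse_graph("s", c("inducer", "of", "apoptosis"),
                   data.frame(left = c(0, 1), right = c(1, 2),
                              full_label = c("Mp", "Js")))
  ts <- tagged_sentence(g, 0L, data.frame(start = 2L, end = 2L,
                                          placeholder = "@SYMPTOM"))
  rules <- learn_rules(ts)
  expect_equal(format(rules[[1]]), "induc :: M+ (of) J+ @SYMPTOM")
  expect_equal(rules[[1]]$steps$node_stem, c("of", NA))
})

test_that("an unreachable concept is a learning error", {
  g <- parse_graph("s", c("induces", "x", "orphan"),
                   data.frame(left = 0, right = 1, full_label = "Os"))
  ts <- tagged_sentence(g, 0L, data.frame(start = 2L, end = 2L,
                                          placeholder = "@DISEASE"))
  expect_error(learn_rules(ts), "not reachable")
})

test_that("rulebooks round-trip bit-identically and report malformed lines", {
  fx <- fixture_svo_pp()
  extra <- extraction_rule(
    "reduc",
    tibble::tibble(reduced_label = c("MV", "J"), direction = c("+", "+"),
                   node_stem = c("of", NA)),
    "@SYMPTOM"
  )
  rules <- c(fx$rules, list(extra))
  f <- withr::local_tempfile(fileext = ".rules")
  write_rulebook(rules, f)
  back <- read_rulebook(f)
  expect_setequal(vapply(back, format, character(1)),
                  unique(vapply(rules, format, character(1))))
  f2 <- withr::local_tempfile(fileext = ".rules")
  write_rulebook(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # empty rule set -> empty file
  fe <- withr::local_tempfile(fileext = ".rules")
  write_rulebook(list(), fe)
  expect_length(readLines(fe), 0)

  fbad <- withr::local_tempfile(fileext = ".rules")
  writeLines(c("induc :: S- @SUBSTANCE", "not a rule"), fbad)
  expect_error(read_rulebook(fbad), "line 2")
})

test_that("rule matching respects direction and finds all bindings", {
  f <- withr::local_tempfile()
  writeLines("induc :: S- @SUBSTANCE", f)
  rule <- read_rulebook(f)[[1]]

  g <- parse_graph("fig4", c("tolfenamic", "acid", "induces", "degradation"),
                   data.frame(left = c(0, 1, 2), right = c(1, 2, 3),
                              full_label = c("AN", "Ss", "Os")))
  hits <- match_rule(g, 2L, rule)
  expect_length(hits, 1)
  expect_equal(hits[[1]], c(0L, 1L))  # expanded span "tolfenamic acid"

  # rightward-only S link cannot satisfy S-
  g_right <- parse_graph("r", c("induces", "acid"),
                         data.frame(left = 0, right = 1, full_label = "Ss"))
  expect_length(match_rule(g_right, 0L, rule), 0)

  # two leftward S links -> two bindings
  g_two <- parse_graph("t", c("aspirin", "fisetin", "induces"),
                       data.frame(left = c(0, 1), right = c(2, 2),
                                  full_label = c("Sp", "Ss")))
  expect_length(match_rule(g_two, 2L, rule), 2)
})

test_that("the rulebook aggregates slot bindings and dedupes", {
  g <- toy_linker("Tolfenamic acid induces Sp protein degradation in several cancer cell lines")
  ts <- tagged_sentence(g, 2L, tibble::tibble(
    start = c(0L, 3L, 8L), end = c(1L, 5L, 10L),
    placeholder = c("@SUBSTANCE", "@SYMPTOM", "@BODYPART")
  ))
  rules <- learn_rules(ts)
  m <- list(pmid = "19258429", sentence = "s", effect_surface = "induces",
            effect_stem = "induc")
  raw <- apply_rulebook(g, m, rules)
  expect_equal(raw$slots[["@SUBSTANCE"]], "Tolfenamic acid")
  expect_equal(raw$slots[["@SYMPTOM"]], "Sp protein degradation")
  expect_equal(raw$slots[["@BODYPART"]], "cancer cell lines")

  # duplicated rules do not duplicate slot entries
  raw2 <- apply_rulebook(g, m, c(rules, rules))
  expect_equal(raw2$slots, raw$slots)

  # no rule fires -> NULL (rule exists for the stem but route incomplete)
  g_min <- parse_graph("m", c("induces", "apoptosis"),
                       data.frame(left = 0, right = 1, full_label = "Os"))
  sub_rule <- rules[[which(vapply(rules, \(r) r$placeholder, character(1)) == "@SUBSTANCE")]]
  expect_null(apply_rulebook(g_min, m, list(sub_rule)))
})

test_that("learn-then-match closure re-binds exactly the tagged spans", {
  sentences <- list(
    fixture_svo_pp("Fisetin induces apoptosis in HCT-116 cells"),
    fixture_svo_pp("Wogonin induces apoptosis in malignant T cells")
  )
  for (fx in sentences) {
    raw <- apply_rulebook(
      fx$graph,
      list(pmid = "p", sentence = "s", effect_surface = "induces",
           effect_stem = "induc"),
      fx$rules
    )
    tagged_texts <- vapply(seq_len(nrow(fx$tagged$tags)), function(i) {
      paste(fx$graph$tokens$surface[(fx$tagged$tags$start[i] + 1):(fx$tagged$tags$end[i] + 1)],
            collapse = " ")
    }, character(1))
    expect_setequal(unlist(raw$slots), tagged_texts)
  }
})

test_that("learned rule paths are shortest paths", {
  # direct S edge plus a longer detour: learning must take the 1-step path
  g <- parse_graph("s", c("acid", "induces", "quickly"),
                   data.frame(left = c(0, 0, 1), right = c(1, 2, 2),
                              full_label = c("Ss", "Xa", "MVa")))
  ts <- tagged_sentence(g, 1L, data.frame(start = 0L, end = 0L,
                                          placeholder = "@SUBSTANCE"))
  rules <- learn_rules(ts)
  expect_equal(nrow(rules[[1]]$steps), 1)
  expect_equal(format(rules[[1]]), "induc :: S- @SUBSTANCE")
})
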