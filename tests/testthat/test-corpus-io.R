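test_that("jsonl and csv readers load records and skip bad timestamps", {
  df <- tinyTweetDf()
  jl <- tempfile(fileext = ".jsonl")
  writeTweets(df, jl, format = "jsonl")
  got <- readTweets(jl, format = "jsonl")
  expect_equal(nrow(got), 5)
  expect_equal(got$id, df$id)
  expect_equal(got$text, df$text)
  expect_equal(got$timestamp, df$timestamp)
  expect_equal(attr(got, "loadReport")$skipped, 0L)

  # csv with one unparseable timestamp among 5 rows
  csv <- tempfile(fileext = ".csv")
  bad <- df
  bad$timestamp <- format(bad$timestamp, "%Y-%m-%d %H:%M:%S")
  bad$timestamp[3] <- "not a time"
  write.csv(bad[, c("id", "text", "timestamp", "location", "label")],
            csv, row.names = FALSE)
  got2 <- readTweets(csv, format = "csv")
  expect_equal(nrow(got2), 4)
  expect_equal(attr(got2, "loadReport")$skipped, 1L)
  expect_false("t3" %in% got2$id)
})

test_that("reader errors on a missing mapped column, empty file is empty", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1, b = 2), csv, row.names = FALSE)
  expect_error(readTweets(csv, format = "csv"), "mapped column")

  empty <- tempfile(fileext = ".jsonl")
  file.create(empty)
  got <- readTweets(empty, format = "jsonl")
  expect_equal(nrow(got), 0)
  expect_equal(attr(got, "loadReport")$read, 0L)
})

test_that("preprocessing follows the normalisation rules", {
  expect_equal(preprocessText("Stay HOME!!! https://t.co/x")[[1]],
               c("stay", "home", "xurl"))
  expect_equal(preprocessText("")[[1]], character())
  expect_equal(preprocessText("the and of")[[1]], character())
  # repeated characters collapse, mentions and RT marker vanish
  expect_equal(preprocessText("RT @someone: soooo happy")[[1]],
               c("soo", "happi"))
  # URL replacement happens before punctuation stripping
  expect_true("xurl" %in% preprocessText("look: http://ex.com/a?b=1.")[[1]])
})

test_that("preprocessing is idempotent on its own output", {
  texts <- c(tinyTweetDf()$text,
             "Running quickly!!! towards the #finish line",
             "ponies and caresses, motoring hopefully")
  for (tx in texts) {
    once <- preprocessText(tx)[[1]]
    twice <- preprocessText(paste(once, collapse = " "))[[1]]
    expect_equal(twice, once, info = tx)
  }
})

test_that("vocabulary respects frequency threshold, exclusion and order", {
  docs <- list(c("a", "a", "b"), c("a", "a", "a"), c("b", "covid19"))
  v <- buildVocabulary(docs, minCount = 2, exclude = character())
  expect_equal(unname(v[1]), "a")                   # 5 occurrences first
  expect_true(all(c("a", "b") %in% v))
  expect_equal(buildVocabulary(docs, minCount = 6, exclude = character()),
               character(), ignore_attr = TRUE)
  v2 <- buildVocabulary(docs, minCount = 1)         # default exclusions
  expect_false("covid19" %in% v2)
  expect_equal(buildVocabulary(list(), minCount = 1), character(),
               ignore_attr = TRUE)
  # ties broken lexicographically
  v3 <- buildVocabulary(list(c("z", "y")), minCount = 1,
                        exclude = character())
  expect_equal(as.character(v3), c("y", "z"))
})

test_that("collection keywords never enter a default vocabulary", {
  docs <- preprocessText(c("covid19 everywhere coronavirus covid",
                           "covid-19 covid_19 coronaoutbreak news"))
  v <- buildVocabulary(docs, minCount = 1)
  expect_length(intersect(v, covidKeywords()), 0)
})

test_that("vectorisation counts in-vocabulary tokens and ignores OOV", {
  vocab <- c("a", "b")
  bow <- bowCorpus(list(c("a", "a", "b"), "z"), vocab)
  m <- as.matrix(counts(bow))
  expect_equal(unname(m[1, ]), c(2, 1))
  expect_equal(unname(m[2, ]), c(0, 0))
  expect_equal(vocabulary(bow), vocab)
  expect_equal(docIds(bow), c("doc1", "doc2"))
})

test_that("column sums of the bow equal the corpus term-frequency table", {
  set.seed(9)
  docs <- replicate(30, sample(letters[1:6], sample(2:8, 1), replace = TRUE),
                    simplify = FALSE)
  vocab <- buildVocabulary(docs, minCount = 1, exclude = character())
  bow <- bowCorpus(docs, vocab)
  freqs <- table(unlist(docs))
  expect_equal(as.numeric(Matrix::colSums(counts(bow))),
               as.numeric(freqs[vocabulary(bow)]))
  # row sums equal per-document in-vocab token counts
  expect_equal(as.numeric(Matrix::rowSums(counts(bow))),
               vapply(docs, function(d) sum(d %in% vocab), numeric(1)))
})

test_that("field maps load from key=value config files and rename columns", {
  fm <- tempfile()
  writeLines(c("# mapping", "id=tid", "text=body", "timestamp=when"), fm)
  map <- readFieldMap(fm)
  expect_equal(map[["text"]], "body")
  jl <- tempfile(fileext = ".jsonl")
  writeLines(c('{"tid":"a1","body":"hello world","when":"2020-03-01 10:00"}',
               '{"tid":"a2","body":"second","when":"2020-03-02 11:30"}'), jl)
  got <- readTweets(jl, format = "jsonl", fieldMap = map)
  expect_equal(got$id, c("a1", "a2"))
  expect_equal(got$text, c("hello world", "second"))
  writeLines("nonsense line", fm)
  expect_error(readFieldMap(fm), "malformed")
})

test_that("location mapping hits the gazetteer and falls back to oth", {
  expect_equal(mapLocation(c("Sydney", "new south wales", "Australia",
                             "mars", "", NA)),
               c("syd", "nsw", "au", "oth", "oth", "oth"))
})

test_that("the Porter stemmer matches canonical examples", {
  pairs <- c(caresses = "caress", ponies = "poni", cats = "cat",
             feed = "feed", agreed = "agre", plastered = "plaster",
             motoring = "motor", hopping = "hop", falling = "fall",
             filing = "file", happy = "happi", relational = "relat",
             conditional = "condit", rational = "ration",
             digitizer = "digit", operator = "oper", feudalism = "feudal",
             decisiveness = "decis", hopefulness = "hope",
             formaliti = "formal", triplicate = "triplic",
             formative = "form", formalize = "formal",
             electriciti = "electr", electrical = "electr",
             hopeful = "hope", goodness = "good", revival = "reviv",
             allowance = "allow", inference = "infer", airliner = "airlin",
             adjustable = "adjust", defensible = "defens",
             replacement = "replac", adjustment = "adjust",
             dependent = "depend", adoption = "adopt",
             communism = "commun", activate = "activ",
             effective = "effect", probate = "probat", rate = "rate",
             cease = "ceas", controll = "control", roll = "roll",
             stay = "stay")
  expect_equal(porterStem(names(pairs)), unname(pairs))
  # non-alphabetic tokens pass through untouched
  expect_equal(porterStem(c("xurl", "covid19", "h1n1")),
               c("xurl", "covid19", "h1n1"))
})
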