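test_that("slot histogram bins posts by 3-hour UTC slot", {
  h <- slot_histogram(posts_at(c("2018-02-03 00:10:00", "2018-02-03 00:20:00",
                                 "2018-02-03 04:00:00")))
  # hours 0 and 0 fall in slot 0 ([00, 03)), hour 4 in slot 1 ([03, 06))
  expect_equal(h$n, c(2, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(slot_histogram(posts_at("2018-02-03 06:00:00"))$n,
               c(0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(slot_histogram(posts_at(character(0)))$n, rep(0, 8))
  hourly <- posts_at(sprintf("2018-02-03 %02d:30:00", 0:23))
  expect_equal(slot_histogram(hourly)$n, rep(3, 8))
})

test_that("sttr equals the brute-force circular pair minimum, exactly", {
  expect_equal(sttr(rep(5, 8), 40), 0.25)
  expect_equal(sttr(c(40, 0, 0, 0, 0, 0, 0, 0), 40), 0)
  expect_equal(sttr(c(5, 0, 1, 2, 10, 10, 10, 2), 40), 1 / 40)
  set.seed(42)
  for (i in 1:1000) {
    counts <- rpois(8, sample(0:30, 1))
    total <- sum(counts) + sample(0:20, 1)
    if (total == 0) next
    expect_identical(sttr(counts, total), sttr_oracle(counts, total))
  }
  expect_error(sttr(rep(1, 8), 0), "positive")
  expect_error(sttr(rep(5, 8), 30), "at least")
})

test_that("dttr is the exact complement", {
  expect_equal(dttr(0), 1)
  expect_equal(dttr(0.25), 0.75)
  expect_equal(dttr(0.02), 0.98)
  expect_error(dttr(1.2))
})

test_that("behavioral features follow their stated definitions", {
  # all SPV posts on Saturdays
  sat <- posts_at(c("2018-03-03 10:00:00", "2018-03-10 11:00:00"))
  b <- behavioral_features(sat, sat, year = 2018, total = 10)
  expect_equal(b$weekend_ratio, 1)
  expect_equal(b$weekday_ratio, 0)
  # median gap of posts at t, t+60, t+180 is 90 s
  g <- posts_at(c("2018-05-01 10:00:00", "2018-05-01 10:01:00", "2018-05-01 10:03:00"))
  expect_equal(behavioral_features(g, g, year = 2018, total = 3)$median_gap_s, 90)
  # 10 SPV posts all in Q1 of a 1000-post profile
  q1 <- posts_at(sprintf("2018-02-%02d 09:00:00", 1:10))
  bq <- behavioral_features(q1, q1, year = 2018, total = 1000)
  expect_equal(c(bq$q1_ratio, bq$q2_ratio, bq$q3_ratio, bq$q4_ratio),
               c(0.01, 0, 0, 0))
  # single-post SPV: median gap undefined, flagged for imputation
  one <- posts_at("2018-05-01 10:00:00")
  expect_true(is.na(behavioral_features(one, one, year = 2018, total = 5)$median_gap_s))
})

test_that("tweet statistics match hand-computed values", {
  spv_posts <- tibble::tibble(
    spvc_score = c(0.9, 0.7, 0.8),
    n_tokens = c(13L, 11L, 20L)
  )
  st <- tweet_statistics(spv_posts, total = 300, statuses_total = 1200)
  expect_equal(st$median_spvc_score, 0.8)
  expect_equal(st$n_spv, 3)
  expect_equal(st$statuses_total, 1200)
  st15 <- tweet_statistics(spv_posts[rep(1, 15), ], total = 300, statuses_total = 400)
  expect_equal(st15$spv_ratio, 0.05)
  five <- tibble::tibble(spvc_score = rep(0.6, 5), n_tokens = c(13L, 11L, 20L, 5L, 13L))
  expect_equal(tweet_statistics(five, 100, 100)$median_tweet_len, 13)
  empty <- tweet_statistics(five[0, ], total = 10, statuses_total = 10)
  expect_true(is.na(empty$median_spvc_score) && is.na(empty$median_tweet_len))
  expect_equal(empty$n_spv, 0)
})

test_that("relational features pass metadata through and summarize SPV engagement", {
  user <- tibble::tibble(followers_count = 120L, friends_count = 372L,
                         favorites_given = 900L)
  spv_posts <- tibble::tibble(favorite_count = c(1L, 0L, 4L),
                              retweet_count = c(0L, 0L, 5L))
  r <- relational_features(user, spv_posts)
  expect_equal(r$friends, 372)
  expect_equal(r$median_retweets, 0)
  expect_equal(r$median_favorites, 1)
  r0 <- relational_features(user, spv_posts[0, ])
  expect_equal(r0$followers, 120)
  expect_true(is.na(r0$median_favorites) && is.na(r0$median_retweets))
})

test_that("lexicon counting is greedy, longest-first, non-overlapping and normalized", {
  lex <- structure(list(suicide_explicit = "quiero morir"), class = "spv_lexicon")
  lc <- lexicon_counts(c("me", "quiero", "morir", "hoy"), lex)
  expect_equal(lc$lex_suicide_explicit, 0.25)
  lex2 <- structure(list(cat = "morir"), class = "spv_lexicon")
  expect_equal(lexicon_counts(c("morir", "morir"), lex2)$lex_cat, 1)
  # longest match wins and consumes its tokens
  lex3 <- structure(list(cat = c("no puedo dormir", "dormir", "no")), class = "spv_lexicon")
  expect_equal(lexicon_counts(c("no", "puedo", "dormir"), lex3)$lex_cat, 1 / 3)
  # bound and absence
  expect_lte(lexicon_counts(rep("morir", 5), lex2)$lex_cat, 1)
  expect_equal(lexicon_counts(c("hola", "mundo"), lex2)$lex_cat, 0)
  # degenerate input flagged
  z <- lexicon_counts(character(0), lex2)
  expect_equal(z$lex_cat, 0)
  expect_true(attr(z, "degenerate"))
})

test_that("lexicon files are validated at load", {
  bad <- tempfile(fileext = ".json")
  writeLines('{"a": [], "b": ["hola"]}', bad)
  expect_error(read_lexicon(bad), "empty lexicon category")
  long <- tempfile(fileext = ".json")
  writeLines('{"a": ["uno dos tres cuatro"]}', long)
  expect_error(read_lexicon(long), "1-3 tokens")
  lex <- default_lexicon()
  expect_s3_class(lex, "spv_lexicon")
  expect_gte(length(lex), 3)
})

test_that("sentiment and image aggregates follow their definitions", {
  fake_scorer <- function(tl) c(0.2, 0.8, 0.5)[seq_along(tl)]
  spv_posts <- tibble::tibble(tokens = list("a", "b", "c"))
  expect_equal(sentiment_feature(spv_posts, fake_scorer), 0.5)
  const <- function(tl) rep(0.7, length(tl))
  expect_equal(sentiment_feature(spv_posts, const), 0.7)
  scorer <- polarity_scorer()
  expect_gt(scorer(list(c("feliz", "genial", "amor")))[1], 0.5)
  expect_lt(scorer(list(c("triste", "odio")))[1], 0.5)
  expect_equal(scorer(list(c("casa", "mesa")))[1], 0.5)
  expect_true(is.na(sentiment_feature(spv_posts[0, ], scorer)))

  expect_equal(image_user_score(c(0.2, 0.4)), 0.3)
  expect_true(is.na(image_user_score(numeric(0))))
  expect_equal(image_user_score(0.24), 0.24)
  expect_error(image_user_score(c(0.5, 1.2)))
})

test_that("the SNPSY bank has the documented width and is deterministic", {
  co <- fix_cohort()
  spv <- fix_spv()
  lex3 <- structure(list(a = "quiero morir", b = "triste", c = "trabajo"),
                    class = "spv_lexicon")
  sn3 <- assemble_snpsy(co, spv, lexicon = lex3)
  snpsy_cols <- setdiff(names(sn3)[vapply(sn3, is.numeric, TRUE)], "image_score")
  expect_length(snpsy_cols, 23)  # 9 behavioral + 5 statistics + 5 relational + 3 lexicon + 1 sentiment
  sn_default <- fix_snpsy()
  defo_cols <- setdiff(names(sn_default)[vapply(sn_default, is.numeric, TRUE)], "image_score")
  expect_length(defo_cols, 19 + length(default_lexicon()) + 1)
  expect_identical(sn3, assemble_snpsy(co, spv, lexicon = lex3))
})

test_that("SNPSY invariants hold on a generated cohort", {
  sn <- fix_snpsy()
  expect_equal(sn$sttr + sn$dttr, rep(1, nrow(sn)))
  with_spv <- sn$n_spv > 0
  expect_equal(sn$weekday_ratio[with_spv] + sn$weekend_ratio[with_spv],
               rep(1, sum(with_spv)))
  ratio_cols <- c("weekday_ratio", "weekend_ratio", "sttr", "dttr", "spv_ratio",
                  grep("^q[1-4]_ratio$", names(sn), value = TRUE))
  for (cl in ratio_cols) {
    v <- sn[[cl]][!is.na(sn[[cl]])]
    expect_true(all(v >= 0 & v <= 1), info = cl)
  }
  qsum <- sn$q1_ratio + sn$q2_ratio + sn$q3_ratio + sn$q4_ratio
  expect_true(all(qsum <= 1 + 1e-12))
  lex_cols <- grep("^lex_", names(sn), value = TRUE)
  for (cl in lex_cols) expect_true(all(is.na(sn[[cl]]) | sn[[cl]] <= 1), info = cl)
  # planted circadian contrast: risk group tweets more at night
  expect_gt(mean(sn$sttr[sn$group == "risk"]),
            mean(sn$sttr[sn$group == "generic_control"]))
})

test_that("imputation fills SPV-sourced gaps with training statistics", {
  sn <- fix_snpsy()
  feat <- sn[, vapply(sn, is.numeric, TRUE)]
  train <- seq_len(40)
  imp_tr <- impute_features(feat[train, ])
  expect_false(anyNA(imp_tr))
  st <- attr(imp_tr, "impute_stats")
  expect_equal(st$image_score, mean(feat$image_score[train], na.rm = TRUE))
  na_cols <- setdiff(names(feat)[vapply(feat[train, ], anyNA, TRUE)], "image_score")
  for (cl in na_cols) {
    expect_equal(st[[cl]], median(feat[[cl]][train], na.rm = TRUE))
  }
  imp_all <- impute_features(feat, stats = st)
  expect_false(anyNA(imp_all))
  # test rows filled with *training* statistics
  miss <- which(is.na(feat$median_gap_s) & seq_len(nrow(feat)) > 40)
  if (length(miss) > 0) {
    expect_equal(imp_all$median_gap_s[miss[1]], st$median_gap_s)
  }
})
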