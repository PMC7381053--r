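test_that("preprocessing replaces generic spans with placeholders", {
  expect_equal(preprocess_text("Tengo $50")[[1]], c("tengo", "<money>"))
  expect_equal(preprocess_text("hola #fuerza \U0001F622")[[1]],
               c("hola", "<hashtag>", "<emoticon>"))
  expect_equal(preprocess_text("")[[1]], character(0))
  expect_equal(preprocess_text("llama al 612-345-678 ya")[[1]],
               c("llama", "al", "<phone>", "ya"))
  expect_equal(preprocess_text("son 3 cosas")[[1]], c("son", "<digit>", "cosas"))
  expect_identical(preprocess_text("Hola, mundo!"), preprocess_text("Hola, mundo!"))
})

test_that("the document-frequency floor uses raw document counts", {
  docs <- tibble::tibble(
    user_id = sprintf("u%02d", 1:30),
    tokens = c(list(c("raro", "comun")), list(c("raro2", "comun", "raro2")),
               replicate(28, c("comun", "otra"), simplify = FALSE))
  )
  bm <- fit_user_bow(docs, ngram_range = c(1, 1), df_floor = 0.05,
                     stopwords = character(0))
  expect_false("raro" %in% bm$vocabulary)   # 1/30 < 0.05
  expect_true("comun" %in% bm$vocabulary)   # 30/30
  expect_true("otra" %in% bm$vocabulary)    # 28/30
  docs2 <- docs
  docs2$tokens[[3]] <- c("raro", "comun")   # now df("raro") = 2/30 >= 0.05
  bm2 <- fit_user_bow(docs2, ngram_range = c(1, 1), df_floor = 0.05,
                      stopwords = character(0))
  expect_true("raro" %in% bm2$vocabulary)
})

test_that("stopword-only corpora fail with a diagnostic", {
  docs <- tibble::tibble(user_id = c("a", "b", "c"),
                         tokens = replicate(3, c("de", "la", "el"), simplify = FALSE))
  expect_error(fit_user_bow(docs), "stopword-only|empty")
  expect_error(fit_user_bow(docs[1, ]), "at least 2")
})

test_that("bag-of-words fits are reproducible and transforms align columns", {
  co <- fix_cohort()
  spv <- fix_spv()
  docs <- user_documents(co, spv, variant = "spv")
  b1 <- fit_user_bow(docs[1:30, ])
  b2 <- fit_user_bow(docs[1:30, ])
  expect_identical(b1$vocabulary, b2$vocabulary)
  expect_equal(as.matrix(b1$matrix), as.matrix(b2$matrix))
  tx <- bow_transform(b1, docs[31:40, ])
  expect_equal(ncol(tx), length(b1$vocabulary))
  # transforming the training docs reproduces the fitted matrix
  tx0 <- bow_transform(b1, docs[1:30, ])
  expect_equal(as.matrix(tx0), as.matrix(b1$matrix), tolerance = 1e-12)
})

test_that("full-profile documents concatenate all posts in order", {
  co <- fix_cohort()
  docs <- user_documents(co, variant = "full_profile")
  u <- co$users$user_id[3]
  expect_equal(docs$tokens[[3]],
               unlist(co$posts$tokens[co$posts$user_id == u], use.names = FALSE))
})

test_that("out-of-fold probabilities separate a separable matrix and stay at the prior for constants", {
  set.seed(9)
  n <- 60
  y <- factor(rep(c("control", "risk"), each = n / 2), levels = c("control", "risk"))
  x <- cbind(sig = ifelse(y == "risk", 1, -1) + rnorm(n, 0, 0.05),
             noise = rnorm(n))
  oof <- bow_outputted_feature(x, y, n_folds = 10, seed = 3)
  expect_true(all(oof$oof$prob[y == "risk"] >= 0.9))
  expect_true(all(oof$oof$prob[y == "control"] <= 0.1))
  # held-out prediction from the full-train model
  xt <- cbind(sig = c(1, -1), noise = c(0, 0))
  pt <- predict(oof, xt)
  expect_gt(pt[1], 0.9); expect_lt(pt[2], 0.1)

  xc <- matrix(1, n, 3)
  oofc <- bow_outputted_feature(xc, y, n_folds = 5, seed = 3)
  expect_true(all(abs(oofc$oof$prob - 0.5) < 0.05))
  expect_error(bow_outputted_feature(x, factor(rep("risk", n))), "two classes")
})

test_that("out-of-fold values come from models that never saw the user's fold", {
  set.seed(21)
  n <- 40
  y <- factor(rep(c("control", "risk"), n / 2), levels = c("control", "risk"))
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 1] <- x[, 1] + ifelse(y == "risk", 1, -1)
  oof <- bow_outputted_feature(x, y, n_folds = 5, seed = 13, lambda = 0.01)
  # oracle: refit the same ridge-logistic per fold with glmnet directly
  lam_path <- sort(unique(0.01 * c(100, 30, 10, 3, 1)), decreasing = TRUE)
  for (f in unique(oof$oof$fold)) {
    tr <- oof$oof$fold != f
    fit <- glmnet::glmnet(x[tr, ], as.integer(y[tr] == "risk"),
                          family = "binomial", alpha = 0, lambda = lam_path,
                          standardize = TRUE)
    p_or <- as.numeric(predict(fit, x[oof$oof$fold == f, , drop = FALSE],
                               s = 0.01, type = "response"))
    expect_equal(oof$oof$prob[oof$oof$fold == f], p_or, tolerance = 1e-10)
  }
})

test_that("the SPV text model is at least as good as the full-profile one in most replicates", {
  m <- fix_spvc()
  wins <- 0L; reps <- 15L
  for (r in seq_len(reps)) {
    cfg <- cohort_config(n_per_group = 12, tweets_median = c(120, 130, 40),
                         seed = 500 + r)
    co <- generate_cohort(cfg, seed = 500 + r)
    keep <- co$users$group %in% c("risk", "focused_control")
    ids <- co$users$user_id[keep]
    y <- factor(ifelse(co$users$group[keep] == "risk", "risk", "control"),
                levels = c("control", "risk"))
    spv <- build_spv(m, co)
    auc_for <- function(variant) {
      docs <- user_documents(co, spv, variant = variant)
      docs <- docs[match(ids, docs$user_id), ]
      tr <- rep(c(TRUE, FALSE), length.out = length(ids))
      bm <- fit_user_bow(docs[tr, ], df_floor = 0.05)
      oof <- bow_outputted_feature(bm$matrix, y[tr], n_folds = 4, seed = r)
      p <- predict(oof, bow_transform(bm, docs[!tr, ]))
      auc_oracle(p[y[!tr] == "risk"], p[y[!tr] == "control"])
    }
    a_spv <- auc_for("spv"); a_full <- auc_for("full_profile")
    if (a_spv >= a_full) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.6)
})
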