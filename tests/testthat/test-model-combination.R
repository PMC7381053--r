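test_that("Mann-Whitney screening matches exact enumeration on small samples", {
  x <- cbind(sep6 = c(1, 2, 3, 4, 5, 6),
             same = c(1, 2, 3, 1, 2, 3))
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  scr <- mannwhitney_screen(x, y, alpha = 0.05)
  # {1,2,3} vs {4,5,6}: the two extreme arrangements of C(6,3)=20 -> P = 2/20
  expect_equal(scr$p_value[scr$feature == "sep6"], 0.1, tolerance = 1e-12)
  expect_false(scr$selected[scr$feature == "sep6"])
  expect_false(scr$selected[scr$feature == "same"])

  x2 <- cbind(strong = 1:20)
  y2 <- factor(rep(c("a", "b"), each = 10))
  p <- mannwhitney_screen(x2, y2, alpha = 0.001)$p_value
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(mannwhitney_screen(x2, y2, alpha = 0.05)$selected)
  expect_true(mannwhitney_screen(x2, y2, alpha = 0.001)$selected)
})

test_that("screening handles constants and enforces preconditions", {
  x <- cbind(const = rep(3, 12), ok = rnorm(12))
  y <- factor(rep(c("a", "b"), 6))
  scr <- mannwhitney_screen(x, y)
  expect_equal(scr$p_value[scr$feature == "const"], 1)
  expect_false(scr$selected[scr$feature == "const"])
  expect_error(mannwhitney_screen(x, factor(rep("a", 12))), "two classes")
  expect_error(mannwhitney_screen(x[1:4, ], y[1:4]), "at least 3")
})

test_that("selection at alpha .001 is nested within selection at .05", {
  set.seed(5)
  for (r in 1:20) {
    x <- matrix(rnorm(40 * 30), 40, 30)
    x[1:20, 1:3] <- x[1:20, 1:3] + r / 10
    y <- factor(rep(c("a", "b"), each = 20))
    s1 <- mannwhitney_screen(x, y, alpha = 0.05)
    s2 <- mannwhitney_screen(x, y, alpha = 0.001)
    expect_true(all(s2$feature[s2$selected] %in% s1$feature[s1$selected]))
  }
})

test_that("the overlap index matches closed forms and limiting cases", {
  set.seed(11)
  a <- rnorm(20000); b <- rnorm(20000, 2)
  expect_lt(abs(overlap_index(a, b) - 2 * pnorm(-1)), 0.03)
  s <- rnorm(5000)
  expect_gte(overlap_index(s, s), 0.98)
  expect_lte(overlap_index(runif(2000), runif(2000, 10, 11)), 0.02)
  # zero-variance fallback
  expect_equal(overlap_index(rep(1, 5), rep(1, 7)), 1)
  expect_lte(overlap_index(rep(0, 5), rep(10, 5)), 0.02)
  expect_error(overlap_index(1, c(1, 2)))
})

test_that("the Yeo-Johnson transform normalizes and is fitted on training rows only", {
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  set.seed(3)
  x <- cbind(normalish = rnorm(4000), skewed = rlnorm(4000, 0, 1))
  tr <- transform_features(x)
  expect_lt(abs(skew(tr$train[, "normalish"]) - skew(x[, "normalish"])), 0.05)
  expect_lt(abs(skew(tr$train[, "skewed"])), abs(skew(x[, "skewed"])) / 2)
  expect_equal(unname(colMeans(tr$train)), c(0, 0), tolerance = 1e-8)
  # training-only fit: applying to new rows reuses the stored parameters
  x_new <- cbind(normalish = rnorm(50, 5), skewed = rlnorm(50, 2, 1))
  tr2 <- transform_features(x, x_new)
  expect_equal(tr2$train, tr$train)
  expect_gt(mean(tr2[[4]][, "normalish"]), 2)  # shifted data stays shifted
  # zero-variance column passes through as zeros
  xz <- cbind(v = rnorm(60), z = rep(2, 60))
  trz <- transform_features(xz)
  expect_equal(unname(trz$train[, "z"]), rep(0, 60))
  expect_equal(trz$zero_variance, "z")
})

test_that("classification metrics match hand-computed confusion arithmetic", {
  # TP=22 FN=4 FP=3 TN=23
  truth <- factor(c(rep("risk", 26), rep("control", 26)), levels = c("control", "risk"))
  prob <- c(rep(0.9, 22), rep(0.1, 4), rep(0.9, 3), rep(0.1, 23))
  m <- classification_metrics(truth, prob)
  expect_equal(m$precision, 22 / 25)
  expect_equal(m$recall, 22 / 26)
  expect_equal(m$f1, 2 * (22/25) * (22/26) / ((22/25) + (22/26)))
  expect_equal(m$accuracy, 45 / 52)
  # perfect separation
  mp <- classification_metrics(truth, ifelse(truth == "risk", 0.99, 0.01))
  expect_equal(unlist(mp), c(precision = 1, recall = 1, f1 = 1, accuracy = 1, auc = 1))
  # AUC equals the rank-based oracle
  set.seed(8)
  pr <- runif(52)
  expect_equal(classification_metrics(truth, pr)$auc,
               auc_oracle(pr[truth == "risk"], pr[truth == "control"]))
})

test_that("random scores give chance-level AUC over 20 seeds", {
  truth <- factor(rep(c("control", "risk"), each = 100), levels = c("control", "risk"))
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    classification_metrics(truth, runif(200))$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("DeLong comparison behaves at its fixed points", {
  set.seed(2)
  y <- factor(rep(c("control", "risk"), each = 100), levels = c("control", "risk"))
  s <- runif(200)
  d0 <- suppressWarnings(delong_compare(s, s, y))
  expect_equal(d0$delta, 0)
  expect_equal(d0$p_value, 1)
  perfect <- ifelse(y == "risk", 1, 0) + rnorm(200, 0, 1e-3)
  d1 <- delong_compare(perfect, runif(200), y)
  expect_lt(d1$p_value, 0.001)
  expect_gt(d1$auc_a, 0.99)
  expect_error(delong_compare(s, s, factor(rep("risk", 200))), "two classes")
})

test_that("DeLong decisions agree with a paired-bootstrap oracle", {
  boot_p <- function(sa, sb, y, reps = 2000) {
    pos <- which(y == "risk"); neg <- which(y == "control")
    d0 <- auc_oracle(sa[pos], sa[neg]) - auc_oracle(sb[pos], sb[neg])
    ds <- vapply(seq_len(reps), function(i) {
      ip <- sample(pos, replace = TRUE); ineg <- sample(neg, replace = TRUE)
      auc_oracle(sa[ip], sa[ineg]) - auc_oracle(sb[ip], sb[ineg])
    }, 0)
    se <- sd(ds)
    if (se == 0) return(1)
    2 * pnorm(-abs(d0) / se)
  }
  set.seed(77)
  y <- factor(rep(c("control", "risk"), each = 20), levels = c("control", "risk"))
  agree <- vapply(1:20, function(i) {
    base <- rnorm(40)
    shift <- sample(c(0, 0.6, 1.5), 1)
    sa <- base + ifelse(y == "risk", shift, 0) + rnorm(40, 0, 0.5)
    sb <- base + rnorm(40, 0, 0.5)
    pd <- suppressWarnings(delong_compare(sa, sb, y)$p_value)
    pb <- boot_p(sa, sb, y)
    (pd < 0.05) == (pb < 0.05)
  }, TRUE)
  expect_gte(mean(agree), 0.95)
})

test_that("feature ranking finds planted signal in both modes", {
  set.seed(4)
  n <- 120
  y <- factor(rep(c("control", "risk"), each = n / 2), levels = c("control", "risk"))
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  x[, 4] <- x[, 4] + ifelse(y == "risk", 2, 0)
  x[, 7] <- 5  # constant
  ri <- rank_features(x, y, mode = "impurity", seed = 1)
  rc <- rank_features(x, y, mode = "class_correlation")
  expect_equal(ri$feature[1], "f4")
  expect_equal(rc$feature[1], "f4")
  expect_equal(rc$score[rc$feature == "f7"], 0)
  expect_equal(ri$score[ri$feature == "f7"], 0)
  # duplicated informative feature occupies the top two correlation ranks
  x2 <- cbind(x, f4b = x[, 4])
  rc2 <- rank_features(x2, y, mode = "class_correlation")
  expect_setequal(rc2$feature[1:2], c("f4", "f4b"))
})

test_that("design matrices follow the recipe contracts", {
  n <- 12
  snpsy <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("s", 1:4)))
  bow <- Matrix::rsparsematrix(n, 6, 0.5)
  colnames(bow) <- paste0("t", 1:6)
  img <- c(runif(n - 2), NA, NA)
  oofb <- runif(n); oofs <- runif(n)

  m1 <- build_design_matrix("images_bow_snpsy_1", bow_oof = oofb,
                            snpsy_oof = oofs, image_score = img)
  expect_equal(ncol(m1$x), 3)
  expect_equal(nrow(m1$x), n - 2)          # rows with missing scores removed
  expect_equal(m1$rows, seq_len(n - 2))

  m2 <- build_design_matrix("images_snpsy", snpsy = snpsy, image_score = img)
  expect_equal(ncol(m2$x), ncol(snpsy) + 1)
  expect_equal(nrow(m2$x), n)              # missing scores mean-imputed
  expect_equal(unname(m2$x[n, "image_score"]), mean(img, na.rm = TRUE))

  m3 <- build_design_matrix("images_bow_snpsy_2", snpsy = snpsy, bow_oof = oofb,
                            image_score = img)
  expect_equal(colnames(m3$x), c(colnames(snpsy), "image_score", "bow_outputted"))

  mb <- build_design_matrix("images_bow", bow = bow, image_score = img)
  expect_equal(ncol(mb$x), 7)
  expect_equal(colnames(mb$x)[7], "image_score")

  expect_error(build_design_matrix("bow_snpsy", snpsy = snpsy), "needs")
  expect_error(build_design_matrix("nope", snpsy = snpsy), "unknown recipe")

  y <- factor(rep(c("a", "b"), n / 2))
  pooled <- pooled_features(snpsy, bow, ifelse(is.na(img), mean(img, na.rm = TRUE), img))
  scr <- mannwhitney_screen(pooled, y, alpha = 0.5)
  ms <- build_design_matrix("selected_1", snpsy = snpsy, bow = bow,
                            image_score = img, screen = scr)
  expect_equal(ncol(ms$x), sum(scr$selected))
})

test_that("nested evaluation is perfect on a separable task and honest on noise", {
  set.seed(10)
  n <- 80
  y <- factor(rep(c("control", "risk"), each = n / 2), levels = c("control", "risk"))
  x <- cbind(a = ifelse(y == "risk", 2, -2) + rnorm(n, 0, 0.1),
             b = rnorm(n))
  tr <- rep(c(TRUE, TRUE, TRUE, FALSE), n / 4)
  ev <- fit_select_evaluate(x[tr, ], y[tr], x[!tr, ], y[!tr],
                            algorithms = c("logistic", "svm"), seed = 1)
  expect_equal(unlist(ev$metrics),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1, auc = 1))
  # pure-noise features: held-out AUC near chance across seeds
  aucs <- vapply(1:20, function(s) {
    set.seed(s + 400)
    xn <- matrix(rnorm(n * 5), n, 5)
    ev0 <- fit_select_evaluate(xn[tr, ], y[tr], xn[!tr, ], y[!tr],
                               algorithms = "logistic", seed = s, n_runs = 1)
    ev0$metrics$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("infeasible fold counts are reduced with a warning", {
  set.seed(12)
  y <- factor(rep(c("control", "risk"), c(5, 5)), levels = c("control", "risk"))
  x <- cbind(a = rnorm(10), b = rnorm(10))
  expect_warning(
    fit_select_evaluate(x, y, x, y, algorithms = "logistic",
                        cv_folds = 10, grid_folds = 5, seed = 1),
    "reducing folds"
  )
})
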