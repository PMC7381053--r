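#' Train the short-profile-version classifier (SPVC)
#'
#' Fits the tweet-level binary classifier that distinguishes suicide-related
#' posts from control posts: word n-grams (1-5 by default) weighted by
#' tf.idf, a linear principal-component reduction retaining
#' `var_explained` of the variance (capped at `n - 1` components), and a
#' ridge-regularized logistic scoring function. Fold-wise precision, recall
#' and F1 at the decision threshold are estimated by stratified
#' cross-validation and stored in the returned model.
#'
#' The fitted scorer is collapsed to a single vocabulary-length weight vector,
#' so scoring large post streams never materializes principal-component
#' scores.
#'
#' @param corpus tibble with a `class` factor
#'   (levels `suicide_related`, `control`) and either a `tokens` list-column
#'   or a `raw_text` column; both classes need at least 20 posts.
#' @param ngram_range integer pair, lowest and highest n-gram order.
#' @param threshold decision threshold; a post enters an SPV only with a
#'   score strictly above it.
#' @param var_explained fraction of variance retained by the reduction.
#' @param lambda ridge penalty of the logistic fit.
#' @param cv_folds folds for the reported cross-validated metrics (0 skips).
#' @param seed integer seed for fold assignment.
#' @return an object of class `spvc_model`.
#' @export
train_spvc <- function(corpus, ngram_range = c(1, 5), threshold = 0.5,
                       var_explained = 0.95, lambda = 0.01, cv_folds = 10,
                       seed = 1) {
  y <- corpus$class
  if (length(unique(y)) < 2) stop("corpus must contain both classes")
  if (min(table(y)) < 20) stop("need at least 20 posts per class")
  toks <- corpus_tokens(corpus)
  cv <- NULL
  if (cv_folds > 0) {
    fold <- stratified_folds(y, cv_folds, seed = seed)
    cv <- dplyr::bind_rows(lapply(sort(unique(fold)), function(f) {
      fit <- spvc_fit_core(toks[fold != f], y[fold != f], ngram_range,
                           var_explained, lambda)
      sc <- spvc_score_core(fit, toks[fold == f])
      m <- confusion_metrics(y[fold == f] == "suicide_related", sc > threshold)
      tibble(fold = f, precision = m["precision"], recall = m["recall"], f1 = m["f1"])
    }))
  }
  core <- spvc_fit_core(toks, y, ngram_range, var_explained, lambda)
  structure(list(core = core, threshold = threshold, ngram_range = ngram_range,
                 var_explained = var_explained, lambda = lambda,
                 cv = cv, seed = seed, n_docs = length(toks)),
            class = "spvc_model")
}

corpus_tokens <- function(x) {
  if ("tokens" %in% names(x)) x$tokens else preprocess_text(x$raw_text)
}

spvc_fit_core <- function(token_list, y, ngram_range, var_explained, lambda) {
  fit <- ngram_fit(token_list, orders = ngram_range[1]:ngram_range[2], min_df = 1L)
  idf <- idf_fit(fit$dtm)
  X <- tfidf_apply(fit$dtm, idf)
  n <- nrow(X)
  K <- as.matrix(Matrix::tcrossprod(X))
  rs <- rowMeans(K); gm <- mean(K)
  Kc <- K - outer(rs, rep(1, n)) - outer(rep(1, n), rs) + gm
  eig <- eigen(Kc, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  pos <- ev > max(ev) * 1e-9
  cum <- cumsum(ev[pos]) / sum(ev[pos])
  r <- min(which(cum >= var_explained), n - 1L)
  d <- sqrt(ev[seq_len(r)])
  scores <- eig$vectors[, seq_len(r), drop = FALSE] %*% diag(d, r)
  yb <- as.integer(y == "suicide_related")
  lam_path <- sort(unique(c(lambda * c(100, 30, 10, 3, 1))), decreasing = TRUE)
  gfit <- glmnet::glmnet(scores, yb, family = "binomial", alpha = 0,
                         lambda = lam_path, standardize = FALSE)
  beta <- as.numeric(stats::coef(gfit, s = lambda))
  a0 <- beta[1]; beta <- beta[-1]
  # collapse to vocabulary weights: w = Xc' U D^{-1} beta
  u <- eig$vectors[, seq_len(r), drop = FALSE] %*% (beta / d)
  m <- Matrix::colMeans(X)
  w <- as.numeric(Matrix::crossprod(X, u)) - m * sum(u)
  list(engine = fit$engine, idf = idf, w = w, b = a0 - sum(m * w),
       rank = r, n_terms = ncol(fit$dtm))
}

spvc_score_core <- function(core, token_list) {
  if (length(token_list) == 0) return(numeric(0))
  X <- ngram_transform(core$engine, token_list)
  X <- tfidf_apply(X, core$idf)
  plogis(as.numeric(X %*% core$w) + core$b)
}

#' Score posts with a fitted SPVC
#'
#' Deterministic probability-like score for the suicide-related class, one per
#' post. Posts with no tokens receive the model's intercept-driven score.
#'
#' @param model a fitted [train_spvc()] model.
#' @param posts tibble with a `tokens` list-column or `raw_text`.
#' @return the input with an `spvc_score` column appended.
#' @export
score_posts <- function(model, posts) {
  stopifnot(inherits(model, "spvc_model"))
  posts$spvc_score <- spvc_score_core(model$core, corpus_tokens(posts))
  posts
}

#' Build each user's short profile version
#'
#' Retains, per user, the at-most-`k` highest-scoring posts whose SPVC score
#' is strictly above the threshold. Ties in score are broken by more recent
#' `created_at`, then by `post_id`. Users with no post above the threshold are
#' kept with `has_spv = FALSE` and an empty retained set, never dropped.
#'
#' @param model a fitted [train_spvc()] model.
#' @param x an `spv_cohort` or a posts tibble with `user_id`.
#' @param k maximum SPV size.
#' @param threshold decision threshold (defaults to the model's).
#' @return tibble with one row per user: `user_id`, `retained` (list-column of
#'   retained posts with scores, sorted descending by score), `has_spv`,
#'   `n_spv`.
#' @export
build_spv <- function(model, x, k = 15, threshold = model$threshold) {
  posts <- if (inherits(x, "spv_cohort")) x$posts else x
  all_users <- if (inherits(x, "spv_cohort")) x$users$user_id else unique(posts$user_id)
  scored <- score_posts(model, posts)
  scored$n_tokens <- lengths(scored$tokens)
  spv_select(scored, users = all_users, k = k, threshold = threshold)
}

#' Select each user's SPV from scored posts
#'
#' The selection rule applied by [build_spv()]: per user, keep the at-most-`k`
#' posts whose `spvc_score` strictly exceeds the threshold, ordered by
#' descending score with ties broken by more recent `created_at`, then by
#' `post_id`.
#'
#' @param scored posts tibble with `user_id`, `spvc_score` and `created_at`.
#' @param users user ids to report (defaults to those present in `scored`);
#'   users with no qualifying post get `has_spv = FALSE`.
#' @param k maximum SPV size.
#' @param threshold strict lower bound on retained scores.
#' @return an `spv_result` tibble (see [build_spv()]).
#' @export
spv_select <- function(scored, users = unique(scored$user_id), k = 15,
                       threshold = 0.5) {
  if (!"n_tokens" %in% names(scored)) {
    scored$n_tokens <- if ("tokens" %in% names(scored)) lengths(scored$tokens) else NA_integer_
  }
  for (cl in c("retweet_count", "favorite_count")) {
    if (!cl %in% names(scored)) scored[[cl]] <- NA_integer_
  }
  if (!"tokens" %in% names(scored)) {
    scored$tokens <- replicate(nrow(scored), character(0), simplify = FALSE)
  }
  kept <- scored %>%
    filter(.data$spvc_score > threshold) %>%
    arrange(.data$user_id, dplyr::desc(.data$spvc_score),
            dplyr::desc(.data$created_at), .data$post_id) %>%
    group_by(.data$user_id) %>%
    slice_head(n = k) %>%
    ungroup()
  nested <- kept %>%
    select("user_id", "post_id", "created_at", "spvc_score", "n_tokens",
           "retweet_count", "favorite_count", "tokens") %>%
    tidyr::nest(retained = -"user_id")
  out <- tibble(user_id = users) %>%
    left_join(nested, by = "user_id") %>%
    mutate(
      retained = purrr::map(.data$retained, function(r) {
        if (is.null(r)) tibble(post_id = character(0), created_at = as.POSIXct(character(0), tz = "UTC"),
                               spvc_score = numeric(0), n_tokens = integer(0),
                               retweet_count = integer(0), favorite_count = integer(0),
                               tokens = list()) else r
      }),
      n_spv = purrr::map_int(.data$retained, nrow),
      has_spv = .data$n_spv > 0L
    )
  class(out) <- c("spv_result", class(out))
  out
}

#' @export
tidy.spvc_model <- function(x, ...) {
  if (is.null(x$cv)) return(tibble(fold = integer(0), precision = numeric(0),
                                   recall = numeric(0), f1 = numeric(0)))
  x$cv
}

#' @export
glance.spvc_model <- function(x, ...) {
  tibble(
    n_docs = x$n_docs, n_terms = x$core$n_terms, rank = x$core$rank,
    threshold = x$threshold,
    cv_precision = if (is.null(x$cv)) NA_real_ else mean(x$cv$precision),
    cv_recall = if (is.null(x$cv)) NA_real_ else mean(x$cv$recall),
    cv_f1 = if (is.null(x$cv)) NA_real_ else mean(x$cv$f1)
  )
}

#' @export
print.spvc_model <- function(x, ...) {
  g <- glance(x)
  cat("<spvc_model> ", g$n_terms, " n-gram terms, rank ", g$rank,
      ", threshold ", g$threshold, "\n", sep = "")
  if (!is.null(x$cv)) {
    cat(sprintf("  %d-fold CV: Pr=%.3f R=%.3f F1=%.3f\n", nrow(x$cv),
                g$cv_precision, g$cv_recall, g$cv_f1))
  }
  invisible(x)
}

# precision/recall/F1 of a logical prediction against logical truth
confusion_metrics <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  c(precision = pr, recall = rc, f1 = f1)
}
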