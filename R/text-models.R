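#' Tokenize raw post text
#'
#' Lowercases and tokenizes, replacing generic spans by placeholder tokens:
#' hashtags by `<hashtag>`, money amounts by `<money>`, phone-like digit runs
#' by `<phone>`, remaining digit runs by `<digit>` and emoticons/emoji by
#' `<emoticon>`. Remaining punctuation is stripped. Deterministic.
#'
#' @param x character vector of raw texts.
#' @return list of character token vectors, one per input element.
#' @export
preprocess_text <- function(x) {
  x <- tolower(as.character(x))
  x <- stringr::str_replace_all(x, "#[\\p{L}\\p{N}_]+", " <hashtag> ")
  x <- stringr::str_replace_all(x, "\\$\\s?\\d+(?:[.,]\\d+)?|\\d+(?:[.,]\\d+)?\\s?(?:€|euros?|dolares)", " <money> ")
  x <- stringr::str_replace_all(x, "\\+?\\d[\\d\\s-]{6,}\\d", " <phone> ")
  x <- stringr::str_replace_all(x, "\\d+", " <digit> ")
  x <- stringr::str_replace_all(x, "[\U0001F300-\U0001FAFF☀-➿❤]|:-?[)(dp]|;-?\\)|:'\\(|xd", " <emoticon> ")
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N}<>_]", " ")
  strsplit(stringr::str_squish(x), " ", fixed = TRUE) |>
    lapply(function(t) t[t != ""])
}

#' Build user-level documents
#'
#' Represents each user as the concatenation of their post tokens, either
#' over the full profile or over the SPV. Empty documents occur only for
#' users without an SPV (carried, not dropped).
#'
#' @param cohort an `spv_cohort`.
#' @param spv a [build_spv()] result (required for the SPV variant).
#' @param variant `"spv"` or `"full_profile"`.
#' @return tibble: `user_id`, `tokens` list-column, `variant`.
#' @export
user_documents <- function(cohort, spv = NULL,
                           variant = c("spv", "full_profile")) {
  variant <- match.arg(variant)
  users <- cohort$users$user_id
  if (variant == "full_profile") {
    idx <- match(cohort$posts$user_id, users)
    tok <- unlist(cohort$posts$tokens, use.names = FALSE)
    tok_user <- rep.int(idx, lengths(cohort$posts$tokens))
    ord <- order(tok_user)
    docs <- split(tok[ord], factor(tok_user[ord], levels = seq_along(users)))
    tokens <- unname(docs)
  } else {
    if (is.null(spv)) stop("the SPV variant needs a build_spv() result")
    spv <- spv[match(users, spv$user_id), ]
    tokens <- purrr::map(spv$retained, ~ unlist(.x$tokens, use.names = FALSE) %||% character(0))
  }
  tibble(user_id = users, tokens = tokens, variant = variant)
}

#' Fit a user-level bag-of-words model
#'
#' tf.idf-weighted word n-grams (1-5 by default) over user documents, after
#' stopword removal. N-grams present in fewer than `ceiling(df_floor * n)`
#' documents are dropped (the document-frequency floor applies to raw counts,
#' before weighting).
#'
#' @param documents a [user_documents()] tibble (or any tibble with
#'   `user_id` and a `tokens` list-column).
#' @param ngram_range integer pair of n-gram orders.
#' @param df_floor minimum document-frequency fraction.
#' @param stopwords character vector removed from token streams before
#'   n-gram formation.
#' @return object of class `bow_model`: the fitted engine, idf weights, the
#'   user x term tf.idf `matrix` (rows follow document order), `vocabulary`,
#'   and a `manifest` of the preprocessing choices.
#' @export
fit_user_bow <- function(documents, ngram_range = c(1, 5), df_floor = 0.05,
                         stopwords = spanish_stopwords()) {
  if (nrow(documents) < 2) stop("need at least 2 documents")
  toks <- lapply(documents$tokens, function(t) t[!(t %in% stopwords)])
  n <- length(toks)
  min_df <- max(1L, as.integer(ceiling(df_floor * n)))
  fit <- tryCatch(
    ngram_fit(toks, orders = ngram_range[1]:ngram_range[2], min_df = min_df),
    error = function(e) stop("bag-of-words fit failed (", conditionMessage(e),
                             "); documents may be empty or stopword-only", call. = FALSE)
  )
  idf <- idf_fit(fit$dtm)
  w <- tfidf_apply(fit$dtm, idf)
  rownames(w) <- documents$user_id
  structure(list(
    engine = fit$engine, idf = idf, matrix = w, stopwords = stopwords,
    vocabulary = fit$engine$term_strings, df = fit$engine$df, n_docs = n,
    manifest = list(ngram_range = ngram_range, df_floor = df_floor,
                    stopword_hash = rlang::hash(sort(stopwords)),
                    sublinear_tf = FALSE, idf = "smooth", norm = "l2")
  ), class = "bow_model")
}

#' Transform new documents with a fitted bag-of-words model
#'
#' @param model a [fit_user_bow()] model.
#' @param documents tibble with a `tokens` list-column.
#' @return sparse tf.idf matrix aligned with the model's vocabulary.
#' @export
bow_transform <- function(model, documents) {
  toks <- lapply(documents$tokens, function(t) t[!(t %in% model$stopwords)])
  dtm <- ngram_transform(model$engine, toks)
  w <- tfidf_apply(dtm, model$idf)
  rownames(w) <- documents$user_id
  w
}

#' @export
print.bow_model <- function(x, ...) {
  cat("<bow_model> ", x$n_docs, " documents, ", length(x$vocabulary),
      " n-gram terms (df floor ", x$manifest$df_floor, ")\n", sep = "")
  invisible(x)
}

#' Out-of-fold stacked probability feature
#'
#' Turns a feature matrix into a single per-user probability column without
#' leakage: every training user's value comes from a ridge-logistic model fit
#' on stratified folds that exclude that user; held-out users are later scored
#' by a model fit on the full training set (`predict()` on the returned
#' object). Users with all-zero rows (no SPV, hence an empty document)
#' receive the training class prior.
#'
#' @param x numeric or sparse matrix, training users by features.
#' @param labels binary factor aligned with rows.
#' @param n_folds folds for the out-of-fold scheme.
#' @param seed fold-assignment seed.
#' @param positive positive-class label.
#' @param lambda ridge penalty.
#' @return object of class `oof_feature`: `oof` (per-row probability and fold
#'   id) plus the full-data model for new users.
#' @export
bow_outputted_feature <- function(x, labels, n_folds = 10, seed = 1,
                                  positive = "risk", lambda = 0.01) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (!positive %in% levels(labels)) positive <- levels(labels)[2]
  x <- as_model_matrix(x)
  zero_row <- Matrix::rowSums(x != 0) == 0
  prior <- mean(labels == positive)
  fold <- stratified_folds(labels, n_folds, seed = seed)
  prob <- rep(NA_real_, nrow(x))
  for (f in sort(unique(fold))) {
    tr <- fold != f & !zero_row
    fit <- ridge_logistic_fit(x[tr, , drop = FALSE], labels[tr], positive, lambda)
    prob[fold == f] <- ridge_logistic_prob(fit, x[fold == f, , drop = FALSE])
  }
  prob[zero_row] <- prior
  full <- ridge_logistic_fit(x[!zero_row, , drop = FALSE], labels[!zero_row], positive, lambda)
  structure(list(
    oof = tibble(row = seq_len(nrow(x)), fold = fold, prob = prob),
    model = full, prior = prior, positive = positive, lambda = lambda,
    seed = seed, n_folds = max(fold)
  ), class = "oof_feature")
}

#' @export
predict.oof_feature <- function(object, newx, ...) {
  newx <- as_model_matrix(newx)
  p <- ridge_logistic_prob(object$model, newx)
  p[Matrix::rowSums(newx != 0) == 0] <- object$prior
  p
}

# TRUE when every column of the design is constant across rows
const_design <- function(x) {
  # cheap probe first: any variation in a small row sample settles it
  probe <- as.matrix(x[seq_len(min(nrow(x), 50L)), , drop = FALSE])
  if (any(probe != matrix(probe[1, ], nrow(probe), ncol(probe), byrow = TRUE))) {
    return(FALSE)
  }
  xm <- as.matrix(x)
  all(xm == matrix(xm[1, ], nrow(xm), ncol(xm), byrow = TRUE))
}

as_model_matrix <- function(x) {
  if (inherits(x, "sparseMatrix")) return(methods::as(x, "CsparseMatrix"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

ridge_logistic_fit <- function(x, y, positive, lambda) {
  if (length(unique(y)) < 2) stop("degenerate single-class input")
  if (ncol(x) < 2) x <- cbind(x, `..pad` = 0)
  yb <- as.integer(y == positive)
  # uninformative design (all columns constant): intercept-only model
  if (const_design(x)) {
    return(list(fit = NULL, prior = mean(yb), lambda = lambda, p = ncol(x)))
  }
  lam_path <- sort(unique(lambda * c(100, 30, 10, 3, 1)), decreasing = TRUE)
  fit <- suppressWarnings(glmnet::glmnet(x, yb, family = "binomial", alpha = 0,
                                         lambda = lam_path, standardize = TRUE))
  list(fit = fit, lambda = lambda, p = ncol(x))
}

ridge_logistic_prob <- function(model, newx) {
  if (is.null(model$fit)) return(rep(model$prior, nrow(newx)))
  if (ncol(newx) < model$p) newx <- cbind(newx, `..pad` = 0)
  as.numeric(predict(model$fit, newx, s = model$lambda, type = "response"))
}
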