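#' Circadian time-slot histogram
#'
#' Counts posts into 8 fixed 3-hour UTC slots (slot `i` covers hours
#' `[3i, 3i + 3)`). The slots are circular: slot 7 (21:00-24:00) is adjacent
#' to slot 0 (00:00-03:00).
#'
#' @param x a posts tibble with `created_at`, or a POSIXct vector.
#' @return tibble with columns `slot` (0-7) and `n`.
#' @export
slot_histogram <- function(x) {
  ts <- if (is.data.frame(x)) x$created_at else x
  hr <- as.POSIXlt(ts, tz = "UTC")$hour
  tibble(slot = 0:7, n = tabulate(hr %/% 3 + 1L, nbins = 8L))
}

#' Sleep-time tweet ratio (STTR)
#'
#' The minimum, over the 8 circular pairs of adjacent 3-hour slots, of the
#' summed post counts, normalized by the user's total in-window post count
#' `total`. The pair with the fewest posts is taken as the user's inferred
#' 6-hour sleep period. The daytime tweet ratio is its complement,
#' `dttr(s) = 1 - s`.
#'
#' @param hist a [slot_histogram()] tibble or a numeric vector of 8 counts.
#' @param total total in-window post count of the full profile (the
#'   normalizer); must be at least `sum(hist)` and positive.
#' @return ratio in \[0, 1\].
#' @export
sttr <- function(hist, total) {
  counts <- if (is.data.frame(hist)) hist$n else hist
  stopifnot(length(counts) == 8)
  if (is.na(total) || total <= 0) stop("undefined STTR: total post count must be positive")
  if (total < sum(counts)) stop("total must be at least the histogram mass")
  pairs <- counts + counts[c(2:8, 1)]
  min(pairs) / total
}

#' @rdname sttr
#' @param sttr_value an STTR value in \[0, 1\].
#' @export
dttr <- function(sttr_value) {
  stopifnot(all(sttr_value >= 0 & sttr_value <= 1))
  1 - sttr_value
}

# weekday index 0 = Monday ... 6 = Sunday, from UTC dates
utc_wday <- function(ts) (as.POSIXlt(ts, tz = "UTC")$wday + 6L) %% 7L

#' Behavioral features for one user
#'
#' Weekday/weekend posting ratios, the median gap in seconds between
#' consecutive SPV posts, the 4 quarterly posting ratios (SPV posts per fixed
#' calendar quarter of `year`, normalized by the full-profile in-window
#' count), and STTR/DTTR computed from the full-profile posts.
#'
#' @param posts the user's full-profile posts tibble.
#' @param spv_posts the user's retained SPV posts tibble (may have 0 rows).
#' @param year calendar year whose quarters are counted.
#' @param total in-window post count (defaults to `nrow(posts)`).
#' @return one-row tibble of 9 features; SPV-sourced entries are `NA` when
#'   the SPV is empty (median gap additionally needs 2 posts) and are filled
#'   by [impute_features()].
#' @export
behavioral_features <- function(posts, spv_posts, year, total = nrow(posts)) {
  n_spv <- nrow(spv_posts)
  if (n_spv > 0) {
    wd <- utc_wday(spv_posts$created_at)
    weekday_ratio <- mean(wd < 5)
    weekend_ratio <- mean(wd >= 5)
    gaps <- diff(sort(as.numeric(spv_posts$created_at)))
    median_gap_s <- if (n_spv >= 2) median(gaps) else NA_real_
    qt <- as.POSIXlt(spv_posts$created_at, tz = "UTC")
    in_year <- qt$year + 1900L == year
    q <- tabulate((qt$mon[in_year] %/% 3L) + 1L, nbins = 4L)
    qr <- q / total
  } else {
    weekday_ratio <- weekend_ratio <- median_gap_s <- NA_real_
    qr <- c(0, 0, 0, 0)
  }
  s <- if (total > 0) sttr(slot_histogram(posts), total) else NA_real_
  tibble(weekday_ratio = weekday_ratio, weekend_ratio = weekend_ratio,
         median_gap_s = median_gap_s, sttr = s, dttr = dttr_or_na(s),
         q1_ratio = qr[1], q2_ratio = qr[2], q3_ratio = qr[3], q4_ratio = qr[4])
}

dttr_or_na <- function(s) if (is.na(s)) NA_real_ else dttr(s)

#' Tweet-statistic features for one user
#'
#' @inheritParams behavioral_features
#' @param statuses_total lifetime post count from the account metadata.
#' @return one-row tibble: SPV-retention ratio, median SPVC score, median SPV
#'   tweet length in word tokens, SPV size, lifetime statuses.
#' @export
tweet_statistics <- function(spv_posts, total, statuses_total) {
  n_spv <- nrow(spv_posts)
  tibble(
    spv_ratio = if (total > 0) n_spv / total else 0,
    median_spvc_score = safe_median(spv_posts$spvc_score),
    median_tweet_len = safe_median(as.numeric(spv_posts$n_tokens)),
    n_spv = as.numeric(n_spv),
    statuses_total = as.numeric(statuses_total)
  )
}

#' Relational features for one user
#'
#' Account metadata pass-throughs plus medians of favorites and retweets
#' received over the SPV posts.
#'
#' @param user one-row tibble of user metadata.
#' @param spv_posts the user's retained SPV posts.
#' @return one-row tibble of 5 features.
#' @export
relational_features <- function(user, spv_posts) {
  tibble(
    followers = as.numeric(user$followers_count),
    friends = as.numeric(user$friends_count),
    favorites_given = as.numeric(user$favorites_given),
    median_favorites = safe_median(as.numeric(spv_posts$favorite_count)),
    median_retweets = safe_median(as.numeric(spv_posts$retweet_count))
  )
}

#' Lexicon category features
#'
#' Counts phrase matches per lexicon category over a user's concatenated SPV
#' tokens — greedy left-to-right, longest match first, non-overlapping within
#' a category — and normalizes each count by the total token count of the
#' concatenated text.
#'
#' @param tokens character vector: the user's concatenated SPV tokens.
#' @param lexicon a lexicon from [read_lexicon()].
#' @return one-row tibble with one `lex_<category>` column per category; all
#'   zero, with attribute `degenerate = TRUE`, when `tokens` is empty.
#' @export
lexicon_counts <- function(tokens, lexicon) {
  n <- length(tokens)
  vals <- vapply(names(lexicon), function(cat) {
    if (n == 0) return(0)
    count_phrases(tokens, lexicon[[cat]]) / n
  }, 0)
  out <- as_tibble(as.list(setNames(vals, paste0("lex_", names(lexicon)))))
  attr(out, "degenerate") <- n == 0
  out
}

# greedy non-overlapping longest-match-first phrase count
count_phrases <- function(tokens, phrases) {
  pl <- strsplit(phrases, " ", fixed = TRUE)
  by_len <- split(vapply(pl, paste, "", collapse = " "), lengths(pl))
  lens <- sort(as.integer(names(by_len)), decreasing = TRUE)
  n <- length(tokens)
  # precollapsed windows per phrase length
  win <- lapply(setNames(lens, lens), function(L) {
    if (n < L) return(character(0))
    if (L == 1) return(tokens)
    idx <- seq_len(n - L + 1L)
    g <- tokens[idx]
    for (j in 2:L) g <- paste(g, tokens[idx + j - 1L])
    g
  })
  count <- 0L; i <- 1L
  while (i <= n) {
    matched <- 0L
    for (L in lens) {
      if (i + L - 1L <= n && win[[as.character(L)]][i] %in% by_len[[as.character(L)]]) {
        matched <- L; break
      }
    }
    if (matched > 0L) { count <- count + 1L; i <- i + matched } else i <- i + 1L
  }
  count
}

#' Default polarity scorer
#'
#' A transparent lexicon-based per-post polarity function: with `p` positive
#' and `q` negative word hits the score is `(1 + (p - q)/(p + q))/2`, and 0.5
#' when no sentiment word occurs. Any function mapping a list of token
#' vectors to scores in \[0, 1\] can be plugged in instead.
#'
#' @param positive,negative word lists.
#' @return function from a list of token vectors to numeric scores.
#' @export
polarity_scorer <- function(positive = positive_words, negative = negative_words) {
  function(token_list) {
    vapply(token_list, function(tk) {
      p <- sum(tk %in% positive); q <- sum(tk %in% negative)
      if (p + q == 0) 0.5 else (1 + (p - q) / (p + q)) / 2
    }, 0)
  }
}

#' Median sentiment over a user's SPV
#'
#' @param spv_posts retained SPV posts tibble (with `tokens`).
#' @param scorer per-post polarity function (see [polarity_scorer()]).
#' @return median per-post polarity, `NA` for an empty SPV.
#' @export
sentiment_feature <- function(spv_posts, scorer = polarity_scorer()) {
  if (nrow(spv_posts) == 0) return(NA_real_)
  s <- scorer(spv_posts$tokens)
  stopifnot(all(s >= 0 & s <= 1))
  median(s)
}

#' Per-user image score
#'
#' Arithmetic mean of the user's per-image scores; `NA` (missing, to be
#' mean-imputed downstream) when the user has no scored images.
#'
#' @param image_scores numeric vector of per-image scores in \[0, 1\].
#' @return scalar mean or `NA`.
#' @export
image_user_score <- function(image_scores) {
  stopifnot(all(image_scores >= 0 & image_scores <= 1))
  if (length(image_scores) == 0) NA_real_ else mean(image_scores)
}

#' Assemble the SNPSY feature table
#'
#' Computes the full SNPSY bank for every user of a cohort: 9 behavioral + 5
#' tweet-statistic + 5 relational features, one feature per lexicon category,
#' and the sentiment median — `19 + K + 1` columns for `K` categories.
#' SPV-sourced features of users without an SPV are `NA` here; apply
#' [impute_features()] with training-set statistics before modeling. The
#' per-user image score is returned alongside (appended to design matrices
#' only by the recipes that use it).
#'
#' @param cohort an `spv_cohort`.
#' @param spv the [build_spv()] result for the same cohort.
#' @param lexicon lexicon for the category features.
#' @param scorer per-post polarity function.
#' @param year calendar year for the quarterly ratios (defaults to the year
#'   of the configured collection window's end).
#' @return tibble: `user_id`, `group`, all SNPSY columns, `image_score`.
#' @export
assemble_snpsy <- function(cohort, spv, lexicon = default_lexicon(),
                           scorer = polarity_scorer(), year = NULL) {
  stopifnot(inherits(cohort, "spv_cohort"))
  year <- year %||% (as.POSIXlt(as.POSIXct(
    if (!is.null(cohort$config)) as.character(cohort$config$window_end) else max(cohort$posts$created_at),
    tz = "UTC"))$year + 1900L)
  # full-profile slot counts, vectorized across the whole cohort
  hr <- as.POSIXlt(cohort$posts$created_at, tz = "UTC")$hour
  uidx <- match(cohort$posts$user_id, cohort$users$user_id)
  slot_tab <- matrix(0L, nrow(cohort$users), 8)
  cnt <- table_counts((uidx - 1) * 8 + (hr %/% 3) + 1)
  slot_tab[cbind((cnt$key - 1) %/% 8 + 1, (cnt$key - 1) %% 8 + 1)] <- cnt$n
  totals <- tabulate(uidx, nbins = nrow(cohort$users))
  spv <- spv[match(cohort$users$user_id, spv$user_id), ]
  rows <- lapply(seq_len(nrow(cohort$users)), function(i) {
    u <- cohort$users[i, ]
    sp <- spv$retained[[i]]
    total <- totals[i]
    pairs <- slot_tab[i, ] + slot_tab[i, c(2:8, 1)]
    s <- if (total > 0) min(pairs) / total else NA_real_
    beh <- if (nrow(sp) > 0) {
      b <- behavioral_features(tibble(created_at = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")),
                               sp, year, total = total)
      b$sttr <- s; b$dttr <- dttr_or_na(s)
      b
    } else {
      tibble(weekday_ratio = NA_real_, weekend_ratio = NA_real_,
             median_gap_s = NA_real_, sttr = s, dttr = dttr_or_na(s),
             q1_ratio = 0, q2_ratio = 0, q3_ratio = 0, q4_ratio = 0)
    }
    stats <- tweet_statistics(sp, total, u$statuses_total)
    rel <- relational_features(u, sp)
    lex <- lexicon_counts(unlist(sp$tokens, use.names = FALSE), lexicon)
    # no-SPV users: lexicon features are SPV-sourced, leave them for imputation
    if (isTRUE(attr(lex, "degenerate"))) lex[1, ] <- NA_real_
    dplyr::bind_cols(
      tibble(user_id = u$user_id, group = u$group),
      beh, stats, rel, lex,
      tibble(sentiment_median = sentiment_feature(sp, scorer),
             image_score = image_user_score(u$image_scores[[1]]))
    )
  })
  dplyr::bind_rows(rows)
}

#' Impute missing feature values
#'
#' Fills `NA` entries of SPV-sourced features with per-feature statistics
#' computed from a reference (training) set: the median for every feature
#' except `image_score`, which uses the cohort mean (mirroring the
#' missing-image policy of the analysis). Statistics computed on one table
#' can be re-applied to another (train-fit, test-apply).
#'
#' @param features a feature tibble from [assemble_snpsy()].
#' @param stats optional statistics from a previous call (its
#'   `"impute_stats"` attribute); computed from `features` when `NULL`.
#' @return the imputed tibble, with the statistics attached as attribute
#'   `"impute_stats"` and the per-user list of imputed fields as
#'   `"imputed_fields"`.
#' @export
impute_features <- function(features, stats = NULL) {
  num_cols <- names(features)[vapply(features, is.numeric, TRUE)]
  if (is.null(stats)) {
    stats <- lapply(setNames(num_cols, num_cols), function(cl) {
      v <- features[[cl]]
      if (cl == "image_score") mean(v, na.rm = TRUE) else median(v, na.rm = TRUE)
    })
  }
  imputed_fields <- lapply(seq_len(nrow(features)), function(i) {
    num_cols[vapply(num_cols, function(cl) is.na(features[[cl]][i]), TRUE)]
  })
  for (cl in num_cols) {
    miss <- is.na(features[[cl]])
    if (any(miss)) features[[cl]][miss] <- stats[[cl]]
  }
  attr(features, "impute_stats") <- stats
  attr(features, "imputed_fields") <- imputed_fields
  features
}
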