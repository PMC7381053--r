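#' Lexicon files
#'
#' A lexicon is a named list of categories, each a character vector of
#' lowercase phrases of one to three word tokens. `read_lexicon()` loads and
#' validates a JSON file mapping category names to phrase arrays;
#' `default_lexicon()` loads the small synthetic Spanish-like lexicon shipped
#' with the package (a stand-in for proprietary category dictionaries, which
#' cannot be redistributed).
#'
#' @param path path to a JSON lexicon file.
#' @return named list of character vectors, classed `"spv_lexicon"`.
#' @export
read_lexicon <- function(path) {
  lex <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(lex) || is.null(names(lex)) || any(names(lex) == "")) {
    stop("lexicon must be a JSON object mapping category names to phrase arrays")
  }
  lex <- lapply(lex, as.character)
  if (any(lengths(lex) == 0)) {
    stop("empty lexicon category: ", paste(names(lex)[lengths(lex) == 0], collapse = ", "))
  }
  for (cat in names(lex)) {
    nt <- lengths(strsplit(lex[[cat]], " ", fixed = TRUE))
    if (any(nt < 1 | nt > 3)) stop("lexicon phrases must have 1-3 tokens (category ", cat, ")")
    if (any(lex[[cat]] != tolower(lex[[cat]]))) stop("lexicon phrases must be lowercase (category ", cat, ")")
  }
  structure(lex, class = "spv_lexicon")
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon_synthetic_es.json", package = "spvscreen"))
}

#' Spanish stopword list
#'
#' Reads the short Spanish stopword list shipped with the package (used by the
#' user-level bag-of-words models), or a caller-supplied one-per-line file.
#'
#' @param path optional path to a one-word-per-line text file.
#' @return character vector of stopwords.
#' @export
spanish_stopwords <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stopwords_es.txt", package = "spvscreen")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

group_levels <- c("risk", "focused_control", "generic_control")

as_group3 <- function(x) {
  stats::setNames(as.numeric(x), group_levels)
}

#' Cohort generator configuration
#'
#' Collects every generative parameter of the synthetic three-group cohort:
#' a suicidal-ideation risk group, a focused control group (users who use
#' suicide-related vocabulary without being at risk) and a generic control
#' group. Defaults are calibrated to the descriptive statistics of the study
#' cohort the pipeline was designed around: 84 users per group, median posts
#' per user 2797.5 / 2984 / 716, median tweet length 11 / 19 / 14 tokens,
#' friends-count medians 372 / 578.5, image-score medians 0.24 / 0.23 / 0.23,
#' and a higher night-posting propensity for the risk group.
#'
#' All per-group vectors are ordered (risk, focused_control, generic_control).
#'
#' @param n_per_group users per group.
#' @param window_start,window_end collection window (UTC dates); posts are
#'   generated strictly inside it.
#' @param tweets_median per-group median number of in-window posts per user
#'   (log-normal).
#' @param tweets_sdlog log-scale spread of the per-user post count.
#' @param length_median per-group median tweet length in word tokens
#'   (shifted Poisson).
#' @param night_propensity per-group extra probability mass placed on the
#'   03:00-09:00 UTC sleep band; drives the sleep-time tweet ratio contrast.
#' @param weekend_boost per-group multiplicative weight on Saturday/Sunday
#'   when drawing post dates.
#' @param lexicon_rates category x group matrix of per-unit emission
#'   probabilities for lexicon-category phrases (see
#'   [default_lexicon_rates()]).
#' @param sentiment_neg_rate,sentiment_pos_rate per-group emission rates of
#'   negative/positive sentiment words.
#' @param friends_median,friends_sdlog,followers_median,followers_sdlog,favorites_median,favorites_sdlog
#'   log-normal parameters of the relational metadata.
#' @param image_score_median per-group Beta median of per-image scores.
#' @param image_concentration Beta concentration (shape1 + shape2).
#' @param n_images_mean per-group mean image count (Poisson, capped).
#' @param max_images per-user image cap.
#' @param p_missing_images probability a user has no image scores at all.
#' @param p_no_spv_focused fraction of focused-control users generated with no
#'   suicide-related vocabulary at all, to exercise the no-SPV path.
#' @param statuses_multiplier lifetime statuses are the in-window count times
#'   this factor (at least).
#' @param seed mandatory integer seed.
#' @param lexicon lexicon used for phrase emission (defaults to the shipped
#'   synthetic lexicon).
#' @return a classed list of validated parameters.
#' @export
cohort_config <- function(n_per_group = 84,
                          window_start = "2017-12-21",
                          window_end = "2018-12-21",
                          tweets_median = c(2797.5, 2984, 716),
                          tweets_sdlog = 0.35,
                          length_median = c(11, 19, 14),
                          night_propensity = c(0.03, 0.015, 0.01),
                          weekend_boost = c(1.25, 0.9, 0.9),
                          lexicon_rates = default_lexicon_rates(),
                          sentiment_neg_rate = c(0.06, 0.02, 0.015),
                          sentiment_pos_rate = c(0.01, 0.03, 0.03),
                          friends_median = c(372, 578.5, 500),
                          friends_sdlog = 0.6,
                          followers_median = c(300, 420, 380),
                          followers_sdlog = 0.8,
                          favorites_median = c(1800, 2400, 4000),
                          favorites_sdlog = 0.7,
                          image_score_median = c(0.24, 0.23, 0.23),
                          image_concentration = 10,
                          n_images_mean = c(450, 900, 190),
                          max_images = 1000,
                          p_missing_images = 0.02,
                          p_no_spv_focused = 0.05,
                          statuses_multiplier = 1.4,
                          seed = 7,
                          lexicon = default_lexicon()) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (is.na(window_start) || is.na(window_end) || window_end <= window_start) {
    stop("invalid collection window: end must be after start")
  }
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    window_start = window_start, window_end = window_end,
    tweets_median = as_group3(tweets_median), tweets_sdlog = tweets_sdlog,
    length_median = as_group3(length_median),
    night_propensity = as_group3(night_propensity),
    weekend_boost = as_group3(weekend_boost),
    lexicon_rates = lexicon_rates,
    sentiment_neg_rate = as_group3(sentiment_neg_rate),
    sentiment_pos_rate = as_group3(sentiment_pos_rate),
    friends_median = as_group3(friends_median), friends_sdlog = friends_sdlog,
    followers_median = as_group3(followers_median), followers_sdlog = followers_sdlog,
    favorites_median = as_group3(favorites_median), favorites_sdlog = favorites_sdlog,
    image_score_median = as_group3(image_score_median),
    image_concentration = image_concentration,
    n_images_mean = as_group3(n_images_mean), max_images = max_images,
    p_missing_images = p_missing_images,
    p_no_spv_focused = p_no_spv_focused,
    statuses_multiplier = statuses_multiplier,
    seed = as.integer(seed),
    lexicon = lexicon
  )
  rates <- c(cfg$lexicon_rates, cfg$sentiment_neg_rate, cfg$sentiment_pos_rate,
             cfg$night_propensity, cfg$p_missing_images, cfg$p_no_spv_focused)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(c(cfg$tweets_median, cfg$length_median, cfg$friends_median) <= 0)) {
    stop("medians must be positive")
  }
  if (!setequal(rownames(cfg$lexicon_rates), names(cfg$lexicon))) {
    stop("lexicon_rates rows must match the lexicon categories")
  }
  structure(cfg, class = "cohort_config")
}

#' Default per-group lexicon emission rates
#'
#' Per-unit emission probability of a phrase from each lexicon category, one
#' column per group (risk, focused_control, generic_control). The planted
#' contrasts follow the direction of the study groups: risk users emit more
#' first-person and suicide-related vocabulary; focused controls use
#' suicide-related terms at lower, news-like rates; generic controls barely
#' use them but talk more about work and money.
#'
#' @return numeric matrix, categories x groups.
#' @export
default_lexicon_rates <- function() {
  m <- rbind(
    first_person    = c(0.100, 0.045, 0.045),
    suicide_explicit = c(0.030, 0.012, 0.0005),
    depression      = c(0.022, 0.008, 0.0010),
    self_loathing   = c(0.015, 0.002, 0.0005),
    insomnia        = c(0.008, 0.002, 0.0010),
    anxiety         = c(0.010, 0.003, 0.0010),
    negation        = c(0.050, 0.030, 0.0300),
    social_support  = c(0.008, 0.012, 0.0100),
    health          = c(0.015, 0.008, 0.0050),
    work_money      = c(0.008, 0.015, 0.0300)
  )
  colnames(m) <- group_levels
  m
}

# Sentiment word lists used by both the generator and the default polarity
# scorer. Deliberately disjoint from lexicon phrases' first tokens.
positive_words <- c("feliz", "bien", "genial", "amor", "gracias", "alegre",
                    "bonito", "risa", "fiesta", "sonrisa")
negative_words <- c("triste", "mal", "odio", "horrible", "miedo", "peor",
                    "cansado", "sufrir", "oscuro", "culpa")

# Deterministic pseudo-word filler vocabulary.
filler_vocab <- function(n = 220) {
  syl <- c("ca", "mi", "to", "ra", "lu", "pe", "sa", "ne", "vi", "do",
           "ta", "ri", "mo", "le", "su", "ba")
  two <- outer(syl, syl, paste0)
  words <- unique(c(as.vector(two), as.vector(outer(as.vector(two[1:8, 1:8]), syl, paste0))))
  words <- setdiff(words, c(positive_words, negative_words))
  words[seq_len(n)]
}

# Emission unit table for one group: a tibble of units (word or phrase),
# their token expansion and sampling probability.
group_unit_table <- function(config, group, mute_suicide = FALSE) {
  lex <- config$lexicon
  rates <- config$lexicon_rates[, group]
  if (mute_suicide) {
    # news-like informative account: no suicide-related or self-referential
    # vocabulary, dominated by work/money topics and a dedicated newsroom
    # vocabulary; these users' posts stay clearly below the SPVC threshold
    rates[] <- 0
    if ("work_money" %in% names(rates)) rates[["work_money"]] <- 0.5
    if ("social_support" %in% names(rates)) rates[["social_support"]] <- 0.02
    units <- character(0); prob <- numeric(0)
    for (cat in names(lex)) {
      ph <- lex[[cat]]
      units <- c(units, ph)
      prob <- c(prob, rep(rates[[cat]] / length(ph), length(ph)))
    }
    units <- c(units, positive_words, sprintf("noticia%02d", 1:40))
    prob <- c(prob, rep(0.05 / length(positive_words), length(positive_words)))
    prob <- c(prob, rep((1 - sum(prob)) / 40, 40))
    toks <- strsplit(units, " ", fixed = TRUE)
    return(list(units = units, prob = prob, tokens = toks, n_tokens = lengths(toks)))
  }
  units <- character(0); prob <- numeric(0)
  for (cat in names(lex)) {
    ph <- lex[[cat]]
    units <- c(units, ph)
    prob <- c(prob, rep(rates[[cat]] / length(ph), length(ph)))
  }
  units <- c(units, negative_words, positive_words)
  prob <- c(prob,
            rep(config$sentiment_neg_rate[[group]] / length(negative_words), length(negative_words)),
            rep(config$sentiment_pos_rate[[group]] / length(positive_words), length(positive_words)))
  fill <- filler_vocab()
  p_fill <- max(0, 1 - sum(prob))
  # mildly uneven filler distribution so tf.idf has structure
  w <- 1 / sqrt(seq_along(fill))
  units <- c(units, fill)
  prob <- c(prob, p_fill * w / sum(w))
  toks <- strsplit(units, " ", fixed = TRUE)
  list(units = units, prob = prob, tokens = toks, n_tokens = lengths(toks))
}

# Vectorized expansion of sampled unit indices into a token stream.
expand_units <- function(unit_tab, unit_idx, post_of_unit) {
  k <- unit_tab$n_tokens[unit_idx]
  total <- sum(k)
  tok <- character(total)
  starts <- cumsum(c(1L, k[-length(k)]))
  first <- vapply(unit_tab$tokens, `[[`, "", 1L)
  tok[starts] <- first[unit_idx]
  ge2 <- which(k >= 2L)
  if (length(ge2)) {
    second <- vapply(unit_tab$tokens, function(t) if (length(t) >= 2) t[[2]] else "", "")
    tok[starts[ge2] + 1L] <- second[unit_idx[ge2]]
  }
  ge3 <- which(k >= 3L)
  if (length(ge3)) {
    third <- vapply(unit_tab$tokens, function(t) if (length(t) >= 3) t[[3]] else "", "")
    tok[starts[ge3] + 2L] <- third[unit_idx[ge3]]
  }
  list(tokens = tok, post = rep.int(post_of_unit, k))
}

# Collapse a token stream into one string per post without per-post paste().
collapse_posts <- function(tokens, post_ids, n_posts) {
  if (length(tokens) == 0) return(character(n_posts))
  big <- paste(tokens, collapse = " ")
  ends <- cumsum(nchar(tokens) + 1L)
  last_tok <- cumsum(tabulate(post_ids, nbins = n_posts))
  n_tok <- tabulate(post_ids, nbins = n_posts)
  out <- character(n_posts)
  nz <- n_tok > 0
  last <- ends[last_tok[nz]] - 1L
  first_tok <- last_tok[nz] - n_tok[nz] + 1L
  start <- c(0L, ends)[first_tok] + 1L
  out[nz] <- substring(big, start, last)
  out
}

# Draw UTC timestamps inside the window: dates weighted by weekend boost,
# hours from the 8-slot circadian distribution plus the night band.
draw_timestamps <- function(n, config, group) {
  days <- seq(config$window_start, config$window_end - 1, by = "day")
  wd <- as.POSIXlt(days)$wday
  dw <- ifelse(wd %in% c(0, 6), config$weekend_boost[[group]], 1)
  day <- sample(length(days), n, replace = TRUE, prob = dw / sum(dw))
  base <- c(0.02, 0.005, 0.005, 0.10, 0.17, 0.21, 0.25, 0.24)
  w <- config$night_propensity[[group]]
  p_slot <- (1 - w) * base
  p_slot[2:3] <- p_slot[2:3] + w / 2   # slots covering 03:00-09:00 UTC
  slot <- sample(8L, n, replace = TRUE, prob = p_slot) - 1L
  secs <- slot * 10800L + sample.int(10800L, n, replace = TRUE) - 1L
  as.POSIXct(days[day], tz = "UTC") + secs
}

beta_shapes <- function(m, conc) {
  f <- function(a) stats::qbeta(0.5, a, conc - a) - m
  a <- suppressWarnings(stats::uniroot(f, c(0.05, conc - 0.05))$root)
  c(shape1 = a, shape2 = conc - a)
}

#' Generate per-image scores for a group
#'
#' Beta-distributed scores in \[0, 1\] whose median matches the configured
#' group anchor (risk 0.24, controls 0.23 by default).
#'
#' @param group one of `"risk"`, `"focused_control"`, `"generic_control"`.
#' @param n_images number of scores to draw.
#' @param seed integer seed.
#' @param config a [cohort_config()].
#' @return numeric vector of length `n_images`.
#' @export
generate_image_scores <- function(group, n_images, seed = 1,
                                  config = cohort_config()) {
  group <- match.arg(group, group_levels)
  stopifnot(n_images >= 0)
  if (n_images == 0) return(numeric(0))
  sh <- beta_shapes(config$image_score_median[[group]], config$image_concentration)
  with_seed(seed, rbeta(n_images, sh[["shape1"]], sh[["shape2"]]))
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_per_group` users for each of the three study groups with the
#' configured group contrasts planted: risk users write shorter tweets, post
#' more in the 03:00-09:00 UTC band, emit more first-person and
#' suicide-lexicon vocabulary and follow fewer accounts; generic controls
#' post far fewer tweets and barely use suicide-related vocabulary. Output is
#' fully determined by `(config, seed)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `spv_cohort`: a list with `users` (one row per
#'   user: metadata, group, `image_scores` list-column) and `posts` (one row
#'   per post: `user_id`, `post_id`, `created_at`, `tokens` list-column,
#'   `raw_text`, engagement counts), both tibbles, plus the `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  with_seed(seed, {
    users_list <- list(); posts_list <- list()
    for (group in group_levels) {
      n <- config$n_per_group
      uid <- sprintf("%s_%03d", sub("_control", "", group), seq_len(n))
      no_spv <- if (group == "focused_control") {
        runif(n) < config$p_no_spv_focused
      } else rep(FALSE, n)
      n_posts <- pmax(1L, as.integer(round(rlnorm(n, log(config$tweets_median[[group]]),
                                                  config$tweets_sdlog))))
      n_im <- pmin(config$max_images, rpois(n, config$n_images_mean[[group]]))
      n_im[runif(n) < config$p_missing_images] <- 0L
      sh <- beta_shapes(config$image_score_median[[group]], config$image_concentration)
      img <- split(rbeta(sum(n_im), sh[["shape1"]], sh[["shape2"]]),
                   rep.int(seq_len(n), n_im))
      image_scores <- rep(list(numeric(0)), n)
      image_scores[as.integer(names(img))] <- img
      followers <- as.integer(round(rlnorm(n, log(config$followers_median[[group]]), config$followers_sdlog)))
      friends <- as.integer(round(rlnorm(n, log(config$friends_median[[group]]), config$friends_sdlog)))
      favgiven <- as.integer(round(rlnorm(n, log(config$favorites_median[[group]]), config$favorites_sdlog)))
      statuses <- as.integer(ceiling(n_posts * config$statuses_multiplier * runif(n, 1, 1.3)))
      users <- tibble(
        user_id = uid, group = factor(group, group_levels),
        followers_count = followers,
        friends_count = friends,
        favorites_given = favgiven,
        n_posts = n_posts,
        statuses_total = statuses,
        image_scores = image_scores,
        no_spv_flag = no_spv
      )
      posts <- generate_group_posts(config, group, uid, n_posts, no_spv)
      users_list[[group]] <- users
      posts_list[[group]] <- posts
    }
    cohort <- list(users = dplyr::bind_rows(users_list),
                   posts = dplyr::bind_rows(posts_list),
                   config = config)
    class(cohort) <- "spv_cohort"
    cohort
  })
}

generate_group_posts <- function(config, group, uid, n_posts, no_spv) {
  total <- sum(n_posts)
  user_of_post <- rep.int(seq_along(uid), n_posts)
  lambda <- config$length_median[[group]] - 1
  n_units <- 1L + rpois(total, lambda)
  strata <- if (any(no_spv)) list(which(!no_spv[user_of_post]), which(no_spv[user_of_post])) else list(seq_len(total))
  tok_all <- vector("list", length(strata)); post_all <- vector("list", length(strata))
  for (s in seq_along(strata)) {
    posts_s <- strata[[s]]
    if (length(posts_s) == 0) next
    tab <- group_unit_table(config, group, mute_suicide = (s == 2))
    U <- sum(n_units[posts_s])
    unit_idx <- sample.int(length(tab$units), U, replace = TRUE, prob = tab$prob)
    ex <- expand_units(tab, unit_idx, rep.int(posts_s, n_units[posts_s]))
    tok_all[[s]] <- ex$tokens; post_all[[s]] <- ex$post
  }
  tok <- unlist(tok_all, use.names = FALSE)
  post_of_tok <- unlist(post_all, use.names = FALSE)
  ord <- order(post_of_tok)
  tok <- tok[ord]; post_of_tok <- post_of_tok[ord]
  created <- draw_timestamps(total, config, group)
  # chronological order within user; opaque ids follow that order
  ord_post <- order(user_of_post, created)
  rank_of <- integer(total); rank_of[ord_post] <- seq_len(total)
  new_post_id <- rank_of[post_of_tok]
  ord2 <- order(new_post_id)
  tokens_list <- split(tok[ord2], new_post_id[ord2])
  tokens_col <- rep(list(character(0)), total)
  tokens_col[as.integer(names(tokens_list))] <- tokens_list
  user_sorted <- user_of_post[ord_post]
  created_sorted <- created[ord_post]
  seq_in_user <- sequence(n_posts)
  raw <- collapse_posts(tok[ord2], new_post_id[ord2], total)
  tibble(
    user_id = uid[user_sorted],
    post_id = sprintf("%s_p%05d", uid[user_sorted], seq_in_user),
    created_at = created_sorted,
    tokens = tokens_col,
    raw_text = raw,
    retweet_count = rpois(total, 0.5),
    favorite_count = rpois(total, 1.2)
  )
}

#' @export
print.spv_cohort <- function(x, ...) {
  cat("<spv_cohort> ", nrow(x$users), " users, ", nrow(x$posts), " posts\n", sep = "")
  print(dplyr::count(x$users, .data$group))
  invisible(x)
}

#' Generate a labeled tweet-level training corpus
#'
#' Builds the training analog for the tweet-level short-profile-version
#' classifier: positive posts draw from the risk group's emission mixture
#' (suicide-lexicon phrase templates included), negatives from the generic
#' vocabulary. `separation` linearly interpolates the positive class's
#' emission rates between the generic-control distribution (0, a null corpus
#' with identical vocabularies) and the risk distribution (1, the default).
#'
#' @param config a [cohort_config()].
#' @param n_pos,n_neg posts per class.
#' @param seed integer seed.
#' @param separation contrast scale: 0 gives identical class vocabularies, 1
#'   the risk-group emission rates; values above 1 extrapolate the contrast
#'   (clamped at zero and renormalized) for a strongly separable corpus.
#' @return tibble of posts with a `class` factor
#'   (`suicide_related` / `control`).
#' @export
generate_tweet_corpus <- function(config = cohort_config(), n_pos = 500,
                                  n_neg = 500, seed = 1, separation = 1) {
  stopifnot(n_pos > 0, n_neg > 0, separation >= 0)
  with_seed(seed, {
    tab_risk <- group_unit_table(config, "risk")
    tab_gen <- group_unit_table(config, "generic_control")
    # shared unit list: identical between the tables by construction
    p_pos <- (1 - separation) * tab_gen$prob + separation * tab_risk$prob
    p_pos <- pmax(p_pos, 0)
    p_pos <- p_pos / sum(p_pos)
    n <- n_pos + n_neg
    cls <- rep(c("suicide_related", "control"), c(n_pos, n_neg))
    n_units <- 1L + rpois(n, 11)
    out_tok <- vector("list", 2); out_post <- vector("list", 2)
    for (s in 1:2) {
      posts_s <- which(cls == c("suicide_related", "control")[s])
      U <- sum(n_units[posts_s])
      prob <- if (s == 1) p_pos else tab_gen$prob
      unit_idx <- sample.int(length(tab_gen$units), U, replace = TRUE, prob = prob)
      ex <- expand_units(tab_gen, unit_idx, rep.int(posts_s, n_units[posts_s]))
      out_tok[[s]] <- ex$tokens; out_post[[s]] <- ex$post
    }
    tok <- unlist(out_tok, use.names = FALSE)
    post_of_tok <- unlist(out_post, use.names = FALSE)
    ord <- order(post_of_tok)
    tokens_list <- split(tok[ord], post_of_tok[ord])
    tokens_col <- rep(list(character(0)), n)
    tokens_col[as.integer(names(tokens_list))] <- tokens_list
    tibble(
      post_id = sprintf("c_%06d", seq_len(n)),
      created_at = draw_timestamps(n, config, "generic_control"),
      tokens = tokens_col,
      raw_text = collapse_posts(tok[ord], post_of_tok[ord], n),
      class = factor(cls, levels = c("suicide_related", "control"))
    )
  })
}

#' Serialize / load a cohort as JSONL
#'
#' One JSON object per line; timestamps are written as ISO-8601 UTC strings.
#'
#' @param cohort an `spv_cohort`.
#' @param users_path,posts_path output file paths.
#' @return `read_cohort_jsonl()` returns an `spv_cohort` (without a config).
#' @export
write_cohort_jsonl <- function(cohort, users_path, posts_path) {
  u <- cohort$users
  u$group <- as.character(u$group)
  writeLines(vapply(seq_len(nrow(u)), function(i) {
    jsonlite::toJSON(lapply(as.list(u[i, ]), function(col) {
      if (is.list(col)) col[[1]] else col
    }), auto_unbox = TRUE, digits = NA)
  }, ""), users_path)
  p <- cohort$posts
  iso <- format(p$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  writeLines(vapply(seq_len(nrow(p)), function(i) {
    jsonlite::toJSON(list(
      user_id = p$user_id[i], post_id = p$post_id[i], created_at = iso[i],
      tokens = p$tokens[[i]], raw_text = p$raw_text[i],
      retweet_count = p$retweet_count[i], favorite_count = p$favorite_count[i]
    ), auto_unbox = TRUE, digits = NA)
  }, ""), posts_path)
  invisible(c(users = users_path, posts = posts_path))
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(users_path, posts_path) {
  ul <- lapply(readLines(users_path, warn = FALSE), jsonlite::fromJSON)
  users <- dplyr::bind_rows(lapply(ul, function(x) {
    x$image_scores <- list(as.numeric(unlist(x$image_scores)))
    as_tibble(x)
  }))
  users$group <- factor(users$group, group_levels)
  pl <- lapply(readLines(posts_path, warn = FALSE), jsonlite::fromJSON)
  posts <- dplyr::bind_rows(lapply(pl, function(x) {
    tibble(user_id = x$user_id, post_id = x$post_id,
           created_at = as.POSIXct(x$created_at, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
           tokens = list(as.character(unlist(x$tokens))), raw_text = x$raw_text %||% "",
           retweet_count = x$retweet_count, favorite_count = x$favorite_count)
  }))
  structure(list(users = users, posts = posts, config = NULL), class = "spv_cohort")
}
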