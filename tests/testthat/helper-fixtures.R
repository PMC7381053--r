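# Shared fixtures, built once per test run and memoised.

.fix <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# small cohort configuration: study-group contrasts at reduced post volume
small_config <- function(...) {
  cohort_config(n_per_group = 20, tweets_median = c(250, 270, 70), seed = 7, ...)
}

fix_cohort <- function() memo("cohort", function() generate_cohort(small_config(), seed = 7))

fix_corpus <- function() memo("corpus", function() {
  generate_tweet_corpus(small_config(), n_pos = 300, n_neg = 300, seed = 1)
})

# separable corpus and its fitted SPV classifier (no CV, fast)
fix_spvc <- function() memo("spvc", function() train_spvc(fix_corpus(), cv_folds = 0))

fix_spv <- function() memo("spv", function() build_spv(fix_spvc(), fix_cohort()))

fix_snpsy <- function() memo("snpsy", function() assemble_snpsy(fix_cohort(), fix_spv()))

# posts tibble at given UTC timestamp strings
posts_at <- function(times, user_id = "u1") {
  tibble::tibble(
    user_id = user_id,
    post_id = sprintf("%s_p%03d", user_id, seq_along(times)),
    created_at = as.POSIXct(times, tz = "UTC"),
    tokens = replicate(length(times), c("hola", "mundo"), simplify = FALSE),
    raw_text = "hola mundo",
    retweet_count = 0L, favorite_count = 0L
  )
}

# brute-force STTR oracle: enumerate the 8 circular adjacent pair sums
sttr_oracle <- function(counts, total) {
  sums <- vapply(1:8, function(i) counts[i] + counts[if (i == 8) 1 else i + 1], 0)
  min(sums) / total
}

# rank-based AUC oracle used where an independent check is needed
auc_oracle <- function(pos_scores, neg_scores) {
  mean(outer(pos_scores, neg_scores, ">") + 0.5 * outer(pos_scores, neg_scores, "=="))
}
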