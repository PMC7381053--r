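#' Experiment configuration
#'
#' Collects every knob of an end-to-end run: the cohort generator
#' configuration, the tweet-corpus sizes for the SPV classifier, SPV
#' construction settings, the recipe and algorithm lists, screening levels,
#' the train fraction and the master seed. `screen_scope` controls whether
#' Mann-Whitney screening for the selected-features recipes sees training
#' rows only (`"train"`, the default, leakage-safe) or the whole task sample
#' (`"all"`, the permissive variant).
#'
#' @param cohort a [cohort_config()].
#' @param n_pos,n_neg tweet-corpus class sizes.
#' @param spvc_ngram_range,spvc_threshold,spv_k SPV classifier settings.
#' @param recipes recipe ids (see [model_recipes()]).
#' @param algorithms classifier families for [fit_select_evaluate()].
#' @param alphas screening levels of the two selected-features recipes.
#' @param tasks which control groups to run against.
#' @param train_frac stratified train fraction.
#' @param screen_scope `"train"` or `"all"`.
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return classed configuration list.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              n_pos = 500, n_neg = 500,
                              spvc_ngram_range = c(1, 5),
                              spvc_threshold = 0.5, spv_k = 15,
                              recipes = model_recipes()$recipe_id,
                              algorithms = c("rf", "mlp", "logistic", "svm"),
                              alphas = c(0.05, 0.001),
                              tasks = c("focused_control", "generic_control"),
                              train_frac = 0.7,
                              screen_scope = c("train", "all"),
                              seed = 1, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  screen_scope <- match.arg(screen_scope)
  bad <- setdiff(recipes, model_recipes()$recipe_id)
  if (length(bad) > 0) stop("unknown recipes: ", paste(bad, collapse = ", "))
  structure(list(cohort = cohort, n_pos = n_pos, n_neg = n_neg,
                 spvc_ngram_range = spvc_ngram_range,
                 spvc_threshold = spvc_threshold, spv_k = spv_k,
                 recipes = recipes, algorithms = algorithms, alphas = alphas,
                 tasks = tasks, train_frac = train_frac,
                 screen_scope = screen_scope, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Scalar fields override [experiment_config()] defaults; the `cohort` block
#' overrides [cohort_config()] defaults. A `lexicon` entry must name an
#' existing JSON lexicon file.
#'
#' @param path configuration file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cohort_args <- cfg$cohort %||% list()
  if (!is.null(cfg$lexicon)) {
    if (!file.exists(cfg$lexicon)) {
      stop("configuration error: field 'lexicon' names a missing file: ", cfg$lexicon)
    }
    cohort_args$lexicon <- read_lexicon(cfg$lexicon)
  }
  cohort <- do.call(cohort_config, cohort_args)
  args <- cfg[setdiff(names(cfg), c("cohort", "lexicon"))]
  args$cohort <- cohort
  do.call(experiment_config, args)
}

# stratified train/test split; returns logical train indicator
stratified_split <- function(y, train_frac, seed) {
  train <- logical(length(y))
  with_seed(seed, {
    for (lv in levels(as.factor(y))) {
      idx <- which(y == lv)
      n_tr <- round(train_frac * length(idx))
      train[sample(idx, n_tr)] <- TRUE
    }
  })
  train
}

#' Run the full screening experiment
#'
#' Executes the whole analysis on a synthetic cohort: generate the cohort and
#' tweet corpus, train the SPV classifier, build each user's SPV, extract
#' SNPSY features, fit user-level bag-of-words models, assemble every
#' configured feature-combination recipe, and evaluate each with the nested
#' cross-validation protocol against both control groups. Returns the
#' evaluation report (one row per recipe and task), the screening and
#' ranking tables, DeLong comparisons of every recipe against the
#' full-profile text baseline, and a reproducibility manifest.
#'
#' @param config an [experiment_config()], or a path to a YAML/JSON file.
#' @return object of class `spv_experiment`.
#' @export
run_experiment <- function(config = experiment_config()) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  t0 <- Sys.time()
  cohort <- generate_cohort(config$cohort, seed = child_seed(seed, 1))
  corpus <- generate_tweet_corpus(config$cohort, config$n_pos, config$n_neg,
                                  seed = child_seed(seed, 2))
  spvc <- train_spvc(corpus, ngram_range = config$spvc_ngram_range,
                     threshold = config$spvc_threshold,
                     seed = child_seed(seed, 3))
  spv <- build_spv(spvc, cohort, k = config$spv_k)
  lexicon <- config$cohort$lexicon
  snpsy_all <- assemble_snpsy(cohort, spv, lexicon = lexicon)
  docs_spv <- user_documents(cohort, spv, variant = "spv")
  docs_full <- user_documents(cohort, variant = "full_profile")
  tasks <- lapply(config$tasks, function(ctrl) {
    run_task(cohort, snpsy_all, docs_spv, docs_full, ctrl, config,
             seed = child_seed(seed, match(ctrl, config$tasks) * 1000))
  })
  names(tasks) <- config$tasks
  report <- dplyr::bind_rows(lapply(tasks, `[[`, "report"))
  out <- structure(list(
    report = report,
    screening = dplyr::bind_rows(lapply(tasks, `[[`, "screening")),
    rankings = dplyr::bind_rows(lapply(tasks, `[[`, "rankings")),
    delong = dplyr::bind_rows(lapply(tasks, `[[`, "delong")),
    tasks = tasks, spvc = spvc, spv = spv, cohort = cohort,
    config = config,
    manifest = NULL
  ), class = "spv_experiment")
  out$manifest <- experiment_manifest(out, t0)
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

run_task <- function(cohort, snpsy_all, docs_spv, docs_full, control_group,
                     config, seed) {
  users <- cohort$users %>%
    filter(.data$group %in% c("risk", control_group))
  ids <- users$user_id
  y <- factor(ifelse(users$group == "risk", "risk", "control"),
              levels = c("control", "risk"))
  train <- stratified_split(y, config$train_frac, seed = child_seed(seed, 1))
  sn <- snpsy_all[match(ids, snpsy_all$user_id), ]
  image_raw <- sn$image_score
  feat_cols <- setdiff(names(sn)[vapply(sn, is.numeric, TRUE)], "image_score")
  sn_feat <- sn[, feat_cols]
  imp_train <- impute_features(sn_feat[train, ])
  sn_imp <- impute_features(sn_feat, stats = attr(imp_train, "impute_stats"))
  snpsy_x <- as.matrix(sn_imp)
  rownames(snpsy_x) <- ids
  image_mean_train <- mean(image_raw[train], na.rm = TRUE)

  sel <- function(d) d[match(ids, d$user_id), ]
  docs <- list(bow_spv = sel(docs_spv), bow_full = sel(docs_full))
  bow_models <- lapply(docs, function(d) fit_user_bow(d[train, ]))
  bow_mats <- lapply(names(docs), function(nm) {
    m <- bow_models[[nm]]
    x <- Matrix::Matrix(0, length(ids), ncol(m$matrix),
                        dimnames = list(ids, colnames(m$matrix)), sparse = TRUE)
    x[train, ] <- m$matrix
    x[!train, ] <- bow_transform(m, docs[[nm]][!train, ])
    x
  })
  names(bow_mats) <- names(docs)

  oof_bow <- bow_outputted_feature(bow_mats$bow_spv[train, ], y[train],
                                   seed = child_seed(seed, 2))
  oof_snpsy <- bow_outputted_feature(snpsy_x[train, ], y[train],
                                     seed = child_seed(seed, 3))
  bow_oof_col <- numeric(length(ids))
  bow_oof_col[train] <- oof_bow$oof$prob
  bow_oof_col[!train] <- predict(oof_bow, bow_mats$bow_spv[!train, , drop = FALSE])
  snpsy_oof_col <- numeric(length(ids))
  snpsy_oof_col[train] <- oof_snpsy$oof$prob
  snpsy_oof_col[!train] <- predict(oof_snpsy, snpsy_x[!train, , drop = FALSE])

  img_for_pool <- ifelse(is.na(image_raw), image_mean_train, image_raw)
  pooled <- pooled_features(snpsy_x, bow_mats$bow_spv, img_for_pool)
  scr_rows <- if (config$screen_scope == "train") which(train) else seq_along(ids)
  screens <- lapply(config$alphas, function(a) {
    mannwhitney_screen(pooled[scr_rows, , drop = FALSE], y[scr_rows], alpha = a)
  })
  names(screens) <- paste0("alpha_", config$alphas)

  evals <- list(); delong <- list(); probs <- list()
  for (rid in config$recipes) {
    scr <- if (rid == "selected_1") screens[[1]] else if (rid == "selected_2") screens[[2]] else NULL
    dm <- build_design_matrix(
      rid,
      snpsy = snpsy_x,
      bow = if (rid == "bow_full") bow_mats$bow_full else bow_mats$bow_spv,
      bow_oof = bow_oof_col, snpsy_oof = snpsy_oof_col,
      image_score = image_raw, screen = scr, image_mean = image_mean_train
    )
    keep <- dm$rows
    tr_rows <- intersect(keep, which(train)); te_rows <- intersect(keep, which(!train))
    xk <- dm$x
    tr_idx <- match(tr_rows, keep); te_idx <- match(te_rows, keep)
    if (ncol(xk) == 0) next
    ev <- fit_select_evaluate(xk[tr_idx, , drop = FALSE], y[tr_rows],
                              xk[te_idx, , drop = FALSE], y[te_rows],
                              algorithms = config$algorithms,
                              seed = child_seed(seed, 10 + match(rid, config$recipes)))
    evals[[rid]] <- ev
    probs[[rid]] <- tibble(row = te_rows, prob = ev$prob_test)
  }
  report <- dplyr::bind_rows(lapply(names(evals), function(rid) {
    dplyr::bind_cols(tibble(task = paste0("risk_vs_", control_group), recipe = rid),
                     glance(evals[[rid]]))
  }))
  base_id <- intersect(c("bow_full", "bow_spv"), names(evals))[1]
  if (!is.na(base_id)) {
    for (rid in setdiff(names(evals), base_id)) {
      shared <- intersect(probs[[base_id]]$row, probs[[rid]]$row)
      if (length(shared) < 4) next
      pa <- probs[[rid]]$prob[match(shared, probs[[rid]]$row)]
      pb <- probs[[base_id]]$prob[match(shared, probs[[base_id]]$row)]
      yl <- y[shared]
      if (nlevels(droplevels(yl)) < 2) next
      dl <- suppressWarnings(delong_compare(pa, pb, yl))
      delong[[rid]] <- dplyr::bind_cols(
        tibble(task = paste0("risk_vs_", control_group), recipe = rid,
               baseline = base_id), dl)
    }
  }
  # feature relevance over the widest compact recipe (SNPSY + image + stacked BoW)
  dm2 <- build_design_matrix("images_bow_snpsy_2", snpsy = snpsy_x,
                             bow_oof = bow_oof_col, image_score = image_raw,
                             image_mean = image_mean_train)
  rankings <- dplyr::bind_rows(lapply(c("impurity", "class_correlation"), function(md) {
    rank_features(dm2$x[train, , drop = FALSE], y[train], mode = md,
                  seed = child_seed(seed, 99)) %>%
      mutate(task = paste0("risk_vs_", control_group), mode = md, .before = 1)
  }))
  list(report = report, evals = evals,
       screening = dplyr::bind_rows(lapply(names(screens), function(nm) {
         screens[[nm]] %>% mutate(task = paste0("risk_vs_", control_group),
                                  alpha = sub("alpha_", "", nm), .before = 1)
       })),
       rankings = rankings, delong = dplyr::bind_rows(delong),
       train = train, y = y, ids = ids, snpsy_x = snpsy_x,
       bow_oof = bow_oof_col, snpsy_oof = snpsy_oof_col, image = image_raw)
}

experiment_manifest <- function(exp, t0) {
  cfg <- exp$config
  list(
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    n_users = nrow(exp$cohort$users), n_posts = nrow(exp$cohort$posts),
    spvc_cv_f1 = mean(exp$spvc$cv$f1),
    artifact_hashes = list(
      report = rlang::hash(exp$report),
      screening = rlang::hash(exp$screening),
      rankings = rlang::hash(exp$rankings),
      cohort_users = rlang::hash(exp$cohort$users)
    )
  )
}

write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(exp$report, file.path(out_dir, "report.csv"), row.names = FALSE)
  utils::write.csv(exp$screening, file.path(out_dir, "screening.csv"), row.names = FALSE)
  if (!is.null(exp$rankings)) {
    utils::write.csv(exp$rankings, file.path(out_dir, "rankings.csv"), row.names = FALSE)
  }
  if (nrow(exp$delong %||% tibble()) > 0) {
    utils::write.csv(exp$delong, file.path(out_dir, "delong.csv"), row.names = FALSE)
  }
  jsonlite::write_json(exp$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.spv_experiment <- function(x, ...) {
  cat("<spv_experiment> seed", x$config$seed, "\n")
  print(x$report %>% select(dplyr::any_of(c("task", "recipe", "precision", "recall",
                                            "f1", "accuracy", "auc", "classifier"))))
  invisible(x)
}

#' Screen an unlabeled cohort with a fitted model
#'
#' Applies an evaluated recipe model to the feature rows of an unlabeled
#' cohort at the 0.5 decision threshold and reports the fraction predicted
#' positive (at risk) — the analysis performed on annotator-doubtful users.
#'
#' @param fit an `spv_eval`.
#' @param features matrix or tibble containing the model's feature columns.
#' @return fraction of rows predicted positive.
#' @export
doubtful_screen <- function(fit, features) {
  stopifnot(inherits(fit, "spv_eval"))
  x <- as.matrix(features)
  if (nrow(x) == 0) stop("empty cohort: no rows to screen")
  mean(predict(fit, x) > 0.5)
}
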