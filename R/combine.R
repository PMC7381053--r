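#' Feature-combination recipes
#'
#' The ten ways the pipeline combines its three feature families — user-level
#' bag-of-words (full-profile and SPV variants are the two text baselines),
#' the SNPSY bank, and the per-user image score. Stacked single-column
#' "outputted features" are out-of-fold predicted probabilities from the BoW
#' and SNPSY models. The two selected-features recipes keep the columns of
#' the pooled feature space that pass Mann-Whitney screening at their alpha.
#'
#' @return tibble describing each recipe.
#' @export
model_recipes <- function() {
  tibble(
    recipe_id = c("bow_full", "bow_spv", "snpsy", "bow_snpsy", "images_bow",
                  "images_snpsy", "images_bow_snpsy_1", "images_bow_snpsy_2",
                  "selected_1", "selected_2"),
    columns = c("BoW tf.idf terms (full profile)", "BoW tf.idf terms (SPV)",
                "SNPSY features", "SNPSY + BoW outputted feature",
                "BoW terms + image user score", "SNPSY + image user score",
                "image user score + BoW outputted + SNPSY outputted (3 columns)",
                "SNPSY + image user score + BoW outputted feature",
                "pooled features with screening P < .05",
                "pooled features with screening P < .001")
  )
}

#' Build a recipe's design matrix
#'
#' Assembles the user-by-feature matrix of one [model_recipes()] recipe.
#' Missing image scores are imputed with the cohort mean, except for the
#' 3-column ensemble recipe (`images_bow_snpsy_1`), where rows with a missing
#' score are removed instead.
#'
#' @param recipe_id recipe name (see [model_recipes()]).
#' @param snpsy numeric matrix of imputed SNPSY features.
#' @param bow sparse tf.idf user-term matrix.
#' @param bow_oof,snpsy_oof per-user out-of-fold probability columns.
#' @param image_score per-user image score, `NA` when missing.
#' @param screen a [mannwhitney_screen()] result over the pooled feature
#'   space (required by the selected-features recipes).
#' @param image_mean cohort mean used for imputation (defaults to the mean of
#'   the non-missing entries; pass the training-set mean when transforming
#'   held-out users).
#' @return list with `x` (matrix) and `rows` (kept row indices).
#' @export
build_design_matrix <- function(recipe_id, snpsy = NULL, bow = NULL,
                                bow_oof = NULL, snpsy_oof = NULL,
                                image_score = NULL, screen = NULL,
                                image_mean = NULL) {
  need <- function(arg, nm) if (is.null(arg)) stop("recipe ", recipe_id, " needs ", nm) else arg
  rows <- NULL
  if (!is.null(image_score)) {
    image_mean <- image_mean %||% mean(image_score, na.rm = TRUE)
    img_imp <- ifelse(is.na(image_score), image_mean, image_score)
  }
  x <- switch(recipe_id,
    bow_full = ,
    bow_spv = need(bow, "a bag-of-words matrix"),
    snpsy = need(snpsy, "the SNPSY table"),
    bow_snpsy = cbind(need(snpsy, "the SNPSY table"),
                      bow_outputted = need(bow_oof, "the BoW outputted feature")),
    images_bow = {
      b <- need(bow, "a bag-of-words matrix")
      xb <- cbind2(b, Matrix::Matrix(need(img_imp, "image scores"), ncol = 1, sparse = TRUE))
      colnames(xb) <- c(colnames(b), "image_score")
      xb
    },
    images_snpsy = cbind(need(snpsy, "the SNPSY table"), image_score = need(img_imp, "image scores")),
    images_bow_snpsy_1 = {
      rows <- which(!is.na(need(image_score, "image scores")))
      cbind(image_score = image_score,
            bow_outputted = need(bow_oof, "the BoW outputted feature"),
            snpsy_outputted = need(snpsy_oof, "the SNPSY outputted feature"))[rows, , drop = FALSE]
    },
    images_bow_snpsy_2 = cbind(need(snpsy, "the SNPSY table"),
                               image_score = need(img_imp, "image scores"),
                               bow_outputted = need(bow_oof, "the BoW outputted feature")),
    selected_1 = ,
    selected_2 = {
      scr <- need(screen, "a screening result")
      pooled <- pooled_features(snpsy, bow, img_imp)
      sel <- scr$feature[scr$selected]
      pooled[, colnames(pooled) %in% sel, drop = FALSE]
    },
    stop("unknown recipe: ", recipe_id)
  )
  rows <- rows %||% seq_len(nrow(x))
  list(x = x, rows = rows)
}

#' Pooled feature space for screening
#'
#' All feature types side by side: SNPSY columns, BoW terms and the image
#' score — the space over which the selected-features recipes screen.
#'
#' @inheritParams build_design_matrix
#' @return sparse matrix with named columns.
#' @export
pooled_features <- function(snpsy, bow, image_score) {
  sn <- Matrix::Matrix(as.matrix(snpsy), sparse = TRUE)
  out <- cbind2(cbind2(sn, bow), Matrix::Matrix(image_score, ncol = 1, sparse = TRUE))
  colnames(out) <- make.unique(c(colnames(snpsy), colnames(bow), "image_score"))
  rownames(out) <- rownames(snpsy)
  out
}

#' Mann-Whitney feature screening
#'
#' Two-sided Mann-Whitney U test of every feature between the two classes.
#' The exact null distribution is used when the combined sample size is at
#' most 20 and there are no ties; otherwise the tie-corrected normal
#' approximation. A feature is selected when `P <` `alpha`. Zero-variance
#' features yield `P = 1`, never an error.
#'
#' @param x matrix or data frame of features (rows = users).
#' @param labels binary factor.
#' @param alpha selection level.
#' @param compute_ovl also estimate the per-feature overlapping index of the
#'   two class distributions (slower).
#' @return tibble of class `spv_screen`: `feature`, `statistic` (U for the
#'   first class level), `p_value`, `selected`, and `ovl` when requested.
#' @export
mannwhitney_screen <- function(x, labels, alpha = 0.05, compute_ovl = FALSE) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (min(table(labels)) < 3) stop("need at least 3 observations per class")
  xm <- as_model_matrix(x)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("f", seq_len(ncol(xm)))
  ga <- labels == levels(labels)[1]
  res <- lapply(seq_len(ncol(xm)), function(j) {
    v <- as.numeric(xm[, j])
    a <- v[ga]; b <- v[!ga]
    if (var(v) == 0) {
      u <- length(a) * length(b) / 2; p <- 1
    } else {
      exact_ok <- (length(v) <= 20) && !any(duplicated(v))
      wt <- suppressWarnings(wilcox.test(a, b, exact = exact_ok, correct = TRUE))
      u <- unname(wt$statistic); p <- wt$p.value
      if (is.na(p) || is.nan(p)) p <- 1
    }
    ovl <- if (compute_ovl) overlap_index(a, b) else NA_real_
    tibble(feature = colnames(xm)[j], statistic = u, p_value = p, ovl = ovl)
  })
  out <- dplyr::bind_rows(res) %>% mutate(selected = .data$p_value < alpha)
  if (!compute_ovl) out$ovl <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "classes") <- levels(labels)
  class(out) <- c("spv_screen", class(out))
  out
}

#' Overlapping index of two samples
#'
#' The overlapping coefficient of the two empirical densities: Gaussian
#' kernel estimates with Silverman's bandwidth on a shared 512-point grid
#' spanning the pooled range plus 3 bandwidths, integrating the pointwise
#' minimum by the trapezoidal rule. 1 for identical distributions, 0 for
#' disjoint supports. Zero-variance samples fall back to a shared-bin
#' histogram estimate.
#'
#' @param a,b numeric samples (each of size at least 2).
#' @return overlap estimate in \[0, 1\].
#' @export
overlap_index <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 || sd(b) == 0) {
    rng <- range(c(a, b))
    if (diff(rng) == 0) return(1)
    breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 33)
    pa <- tabulate(findInterval(a, breaks, all.inside = TRUE), 32) / length(a)
    pb <- tabulate(findInterval(b, breaks, all.inside = TRUE), 32) / length(b)
    return(sum(pmin(pa, pb)))
  }
  bwa <- stats::bw.nrd0(a); bwb <- stats::bw.nrd0(b)
  h <- max(bwa, bwb)
  lo <- min(a, b) - 3 * h; hi <- max(a, b) + 3 * h
  da <- density(a, bw = bwa, from = lo, to = hi, n = 512)$y
  db <- density(b, bw = bwb, from = lo, to = hi, n = 512)$y
  y <- pmin(da, db)
  dx <- (hi - lo) / 511
  min(1, sum((y[-1] + y[-length(y)]) / 2) * dx)
}

#' Yeo-Johnson feature transform
#'
#' Per-column Yeo-Johnson power transform with centering and scaling, fitted
#' on training rows only and applied to any further matrix. Zero-variance
#' training columns are passed through centered at zero.
#'
#' @param train training matrix (rows = users).
#' @param ... further matrices to transform with the fitted parameters.
#' @return list of class `spv_transform`: `train`, one transformed matrix per
#'   `...` argument, and the fitted parameter object `pp`.
#' @export
transform_features <- function(train, ...) {
  train <- as.matrix(train)
  if (is.null(colnames(train))) colnames(train) <- paste0("f", seq_len(ncol(train)))
  sds <- apply(train, 2, sd)
  keep <- which(sds > 0)
  pp <- if (length(keep) > 0) {
    caret::preProcess(as.data.frame(train[, keep, drop = FALSE]),
                      method = c("YeoJohnson", "center", "scale"))
  } else NULL
  apply_pp <- function(m) {
    m <- as.matrix(m)
    out <- matrix(0, nrow(m), ncol(train), dimnames = list(rownames(m), colnames(train)))
    if (length(keep) > 0) {
      out[, keep] <- as.matrix(predict(pp, as.data.frame(m[, keep, drop = FALSE])))
    }
    out
  }
  extra <- lapply(list(...), apply_pp)
  structure(c(list(train = apply_pp(train), pp = pp,
                   zero_variance = setdiff(colnames(train), colnames(train)[keep])),
              extra),
            class = "spv_transform")
}

#' Classification metrics for the positive class
#'
#' Precision, recall, F1, accuracy (prediction positive when the probability
#' exceeds `threshold`) and the rank-based AUC, all referenced to the
#' positive class.
#'
#' @param truth factor of true labels.
#' @param prob positive-class probability per observation.
#' @param positive positive-class label.
#' @param threshold decision threshold.
#' @return one-row tibble: `precision`, `recall`, `f1`, `accuracy`, `auc`.
#' @export
classification_metrics <- function(truth, prob, positive = "risk",
                                   threshold = 0.5) {
  truth <- as.factor(truth)
  is_pos <- truth == positive
  m <- confusion_metrics(is_pos, prob > threshold)
  tibble(precision = m[["precision"]], recall = m[["recall"]], f1 = m[["f1"]],
         accuracy = mean((prob > threshold) == is_pos),
         auc = auc_rank(is_pos, prob, positive = "TRUE"))
}

#' DeLong comparison of two correlated ROC curves
#'
#' Tests the AUC difference of two score vectors for the same instances with
#' the DeLong variance estimate for paired ROC curves.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary factor.
#' @param positive positive-class label.
#' @return one-row tibble: `auc_a`, `auc_b`, `delta`, `p_value` (two-sided).
#' @export
delong_compare <- function(scores_a, scores_b, labels, positive = "risk") {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  neg <- setdiff(levels(labels), positive)
  ra <- pROC::roc(labels, scores_a, levels = c(neg, positive), direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, levels = c(neg, positive), direction = "<", quiet = TRUE)
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  tibble(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
         delta = as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
         p_value = tt$p.value)
}

#' Rank features by predictive relevance
#'
#' `impurity`: mean impurity (Gini) decrease across the trees of a random
#' forest. `class_correlation`: absolute point-biserial correlation of each
#' feature with the binary class. Constant features score 0 in both modes.
#'
#' @param x feature matrix.
#' @param labels binary factor.
#' @param mode ranking mode.
#' @param model optional pre-fitted `randomForest` (impurity mode).
#' @param seed seed for the forest fit.
#' @param ntree trees when fitting internally.
#' @return tibble `feature`, `score`, `rank`, ordered by descending score.
#' @export
rank_features <- function(x, labels, mode = c("impurity", "class_correlation"),
                          model = NULL, seed = 1, ntree = 500) {
  mode <- match.arg(mode)
  xm <- as.matrix(x)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("f", seq_len(ncol(xm)))
  labels <- droplevels(as.factor(labels))
  if (mode == "impurity") {
    if (is.null(model)) {
      model <- with_seed(seed, randomForest::randomForest(xm, labels, ntree = ntree))
    }
    imp <- randomForest::importance(model, type = 2)
    score <- setNames(as.numeric(imp), rownames(imp))[colnames(xm)]
    score[is.na(score)] <- 0
  } else {
    y <- as.numeric(labels == levels(labels)[2])
    score <- apply(xm, 2, function(v) if (sd(v) == 0) 0 else abs(cor(v, y)))
  }
  tibble(feature = colnames(xm), score = unname(score)) %>%
    arrange(dplyr::desc(.data$score)) %>%
    mutate(rank = dplyr::row_number())
}
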