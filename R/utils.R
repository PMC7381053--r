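#' @importFrom rlang %||% .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2
#' @importFrom stats median quantile plogis rbinom rpois rlnorm rbeta runif
#'   setNames density wilcox.test cor predict sd var
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All package randomness funnels through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible child seed (kept within 32-bit integer range).
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 1000003 + offset) %% 2147483647
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that class proportions are
#' preserved as closely as integer arithmetic allows.
#'
#' @param y binary label vector (factor or coercible).
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  y <- as.factor(y)
  if (k > min(table(y))) {
    k <- max(2L, min(table(y)))
    warning("reducing folds to smallest class count: k = ", k)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# Rank-based AUC of `scores` for the positive class (fast; ties averaged).
auc_rank <- function(labels, scores, positive = levels(as.factor(labels))[2]) {
  pos <- as.factor(labels) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# L2-normalize the rows of a sparse matrix (zero rows left untouched).
l2_normalize_rows <- function(x) {
  nrm <- sqrt(Matrix::rowSums(x^2))
  nrm[nrm == 0] <- 1
  out <- Matrix::Diagonal(x = 1 / nrm) %*% x
  dimnames(out) <- dimnames(x)
  out
}

safe_median <- function(x) if (length(x) == 0) NA_real_ else median(x)
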