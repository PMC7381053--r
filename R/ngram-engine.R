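# Word n-gram counting engine.
#
# Grams of order k are identified by integer prefix chains: the id of a k-gram
# is its position in the order-k dictionary, and the dictionary key of a k-gram
# is (prefix_id - 1) * (V + 1) + last_token_id, where prefix_id is the id of
# its (k-1)-gram prefix and V the unigram id-space size. Matching a stream
# against a dictionary is then a sequence of vectorized match() calls on
# numeric keys, which stays fast at millions of tokens. Document-frequency
# pruning uses the apriori property (a gram can only reach the floor if its
# prefix does), so dictionaries stay small at higher orders.

# Build dictionaries and a document-term count matrix from a token list.
# min_df is an absolute document count; terms below it are dropped (and never
# extended to higher orders).
ngram_fit <- function(token_list, orders = 1:5, min_df = 1L) {
  stopifnot(length(token_list) >= 1)
  kmax <- max(orders)
  doc <- rep.int(seq_along(token_list), lengths(token_list))
  tok <- unlist(token_list, use.names = FALSE)
  ndoc <- length(token_list)
  tokens <- sort(unique(tok))
  V <- length(tokens)
  if (V == 0) stop("no tokens in any document; cannot fit an n-gram model")
  ids <- match(tok, tokens)
  N <- length(ids)

  dicts <- vector("list", kmax)
  triplets_i <- list(); triplets_j <- list(); triplets_x <- list()
  df_list <- list()
  offset <- 0L
  n_terms <- integer(kmax)
  state <- NULL

  for (k in seq_len(kmax)) {
    if (k == 1L) {
      key <- as.numeric(ids)
      pos_doc <- doc
    } else {
      np <- N - k + 1L
      if (np < 1) break
      idx <- seq_len(np)
      prev <- state[idx]
      nxt <- ids[idx + k - 1L]
      ok <- !is.na(prev) & doc[idx] == doc[idx + k - 1L]
      key <- (prev - 1) * (V + 1) + nxt
      key[!ok] <- NA_real_
      pos_doc <- doc[idx]
    }
    keep_pos <- which(!is.na(key))
    if (length(keep_pos) == 0) {
      for (kk in k:kmax) {
        dicts[[kk]] <- numeric(0); n_terms[kk] <- 0L; df_list[[kk]] <- integer(0)
      }
      break
    }
    ukey <- sort(unique(key[keep_pos]))
    gid <- match(key, ukey)
    # document frequency per candidate gram
    pairkey <- (gid[keep_pos] - 1) * ndoc + pos_doc[keep_pos]
    upair <- unique(pairkey)
    dfk <- tabulate((upair - 1) %/% ndoc + 1, nbins = length(ukey))
    sel <- dfk >= min_df
    dict_k <- ukey[sel]
    dicts[[k]] <- dict_k
    df_list[[k]] <- dfk[sel]
    n_terms[k] <- length(dict_k)
    # remap state to pruned dictionary
    st <- match(key, dict_k)
    if (k %in% orders && length(dict_k) > 0) {
      ok2 <- which(!is.na(st))
      pk <- (st[ok2] - 1) * ndoc + pos_doc[ok2]
      cnt <- table_counts(pk)
      triplets_i[[k]] <- as.integer((cnt$key - 1) %% ndoc + 1)
      triplets_j[[k]] <- as.integer((cnt$key - 1) %/% ndoc + 1) + offset
      triplets_x[[k]] <- cnt$n
    }
    if (k %in% orders) offset <- offset + n_terms[k]
    state <- c(st, rep(NA_integer_, k - 1L))
    if (length(dict_k) == 0 || all(is.na(state))) {
      # nothing survives; higher orders cannot either
      if (k < kmax) {
        for (kk in (k + 1L):kmax) {
          dicts[[kk]] <- numeric(0); n_terms[kk] <- 0L; df_list[[kk]] <- integer(0)
        }
      }
      break
    }
  }

  total_terms <- offset
  if (total_terms == 0) stop("empty vocabulary after document-frequency filtering")
  dtm <- Matrix::sparseMatrix(
    i = unlist(triplets_i), j = unlist(triplets_j), x = unlist(triplets_x),
    dims = c(ndoc, total_terms)
  )
  eng <- list(tokens = tokens, V = V, dicts = dicts, orders = orders,
              n_terms = n_terms, n_docs = ndoc,
              df = unlist(df_list[orders[orders <= length(df_list)]]))
  eng$term_strings <- ngram_term_strings(eng)
  colnames(dtm) <- eng$term_strings
  list(engine = eng, dtm = dtm)
}

# Count occurrences of a fitted engine's vocabulary in new documents.
# Returns a sparse document x term matrix aligned with the fit's columns.
ngram_transform <- function(engine, token_list) {
  ndoc <- length(token_list)
  total_terms <- sum(engine$n_terms[engine$orders])
  if (ndoc == 0) return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(0, total_terms)))
  doc <- rep.int(seq_along(token_list), lengths(token_list))
  tok <- unlist(token_list, use.names = FALSE)
  ids <- match(tok, engine$tokens)
  N <- length(ids)
  V <- engine$V
  ti <- list(); tj <- list(); tx <- list()
  offset <- 0L
  state <- NULL
  kmax <- length(engine$dicts)
  for (k in seq_len(kmax)) {
    dict_k <- engine$dicts[[k]]
    if (k == 1L) {
      key <- as.numeric(ids)
      pos_doc <- doc
    } else {
      np <- N - k + 1L
      if (np < 1 || is.null(dict_k) || length(dict_k) == 0 || is.null(state)) { state <- NULL; if (k %in% engine$orders) offset <- offset + engine$n_terms[k]; next }
      idx <- seq_len(np)
      prev <- state[idx]
      nxt <- ids[idx + k - 1L]
      ok <- !is.na(prev) & !is.na(nxt) & doc[idx] == doc[idx + k - 1L]
      key <- (prev - 1) * (V + 1) + nxt
      key[!ok] <- NA_real_
      pos_doc <- doc[idx]
    }
    st <- match(key, dict_k)
    okp <- which(!is.na(st))
    if (k %in% engine$orders && length(okp) > 0) {
      pk <- (st[okp] - 1) * ndoc + pos_doc[okp]
      cnt <- table_counts(pk)
      ti[[k]] <- as.integer((cnt$key - 1) %% ndoc + 1)
      tj[[k]] <- as.integer((cnt$key - 1) %/% ndoc + 1) + offset
      tx[[k]] <- cnt$n
    }
    if (k %in% engine$orders) offset <- offset + engine$n_terms[k]
    state <- c(st, rep(NA_integer_, k - 1L))
  }
  dtm <- Matrix::sparseMatrix(i = unlist(ti) %||% integer(0), j = unlist(tj) %||% integer(0),
                              x = unlist(tx) %||% numeric(0),
                              dims = c(ndoc, total_terms))
  colnames(dtm) <- engine$term_strings
  dtm
}

# Frequency table of a numeric key vector, returned as (key, n).
table_counts <- function(key) {
  ukey <- sort(unique(key))
  n <- tabulate(match(key, ukey), nbins = length(ukey))
  list(key = ukey, n = n)
}

# Reconstruct human-readable gram strings from the prefix-chain dictionaries.
ngram_term_strings <- function(engine) {
  V <- engine$V
  strings_by_order <- vector("list", length(engine$dicts))
  out <- character(0)
  for (k in seq_along(engine$dicts)) {
    dict_k <- engine$dicts[[k]]
    if (is.null(dict_k) || length(dict_k) == 0) { strings_by_order[[k]] <- character(0); next }
    if (k == 1L) {
      s <- engine$tokens[dict_k]
    } else {
      prefix <- (dict_k - 1) %/% (V + 1) + 1
      last <- dict_k - (prefix - 1) * (V + 1)
      s <- paste(strings_by_order[[k - 1]][prefix], engine$tokens[last])
    }
    strings_by_order[[k]] <- s
    if (k %in% engine$orders) out <- c(out, s)
  }
  out
}

# Smoothed idf (log((1+n)/(1+df)) + 1) fitted from a count matrix.
idf_fit <- function(dtm) {
  n <- nrow(dtm)
  df <- Matrix::colSums(dtm > 0)
  log((1 + n) / (1 + df)) + 1
}

# tf.idf weighting with L2 row normalization.
tfidf_apply <- function(dtm, idf) {
  w <- dtm %*% Matrix::Diagonal(x = idf)
  dimnames(w) <- dimnames(dtm)
  l2_normalize_rows(w)
}
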