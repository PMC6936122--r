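# RReliefF (regressional ReliefF) attribute importance. Each feature F_i
# receives the weight
#   W(F_i) = P(diff F | diff y) P(diff F) / P(diff y)
#          - (1 - P(diff F | diff y)) P(diff F) / (1 - P(diff y)),
# with the probabilities approximated by exponentially rank-weighted
# accumulation over each instance's k nearest neighbors. Features that track
# the response get positive weights; irrelevant features drift toward 0.

#' Read an RBP feature table
#'
#' Tab-separated with a header; the first column holds RBP names, one column
#' (named by `response`) holds the response (median conservation percent per
#' RBP) and every remaining column is a numeric predictor.
#'
#' @param path path to the TSV (plain or gzip).
#' @param text optional character vector of TSV text.
#' @param response name of the response column (default `"response"`).
#' @return list with `rbp` (names), `y` (response vector) and `x` (numeric
#'   predictor matrix with feature column names).
#' @export
read_feature_table <- function(path = NULL, text = NULL,
                               response = "response") {
  df <- read.table(text = io_lines(path, text), sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, quote = "", check.names = FALSE)
  if (!response %in% names(df))
    stop("response column '", response, "' not found", call. = FALSE)
  x <- as.matrix(df[, setdiff(names(df)[-1], response), drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x) || anyNA(df[[response]]))
    stop("feature table must be complete (no missing values)",
         call. = FALSE)
  list(rbp = as.character(df[[1]]), y = as.numeric(df[[response]]), x = x)
}

# Min-max normalize columns to [0,1]; zero-range columns become all-zero so
# their diffs (and hence their weights) are exactly 0.
minmax <- function(x) {
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  sweep(sweep(x, 2, rng[1, ]), 2, span, "/") *
    rep(ifelse(rng[2, ] - rng[1, ] == 0, 0, 1), each = nrow(x))
}

#' RReliefF attribute importance for a numeric response
#'
#' For each sampled instance, its `k` nearest neighbors (Manhattan distance
#' over min-max-normalized predictors, distance ties broken by row order)
#' contribute feature and response differences with exponential rank weights
#' `exp(-(rank/sigma)^2)` normalized to sum 1; the accumulated probabilities
#' yield the weight of each feature.
#'
#' @param x numeric matrix or data.frame of predictors (RBP rows, feature
#'   columns).
#' @param y numeric response (median conservation percent per RBP).
#' @param k number of nearest neighbors (default 10; must be < number of
#'   rows).
#' @param m number of instances to sample, or `"all"` (the default) to use
#'   every instance once, which makes the result deterministic.
#' @param sigma rank-weighting scale (default 20).
#' @param seed seed for instance sampling (only used when `m != "all"`).
#' @return a `feature_weights` object: list with `weights` (named numeric),
#'   `rank` (feature names by descending weight) and `parameters`.
#' @export
rrelieff <- function(x, y, k = 10, m = "all", sigma = 20, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("F", seq_len(ncol(x)))
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (n < 2) stop("need at least 2 instances", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of rows",
                   call. = FALSE)
  y_range <- diff(range(y))
  if (y_range == 0) stop("zero-variance response", call. = FALSE)

  xn <- minmax(x)
  idx <- if (identical(m, "all")) seq_len(n) else {
    if (!is.numeric(m) || m < 1 || m > n)
      stop("m must be 'all' or a count <= nrow(x)", call. = FALSE)
    with_seed(seed, sample.int(n, m))
  }

  w_rank <- exp(-(seq_len(k) / sigma)^2)
  w_rank <- w_rank / sum(w_rank)

  n_dy <- 0
  n_df <- numeric(ncol(x))
  n_dy_df <- numeric(ncol(x))
  for (i in idx) {
    d <- rowSums(abs(xn - rep(xn[i, ], each = n)))
    ord <- order(d[-i])                 # ties: row order, deterministic
    nb <- seq_len(n)[-i][ord][seq_len(k)]
    d_y <- abs(y[i] - y[nb]) / y_range
    d_f <- abs(xn[nb, , drop = FALSE] - rep(xn[i, ], each = k))
    n_dy <- n_dy + sum(w_rank * d_y)
    n_df <- n_df + colSums(w_rank * d_f)
    n_dy_df <- n_dy_df + colSums((w_rank * d_y) * d_f)
  }
  m_used <- length(idx)
  weights <- n_dy_df / n_dy - (n_df - n_dy_df) / (m_used - n_dy)
  names(weights) <- colnames(x)
  structure(list(
    weights = weights,
    rank = names(sort(weights, decreasing = TRUE)),
    parameters = list(k = k, m = m, sigma = sigma,
                      distance = "manhattan/minmax")
  ), class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat("RReliefF feature weights (k =", x$parameters$k, ", sigma =",
      x$parameters$sigma, "):\n")
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}

#' Shuffle robustness of RReliefF feature ranks
#'
#' Permutes one feature column at a time (`n_shuffles` independent
#' permutations, other columns fixed), reruns [rrelieff()], and summarises
#' where the shuffled feature lands in the ranking. Features whose median
#' post-shuffle rank falls into the bottom third are flagged rank-critical:
#' their standing depends on their actual values, not on distributional
#' accidents.
#'
#' @inheritParams rrelieff
#' @param n_shuffles number of permutations per feature (> 0).
#' @param seed seed for the permutations.
#' @return data.frame with columns `feature`, `original_rank`,
#'   `median_shuffled_rank`, `rank_critical`.
#' @export
shuffle_robustness <- function(x, y, k = 10, m = "all", sigma = 20,
                               n_shuffles = 25, seed = NULL) {
  if (!is.numeric(n_shuffles) || n_shuffles < 1)
    stop("n_shuffles must be a positive integer", call. = FALSE)
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("F", seq_len(ncol(x)))
  base <- rrelieff(x, y, k, m, sigma)
  orig_rank <- match(colnames(x), base$rank)
  n_feat <- ncol(x)
  bottom <- n_feat - ceiling(n_feat / 3) + 1  # bottom-third threshold
  med_rank <- numeric(n_feat)
  with_seed(seed, {
    for (f in seq_len(n_feat)) {
      ranks <- vapply(seq_len(n_shuffles), function(s) {
        xs <- x
        xs[, f] <- sample(xs[, f])
        match(colnames(x)[f], rrelieff(xs, y, k, m, sigma)$rank)
      }, 0)
      med_rank[f] <- median(ranks)
    }
  })
  data.frame(feature = colnames(x), original_rank = orig_rank,
             median_shuffled_rank = med_rank,
             rank_critical = orig_rank < bottom & med_rank >= bottom,
             stringsAsFactors = FALSE)
}

#' Simple regression of the response on one feature
#'
#' Ordinary least-squares regression of the response (median conservation
#' percent) on a single named feature, e.g. the number of binding sites.
#'
#' @inheritParams rrelieff
#' @param feature name of the predictor column.
#' @return list with `slope`, `intercept`, `p.value` (t test on the slope)
#'   and the underlying `lm` fit.
#' @export
regress_response_on_feature <- function(x, y, feature) {
  x <- as.matrix(x)
  if (!feature %in% colnames(x))
    stop("feature '", feature, "' not found", call. = FALSE)
  v <- x[, feature]
  if (length(v) < 3) stop("need at least 3 rows", call. = FALSE)
  if (diff(range(v)) == 0)
    stop("zero-variance feature '", feature, "'", call. = FALSE)
  fit <- lm(y ~ v)
  s <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p.value = unname(s[2, 4]), fit = fit)
}
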