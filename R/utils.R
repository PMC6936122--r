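#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile wilcox.test chisq.test lm coef pnorm
#'   runif rnorm setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom GenomicRanges GRanges findOverlaps seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom ape read.tree cophenetic.phylo rtree write.tree
#' @importFrom tools md5sum
NULL

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a base seed, staying < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1103L + as.double(stream) * 12289L) %% 2147483587
}

#' Two-sided Mann-Whitney U test (tie-corrected normal approximation)
#'
#' Internal fast path used inside permutation loops, where calling
#' [stats::wilcox.test()] thousands of times would dominate runtime. Uses the
#' rank-sum statistic with the standard tie correction of the variance and a
#' 0.5 continuity correction, i.e. the same large-sample p-value that
#' `wilcox.test(x, y, exact = FALSE)` reports.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with elements `statistic` (the Mann-Whitney U of `x`) and
#'   `p.value` (two-sided).
#' @keywords internal
mann_whitney_u <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0L, ny > 0L)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  n <- nx + ny
  ties <- table(r)
  sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p.value = 1))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = u, p.value = min(1, 2 * pnorm(-abs(z))))
}

# Write a headered TSV deterministically (no quoting, no row names).
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "", ...)
}
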