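# Score-weighted permutation gene-set enrichment: conservation-weighted
# binding sites -> per-gene scores (median P) -> per-set permutation
# Mann-Whitney tests -> corrected p-value
#   max(1 - #significant tests / #total tests, 1 / #total tests).

#' Aggregate site conservation scores to gene scores
#'
#' Each gene's score is the median P of its binding sites; a site mapping to
#' several genes contributes its P to each of them. Genes with no scored
#' site are absent from the table.
#'
#' @param records data.frame of mapped sites with a `P` column and a `name`
#'   column identifying each site; unmapped rows (NA P) are ignored.
#' @param site_to_gene data.frame mapping site `name` to gene `symbol`
#'   (one row per site-gene link, so multi-gene sites appear on several
#'   rows).
#' @return named numeric vector of gene scores in [0, 100]; the names form
#'   the scored-gene universe.
#' @export
gene_scores <- function(records, site_to_gene) {
  if (!nrow(site_to_gene)) stop("empty site-to-gene mapping", call. = FALSE)
  stopifnot(all(c("name", "symbol") %in% names(site_to_gene)))
  records <- records[!is.na(records$P), , drop = FALSE]
  merged <- merge(records[c("name", "P")], site_to_gene, by = "name")
  if (!nrow(merged)) return(setNames(numeric(0), character(0)))
  tapply(merged$P, merged$symbol, median)[]
}

#' Permutation enrichment of one gene set against gene conservation scores
#'
#' Repeats `n_perm` times: draw |overlap| genes uniformly without
#' replacement from the scored-gene universe (excluding the overlap by
#' default) and compare the overlap's scores against the drawn genes'
#' scores with a two-sided Mann-Whitney U test. A permutation counts as
#' significant when p < `alpha` and the overlap's median exceeds the drawn
#' median (enrichment looks for *highly* conserved sets). The corrected
#' p-value is `max(1 - n_significant/n_perm, 1/n_perm)`.
#'
#' @param scores named numeric vector from [gene_scores()].
#' @param gene_set a gene set (list with `name` and `genes`, as from
#'   [read_gmt()]).
#' @param n_perm number of permutations (default 1000).
#' @param alpha per-permutation significance level (default 0.05).
#' @param seed seed making the permutation draws reproducible.
#' @param min_overlap minimum overlap with the universe for the set to be
#'   evaluated (default 3).
#' @param exclude_overlap draw random genes from the universe minus the
#'   overlap (default `TRUE`); set `FALSE` to draw from the whole universe.
#' @return an `enrichment_result`: list with `set_name`, `overlap_genes`,
#'   `overlap_size`, `n_significant`, `n_total`, `corrected_p`, `status`
#'   (`"ok"`, `"empty_overlap"` or `"below_min_overlap"`).
#' @export
enrich <- function(scores, gene_set, n_perm = 1000, alpha = 0.05,
                   seed = NULL, min_overlap = 3, exclude_overlap = TRUE) {
  stopifnot(n_perm >= 1)
  universe <- names(scores)
  overlap <- intersect(gene_set$genes, universe)
  skipped <- function(status) structure(list(
    set_name = gene_set$name, overlap_genes = overlap,
    overlap_size = length(overlap), n_significant = NA_integer_,
    n_total = n_perm, corrected_p = NA_real_, status = status),
    class = "enrichment_result")
  if (!length(overlap)) return(skipped("empty_overlap"))
  if (length(overlap) < min_overlap) return(skipped("below_min_overlap"))
  pool <- if (exclude_overlap) setdiff(universe, overlap) else universe
  if (length(pool) < length(overlap)) {
    warning("universe too small to draw ", length(overlap),
            " non-overlap genes; drawing from the full universe",
            call. = FALSE)
    pool <- universe
  }
  if (length(universe) < 2 * length(overlap))
    warning("universe smaller than twice the overlap; permutation draws ",
            "are heavily constrained", call. = FALSE)
  ov_scores <- scores[overlap]
  ov_median <- median(ov_scores)
  pool_scores <- scores[pool]
  n_sig <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      drawn <- pool_scores[sample.int(length(pool_scores),
                                      length(overlap))]
      mw <- mann_whitney_u(ov_scores, drawn)
      mw$p.value < alpha && ov_median > median(drawn)
    }, NA))
  })
  structure(list(
    set_name = gene_set$name, overlap_genes = overlap,
    overlap_size = length(overlap), n_significant = n_sig,
    n_total = n_perm,
    corrected_p = max(1 - n_sig / n_perm, 1 / n_perm), status = "ok"),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment '%s': overlap %d, %s/%d significant tests, corrected p = %s [%s]\n",
              x$set_name, x$overlap_size,
              ifelse(is.na(x$n_significant), "NA", x$n_significant),
              x$n_total,
              ifelse(is.na(x$corrected_p), "NA",
                     format(x$corrected_p, digits = 3)), x$status))
  invisible(x)
}

#' Enrichment of a whole gene-set collection
#'
#' Evaluates every set with an independent seeded permutation stream and
#' ranks the results ascending by corrected p-value, ties broken by
#' descending overlap size. Sets with empty or sub-threshold overlap are
#' kept with their skip status and sort last.
#'
#' @inheritParams enrich
#' @param collection named list of gene sets (from [read_gmt()]).
#' @return data.frame with columns `set`, `overlap_size`, `n_significant`,
#'   `n_total`, `corrected_p`, `significant` (corrected p < 0.05),
#'   `status`; plus attribute `"results"` holding the full
#'   `enrichment_result` objects in the same order.
#' @export
enrich_collection <- function(scores, collection, n_perm = 1000,
                              alpha = 0.05, seed = 1, min_overlap = 3,
                              exclude_overlap = TRUE) {
  if (!length(collection))
    return(data.frame(set = character(), overlap_size = integer(),
                      n_significant = integer(), n_total = integer(),
                      corrected_p = numeric(), significant = logical(),
                      status = character(), stringsAsFactors = FALSE))
  results <- lapply(seq_along(collection), function(i) {
    enrich(scores, collection[[i]], n_perm, alpha,
           seed = child_seed(seed, i), min_overlap, exclude_overlap)
  })
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(set = r$set_name, overlap_size = r$overlap_size,
               n_significant = r$n_significant, n_total = r$n_total,
               corrected_p = r$corrected_p,
               significant = !is.na(r$corrected_p) && r$corrected_p < 0.05,
               status = r$status, stringsAsFactors = FALSE)
  }))
  o <- order(is.na(df$corrected_p), df$corrected_p, -df$overlap_size)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "results") <- results[o]
  df
}
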