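# Core conservation statistic: map binding sites to MAF blocks and compute
# the percentage of aligned species each site is conserved in,
#   P = (N / totalSpecies) * 100,
# where N is the number of distinct species with a row in the site's block.

#' Build an interval index over MAF block reference spans
#'
#' @param blocks list of `maf_block` objects from [read_maf()] (one or more
#'   chromosomes may be mixed).
#' @return a `block_index` object supporting containment lookup of sites.
#' @details A site maps to a block only when it is fully contained in the
#'   block's reference span. Lookup is backed by
#'   [GenomicRanges::findOverlaps()] with `type = "within"`.
#' @export
index_blocks <- function(blocks) {
  if (!length(blocks)) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = vapply(blocks, `[[`, "", "ref_chrom"),
      ranges = IRanges::IRanges(
        # GRanges are 1-based closed; block spans are 0-based half-open
        start = vapply(blocks, `[[`, 0, "ref_start") + 1L,
        end = vapply(blocks, `[[`, 0, "ref_end")))
  }
  structure(list(
    gr = gr,
    blocks = blocks,
    score = vapply(blocks, `[[`, 0, "score"),
    ref_start = vapply(blocks, `[[`, 0, "ref_start"),
    n_species = vapply(blocks, function(b) length(unique(b$rows$species)),
                       0L),
    species = lapply(blocks, function(b) unique(b$rows$species))
  ), class = "block_index")
}

#' @export
print.block_index <- function(x, ...) {
  cat("block_index:", length(x$blocks), "MAF blocks on",
      length(unique(as.character(GenomicRanges::seqnames(x$gr)))),
      "chromosome(s)\n")
  invisible(x)
}

# For each site (0-based half-open), the id of the selected containing block,
# or NA. Among multiple containing blocks: highest score, then lowest
# ref_start.
select_blocks <- function(sites, index) {
  sel <- rep(NA_integer_, nrow(sites))
  if (!nrow(sites) || !length(index$blocks)) return(sel)
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$start + 1L, sites$end))
  # sites on chromosomes absent from the index are simply unmapped
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, index$gr, type = "within"))
  if (!length(hits)) return(sel)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # order hits so the preferred block comes first within each query
  o <- order(qh, -index$score[sh], index$ref_start[sh], sh)
  keep <- !duplicated(qh[o])
  sel[qh[o][keep]] <- sh[o][keep]
  sel
}

#' Map binding sites to MAF blocks and compute conservation percentages
#'
#' A site maps only when fully contained in a single block's reference span;
#' sites straddling block boundaries (or on unindexed chromosomes) are
#' unmapped. When several blocks contain a site, the block with the highest
#' alignment score is selected (ties: lowest reference start). N counts
#' distinct species in the selected block, the reference included.
#'
#' @param sites data.frame of intervals as returned by [read_bed()].
#' @param index a `block_index` from [index_blocks()].
#' @param total_species total number of species in the alignment (the
#'   denominator of P; 46 for the UCSC 46-way vertebrate alignment).
#' @return data.frame: the site columns plus `mapped` (logical), `block_id`
#'   (integer index into the block store, NA when unmapped), `n_species`
#'   (N; NA when unmapped) and `P` (percent in [0, 100]; NA when unmapped).
#' @export
map_sites <- function(sites, index, total_species = 46) {
  if (!is.numeric(total_species) || total_species < 1)
    stop("total_species must be >= 1", call. = FALSE)
  sel <- select_blocks(sites, index)
  n <- ifelse(is.na(sel), NA_integer_, index$n_species[sel])
  out <- sites
  out$mapped <- !is.na(sel)
  out$block_id <- sel
  out$n_species <- n
  out$P <- (n / total_species) * 100
  out
}

#' Map a single binding site
#'
#' Convenience single-site wrapper around [map_sites()].
#'
#' @param chrom,start,end site coordinates (0-based half-open).
#' @inheritParams map_sites
#' @return list with `mapped`, `block_id`, `n_species`, `P`, and
#'   `species_set` (character vector of species in the selected block,
#'   `NULL` when unmapped).
#' @export
map_site <- function(chrom, start, end, index, total_species = 46) {
  rec <- map_sites(data.frame(chrom = chrom, start = start, end = end,
                              stringsAsFactors = FALSE),
                   index, total_species)
  list(mapped = rec$mapped, block_id = rec$block_id,
       n_species = rec$n_species, P = rec$P,
       species_set = if (rec$mapped) index$species[[rec$block_id]] else NULL)
}

#' Conservation profile of one RBP's binding sites
#'
#' Maps all of one RBP's sites and summarises the conservation distribution.
#' Unmapped sites are excluded from the distribution and reported as a count
#' (set `unmapped_as_zero = TRUE` to instead score them P = 0).
#'
#' @param sites data.frame of the RBP's binding sites ([read_bed()]).
#' @inheritParams map_sites
#' @param rbp_name name attached to the profile.
#' @param unmapped_as_zero include unmapped sites as P = 0 instead of
#'   excluding them (default `FALSE`).
#' @return a `conservation_profile`: list with `rbp`, `records` (the
#'   [map_sites()] data.frame), `total_species`, `n_mapped`, `n_unmapped`,
#'   `median_P` and `quartiles` (NA when nothing is mapped).
#' @export
profile_rbp <- function(sites, index, total_species = 46, rbp_name = "RBP",
                        unmapped_as_zero = FALSE) {
  records <- map_sites(sites, index, total_species)
  p <- records$P
  if (unmapped_as_zero) p[is.na(p)] <- 0 else p <- p[!is.na(p)]
  prof <- structure(list(
    rbp = rbp_name,
    records = records,
    total_species = total_species,
    n_mapped = sum(records$mapped),
    n_unmapped = sum(!records$mapped),
    median_P = if (length(p)) median(p) else NA_real_,
    quartiles = if (length(p)) quantile(p, c(.25, .5, .75), names = FALSE)
                else rep(NA_real_, 3)
  ), class = "conservation_profile")
  if (prof$n_mapped == 0L)
    attr(prof, "no_mapped_sites") <- TRUE
  prof
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("conservation_profile '%s': %d sites (%d mapped, %d unmapped), median P = %s\n",
              x$rbp, nrow(x$records), x$n_mapped, x$n_unmapped,
              ifelse(is.na(x$median_P), "NA", sprintf("%.1f", x$median_P))))
  invisible(x)
}

# Mapped P values of a profile.
mapped_P <- function(profile) {
  profile$records$P[profile$records$mapped]
}

#' Per-species presence matrix across RBPs
#'
#' For each RBP (row) and species (column), the percentage of the RBP's
#' mapped binding sites whose MAF block contains at least one row for that
#' species. The reference species column is 100 for any RBP with mapped
#' sites. This presence-fraction matrix is the heatmap used to contrast
#' clades (e.g. mammals vs lower vertebrates).
#'
#' @param profiles list of `conservation_profile` objects.
#' @param index the `block_index` the profiles were mapped against.
#' @return numeric matrix, RBP rows x species columns, values in [0, 100].
#' @export
species_presence_matrix <- function(profiles, index) {
  all_species <- sort(unique(unlist(index$species)))
  m <- matrix(0, nrow = length(profiles), ncol = length(all_species),
              dimnames = list(vapply(profiles, `[[`, "", "rbp"),
                              all_species))
  for (i in seq_along(profiles)) {
    ids <- profiles[[i]]$records$block_id
    ids <- ids[!is.na(ids)]
    if (!length(ids)) next
    counts <- table(factor(unlist(index$species[ids]), levels = all_species))
    m[i, ] <- 100 * as.numeric(counts) / length(ids)
  }
  m
}

# Exact conditional two-sided rank-sum p-value in the presence of ties:
# enumerates (by dynamic programming over doubled midranks) the null
# distribution of the smaller group's rank sum over all subsets of that
# size, i.e. the exact permutation distribution conditional on the observed
# tie pattern. Two-sided p = min(1, 2 * min(lower tail, upper tail)).
exact_ranksum_p <- function(x, y) {
  if (length(y) < length(x)) { tmp <- x; x <- y; y <- tmp }
  k <- length(x)
  r2 <- as.integer(round(2 * rank(c(x, y))))  # doubled midranks: integers
  w2 <- sum(r2[seq_len(k)])
  cols <- sum(r2) + 1L
  f <- matrix(0, k + 1L, cols)
  f[1L, 1L] <- 1
  for (i in seq_along(r2)) {
    v <- r2[i]
    for (j in seq(min(i, k), 1L)) {
      idx <- seq_len(cols - v)
      f[j + 1L, idx + v] <- f[j + 1L, idx + v] + f[j, idx]
    }
  }
  dist <- f[k + 1L, ]
  total <- sum(dist)
  pl <- sum(dist[seq_len(w2 + 1L)]) / total
  pu <- sum(dist[seq(w2 + 1L, cols)]) / total
  min(1, 2 * min(pl, pu))
}

#' Two-sided Wilcoxon rank-sum comparison of two conservation distributions
#'
#' Used for mammal vs lower-vertebrate presence values, RBP vs random-region
#' P distributions, and RBP-pair comparisons. Small samples (both groups
#' <= 50) are tested exactly — via the standard exact distribution when
#' there are no ties, or by exact enumeration of the conditional permutation
#' distribution (dynamic programming over midranks) when there are; larger
#' samples use the tie-corrected normal approximation.
#'
#' @param values_a,values_b numeric vectors of percent values, non-empty.
#' @return list with `statistic` (Mann-Whitney W), `p.value`, `method`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty", call. = FALSE)
  small <- length(values_a) <= 50 && length(values_b) <= 50
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  ht <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided",
                exact = small))
  if (small && ties)
    return(list(statistic = unname(ht$statistic),
                p.value = exact_ranksum_p(values_a, values_b),
                method = "Exact rank-sum test (tie-conditional enumeration)"))
  p <- ht$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(ht$statistic), p.value = p, method = ht$method)
}
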