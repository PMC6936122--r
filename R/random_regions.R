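# Random-region conservation nulls: sample fixed-length regions uniformly
# from an annotation space (whole chromosomes, exons, introns or coding
# spans) and score them with the same conservation machinery as real sites.

#' Define a sampleable annotation space
#'
#' @param region_type one of `"genomic"`, `"exonic"`, `"intronic"`,
#'   `"coding"` (a label; sampling is identical across types).
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) describing the sampleable territory. For `"genomic"` pass
#'   whole chromosomes.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return an `annotation_space` object.
#' @export
annotation_space <- function(region_type = c("genomic", "exonic", "intronic",
                                             "coding"),
                             intervals, chrom_sizes) {
  region_type <- match.arg(region_type)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(intervals$end > intervals$start))
  known <- intervals$chrom %in% names(chrom_sizes)
  if (!all(known))
    stop("interval chromosome(s) absent from chrom_sizes: ",
         paste(unique(intervals$chrom[!known]), collapse = ", "),
         call. = FALSE)
  if (any(intervals$end > chrom_sizes[intervals$chrom]))
    stop("intervals exceed chromosome bounds", call. = FALSE)
  structure(list(region_type = region_type,
                 intervals = intervals[c("chrom", "start", "end")],
                 chrom_sizes = chrom_sizes),
            class = "annotation_space")
}

#' Whole-chromosome annotation space
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return an `annotation_space` of type `"genomic"` covering every
#'   chromosome end to end.
#' @export
genomic_space <- function(chrom_sizes) {
  annotation_space("genomic",
                   data.frame(chrom = names(chrom_sizes), start = 0,
                              end = unname(chrom_sizes),
                              stringsAsFactors = FALSE),
                   chrom_sizes)
}

#' Sample fixed-length random regions from an annotation space
#'
#' Start positions are uniform over all eligible positions pooled across the
#' space's intervals (interval choice weighted by eligible length), so every
#' possible region of the requested length is equally likely. Sampled
#' regions never cross an interval boundary; overlaps among sampled regions
#' are allowed. Intervals shorter than the requested length are skipped with
#' a warning.
#'
#' @param space an `annotation_space`.
#' @param count number of regions to draw (> 0).
#' @param length region length in bp (default 20, the binding-site length).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return data.frame `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   with exactly `count` rows of exactly `length` bp.
#' @export
sample_regions <- function(space, count, length = 20, seed = NULL) {
  stopifnot(inherits(space, "annotation_space"))
  if (!is.numeric(count) || count < 1)
    stop("count must be a positive integer", call. = FALSE)
  iv <- space$intervals
  eligible <- iv$end - iv$start - length + 1
  if (any(eligible < 1))
    warning(sum(eligible < 1), " interval(s) shorter than ", length,
            " bp skipped", call. = FALSE)
  iv <- iv[eligible >= 1, , drop = FALSE]
  eligible <- eligible[eligible >= 1]
  if (!nrow(iv))
    stop("no interval long enough to sample a ", length, " bp region",
         call. = FALSE)
  with_seed(seed, {
    pick <- sample.int(nrow(iv), count, replace = TRUE,
                       prob = eligible / sum(eligible))
    offset <- floor(runif(count) * eligible[pick])
    start <- iv$start[pick] + offset
    data.frame(chrom = iv$chrom[pick], start = start, end = start + length,
               name = sprintf("rand_%d", seq_len(count)), score = 0,
               strand = ".", stringsAsFactors = FALSE)
  })
}

#' Replicate random-region conservation null profiles
#'
#' Draws `n_replicates` independent random-region sets (distinct seeds
#' derived from `seed_base`), scores each against the MAF block index, and
#' reports a replicate-agreement statistic: the minimum pairwise rank-sum
#' p-value across replicate P distributions (values near 1 mean the
#' replicates agree, so any one replicate is representative).
#'
#' @inheritParams sample_regions
#' @param n_replicates number of replicate datasets (default 10).
#' @param seed_base base seed; replicate r uses a seed derived from
#'   `seed_base` and r.
#' @param index a `block_index`.
#' @param total_species denominator of P.
#' @return list with `profiles` (list of `conservation_profile`) and
#'   `min_pairwise_p` (NA with < 2 replicates with mapped sites).
#' @export
null_profile <- function(space, count, length = 20, n_replicates = 10,
                         seed_base = 1, index, total_species = 46) {
  profiles <- lapply(seq_len(n_replicates), function(r) {
    regions <- sample_regions(space, count, length,
                              seed = child_seed(seed_base, r))
    profile_rbp(regions, index, total_species,
                rbp_name = sprintf("%s_null_rep%d", space$region_type, r))
  })
  ps <- c()
  mapped <- lapply(profiles, mapped_P)
  ok <- which(lengths(mapped) > 0)
  if (length(ok) >= 2) {
    for (i in head(ok, -1)) for (j in ok[ok > i])
      ps <- c(ps, compare_groups(mapped[[i]], mapped[[j]])$p.value)
  }
  list(profiles = profiles,
       min_pairwise_p = if (length(ps)) min(ps) else NA_real_)
}
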