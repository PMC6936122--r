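# Strand-aware genic thirds: partition each gene body into 5'/middle/3'
# segments of (near-)equal length in the direction of transcription, assign
# binding sites by midpoint, and compare conservation across the regions.

#' Partition genes into strand-aware 5'/middle/3' thirds
#'
#' Each gene span is tiled by three disjoint segments whose lengths differ
#' by at most 1 bp; remainder bp from the integer division go to the
#' transcriptionally-last segment(s) (the 3' third first, then the middle).
#' The 5' and 3' labels follow the strand: on '-' genes the 5' segment has
#' the larger genomic coordinates.
#'
#' @param genes data.frame as returned by [read_genes()]; every gene must be
#'   at least 3 bp long.
#' @return data.frame with one row per gene x region: `geneId`, `chrom`,
#'   `strand`, `region` (`"5prime"`, `"middle"`, `"3prime"`), `start`,
#'   `end` (0-based half-open genomic coordinates).
#' @export
segment_genes <- function(genes) {
  len <- genes$end - genes$start
  if (any(len < 3))
    stop("gene(s) shorter than 3 bp cannot be split into thirds: ",
         paste(genes$geneId[len < 3], collapse = ", "), call. = FALSE)
  base <- len %/% 3
  rem <- len %% 3
  # transcription-order lengths: remainder to the last, then middle segment
  l5 <- base
  l3 <- base + as.integer(rem >= 1)
  lm <- base + as.integer(rem == 2)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tl <- c(l5[i], lm[i], l3[i])           # 5', middle, 3' in transcription order
    if (g$strand == "+") {
      cuts <- g$start + cumsum(c(0, tl))
      starts <- cuts[1:3]; ends <- cuts[2:4]
      regions <- c("5prime", "middle", "3prime")
    } else {
      cuts <- g$end - cumsum(c(0, tl))     # walk right-to-left from the TSS
      starts <- cuts[2:4]; ends <- cuts[1:3]
      regions <- c("5prime", "middle", "3prime")
    }
    data.frame(geneId = g$geneId, chrom = g$chrom, strand = g$strand,
               region = regions, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Single-gene convenience wrapper for [segment_genes()]
#' @param gene one-row data.frame with `geneId`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return three-row data.frame of segments.
#' @export
segment_gene <- function(gene) segment_genes(gene[1, , drop = FALSE])

#' Assign scored binding sites to genic thirds
#'
#' A site is assigned to the gene segment containing its midpoint
#' (`floor((start + end) / 2)`); sites overlapping several genes get one
#' assignment per gene; intergenic sites are dropped.
#'
#' @param records data.frame of mapped sites with a `P` column (from
#'   [map_sites()] or [profile_rbp()]'s `records`); unmapped rows (NA P) are
#'   ignored.
#' @param genes gene annotation data.frame ([read_genes()]).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `P`, `geneId`,
#'   `region`.
#' @export
assign_sites <- function(records, genes) {
  records <- records[!is.na(records$P), , drop = FALSE]
  segs <- segment_genes(genes)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), P = numeric(),
                      geneId = character(), region = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(records) || !nrow(segs)) return(empty)
  mid <- (records$start + records$end) %/% 2
  q <- GenomicRanges::GRanges(records$chrom,
                              IRanges::IRanges(mid + 1L, mid + 1L))
  s <- GenomicRanges::GRanges(segs$chrom,
                              IRanges::IRanges(segs$start + 1L, segs$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  if (!length(hits)) return(empty)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  data.frame(chrom = records$chrom[qh], start = records$start[qh],
             end = records$end[qh],
             name = if ("name" %in% names(records)) records$name[qh] else "",
             P = records$P[qh], geneId = segs$geneId[sh],
             region = segs$region[sh], stringsAsFactors = FALSE)
}

#' Compare conservation across genic regions
#'
#' Per RBP: the median P per region and pairwise two-sided Wilcoxon
#' rank-sum p-values for 3' vs 5', 3' vs middle, and middle vs 5'. The
#' summary counts RBPs whose 3' sites are significantly more conserved than
#' their 5' sites (higher 3' median and p below `alpha`), mirroring the
#' "x/60 RBPs" style headline. RBPs with sites in fewer than two regions
#' are skipped with a warning.
#'
#' @param assignments data.frame from [assign_sites()]; when comparing many
#'   RBPs, add an `rbp` column and set `per_rbp = TRUE`.
#' @param per_rbp split by an `rbp` column (default `TRUE` when present).
#' @param alpha significance level for the 3' > 5' summary (default 0.05;
#'   raw p-values, no multiplicity adjustment, matching the per-RBP
#'   headline; apply [stats::p.adjust()] downstream if desired).
#' @return list with `medians` (rbp, region, n_sites, median_P), `tests`
#'   (rbp, comparison, p_value), and `summary` (n_rbps, n_3prime_gt_5prime).
#' @export
region_comparison <- function(assignments, per_rbp = "rbp" %in%
                                names(assignments), alpha = 0.05) {
  if (!nrow(assignments)) stop("no assignments", call. = FALSE)
  groups <- if (per_rbp) split(assignments, assignments$rbp)
            else list(all = assignments)
  med_rows <- list(); test_rows <- list(); n_sig <- 0L; n_tested <- 0L
  comparisons <- list(c("3prime", "5prime"), c("3prime", "middle"),
                      c("middle", "5prime"))
  for (rbp in names(groups)) {
    a <- groups[[rbp]]
    by_region <- split(a$P, factor(a$region,
                                   c("5prime", "middle", "3prime")))
    n_regions <- sum(lengths(by_region) > 0)
    for (r in names(by_region)) {
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        rbp = rbp, region = r, n_sites = length(by_region[[r]]),
        median_P = if (length(by_region[[r]])) median(by_region[[r]])
                   else NA_real_, stringsAsFactors = FALSE)
    }
    if (n_regions < 2) {
      warning("RBP '", rbp, "' has sites in fewer than 2 regions; skipped",
              call. = FALSE)
      next
    }
    n_tested <- n_tested + 1L
    for (cmp in comparisons) {
      va <- by_region[[cmp[1]]]; vb <- by_region[[cmp[2]]]
      p <- if (length(va) && length(vb)) compare_groups(va, vb)$p.value
           else NA_real_
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        rbp = rbp, comparison = paste(cmp[1], "vs", cmp[2]), p_value = p,
        stringsAsFactors = FALSE)
      if (identical(cmp, c("3prime", "5prime")) && !is.na(p) &&
          p < alpha && median(va) > median(vb))
        n_sig <- n_sig + 1L
    }
  }
  list(medians = do.call(rbind, med_rows),
       tests = do.call(rbind, test_rows),
       summary = list(n_rbps = n_tested, n_3prime_gt_5prime = n_sig))
}
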