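# Family-level analysis: similarity of binding-site conservation profiles
# between RBPs of one family,
#   SS = 2 * NBS / (N1 + N2),
# where NBS counts binding sites conserved in the same percentage of
# species, tested for association with tree-derived evolutionary distances.

#' Similarity score between two conservation profiles
#'
#' NBS is the multiset intersection of the two profiles' discretized P
#' values: for each distinct P value, min(count in profile 1, count in
#' profile 2), summed. This is the only symmetric counting rule bounded by
#' min(N1, N2); "conserved in the same percentage of species" compares
#' P values on the lattice k / totalSpecies * 100, so P is rounded to
#' `digits` decimals (default 6) before matching to absorb floating-point
#' noise only.
#'
#' @param profile1,profile2 `conservation_profile` objects with at least one
#'   mapped site each.
#' @param digits decimals P is rounded to before matching.
#' @return list with `rbp1`, `rbp2`, `nbs`, `n1`, `n2`, `ss` (in [0, 1]).
#' @export
similarity_score <- function(profile1, profile2, digits = 6) {
  p1 <- round(mapped_P(profile1), digits)
  p2 <- round(mapped_P(profile2), digits)
  if (!length(p1) || !length(p2))
    stop("both profiles need at least one mapped site", call. = FALSE)
  levels <- union(p1, p2)
  c1 <- table(factor(p1, levels = levels))
  c2 <- table(factor(p2, levels = levels))
  nbs <- sum(pmin(as.numeric(c1), as.numeric(c2)))
  list(rbp1 = profile1$rbp, rbp2 = profile2$rbp, nbs = nbs,
       n1 = length(p1), n2 = length(p2),
       ss = 2 * nbs / (length(p1) + length(p2)))
}

#' Patristic distance matrix of a tree's leaves
#'
#' d(a, b) is the sum of branch lengths on the path between leaves a and b.
#'
#' @param tree an [ape::phylo] tree (e.g. from [read_newick()]).
#' @param normalize divide by the maximum pairwise distance so distances lie
#'   in [0, 1] (default `FALSE`; distances are consumed as the tree states
#'   them).
#' @return symmetric numeric matrix with leaf labels as dimnames and zero
#'   diagonal.
#' @export
patristic_distances <- function(tree, normalize = FALSE) {
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label, drop = FALSE]
  if (normalize && max(d) > 0) d <- d / max(d)
  d
}

#' Pairwise family similarity table
#'
#' All unordered pairs of the supplied profiles, with SS and (when a tree is
#' given) the patristic distance between the pair's leaves.
#'
#' @param profiles list of `conservation_profile` objects, one per family
#'   member; profile `rbp` names must match tree leaf labels.
#' @param tree optional [ape::phylo] tree over the family members.
#' @inheritParams patristic_distances
#' @return data.frame with columns `rbp1`, `rbp2`, `nbs`, `n1`, `n2`, `ss`
#'   and `evo_dist` (NA without a tree).
#' @export
family_pairs <- function(profiles, tree = NULL, normalize = FALSE) {
  stopifnot(length(profiles) >= 2)
  dm <- NULL
  if (!is.null(tree)) {
    dm <- patristic_distances(tree, normalize)
    missing_leaves <- setdiff(vapply(profiles, `[[`, "", "rbp"),
                              rownames(dm))
    if (length(missing_leaves))
      stop("tree is missing leaves: ",
           paste(missing_leaves, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (i in seq_len(length(profiles) - 1)) {
    for (j in seq(i + 1, length(profiles))) {
      s <- similarity_score(profiles[[i]], profiles[[j]])
      s$evo_dist <- if (is.null(dm)) NA_real_ else dm[s$rbp1, s$rbp2]
      out[[length(out) + 1L]] <- as.data.frame(s, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Quantile-bin a numeric vector into at most n_bins non-empty bins.
quantile_bins <- function(x, n_bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Chi-square test of association between similarity and evolutionary distance
#'
#' Discretizes SS and patristic distance into quantile bins and applies
#' Pearson's chi-square test of independence (without continuity correction)
#' to the resulting contingency table. A caution is logged when any expected
#' count falls below 5.
#'
#' @param pairs data.frame from [family_pairs()] with `ss` and `evo_dist`.
#' @param n_bins number of quantile bins per axis (default 3); at least
#'   `n_bins^2` pairs are recommended.
#' @return list with `statistic`, `df`, `p.value`, `table` (the contingency
#'   table) and `low_expected` (logical).
#' @export
association_test <- function(pairs, n_bins = 3) {
  stopifnot(all(c("ss", "evo_dist") %in% names(pairs)))
  if (anyNA(pairs$evo_dist))
    stop("evo_dist contains NA; supply a tree to family_pairs()",
         call. = FALSE)
  bd <- quantile_bins(pairs$evo_dist, n_bins)
  bs <- quantile_bins(pairs$ss, n_bins)
  if (nlevels(droplevels(bd)) < 2 || nlevels(droplevels(bs)) < 2)
    stop("degenerate table: all pairs fall in one bin of an axis",
         call. = FALSE)
  tab <- table(distance = droplevels(bd), similarity = droplevels(bs))
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  low <- any(ht$expected < 5)
  if (low)
    warning("expected counts < 5 in the contingency table; ",
            "chi-square approximation is rough", call. = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, table = tab, low_expected = low)
}
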