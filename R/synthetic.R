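# Synthetic fixtures with planted, recoverable structure: clade-structured
# MAF alignments, 20 bp binding sites with controlled mappability and
# positional bias, RBP feature tables with one informative feature, and
# gene-set collections with one high-scoring planted set. Every generator
# is deterministic under its seed and returns a truth table alongside the
# data, so downstream statistics have known expectations.

#' Describe a clade for the synthetic alignment
#'
#' @param name clade label (e.g. `"mammal"`).
#' @param species character vector of species identifiers (disjoint across
#'   clades).
#' @param retention probability in [0, 1] that a species of this clade has a
#'   row in any given background block.
#' @param hot_retention retention probability inside "hot" blocks, the
#'   well-conserved loci where binding sites are planted (defaults to
#'   `retention`).
#' @return a `clade_spec` list.
#' @export
clade_spec <- function(name, species, retention, hot_retention = retention) {
  stopifnot(retention >= 0, retention <= 1,
            hot_retention >= 0, hot_retention <= 1, length(species) >= 1)
  structure(list(name = name, species = species, retention = retention,
                 hot_retention = hot_retention), class = "clade_spec")
}

#' Default synthetic scenario
#'
#' The defaults emulate the study conditions of a 46-way vertebrate
#' alignment: a reference species plus 36 further mammal-like species with
#' high block retention (0.9) and 9 lower-vertebrate-like species with low
#' retention (0.2), mirroring the primate-to-fish conservation gradient. A
#' `hot_fraction` of blocks represents well-conserved loci (retention 0.995
#' mammal-like / 0.7 lower-vertebrate-like) where binding sites are
#' planted, so real sites score above random genomic background.
#'
#' @param chrom_lengths named numeric vector of reference chromosome
#'   lengths.
#' @param block_length_range min/max block length in bp (blocks tile each
#'   chromosome; lengths uniform in the range).
#' @param clades list of [clade_spec()]s; species lists must be disjoint.
#'   The reference species is always present in every block.
#' @param reference reference species identifier (first MAF row).
#' @param ref_chrom_prefix prefix of the reference `src` field
#'   (`"<reference>."` + chromosome).
#' @param hot_fraction fraction of blocks with elevated (hot) retention;
#'   set 0 for a homogeneous alignment.
#' @param gap_fraction fraction of the reference left uncovered between
#'   blocks (default 0: blocks tile end to end).
#' @param n_rbps,sites_per_rbp binding-site simulation defaults.
#' @param unmappable_fraction fraction of simulated sites deliberately
#'   placed across block boundaries, exercising the exclusion rule.
#' @param total_species denominator of P; derived from the clades.
#' @param seed base seed for all generators.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(
    chrom_lengths = c(chrS1 = 60000, chrS2 = 40000),
    block_length_range = c(40, 80),
    clades = list(
      clade_spec("mammal", c("hsap", sprintf("mam%02d", 1:36)),
                 retention = 0.9, hot_retention = 0.995),
      clade_spec("lower_vertebrate", sprintf("low%02d", 1:9),
                 retention = 0.2, hot_retention = 0.7)),
    reference = "hsap",
    hot_fraction = 0.25,
    gap_fraction = 0,
    n_rbps = 20,
    sites_per_rbp = 200,
    unmappable_fraction = 0.1,
    total_species = NULL,
    seed = 1) {
  all_species <- unlist(lapply(clades, `[[`, "species"))
  if (anyDuplicated(all_species))
    stop("clade species lists must be disjoint", call. = FALSE)
  if (!reference %in% all_species)
    stop("reference species must belong to a clade", call. = FALSE)
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            block_length_range[1] >= 20,
            hot_fraction >= 0, hot_fraction <= 1,
            gap_fraction >= 0, gap_fraction < 1,
            n_rbps >= 1, sites_per_rbp >= 0,
            unmappable_fraction >= 0, unmappable_fraction < 1)
  structure(list(
    chrom_lengths = chrom_lengths,
    block_length_range = block_length_range,
    clades = clades, reference = reference,
    species = all_species,
    clade_map = setNames(rep(vapply(clades, `[[`, "", "name"),
                             lengths(lapply(clades, `[[`, "species"))),
                         all_species),
    hot_fraction = hot_fraction, gap_fraction = gap_fraction,
    n_rbps = n_rbps, sites_per_rbp = sites_per_rbp,
    unmappable_fraction = unmappable_fraction,
    total_species = if (is.null(total_species)) length(all_species)
                    else total_species,
    seed = seed), class = "synthetic_scenario")
}

random_dna <- function(n, len) {
  vapply(len, function(l) paste(sample(c("A", "C", "G", "T"), l,
                                       replace = TRUE), collapse = ""), "")
}

#' Simulate a clade-structured MAF alignment
#'
#' Tiles each reference chromosome with non-overlapping blocks (optionally
#' separated by unaligned gaps) whose species membership is drawn per the
#' scenario's clade retention probabilities; the reference is present in
#' every block. Sequence content is uniform random A/C/G/T placeholder
#' text; no statistic in this pipeline reads the bases.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed seed (default: the scenario's).
#' @return list with `maf` (character vector of MAF text lines that
#'   re-parses losslessly through [read_maf()]), `truth` (data.frame
#'   `block`, `chrom`, `start`, `end`, `hot`, `n_species`) and `membership`
#'   (logical blocks x species matrix of planted presence).
#' @export
simulate_maf <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!length(scenario$chrom_lengths)) stop("zero chromosomes",
                                            call. = FALSE)
  with_seed(seed, {
    blr <- scenario$block_length_range
    truth <- list(); chunks <- list("##maf version=1")
    membership <- list()
    block_id <- 0L
    for (chrom in names(scenario$chrom_lengths)) {
      clen <- scenario$chrom_lengths[[chrom]]
      pos <- 0
      while (pos + blr[1] <= clen) {
        len <- min(sample(blr[1]:blr[2], 1), clen - pos)
        hot <- runif(1) < scenario$hot_fraction
        present <- setNames(logical(length(scenario$species)),
                            scenario$species)
        for (cl in scenario$clades) {
          p <- if (hot) cl$hot_retention else cl$retention
          present[cl$species] <- runif(length(cl$species)) < p
        }
        present[scenario$reference] <- TRUE
        block_id <- block_id + 1L
        keep <- names(present)[present]
        keep <- c(scenario$reference, setdiff(keep, scenario$reference))
        seqs <- random_dna(length(keep), rep(len, length(keep)))
        src <- ifelse(keep == scenario$reference,
                      paste0(scenario$reference, ".", chrom),
                      paste0(keep, ".chr1"))
        chunks[[block_id + 1L]] <- c(
          sprintf("a score=%d", block_id),
          sprintf("s %s %d %d + %d %s", src, pos, len,
                  ifelse(keep == scenario$reference, clen, 1000000L), seqs),
          "")
        truth[[block_id]] <- data.frame(
          block = block_id, chrom = chrom, start = pos, end = pos + len,
          hot = hot, n_species = length(keep), stringsAsFactors = FALSE)
        membership[[block_id]] <- present
        pos <- pos + len
        if (scenario$gap_fraction > 0 && runif(1) < scenario$gap_fraction)
          pos <- pos + sample(blr[1]:blr[2], 1)
      }
    }
    list(maf = unlist(chunks), truth = do.call(rbind, truth),
         membership = do.call(rbind, membership))
  })
}

#' Simulate gene spans on the synthetic chromosomes
#'
#' Non-overlapping genes of fixed length laid down left to right with
#' random strands, leaving intergenic space between consecutive genes.
#'
#' @param scenario a [synthetic_scenario()].
#' @param n_genes number of genes to place.
#' @param gene_length gene span length in bp (>= 3).
#' @param spacing intergenic gap between consecutive genes.
#' @param seed seed.
#' @return gene annotation data.frame in the [read_genes()] layout.
#' @export
simulate_genes <- function(scenario, n_genes = 30, gene_length = 1500,
                           spacing = 200, seed = scenario$seed + 1) {
  with_seed(seed, {
    out <- list()
    chroms <- names(scenario$chrom_lengths)
    i <- 0L; ci <- 1L; pos <- 0
    while (i < n_genes && ci <= length(chroms)) {
      if (pos + gene_length > scenario$chrom_lengths[[chroms[ci]]]) {
        ci <- ci + 1L; pos <- 0; next
      }
      i <- i + 1L
      out[[i]] <- data.frame(
        geneId = sprintf("G%04d", i), symbol = sprintf("SYM%04d", i),
        chrom = chroms[ci], start = pos, end = pos + gene_length,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      pos <- pos + gene_length + spacing
    }
    if (i < n_genes)
      warning("only ", i, " of ", n_genes, " genes fit the chromosomes",
              call. = FALSE)
    do.call(rbind, out)
  })
}

#' Simulate per-RBP binding-site BED sets with planted structure
#'
#' Mappable sites are placed fully inside alignment blocks (preferring hot
#' blocks when the scenario has any); a planted `unmappable_fraction` of
#' sites straddles a block boundary so they fail the containment rule.
#' When `positional_bias` is given, mappable sites are instead routed to
#' the 5'/middle/3' thirds of the supplied genes with the stated
#' probabilities.
#'
#' @param scenario a [synthetic_scenario()].
#' @param maf output of [simulate_maf()] (its truth table drives placement).
#' @param genes gene annotation (required for `positional_bias`).
#' @param positional_bias optional named numeric probabilities over
#'   `c("5prime", "middle", "3prime")`, summing to 1.
#' @param site_length site length in bp (default 20).
#' @param seed seed.
#' @return list with `sites` (named list of per-RBP BED data.frames) and
#'   `truth` (data.frame `rbp`, `name`, `chrom`, `start`, `end`,
#'   `intended` = `"mappable"`/`"unmappable"`, `region` = planted third or
#'   NA).
#' @export
simulate_sites <- function(scenario, maf, genes = NULL,
                           positional_bias = NULL, site_length = 20,
                           seed = scenario$seed + 2) {
  bt <- maf$truth
  if (any(bt$end - bt$start < site_length))
    stop("site length ", site_length, " exceeds the shortest block",
         call. = FALSE)
  if (!is.null(positional_bias)) {
    stopifnot(!is.null(genes),
              setequal(names(positional_bias),
                       c("5prime", "middle", "3prime")),
              abs(sum(positional_bias) - 1) < 1e-8)
    segs <- segment_genes(genes)
    segs <- segs[segs$end - segs$start >= site_length, , drop = FALSE]
  }
  target_blocks <- if (any(bt$hot)) which(bt$hot) else seq_len(nrow(bt))
  # boundaries between adjacent tiled blocks, for planted unmappable sites
  adj <- which(bt$chrom[-1] == bt$chrom[-nrow(bt)] &
                 bt$start[-1] == bt$end[-nrow(bt)])
  with_seed(seed, {
    sites <- list(); truth <- list()
    for (r in seq_len(scenario$n_rbps)) {
      rbp <- sprintf("RBP%02d", r)
      n <- scenario$sites_per_rbp
      if (n == 0) {
        sites[[rbp]] <- data.frame(chrom = character(), start = integer(),
                                   end = integer(), name = character(),
                                   score = numeric(), strand = character(),
                                   stringsAsFactors = FALSE)
        next
      }
      unmap <- runif(n) < scenario$unmappable_fraction & length(adj) > 0
      chrom <- character(n); start <- integer(n); region <- rep(NA_character_, n)
      for (i in seq_len(n)) {
        if (unmap[i]) {
          # straddle the shared boundary of two adjacent blocks
          b <- sample(adj, 1)
          chrom[i] <- bt$chrom[b]
          start[i] <- bt$end[b] - sample(seq_len(site_length - 1), 1)
        } else if (!is.null(positional_bias)) {
          region[i] <- sample(names(positional_bias), 1,
                              prob = positional_bias)
          cand <- segs[segs$region == region[i], , drop = FALSE]
          s <- cand[sample.int(nrow(cand), 1), ]
          chrom[i] <- s$chrom
          start[i] <- s$start +
            sample.int(s$end - s$start - site_length + 1, 1) - 1L
        } else {
          b <- target_blocks[sample.int(length(target_blocks), 1)]
          chrom[i] <- bt$chrom[b]
          start[i] <- bt$start[b] +
            sample.int(bt$end[b] - bt$start[b] - site_length + 1, 1) - 1L
        }
      }
      name <- sprintf("%s_site%04d", rbp, seq_len(n))
      sites[[rbp]] <- data.frame(chrom = chrom, start = start,
                                 end = start + site_length, name = name,
                                 score = 0, strand = "+",
                                 stringsAsFactors = FALSE)
      truth[[rbp]] <- data.frame(
        rbp = rbp, name = name, chrom = chrom, start = start,
        end = start + site_length,
        intended = ifelse(unmap, "unmappable", "mappable"),
        region = region, stringsAsFactors = FALSE)
    }
    list(sites = sites, truth = do.call(rbind, truth))
  })
}

#' Simulate an RBP feature table with one planted informative feature
#'
#' The response (median conservation percent) is a linear function of the
#' planted feature plus Gaussian noise; every other feature is independent
#' noise on its own scale. Defaults reflect the 60-RBP, 11-feature shape of
#' the real analysis.
#'
#' @param n_rbps number of rows (default 60).
#' @param features feature (column) names; defaults to the 11 RBP-centric
#'   features of the real table.
#' @param planted_feature name of the informative feature.
#' @param effect response change per standard deviation of the planted
#'   feature (default 10 percent-points; 0 plants nothing).
#' @param noise_sd response noise standard deviation (default 3).
#' @param seed seed.
#' @return list with `rbp`, `y` (response), `x` (feature matrix) — the
#'   [read_feature_table()] layout — plus `planted` (the truth).
#' @export
simulate_feature_table <- function(
    n_rbps = 60,
    features = c("n_binding_sites", "protein_expression",
                 "ppi_count", "rbp_rbp_interactions",
                 "transcript_expression", "tissue_specificity_tau",
                 "rna_binding_domains", "transcript_length",
                 "subcellular_compartments", "rbp_conservation",
                 "n_paralogs"),
    planted_feature = "n_binding_sites", effect = 10, noise_sd = 3,
    seed = 1) {
  stopifnot(n_rbps >= 10, planted_feature %in% features)
  with_seed(seed, {
    x <- matrix(rnorm(n_rbps * length(features)), n_rbps,
                dimnames = list(NULL, features))
    # give columns distinct scales; min-max normalization must undo this
    x <- sweep(x, 2, seq(1, 100, length.out = ncol(x)), "*")
    z <- scale(x[, planted_feature])[, 1]
    y <- 50 + effect * z + rnorm(n_rbps, sd = noise_sd)
    y <- pmin(100, pmax(0, y))
    list(rbp = sprintf("RBP%02d", seq_len(n_rbps)), y = y, x = x,
         planted = list(feature = planted_feature, effect = effect))
  })
}

#' Simulate gene conservation scores with a planted high-scoring subset
#'
#' @param n_genes universe size (default 1000).
#' @param planted_size number of planted genes (default 30).
#' @param shift score shift added to the planted genes (default +30).
#' @param mean_score,sd_score background score distribution N(mean, sd),
#'   truncated to [0, 100].
#' @param seed seed.
#' @return list with `scores` (named numeric vector) and `planted_genes`.
#' @export
simulate_gene_scores <- function(n_genes = 1000, planted_size = 30,
                                 shift = 30, mean_score = 50,
                                 sd_score = 10, seed = 1) {
  stopifnot(n_genes >= 1, planted_size <= n_genes)
  with_seed(seed, {
    genes <- sprintf("SYM%04d", seq_len(n_genes))
    scores <- rnorm(n_genes, mean_score, sd_score)
    planted <- sample(genes, planted_size)
    scores[match(planted, genes)] <- scores[match(planted, genes)] + shift
    scores <- pmin(100, pmax(0, scores))
    list(scores = setNames(scores, genes), planted_genes = planted)
  })
}

#' Simulate a GMT collection with one planted gene set
#'
#' The planted set is the planted high-scoring genes; the remaining sets
#' are uniform random draws of matched size from the universe.
#'
#' @param scores named score vector (the universe).
#' @param planted_genes genes of the planted set (e.g. from
#'   [simulate_gene_scores()]); `NULL` plants nothing.
#' @param n_random number of random decoy sets.
#' @param set_size size of each random set (default: planted size, or 30).
#' @param seed seed.
#' @return named list of gene sets ([read_gmt()] layout); the planted set
#'   is named `"planted_set"`.
#' @export
simulate_gene_sets <- function(scores, planted_genes = NULL, n_random = 9,
                               set_size = NULL, seed = 1) {
  if (!length(scores)) stop("empty gene universe", call. = FALSE)
  if (is.null(set_size))
    set_size <- if (length(planted_genes)) length(planted_genes) else 30
  set_size <- min(set_size, length(scores))
  with_seed(seed, {
    sets <- list()
    if (length(planted_genes))
      sets[["planted_set"]] <- list(name = "planted_set",
                                    description = "planted high-score set",
                                    genes = planted_genes)
    for (i in seq_len(n_random)) {
      nm <- sprintf("random_set_%02d", i)
      sets[[nm]] <- list(name = nm, description = "random decoy set",
                         genes = sample(names(scores), set_size))
    }
    sets
  })
}
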