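# End-to-end orchestration on a synthetic scenario: simulate -> conserve ->
# nulls -> families -> features -> regions -> enrichment, with every stage
# output written as a headered TSV (or MAF/BED/GMT) and recorded in a
# manifest with content checksums. All randomness flows from the config
# seed, so a rerun with the same config reproduces the checksums.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param scenario a [synthetic_scenario()] defining the simulated study
#'   conditions.
#' @param seed master seed; each stage derives its own stream from it.
#' @param stages character vector of stages to run, in dependency order;
#'   any subset of `c("simulate", "conserve", "nulls", "families",
#'   "features", "regions", "enrich")`. Later stages require the earlier
#'   ones in the same run.
#' @param n_null_replicates random-region replicate datasets (default 10).
#' @param n_perm enrichment permutations (default 1000).
#' @param family_size number of RBPs grouped into the synthetic family.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            scenario = synthetic_scenario(),
                            seed = 1,
                            stages = c("simulate", "conserve", "nulls",
                                       "families", "features", "regions",
                                       "enrich"),
                            n_null_replicates = 10,
                            n_perm = 1000,
                            family_size = 6) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, scenario = scenario, seed = seed,
                 stages = stages, n_null_replicates = n_null_replicates,
                 n_perm = n_perm, family_size = family_size),
            class = "pipeline_config")
}

#' Run the conservation pipeline end to end
#'
#' Executes the configured stages in dependency order on the scenario's
#' synthetic data and writes each stage's outputs under `out_dir`:
#' alignment + annotation (`simulate`), per-site conservation records and
#' the species presence matrix (`conserve`), random-region null profiles
#' (`nulls`), family similarity pairs and the distance association test
#' (`families`), RReliefF weights (`features`), genic-thirds medians and
#' pairwise tests (`regions`), and the permutation enrichment table
#' (`enrich`).
#'
#' @param config a [pipeline_config()].
#' @return run manifest: data.frame with `stage`, `file`, `md5`, plus
#'   attribute `"summaries"` (per-stage headline numbers).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$scenario
  manifest <- list(); summaries <- list()
  emit <- function(stage, file) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }
  p <- function(...) file.path(config$out_dir, ...)
  t0 <- Sys.time()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s (%.1fs elapsed)", stage, msg,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  need <- function(stage) stage %in% config$stages

  maf <- genes <- site_sets <- profiles <- index <- NULL

  if (need("simulate")) {
    maf <- simulate_maf(sc, seed = child_seed(config$seed, 1))
    genes <- simulate_genes(sc, seed = child_seed(config$seed, 2))
    site_sets <- simulate_sites(sc, maf, seed = child_seed(config$seed, 3))
    writeLines(maf$maf, p("alignment.maf")); emit("simulate",
                                                 p("alignment.maf"))
    write_genes(genes, p("genes.tsv")); emit("simulate", p("genes.tsv"))
    for (rbp in names(site_sets$sites)) {
      f <- p(sprintf("sites_%s.bed", rbp))
      write_bed(site_sets$sites[[rbp]], f); emit("simulate", f)
    }
    write_tsv(site_sets$truth, p("sites_truth.tsv"))
    emit("simulate", p("sites_truth.tsv"))
    log_stage("simulate", sprintf("%d blocks, %d genes, %d RBPs",
                                  nrow(maf$truth), nrow(genes),
                                  length(site_sets$sites)))
  }

  if (need("conserve")) {
    blocks <- read_maf(text = maf$maf)
    index <- index_blocks(blocks)
    profiles <- lapply(names(site_sets$sites), function(rbp) {
      profile_rbp(site_sets$sites[[rbp]], index, sc$total_species, rbp)
    })
    names(profiles) <- names(site_sets$sites)
    recs <- do.call(rbind, lapply(profiles, function(pr) {
      cbind(rbp = pr$rbp, pr$records)
    }))
    write_tsv(recs, p("conservation_records.tsv"))
    emit("conserve", p("conservation_records.tsv"))
    med <- data.frame(
      rbp = vapply(profiles, `[[`, "", "rbp"),
      n_mapped = vapply(profiles, `[[`, 0L, "n_mapped"),
      n_unmapped = vapply(profiles, `[[`, 0L, "n_unmapped"),
      median_P = vapply(profiles, `[[`, 0, "median_P"))
    write_tsv(med, p("rbp_medians.tsv")); emit("conserve",
                                               p("rbp_medians.tsv"))
    mat <- species_presence_matrix(profiles, index)
    write_tsv(cbind(rbp = rownames(mat), as.data.frame(mat)),
              p("species_presence_matrix.tsv"))
    emit("conserve", p("species_presence_matrix.tsv"))
    summaries$conserve <- list(
      overall_median_P = median(unlist(lapply(profiles, mapped_P))),
      n_mapped = sum(med$n_mapped), n_unmapped = sum(med$n_unmapped))
    log_stage("conserve", sprintf("%d/%d sites mapped, overall median P %.1f",
                                  sum(med$n_mapped),
                                  sum(med$n_mapped) + sum(med$n_unmapped),
                                  summaries$conserve$overall_median_P))
  }

  if (need("nulls")) {
    space <- genomic_space(sc$chrom_lengths)
    np <- null_profile(space, count = sc$sites_per_rbp, length = 20,
                       n_replicates = config$n_null_replicates,
                       seed_base = child_seed(config$seed, 4),
                       index = index, total_species = sc$total_species)
    null_recs <- do.call(rbind, lapply(np$profiles, function(pr) {
      cbind(replicate = pr$rbp, pr$records)
    }))
    write_tsv(null_recs, p("null_genomic_records.tsv"))
    emit("nulls", p("null_genomic_records.tsv"))
    null_P <- mapped_P(np$profiles[[1]])
    site_P <- unlist(lapply(profiles, mapped_P))
    cmp <- compare_groups(site_P, null_P)
    summaries$nulls <- list(
      null_median_P = median(null_P),
      site_median_P = median(site_P),
      site_vs_null_p = cmp$p.value,
      replicate_min_pairwise_p = np$min_pairwise_p)
    write_tsv(data.frame(
      quantity = c("null_median_P", "site_median_P", "site_vs_null_p",
                   "replicate_min_pairwise_p"),
      value = unlist(summaries$nulls)), p("null_summary.tsv"))
    emit("nulls", p("null_summary.tsv"))
    log_stage("nulls", sprintf("null median P %.1f vs site median P %.1f",
                               median(null_P), median(site_P)))
  }

  if (need("families")) {
    fam <- head(names(profiles), config$family_size)
    tree <- with_seed(child_seed(config$seed, 5),
                      ape::rtree(length(fam), tip.label = fam))
    ape::write.tree(tree, p("family_tree.nwk"))
    emit("families", p("family_tree.nwk"))
    pairs <- family_pairs(profiles[fam], tree)
    write_tsv(pairs, p("family_pairs.tsv"))
    emit("families", p("family_pairs.tsv"))
    assoc <- tryCatch(association_test(pairs, n_bins = 2),
                      error = function(e) NULL)
    summaries$families <- list(
      n_pairs = nrow(pairs), mean_ss = mean(pairs$ss),
      assoc_p = if (is.null(assoc)) NA_real_ else assoc$p.value)
    log_stage("families", sprintf("%d pairs, mean SS %.3f", nrow(pairs),
                                  mean(pairs$ss)))
  }

  if (need("features")) {
    ft <- simulate_feature_table(seed = child_seed(config$seed, 6))
    fw <- rrelieff(ft$x, ft$y)
    write_tsv(data.frame(feature = names(fw$weights),
                         weight = unname(fw$weights),
                         rank = match(names(fw$weights), fw$rank)),
              p("feature_weights.tsv"))
    emit("features", p("feature_weights.tsv"))
    reg <- regress_response_on_feature(ft$x, ft$y, ft$planted$feature)
    summaries$features <- list(top_feature = fw$rank[1],
                               planted_feature = ft$planted$feature,
                               regression_slope = reg$slope,
                               regression_p = reg$p.value)
    log_stage("features", sprintf("top feature: %s", fw$rank[1]))
  }

  if (need("regions")) {
    genes_r <- simulate_genes(sc, seed = child_seed(config$seed, 2))
    biased <- simulate_sites(sc, maf, genes = genes_r,
                             positional_bias = c("5prime" = 0.15,
                                                 "middle" = 0.15,
                                                 "3prime" = 0.7),
                             seed = child_seed(config$seed, 7))
    assigns <- do.call(rbind, lapply(names(biased$sites), function(rbp) {
      recs <- map_sites(biased$sites[[rbp]], index, sc$total_species)
      a <- assign_sites(recs, genes_r)
      if (nrow(a)) cbind(rbp = rbp, a) else NULL
    }))
    rc <- suppressWarnings(region_comparison(assigns))
    write_tsv(rc$medians, p("region_medians.tsv"))
    emit("regions", p("region_medians.tsv"))
    write_tsv(rc$tests, p("region_tests.tsv"))
    emit("regions", p("region_tests.tsv"))
    summaries$regions <- rc$summary
    log_stage("regions", sprintf("%d/%d RBPs with 3' > 5' significance",
                                 rc$summary$n_3prime_gt_5prime,
                                 rc$summary$n_rbps))
  }

  if (need("enrich")) {
    gs <- simulate_gene_scores(seed = child_seed(config$seed, 8))
    sets <- simulate_gene_sets(gs$scores, gs$planted_genes,
                               seed = child_seed(config$seed, 9))
    write_gmt(sets, p("gene_sets.gmt")); emit("enrich", p("gene_sets.gmt"))
    et <- enrich_collection(gs$scores, sets, n_perm = config$n_perm,
                            seed = child_seed(config$seed, 10))
    write_tsv(et, p("enrichment.tsv")); emit("enrich", p("enrichment.tsv"))
    summaries$enrich <- list(
      top_set = et$set[1],
      planted_corrected_p = et$corrected_p[et$set == "planted_set"],
      n_significant_sets = sum(et$significant))
    log_stage("enrich", sprintf("top set: %s (corrected p = %g)", et$set[1],
                                et$corrected_p[1]))
  }

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, p("manifest.tsv"))
  attr(manifest, "summaries") <- summaries
  manifest
}
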