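test_that("retention endpoints: all species vs reference-only blocks", {
  sc1 <- synthetic_scenario(
    chrom_lengths = c(chrS1 = 2000),
    clades = list(clade_spec("m", c("hsap", "a", "b"), 1),
                  clade_spec("l", c("x", "y"), 1)),
    hot_fraction = 0)
  maf1 <- simulate_maf(sc1, seed = 41)
  expect_true(all(maf1$membership))
  idx <- index_blocks(read_maf(text = maf1$maf))
  st <- simulate_sites(sc1, maf1, seed = 42)
  recs <- map_sites(st$sites[[1]], idx, sc1$total_species)
  expect_true(all(recs$P[recs$mapped] == 100))

  sc0 <- synthetic_scenario(
    chrom_lengths = c(chrS1 = 2000),
    clades = list(clade_spec("m", c("hsap", "a", "b"), 0),
                  clade_spec("l", c("x", "y"), 0)),
    hot_fraction = 0)
  maf0 <- simulate_maf(sc0, seed = 43)
  expect_true(all(maf0$truth$n_species == 1))
  expect_true(all(maf0$membership[, "hsap"]))
})

test_that("planted clade retention probabilities are recovered from truth", {
  sc <- synthetic_scenario(chrom_lengths = c(chrS1 = 30000),
                           hot_fraction = 0)
  maf <- simulate_maf(sc, seed = 44)
  nb <- nrow(maf$truth)
  expect_gt(nb, 300)
  for (cl in sc$clades) {
    sp <- setdiff(cl$species, sc$reference)
    frac <- mean(maf$membership[, sp])
    n <- nb * length(sp)
    ci <- qbinom(c(0.005, 0.995), n, cl$retention) / n
    expect_gte(frac, ci[1])
    expect_lte(frac, ci[2])
  }
})

test_that("simulated MAF re-parses losslessly and blocks tile the reference", {
  sc <- synthetic_scenario(chrom_lengths = c(chrS1 = 5000, chrS2 = 3000))
  maf <- simulate_maf(sc, seed = 45)
  blocks <- read_maf(text = maf$maf)
  expect_equal(length(blocks), nrow(maf$truth))
  got <- data.frame(
    chrom = vapply(blocks, `[[`, "", "ref_chrom"),
    start = vapply(blocks, `[[`, 0, "ref_start"),
    end = vapply(blocks, `[[`, 0, "ref_end"))
  expect_equal(got$start, maf$truth$start)
  expect_equal(got$end, maf$truth$end)
  expect_equal(got$chrom, maf$truth$chrom)
  # gap_fraction = 0: consecutive blocks on a chromosome abut
  for (ch in names(sc$chrom_lengths)) {
    tt <- maf$truth[maf$truth$chrom == ch, ]
    expect_equal(tt$start[-1], tt$end[-nrow(tt)])
  }
  # species membership in the text matches the truth table
  for (b in sample(seq_along(blocks), 20)) {
    expect_setequal(blocks[[b]]$rows$species,
                    colnames(maf$membership)[maf$membership[b, ]])
  }
  # determinism
  expect_identical(maf$maf, simulate_maf(sc, seed = 45)$maf)
})

test_that("planted unmappable sites fail containment at the planted rate", {
  sc <- synthetic_scenario(chrom_lengths = c(chrS1 = 30000), n_rbps = 1,
                           sites_per_rbp = 1000,
                           unmappable_fraction = 0.1, hot_fraction = 0)
  maf <- simulate_maf(sc, seed = 46)
  idx <- index_blocks(read_maf(text = maf$maf))
  st <- simulate_sites(sc, maf, seed = 47)
  recs <- map_sites(st$sites[[1]], idx, sc$total_species)
  # intent matches outcome exactly: straddlers unmapped, others mapped
  expect_equal(!recs$mapped, st$truth$intended == "unmappable")
  n_unmapped <- sum(!recs$mapped)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(n_unmapped, ci[1])
  expect_lte(n_unmapped, ci[2])
})

test_that("positional bias routes sites to the intended gene thirds", {
  sc <- synthetic_scenario(chrom_lengths = c(chrS1 = 50000), n_rbps = 2,
                           sites_per_rbp = 500, unmappable_fraction = 0)
  maf <- simulate_maf(sc, seed = 48)
  genes <- simulate_genes(sc, n_genes = 20, seed = 49)
  bias <- c("5prime" = 0.15, "middle" = 0.15, "3prime" = 0.7)
  st <- simulate_sites(sc, maf, genes = genes, positional_bias = bias,
                       seed = 50)
  frac3 <- mean(st$truth$region == "3prime")
  n <- nrow(st$truth)
  ci <- qbinom(c(0.005, 0.995), n, 0.7) / n
  expect_gte(frac3, ci[1])
  expect_lte(frac3, ci[2])
  # planted regions agree with assign_sites on the midpoint rule
  recs <- st$sites[[1]]
  recs$P <- 50
  a <- assign_sites(recs, genes)
  truth1 <- st$truth[st$truth$rbp == "RBP01", ]
  m <- merge(a, truth1[, c("name", "region")], by = "name",
             suffixes = c("", ".planted"))
  expect_equal(m$region, m$region.planted)
})

test_that("zero sites per RBP yields empty BED sets", {
  sc <- synthetic_scenario(chrom_lengths = c(chrS1 = 3000), n_rbps = 2,
                           sites_per_rbp = 0)
  maf <- simulate_maf(sc, seed = 51)
  st <- simulate_sites(sc, maf, seed = 52)
  expect_equal(nrow(st$sites[[1]]), 0)
})

test_that("feature table plants exactly one informative feature", {
  ft <- simulate_feature_table(n_rbps = 60, seed = 53)
  expect_equal(dim(ft$x), c(60, 11))
  expect_length(ft$y, 60)
  expect_true(all(ft$y >= 0 & ft$y <= 100))
  cors <- abs(cor(ft$x, ft$y))
  expect_equal(rownames(cors)[which.max(cors)], ft$planted$feature)
  # effect = 0 plants nothing: response uncorrelated with the nominal target
  ft0 <- simulate_feature_table(n_rbps = 60, effect = 0, seed = 54)
  expect_lt(abs(cor(ft0$x[, ft0$planted$feature], ft0$y)), 0.4)
  expect_error(simulate_feature_table(n_rbps = 5), "n_rbps")
})

test_that("gene score and gene set simulators expose their planted truth", {
  gs <- simulate_gene_scores(n_genes = 400, planted_size = 25, shift = 30,
                             seed = 55)
  expect_length(gs$scores, 400)
  expect_length(gs$planted_genes, 25)
  expect_gt(median(gs$scores[gs$planted_genes]),
            median(gs$scores[setdiff(names(gs$scores),
                                     gs$planted_genes)]) + 20)
  sets <- simulate_gene_sets(gs$scores, gs$planted_genes, n_random = 4,
                             seed = 56)
  expect_length(sets, 5)
  expect_equal(sets$planted_set$genes, gs$planted_genes)
  expect_error(simulate_gene_sets(numeric(0)), "empty")
})
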