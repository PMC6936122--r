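test_that("map_site computes P = (N / totalSpecies) * 100 on contained sites", {
  idx <- two_block_index()
  # 23 distinct species in block 1 of 46 -> P = 50
  r <- map_site("chr1", 100, 120, idx, total_species = 46)
  expect_true(r$mapped)
  expect_equal(r$n_species, 23)
  expect_equal(r$P, 50)
  expect_length(r$species_set, 23)
  # straddling the boundary between blocks [100,150) and [150,200)
  expect_false(map_site("chr1", 140, 160, idx, total_species = 46)$mapped)
})

test_that("containment is strict: boundary-straddling sites are unmapped", {
  txt <- maf_text(list(
    list(score = 1, rows = list(srow("hg19.chr1", 100, 50,
                                     src_size = 1000)))))
  idx <- index_blocks(read_maf(text = txt))
  expect_true(map_site("chr1", 100, 150, idx, 46)$mapped)
  expect_false(map_site("chr1", 140, 160, idx, 46)$mapped)
  expect_false(map_site("chr1", 99, 119, idx, 46)$mapped)
  expect_false(map_site("chr2", 100, 120, idx, 46)$mapped)
})

test_that("P endpoints: full block 100, reference-only block 100/46", {
  rows_all <- c(list(srow("hg19.chr1", 0, 30, src_size = 1000)),
                lapply(sprintf("sp%02d", 1:45),
                       function(s) srow(paste0(s, ".c"), 0, 30)))
  txt <- maf_text(list(
    list(score = 1, rows = rows_all),
    list(score = 1, rows = list(srow("hg19.chr1", 30, 30,
                                     src_size = 1000)))))
  idx <- index_blocks(read_maf(text = txt))
  expect_equal(map_site("chr1", 0, 20, idx, 46)$P, 100)
  expect_equal(map_site("chr1", 30, 50, idx, 46)$P, 100 / 46)
  expect_equal(map_site("chr1", 30, 50, idx, 46)$P, 2.1739,
               tolerance = 1e-4)
  expect_error(map_sites(data.frame(chrom = "chr1", start = 0, end = 20),
                         idx, total_species = 0), "total_species")
})

test_that("duplicate rows for one species count once in N", {
  txt <- maf_text(list(
    list(score = 1, rows = list(srow("hg19.chr1", 0, 30, src_size = 1000),
                                srow("mm10.chr3", 0, 30),
                                srow("mm10.chr8", 40, 30)))))
  idx <- index_blocks(read_maf(text = txt))
  expect_equal(map_site("chr1", 0, 20, idx, 46)$n_species, 2)
})

test_that("among multiple containing blocks the highest score wins", {
  txt <- maf_text(list(
    list(score = 3, rows = list(srow("hg19.chr1", 0, 100, src_size = 1000),
                                srow("sp01.c", 0, 100))),
    list(score = 9, rows = list(srow("hg19.chr1", 0, 100,
                                     src_size = 1000))),
    list(score = 9, rows = list(srow("hg19.chr1", 10, 100,
                                     src_size = 1000)))))
  idx <- index_blocks(read_maf(text = txt))
  # score 9 beats 3; between the two score-9 blocks, lower ref_start wins
  expect_equal(map_site("chr1", 20, 40, idx, 46)$block_id, 2)
})

test_that("indexed mapping equals the brute-force containment oracle", {
  sc <- synthetic_scenario(chrom_lengths = c(chrS1 = 6000, chrS2 = 4000),
                           gap_fraction = 0.3)
  maf <- simulate_maf(sc, seed = 21)
  blocks <- read_maf(text = maf$maf)
  idx <- index_blocks(blocks)
  set.seed(22)
  n <- 300
  sites <- data.frame(
    chrom = sample(c("chrS1", "chrS2"), n, TRUE),
    start = sample(0:5900, n, TRUE))
  sites$end <- sites$start + sample(c(5, 20, 60), n, TRUE)
  got <- map_sites(sites, idx, 46)
  for (i in seq_len(n)) {
    want <- brute_force_map(sites[i, ], blocks, 46)
    expect_equal(got$mapped[i], want$mapped)
    expect_equal(got$block_id[i], want$block_id)
    expect_equal(got$P[i], want$P)
  }
})

test_that("profile_rbp summarises mapped records and flags empty profiles", {
  idx <- two_block_index()
  sites <- data.frame(chrom = "chr1", start = c(100, 110, 120, 300),
                      end = c(120, 130, 140, 320))
  pr <- profile_rbp(sites, idx, 46, "X")
  expect_equal(pr$n_mapped, 3)
  expect_equal(pr$n_unmapped, 1)
  expect_equal(pr$median_P, 50)
  # all unmapped -> undefined median, flagged
  pr0 <- profile_rbp(data.frame(chrom = "chrZ", start = 0:3,
                                end = 20:23), idx, 46, "Y")
  expect_equal(pr0$n_unmapped, 4)
  expect_true(is.na(pr0$median_P))
  expect_true(isTRUE(attr(pr0, "no_mapped_sites")))
  # unmapped-as-zero alternative treatment pulls the lower quartile down
  przero <- profile_rbp(sites, idx, 46, "X", unmapped_as_zero = TRUE)
  expect_equal(przero$median_P, 50)
  expect_equal(przero$quartiles[1], quantile(c(0, 50, 50, 50), 0.25,
                                             names = FALSE))
})

test_that("per-site P in synthetic MAF matches a direct recount of rows", {
  sc <- synthetic_scenario(chrom_lengths = c(chrS1 = 4000))
  maf <- simulate_maf(sc, seed = 31)
  blocks <- read_maf(text = maf$maf)
  idx <- index_blocks(blocks)
  st <- simulate_sites(sc, maf, seed = 32)
  recs <- map_sites(st$sites[[1]], idx, sc$total_species)
  m <- recs[recs$mapped, ]
  for (i in seq_len(min(nrow(m), 50))) {
    n_direct <- length(unique(blocks[[m$block_id[i]]]$rows$species))
    expect_equal(m$n_species[i], n_direct)
    expect_equal(m$P[i], n_direct / 46 * 100)
  }
  # scale correctness: 100/totalSpecies <= P <= 100
  expect_true(all(m$P >= 100 / 46 - 1e-12 & m$P <= 100 + 1e-12))
})

test_that("species presence matrix endpoints and reference column", {
  idx <- two_block_index()
  pr <- profile_rbp(data.frame(chrom = "chr1", start = c(100, 105),
                               end = c(120, 125)), idx, 46, "X")
  m <- species_presence_matrix(list(pr), idx)
  expect_equal(unname(m["X", "hg19"]), 100)    # reference in every block
  expect_equal(unname(m["X", "sp01"]), 100)    # present in the only block hit
  expect_true(all(m >= 0 & m <= 100))
  # a profile hitting only the reference-only block: all others 0
  pr2 <- profile_rbp(data.frame(chrom = "chr1", start = 160, end = 180),
                     idx, 46, "Y")
  m2 <- species_presence_matrix(list(pr2), idx)
  expect_equal(unname(m2["Y", "sp01"]), 0)
  expect_equal(unname(m2["Y", "hg19"]), 100)
})

test_that("compare_groups matches exact rank-sum enumeration", {
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
  # identical lists: p = 1 up to tie handling
  expect_gt(compare_groups(c(5, 6, 7), c(5, 6, 7))$p.value, 0.99)
  # complete separation, n = 3 vs 3: enumerate all rank assignments
  a <- c(90, 91, 92); b <- c(10, 11, 12)
  combos <- combn(6, 3)
  w_obs <- sum(rank(c(a, b))[1:3]) - 3 * 4 / 2
  ws <- apply(combos, 2, function(ix) sum(seq_len(6)[ix]) - 6)
  p_enum <- mean(ws >= w_obs) + mean(ws <= (9 - w_obs))  # two-sided
  got <- compare_groups(a, b)
  expect_equal(got$p.value, p_enum)
  expect_equal(got$p.value, 0.1)
  # large shifted samples are overwhelmingly significant
  set.seed(5)
  x <- rnorm(200, 50, 10)
  expect_lt(compare_groups(x + 50, x)$p.value, 1e-6)
})

test_that("tied small samples use exact enumeration of the rank sum", {
  # oracle: enumerate every subset assignment of the pooled tied values
  enum_p <- function(a, b) {
    pool <- c(a, b); na <- length(a)
    r <- rank(pool)
    ws <- apply(combn(length(pool), na), 2, function(ix) sum(r[ix]))
    w <- sum(r[seq_len(na)])
    min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
  }
  set.seed(6)
  for (i in 1:10) {
    a <- sample(1:4, sample(3:5, 1), TRUE)
    b <- sample(2:6, sample(3:5, 1), TRUE)
    expect_equal(compare_groups(a, b)$p.value, enum_p(a, b),
                 tolerance = 1e-12)
  }
  # ties deep in the tails still resolve beyond the normal-approximation
  # floor: complete separation of 37 vs 9 tied-laden values
  a <- rep(c(80, 85, 90), length.out = 37)
  b <- rep(c(10, 15), length.out = 9)
  expect_lt(compare_groups(a, b)$p.value, 1e-8)
})
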