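gene_row <- function(start, end, strand, id = "G1", chrom = "chr1") {
  data.frame(geneId = id, symbol = paste0("SYM_", id), chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("genes split into exact thirds on both strands", {
  s <- segment_gene(gene_row(0, 300, "+"))
  expect_equal(s$start[s$region == "5prime"], 0)
  expect_equal(s$end[s$region == "5prime"], 100)
  expect_equal(s$start[s$region == "middle"], 100)
  expect_equal(s$start[s$region == "3prime"], 200)
  expect_equal(s$end[s$region == "3prime"], 300)
  # strand reflection: 5' has the larger genomic coordinates on '-'
  sm <- segment_gene(gene_row(0, 300, "-"))
  expect_equal(sm$start[sm$region == "5prime"], 200)
  expect_equal(sm$end[sm$region == "5prime"], 300)
  expect_equal(sm$start[sm$region == "3prime"], 0)
  expect_equal(sm$end[sm$region == "3prime"], 100)
  expect_error(segment_gene(gene_row(0, 2, "+")), "shorter than 3")
})

test_that("remainder bp go to the transcriptionally-last segments", {
  s <- segment_gene(gene_row(0, 301, "+"))
  lens <- setNames(s$end - s$start, s$region)
  expect_equal(unname(lens[c("5prime", "middle", "3prime")]),
               c(100, 100, 101))
  s2 <- segment_gene(gene_row(0, 302, "+"))
  lens2 <- setNames(s2$end - s2$start, s2$region)
  expect_equal(unname(lens2[c("5prime", "middle", "3prime")]),
               c(100, 101, 101))
  # on '-' the extra bp sits at the transcriptional 3' end, i.e. low coords
  sm <- segment_gene(gene_row(0, 301, "-"))
  lensm <- setNames(sm$end - sm$start, sm$region)
  expect_equal(unname(lensm[c("5prime", "middle", "3prime")]),
               c(100, 100, 101))
  expect_equal(sm$start[sm$region == "3prime"], 0)
})

test_that("segments tile the gene span disjointly on random genes", {
  set.seed(21)
  for (i in 1:50) {
    start <- sample(0:1000, 1)
    len <- sample(3:777, 1)
    g <- gene_row(start, start + len, sample(c("+", "-"), 1))
    s <- segment_genes(g)
    expect_equal(sum(s$end - s$start), len)
    expect_true(all(abs(diff(range(s$end - s$start))) <= 1))
    o <- s[order(s$start), ]
    expect_equal(o$start[1], start)
    expect_equal(o$end[3], start + len)
    expect_equal(o$start[-1], o$end[-3])  # contiguous, disjoint
  }
})

test_that("sites are assigned to the segment containing their midpoint", {
  g <- gene_row(0, 300, "+")
  rec <- function(start, end, P = 50)
    data.frame(chrom = "chr1", start = start, end = end, name = "s", P = P)
  expect_equal(assign_sites(rec(95, 115), g)$region, "middle")  # mid 105
  expect_equal(assign_sites(rec(95, 115), gene_row(0, 300, "-"))$region,
               "middle")
  # midpoint 20 on a '-' gene falls in the 3' third
  expect_equal(assign_sites(rec(10, 30), gene_row(0, 300, "-"))$region,
               "3prime")
  expect_equal(assign_sites(rec(10, 30), g)$region, "5prime")
  # intergenic sites are unassigned; NA-P (unmapped) records dropped
  expect_equal(nrow(assign_sites(rec(500, 520), g)), 0)
  expect_equal(nrow(assign_sites(rec(10, 30, P = NA), g)), 0)
})

test_that("sites overlapping two genes are assigned once per gene", {
  genes <- rbind(gene_row(0, 300, "+", "G1"), gene_row(100, 400, "+", "G2"))
  a <- assign_sites(data.frame(chrom = "chr1", start = 140, end = 160,
                               name = "s", P = 80), genes)
  expect_equal(nrow(a), 2)
  expect_setequal(a$geneId, c("G1", "G2"))
})

test_that("reversing gene strand swaps 5' and 3' assignments", {
  set.seed(22)
  gp <- gene_row(0, 300, "+"); gm <- gene_row(0, 300, "-")
  for (i in 1:30) {
    st <- sample(0:280, 1)
    rec <- data.frame(chrom = "chr1", start = st, end = st + 20,
                      name = "s", P = 50)
    rp <- assign_sites(rec, gp)$region
    rm <- assign_sites(rec, gm)$region
    expect_equal(rm, chartr("53", "35", rp))
  }
})

test_that("planted 3' > 5' effects are detected and nulls are calibrated", {
  set.seed(23)
  mk_assign <- function(rbp, p3, p5) {
    data.frame(rbp = rbp,
               chrom = "chr1", start = 0, end = 20, name = "s",
               P = c(rnorm(50, p3, 5), rnorm(50, p5, 5),
                     rnorm(50, (p3 + p5) / 2, 5)),
               geneId = "G1",
               region = rep(c("3prime", "5prime", "middle"), each = 50))
  }
  planted <- do.call(rbind, lapply(sprintf("R%02d", 1:10), mk_assign,
                                   p3 = 70, p5 = 40))
  rc <- region_comparison(planted)
  expect_equal(rc$summary$n_rbps, 10)
  expect_gte(rc$summary$n_3prime_gt_5prime, 9)
  expect_equal(nrow(rc$tests), 30)  # 3 comparisons per RBP
  # identical-distribution single RBP with constant values: p = 1
  flat <- data.frame(rbp = "R", chrom = "chr1", start = 0, end = 20,
                     name = "s", P = rep(60, 6), geneId = "G1",
                     region = rep(c("3prime", "5prime"), each = 3))
  rcf <- region_comparison(flat)
  expect_equal(rcf$tests$p_value[rcf$tests$comparison == "3prime vs 5prime"],
               1)
  expect_equal(rcf$summary$n_3prime_gt_5prime, 0)
  # an RBP with all sites in one region is skipped with a warning
  one <- data.frame(rbp = "R", chrom = "chr1", start = 0, end = 20,
                    name = "s", P = rnorm(10, 50), geneId = "G1",
                    region = "middle")
  expect_warning(rc1 <- region_comparison(one), "fewer than 2")
  expect_equal(rc1$summary$n_rbps, 0)
})
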