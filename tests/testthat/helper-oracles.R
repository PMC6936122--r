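# Hand-built fixtures and independent brute-force oracles used across the
# suite. Oracles deliberately share no code with the package paths they
# check.

# Compose MAF text from a list of blocks given as
# list(score, rows = list(c(src, start, size, strand, srcSize, text), ...))
maf_text <- function(blocks, header = TRUE) {
  out <- if (header) "##maf version=1" else character()
  for (b in blocks) {
    out <- c(out, sprintf("a score=%s", b$score),
             vapply(b$rows, function(r) paste("s", paste(r, collapse = " ")),
                    ""),
             "")
  }
  out
}

# A MAF row whose text is just 'A' repeated size times.
srow <- function(src, start, size, strand = "+", src_size = 100000) {
  c(src, start, size, strand, src_size, strclone("A", size))
}
strclone <- function(ch, n) paste(rep(ch, n), collapse = "")

# Brute-force site-to-block mapping: linear scan over all blocks, full
# containment, then highest score / lowest ref_start tie-break; recounts
# species directly from the rows.
brute_force_map <- function(site, blocks, total_species) {
  best <- NULL
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (b$ref_chrom == site$chrom && b$ref_start <= site$start &&
        site$end <= b$ref_end) {
      if (is.null(best) || b$score > blocks[[best]]$score ||
          (b$score == blocks[[best]]$score &&
           b$ref_start < blocks[[best]]$ref_start))
        best <- i
    }
  }
  if (is.null(best))
    return(list(mapped = FALSE, block_id = NA_integer_,
                n_species = NA_integer_, P = NA_real_))
  n <- length(unique(blocks[[best]]$rows$species))
  list(mapped = TRUE, block_id = best, n_species = n,
       P = n / total_species * 100)
}

# Naive RReliefF: plain double loop written straight from the accumulation
# description, no shared helpers with rrelieff().
naive_rrelieff <- function(x, y, k, sigma = 20) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  # min-max normalize
  for (j in seq_len(p)) {
    r <- range(x[, j])
    x[, j] <- if (r[2] > r[1]) (x[, j] - r[1]) / (r[2] - r[1]) else 0
  }
  yr <- max(y) - min(y)
  w_rank <- exp(-(seq_len(k) / sigma)^2); w_rank <- w_rank / sum(w_rank)
  ndy <- 0; ndf <- rep(0, p); ndydf <- rep(0, p)
  for (i in seq_len(n)) {
    d <- rep(0, n)
    for (j in seq_len(n)) d[j] <- sum(abs(x[i, ] - x[j, ]))
    others <- setdiff(seq_len(n), i)
    nb <- others[order(d[others])][seq_len(k)]
    for (r in seq_len(k)) {
      j <- nb[r]
      dy <- abs(y[i] - y[j]) / yr
      ndy <- ndy + w_rank[r] * dy
      for (f in seq_len(p)) {
        df <- abs(x[i, f] - x[j, f])
        ndf[f] <- ndf[f] + w_rank[r] * df
        ndydf[f] <- ndydf[f] + w_rank[r] * dy * df
      }
    }
  }
  w <- ndydf / ndy - (ndf - ndydf) / (n - ndy)
  names(w) <- colnames(x)
  w
}

# Tiny two-block index used by several conservation tests: chr1 has a
# 23-species block [100,150) and a reference-only block [150,200).
two_block_index <- function() {
  species <- c("hg19", sprintf("sp%02d", 1:22))
  rows <- c(list(srow("hg19.chr1", 100, 50, src_size = 1000)),
            lapply(species[-1], function(s) srow(paste0(s, ".chr5"), 0, 50)))
  blocks <- maf_text(list(
    list(score = 10, rows = rows),
    list(score = 5, rows = list(srow("hg19.chr1", 150, 50,
                                     src_size = 1000)))))
  index_blocks(read_maf(text = blocks))
}
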