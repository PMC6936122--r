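# Readers/writers for the standard text formats the pipeline touches:
# MAF (UCSC multiz dialect), BED3-BED6, GMT, Newick, and a gene-annotation
# TSV. All coordinates are 0-based half-open internally, matching the native
# convention of both BED and MAF reference rows.

# Slurp lines from a path (plain or gzip) or from a `text` character vector.
io_lines <- function(path = NULL, text = NULL) {
  if (!is.null(text)) return(unlist(strsplit(text, "\n", fixed = TRUE)))
  stopifnot(is.character(path), length(path) == 1L)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a MAF multiple-alignment file into a list of alignment blocks
#'
#' Parses the UCSC multiz MAF dialect: blocks begin with an `a` line
#' (optionally carrying `score=`), alignment rows are `s` lines; `i`, `e`,
#' and `q` lines, comments and the optional `##maf` header are skipped.
#' The first `s` line of each block is the reference (human) row and anchors
#' the block to 0-based half-open reference coordinates.
#'
#' @param path path to a MAF file (plain or gzip-compressed).
#' @param text optional character vector of MAF text, used instead of `path`.
#' @return list of `maf_block` objects, in file order. Each block is a list
#'   with elements `score`, `ref_chrom`, `ref_start`, `ref_end` (half-open),
#'   and `rows`, a data.frame with columns `src`, `species` (the `src` prefix
#'   before the first '.'), `start`, `size`, `strand`, `src_size`, `text`.
#' @details Blocks whose reference row is on the '-' strand are rejected with
#'   a warning (multiz reference rows are '+'). Malformed `s` lines raise an
#'   error naming the offending line number.
#' @seealso [index_blocks()], [map_sites()]
#' @export
read_maf <- function(path = NULL, text = NULL) {
  lines <- io_lines(path, text)
  # Vectorized single pass: blocks are delimited by 'a' lines; 'i'/'e'/'q'
  # annotation lines, comments and blanks are skipped (only aligned 's' rows
  # count toward species membership).
  a_idx <- grep("^a([ \t]|$)", lines)
  s_idx <- grep("^s[ \t]", lines)
  if (!length(a_idx) || !length(s_idx)) return(list())
  block_of <- findInterval(s_idx, a_idx)
  if (any(block_of == 0L))
    stop("MAF 's' line ", s_idx[block_of == 0L][1],
         " appears before any 'a' block line", call. = FALSE)
  f <- strsplit(trimws(lines[s_idx]), "[ \t]+")
  nf <- lengths(f)
  if (any(nf != 7L))
    stop("malformed MAF 's' line ", s_idx[nf != 7L][1],
         ": expected 7 fields, got ", nf[nf != 7L][1], call. = FALSE)
  fm <- matrix(unlist(f), nrow = 7L)
  start <- suppressWarnings(as.integer(fm[3, ]))
  size <- suppressWarnings(as.integer(fm[4, ]))
  src_size <- suppressWarnings(as.integer(fm[6, ]))
  bad <- is.na(start) | is.na(size) | is.na(src_size)
  if (any(bad))
    stop("malformed MAF 's' line ", s_idx[bad][1],
         ": non-integer coordinate field", call. = FALSE)
  bad <- !fm[5, ] %in% c("+", "-")
  if (any(bad))
    stop("malformed MAF 's' line ", s_idx[bad][1], ": bad strand '",
         fm[5, bad][1], "'", call. = FALSE)
  bad <- nchar(gsub("-", "", fm[7, ], fixed = TRUE)) != size
  if (any(bad))
    stop("malformed MAF 's' line ", s_idx[bad][1],
         ": ungapped sequence length does not match size field",
         call. = FALSE)
  scores <- vapply(lines[a_idx], function(l) {
    m <- regmatches(l, regexpr("score=([-0-9.eE+]+)", l))
    if (length(m)) as.numeric(sub("score=", "", m)) else 0
  }, 0, USE.NAMES = FALSE)

  rows_all <- data.frame(
    src = fm[2, ], species = sub("\\..*$", "", fm[2, ]),
    start = start, size = size, strand = fm[5, ], src_size = src_size,
    text = fm[7, ], stringsAsFactors = FALSE)
  blocks <- vector("list", length(unique(block_of)))
  n_out <- 0L
  for (b in split(seq_along(s_idx), block_of)) {
    rows <- rows_all[b, , drop = FALSE]
    rownames(rows) <- NULL
    if (rows$strand[1] != "+") {
      warning("MAF block with '-' strand reference row rejected (ref src: ",
              rows$src[1], ")", call. = FALSE)
      next
    }
    n_out <- n_out + 1L
    blocks[[n_out]] <- structure(
      list(score = scores[block_of[b[1]]],
           ref_chrom = sub("^[^.]*\\.", "", rows$src[1]),
           ref_start = rows$start[1],
           ref_end = rows$start[1] + rows$size[1],
           rows = rows),
      class = "maf_block")
  }
  blocks[seq_len(n_out)]
}

#' Write alignment blocks as MAF text
#'
#' @param blocks list of `maf_block` objects as returned by [read_maf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines(sprintf("a score=%g", b$score), con)
    writeLines(sprintf("s %s %d %d %s %d %s",
                       b$rows$src, b$rows$start, b$rows$size,
                       b$rows$strand, b$rows$src_size, b$rows$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' @param path path to a BED3-BED6 file (plain or gzip); tab-separated.
#' @param text optional character vector of BED text.
#' @param strict20 if `TRUE`, require every interval to be exactly 20 bp, the
#'   binding-site length this pipeline analyses.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name` (default `""`), `score` (default 0), `strand`
#'   (default `"."`).
#' @export
read_bed <- function(path = NULL, text = NULL, strict20 = FALSE) {
  lines <- io_lines(path, text)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(f)
  if (any(ncols < 3L))
    stop("BED record ", which(ncols < 3L)[1], " has fewer than 3 columns",
         call. = FALSE)
  get_col <- function(j, default) {
    vapply(f, function(x) if (length(x) >= j) x[[j]] else default, "")
  }
  start <- suppressWarnings(as.integer(get_col(2L, NA)))
  end <- suppressWarnings(as.integer(get_col(3L, NA)))
  if (anyNA(start) || anyNA(end))
    stop("BED record ", which(is.na(start) | is.na(end))[1],
         ": non-integer coordinates", call. = FALSE)
  bad <- which(end <= start)
  if (length(bad))
    stop("BED record ", bad[1], ": end <= start (", start[bad[1]], ", ",
         end[bad[1]], ")", call. = FALSE)
  if (strict20) {
    off <- which(end - start != 20L)
    if (length(off))
      stop("BED record ", off[1], ": length ", end[off[1]] - start[off[1]],
           " != 20 with strict20 = TRUE", call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(get_col(5L, "0")))
  score[is.na(score)] <- 0
  strand <- get_col(6L, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  data.frame(chrom = get_col(1L, ""), start = start, end = end,
             name = get_col(4L, ""), score = score, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write intervals to a BED6 file
#'
#' @param x data.frame with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand` filled with BED defaults when absent.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else ""
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end), name, score, strand), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then one or more gene symbols,
#' tab-separated. Duplicate genes within a line are deduplicated; when two
#' lines share a set name the later line wins, with a warning.
#'
#' @param path path to a GMT file (plain or gzip).
#' @param text optional character vector of GMT text.
#' @return named list of gene sets; each element is a list with `name`,
#'   `description` and `genes` (character vector, unique).
#' @export
read_gmt <- function(path = NULL, text = NULL) {
  lines <- io_lines(path, text)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, ": fewer than 3 fields", call. = FALSE)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT line ", i, ": no genes", call. = FALSE)
    if (f[1] %in% names(sets))
      warning("duplicate gene-set name '", f[1], "': later line wins",
              call. = FALSE)
    sets[[f[1]]] <- list(name = f[1], description = f[2], genes = genes)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene sets as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a rooted Newick tree with branch lengths
#'
#' Thin validating wrapper over [ape::read.tree()]: duplicate leaf labels are
#' an error and missing branch lengths default to 0.
#'
#' @param path path to a Newick file.
#' @param text optional Newick string.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(io_lines(path), collapse = "")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in Newick tree", call. = FALSE)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Read a gene-annotation table
#'
#' Tab-separated with header columns `geneId`, `symbol`, `chrom`, `start`,
#' `end`, `strand`; coordinates 0-based half-open; strand must be '+' or '-'.
#'
#' @param path path to the TSV (plain or gzip).
#' @param text optional character vector of TSV text.
#' @return data.frame with those six columns.
#' @export
read_genes <- function(path = NULL, text = NULL) {
  lines <- io_lines(path, text)
  genes <- read.table(text = lines, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "")
  need <- c("geneId", "symbol", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols))
    stop("gene annotation missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'", call. = FALSE)
  if (any(genes$end <= genes$start))
    stop("gene annotation with end <= start", call. = FALSE)
  genes[need]
}

#' Write a gene-annotation table
#' @param genes data.frame as returned by [read_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  write_tsv(genes, path)
}
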