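# Genomic interval plumbing. All user-facing interval tables use the BED
# convention: 0-based start, exclusive end. Conversion to GenomicRanges
# (1-based, closed) happens only inside these helpers.

#' Convert a BED-style interval table to GRanges
#'
#' @param bed data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive); extra columns are carried as metadata.
#' @return A [GenomicRanges::GRanges] object.
#' @keywords internal
bed_to_gr <- function(bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  if (nrow(bed) == 0) {
    return(GenomicRanges::GRanges())
  }
  if (any(bed$start < 0) || any(bed$end <= bed$start)) {
    stop("invalid interval: require 0 <= start < end")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  )
  extra <- setdiff(names(bed), c("chrom", "start", "end"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- bed[, extra, drop = FALSE]
  }
  gr
}

#' Convert GRanges back to a BED-style interval table
#' @param gr A GRanges object.
#' @return data.frame with 0-based half-open `chrom`, `start`, `end`.
#' @keywords internal
gr_to_bed <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

# overlap counts/hits on BED tables with harmonized seqlevels (avoids
# GenomicRanges warnings when the two tables cover different chromosomes)
gr_harmonize <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

bed_count_overlaps <- function(query, subject) {
  gr <- gr_harmonize(bed_to_gr(query), bed_to_gr(subject))
  GenomicRanges::countOverlaps(gr[[1]], gr[[2]])
}

bed_find_overlaps <- function(query, subject) {
  gr <- gr_harmonize(bed_to_gr(query), bed_to_gr(subject))
  GenomicRanges::findOverlaps(gr[[1]], gr[[2]])
}

# sort by (chrom, start, end); stable
sort_bed <- function(bed) {
  bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
}

# validate a named genome vector (chrom -> length in bp)
check_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(genome))) {
    stop("overlapping (duplicated) chromosome definitions in genome")
  }
  if (any(genome <= 0)) stop("chromosome lengths must be positive")
  invisible(genome)
}

# error if any interval extends beyond its chromosome
check_bounds <- function(bed, genome, what = "interval") {
  check_genome(genome)
  bad_chrom <- !(bed$chrom %in% names(genome))
  if (any(bad_chrom)) {
    stop(sprintf("%s on undeclared chromosome: %s", what,
                 paste(unique(bed$chrom[bad_chrom]), collapse = ", ")))
  }
  over <- bed$end > unname(genome[bed$chrom])
  if (any(over)) {
    i <- which(over)[1]
    stop(sprintf("%s beyond chromosome end: %s:%d-%d",
                 what, bed$chrom[i], bed$start[i], bed$end[i]))
  }
  invisible(bed)
}

#' Write intervals as a BED file
#'
#' Writes `chrom`, `start`, `end` plus optional `name` and `score` columns
#' as tab-separated BED (no header). The HDBS writer puts the co-occupancy
#' degree in the score column.
#'
#' @param bed Interval data.frame (0-based half-open).
#' @param path Output file path.
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(bed))
  out <- bed[, cols, drop = FALSE]
  if (!"name" %in% cols && "score" %in% cols) {
    out <- cbind(out[c("chrom", "start", "end")], name = ".",
                 score = out$score)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file into an interval table
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (+ `name`, `score` if present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df
}

#' Write chromatin interaction pairs as BEDPE
#' @param pairs data.frame with columns `chrom1,start1,end1,chrom2,start2,end2`
#'   (0-based half-open) and optional `name`.
#' @param path Output file path.
#' @export
write_bedpe <- function(pairs, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  stopifnot(all(cols %in% names(pairs)))
  out <- pairs[, c(cols, intersect("name", names(pairs))), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of interaction pairs
#' @param path BEDPE file path.
#' @return data.frame of anchor pairs in 0-based half-open coordinates.
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (ncol(df) >= 7) names(df)[7] <- "name"
  df
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors (gene sets).
#' @param path Output file path.
#' @export
write_gmt <- function(sets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sets)) {
    writeLines(paste(c(nm, "pgrnet", sets[[nm]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}
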