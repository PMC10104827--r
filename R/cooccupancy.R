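# Factor x factor binding co-occupancy, sub-class clustering, and
# extraction of high-degree co-occupancy binding sites (HDBS).

#' Binarize factor occupancy over genome bins
#'
#' The genome is tiled with fixed-size bins per chromosome (last bin
#' truncated); a factor occupies a bin iff one of its peaks overlaps the
#' bin by at least 1 bp (half-open arithmetic).
#'
#' @param peaks Named list of interval data.frames (one per factor, BED
#'   convention).
#' @param genome Named vector of chromosome lengths.
#' @param bin_size Bin width in bp.
#' @return Object of class `binned_occupancy`: list with binary `matrix`
#'   (factors x bins), `bin_size`, `genome`, and per-chromosome bin counts.
#' @export
bin_occupancy <- function(peaks, genome, bin_size = 1000L) {
  check_genome(genome)
  n_bins <- ceiling(genome / bin_size)
  offset <- c(0, cumsum(n_bins))[seq_along(genome)]
  names(offset) <- names(genome)
  total <- sum(n_bins)
  M <- matrix(0L, nrow = length(peaks), ncol = total,
              dimnames = list(names(peaks), NULL))
  for (f in seq_along(peaks)) {
    bed <- peaks[[f]]
    if (!nrow(bed)) next
    check_bounds(bed, genome, what = sprintf("peak of '%s'", names(peaks)[f]))
    first <- bed$start %/% bin_size
    last <- (bed$end - 1L) %/% bin_size
    idx <- unlist(Map(seq.int, first, last)) +
      rep.int(offset[bed$chrom], last - first + 1L) + 1L
    M[f, unique(idx)] <- 1L
  }
  structure(list(matrix = M, bin_size = bin_size, genome = genome,
                 n_bins = n_bins), class = "binned_occupancy")
}

#' Pairwise co-occupancy Z-score matrix
#'
#' For factors a, b occupying `m_a`, `m_b` of `N` bins with `O` shared
#' bins, Z = (O - E) / sigma with E = m_a m_b / N and
#' sigma^2 = E (1 - m_a/N) (N - m_b) / (N - 1): the standardized deviation
#' of observed shared binding from a hypergeometric null of random bin
#' assignment. The diagonal is computed identically (and is the row maximum
#' by construction). A factor occupying all bins has sigma = 0; its Z
#' values are set to 0 with a warning.
#'
#' @param occ A [bin_occupancy()] result.
#' @return Symmetric numeric matrix of Z-scores with factor dimnames.
#' @export
cooccupancy_z <- function(occ) {
  stopifnot(inherits(occ, "binned_occupancy"))
  M <- occ$matrix
  if (nrow(M) < 2) stop("need >= 2 factors")
  m <- rowSums(M)
  if (any(m == 0)) {
    stop("factor(s) occupying no bins: ",
         paste(rownames(M)[m == 0], collapse = ", "))
  }
  N <- ncol(M)
  O <- M %*% t(M)
  E <- outer(m, m) / N
  V <- E * outer(1 - m / N, (N - m) / (N - 1))
  Z <- matrix(0, nrow(M), nrow(M), dimnames = dimnames(O))
  pos <- V > 0
  Z[pos] <- (O[pos] - E[pos]) / sqrt(V[pos])
  if (any(!pos)) warning("factor occupying all bins: Z set to 0 where sigma = 0")
  Z
}

#' Cluster factors into co-occupancy sub-classes
#'
#' Average-linkage hierarchical clustering on distance
#' d(a, b) = 1 - Pearson(row_a, row_b) of the Z matrix, with the tree cut
#' to exactly `n_clusters`. Deterministic given the input.
#'
#' @param z Symmetric Z matrix from [cooccupancy_z()].
#' @param n_clusters Number of sub-classes to cut.
#' @return List with `membership` (named integer vector) and `classes`
#'   (list of member-factor vectors, named by cluster).
#' @export
cluster_subclasses <- function(z, n_clusters) {
  if (n_clusters > nrow(z)) stop("n_clusters exceeds number of factors")
  sds <- apply(z, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant Z rows (correlation undefined): ",
         paste(rownames(z)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "average")
  memb <- stats::cutree(hc, k = n_clusters)
  classes <- split(names(memb), memb)
  names(classes) <- sprintf("subclass%02d", as.integer(names(classes)))
  list(membership = memb, classes = classes, hclust = hc)
}

#' Extract high-degree co-occupancy binding sites (k-of-n)
#'
#' All member peak sets are union-merged (touching intervals merge); each
#' merged interval's co-occupancy degree is the number of distinct member
#' factors overlapping it by >= 1 bp; intervals with degree >= k are
#' retained.
#'
#' @param peaks Named list of member interval data.frames (one sub-class).
#' @param k Minimum co-occupancy degree (1 <= k <= number of members).
#' @param name Sub-class name attached to the result.
#' @return data.frame `chrom`, `start`, `end`, `degree` (non-overlapping,
#'   sorted), with attribute `subclass`.
#' @export
hdbs_extract <- function(peaks, k, name = "subclass") {
  n <- length(peaks)
  if (k > n) stop("k exceeds the number of member factors")
  if (k < 1) stop("k must be >= 1")
  all_bed <- do.call(rbind, lapply(peaks, function(p) {
    p[, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (is.null(all_bed) || !nrow(all_bed)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), degree = integer(0))
    attr(out, "subclass") <- name
    return(out)
  }
  merged <- gr_to_bed(GenomicRanges::reduce(bed_to_gr(all_bed)))
  degree <- rep(0L, nrow(merged))
  for (p in peaks) {
    if (!nrow(p)) next
    degree <- degree + as.integer(bed_count_overlaps(merged, p) > 0)
  }
  out <- merged
  out$degree <- degree
  out <- out[out$degree >= k, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "subclass") <- name
  out
}

#' Annotate intervals by position relative to genes
#'
#' Distance is measured from the interval midpoint to the nearest TSS,
#' signed by gene strand (upstream negative). Category priority: promoter
#' (|d| <= `promoter_dist`) > gene body (midpoint inside a gene-body
#' extent) > distal intergenic.
#'
#' @param intervals Interval data.frame (BED convention).
#' @param annotation Gene annotation data.frame (`gene_id`, `chrom`, `tss`,
#'   `strand`, `body_start`, `body_end`).
#' @param promoter_dist Promoter half-width in bp; default 3000.
#' @return `intervals` with added `midpoint`, `nearest_gene`, `distance`,
#'   `category` columns.
#' @export
annotate_peaks <- function(intervals, annotation, promoter_dist = 3000L) {
  if (!nrow(annotation)) stop("empty annotation")
  out <- intervals
  out$midpoint <- (out$start + out$end) %/% 2L
  out$nearest_gene <- NA_character_
  out$distance <- NA_real_
  out$category <- NA_character_
  for (chr in unique(out$chrom)) {
    sel <- which(out$chrom == chr)
    ann <- annotation[annotation$chrom == chr, , drop = FALSE]
    if (!nrow(ann)) next
    ord <- order(ann$tss, ann$gene_id)
    ann <- ann[ord, , drop = FALSE]
    mid <- out$midpoint[sel]
    i <- findInterval(mid, ann$tss)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, nrow(ann))
    d_lo <- abs(mid - ann$tss[lo])
    d_hi <- abs(mid - ann$tss[hi])
    # ties at equal absolute distance go to the lower-coordinate TSS
    pick <- ifelse(d_hi < d_lo, hi, lo)
    pick[i == 0] <- 1L
    g <- ann[pick, , drop = FALSE]
    signed <- ifelse(g$strand == "+", mid - g$tss, g$tss - mid)
    inbody <- vapply(mid, function(p) {
      any(p >= ann$body_start & p < ann$body_end)
    }, logical(1))
    cat <- ifelse(abs(signed) <= promoter_dist, "promoter",
                  ifelse(inbody, "gene_body", "distal_intergenic"))
    out$nearest_gene[sel] <- g$gene_id
    out$distance[sel] <- signed
    out$category[sel] <- cat
  }
  out
}

# lookup bedGraph coverage values at integer positions (0-based);
# positions outside any segment (including off-chromosome) are 0
coverage_at <- function(cov, chrom, pos) {
  val <- numeric(length(pos))
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    seg <- cov[cov$chrom == chr, , drop = FALSE]
    if (!nrow(seg)) next
    seg <- seg[order(seg$start), , drop = FALSE]
    idx <- findInterval(pos[sel], seg$start)
    ok <- idx >= 1L
    ok[ok] <- pos[sel][ok] < seg$end[idx[ok]]
    v <- numeric(sum(sel))
    v[ok] <- seg$value[idx[ok]]
    val[sel] <- v
  }
  val
}

#' Average coverage profile around site centres
#'
#' For each mark, windows of +/- `flank` bp centred at interval midpoints
#' are averaged across sites per position bin. Windows extending past
#' chromosome bounds are zero-filled and still count in the denominator.
#'
#' @param coverage Named list of bedGraph-style data.frames
#'   (`chrom`, `start`, `end`, `value`); positions not covered are 0.
#' @param sites Interval data.frame (e.g. an HDBS set).
#' @param flank Half-window in bp; default 3000.
#' @param bin Position-bin width in bp (must divide `2 * flank`).
#' @return Matrix marks x position-bins of mean coverage; column names are
#'   bin-centre offsets from the site midpoint.
#' @export
histone_profile <- function(coverage, sites, flank = 3000L, bin = 50L) {
  if ((2L * flank) %% bin != 0L) stop("bin must divide 2*flank")
  n_bins <- (2L * flank) %/% bin
  mids <- (sites$start + sites$end) %/% 2L
  offs <- seq.int(-flank, flank - 1L)
  prof <- matrix(0, nrow = length(coverage), ncol = n_bins,
                 dimnames = list(names(coverage),
                                 seq.int(-flank + bin %/% 2L, flank, by = bin)))
  if (!nrow(sites)) return(prof)
  pos <- rep(mids, each = length(offs)) + offs
  chrom <- rep(sites$chrom, each = length(offs))
  for (mk in seq_along(coverage)) {
    v <- coverage_at(coverage[[mk]], chrom, pos)
    by_pos <- matrix(v, nrow = length(offs))  # positions x sites
    avg <- rowMeans(by_pos)
    prof[mk, ] <- colMeans(matrix(avg, nrow = bin))
  }
  prof
}
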