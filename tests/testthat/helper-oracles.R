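# Independent brute-force oracles used across the suite. These stay
# deliberately naive (per-base scans, full enumeration, triple loops) and
# never call the code paths they check.

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
oracle_hyper_enum <- function(N, K, n, k_obs) {
  u <- seq_len(N)
  module <- seq_len(K)
  draws <- utils::combn(N, n)
  ov <- apply(draws, 2, function(d) length(intersect(d, module)))
  mean(ov >= k_obs)
}

# per-base merged intervals + degree counting on a small coordinate range
oracle_hdbs <- function(peaks, k, limit = 1000L) {
  covs <- lapply(peaks, function(p) {
    v <- logical(limit)
    for (i in seq_len(nrow(p))) v[(p$start[i] + 1):p$end[i]] <- TRUE
    v
  })
  any_cov <- Reduce(`|`, covs)
  r <- rle(any_cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), degree = integer(0))
  for (i in which(r$values)) {
    run <- starts[i]:ends[i]
    deg <- sum(vapply(covs, function(v) any(v[run]), logical(1)))
    if (deg >= k) {
      out <- rbind(out, data.frame(chrom = peaks[[1]]$chrom[1],
                                   start = starts[i] - 1L, end = ends[i],
                                   degree = deg))
    }
  }
  out
}

# proximal assignment: plain double loop over (gene, interval)
oracle_proximal <- function(hdbs, annotation, window) {
  hit <- vapply(seq_len(nrow(annotation)), function(g) {
    tss <- annotation$tss[g]
    any(hdbs$chrom == annotation$chrom[g] &
          hdbs$start <= tss + window & hdbs$end > tss - window)
  }, logical(1))
  annotation$gene_id[hit]
}

# distal assignment: triple loop over (interval, pair, gene)
oracle_distal <- function(hdbs, pairs, annotation, window) {
  ov <- function(c1, s1, e1, c2, s2, e2) c1 == c2 && s1 < e2 && s2 < e1
  hits <- character(0)
  for (g in seq_len(nrow(annotation))) {
    pc <- annotation$chrom[g]
    ps <- annotation$tss[g] - window
    pe <- annotation$tss[g] + window + 1L
    for (p in seq_len(nrow(pairs))) {
      for (h in seq_len(nrow(hdbs))) {
        a1h <- ov(pairs$chrom1[p], pairs$start1[p], pairs$end1[p],
                  hdbs$chrom[h], hdbs$start[h], hdbs$end[h])
        a2h <- ov(pairs$chrom2[p], pairs$start2[p], pairs$end2[p],
                  hdbs$chrom[h], hdbs$start[h], hdbs$end[h])
        a1p <- ov(pairs$chrom1[p], pairs$start1[p], pairs$end1[p],
                  pc, ps, pe)
        a2p <- ov(pairs$chrom2[p], pairs$start2[p], pairs$end2[p],
                  pc, ps, pe)
        if ((a1h && a2p) || (a2h && a1p)) {
          hits <- c(hits, annotation$gene_id[g])
        }
      }
    }
  }
  unique(hits)
}

# signed-rank two-sided p by enumeration of all 2^n sign patterns
oracle_signed_rank <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  switch(alternative,
         greater = mean(w_all >= w_obs),
         less = mean(w_all <= w_obs),
         two.sided = min(1, 2 * min(mean(w_all >= w_obs),
                                    mean(w_all <= w_obs))))
}

# naive per-bin occupancy scan
oracle_bin_occupancy <- function(bed, chrom_len, bin_size) {
  n_bins <- ceiling(chrom_len / bin_size)
  vapply(seq_len(n_bins), function(b) {
    lo <- (b - 1L) * bin_size
    hi <- min(b * bin_size, chrom_len)
    as.integer(any(bed$start < hi & bed$end > lo))
  }, integer(1))
}

# naive per-site window averaging for coverage profiles
oracle_profile <- function(cov, sites, flank, bin) {
  value_at <- function(chr, p) {
    seg <- cov[cov$chrom == chr & cov$start <= p & cov$end > p, ]
    if (nrow(seg)) seg$value[1] else 0
  }
  n_bins <- (2 * flank) %/% bin
  acc <- matrix(0, nrow(sites), 2 * flank)
  for (i in seq_len(nrow(sites))) {
    mid <- (sites$start[i] + sites$end[i]) %/% 2
    pos <- (mid - flank):(mid + flank - 1)
    acc[i, ] <- vapply(pos, function(p) value_at(sites$chrom[i], p),
                       numeric(1))
  }
  avg <- colMeans(acc)
  vapply(seq_len(n_bins), function(b) {
    mean(avg[((b - 1) * bin + 1):(b * bin)])
  }, numeric(1))
}

# tiny deterministic sgRNA count fixture
toy_counts <- function() {
  ct <- data.frame(
    sgrna_id = c("a_sg1", "a_sg2", "b_sg1", "b_sg2"),
    gene_id = c("geneA", "geneA", "geneB", "geneB"),
    t0_r1 = c(100, 200, 50, 150), t0_r2 = c(110, 190, 60, 140),
    t14_r1 = c(10, 20, 60, 140), t14_r2 = c(12, 18, 55, 150),
    stringsAsFactors = FALSE)
  attr(ct, "timepoints") <- c(t0_r1 = "t0", t0_r2 = "t0",
                              t14_r1 = "t14", t14_r2 = "t14")
  ct
}

# small config for fast simulation-backed tests
small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 400L, n_common_essential = 20L,
         n_specific_essential = 10L,
         genome = c(chr1 = 600000L, chr2 = 600000L),
         n_shared_sites = 20L, n_background_peaks = 40L,
         n_distractor_pairs = 10L, n_samples_per_group = 5L,
         n_patients = 100L),
    list(...))
  do.call(sim_config, args)
}
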