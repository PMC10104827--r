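# Occupancy binning, co-occupancy Z statistics, sub-class clustering,
# HDBS extraction, peak annotation and coverage profiles.

make_occ <- function(M, n = ncol(M)) {
  structure(list(matrix = M, bin_size = 1000L,
                 genome = c(chr1 = n * 1000L), n_bins = c(chr1 = n)),
            class = "binned_occupancy")
}

test_that("occupancy bits follow half-open bin arithmetic", {
  genome <- c(chr1 = 10000L)
  occ <- bin_occupancy(list(f = data.frame(chrom = "chr1", start = 0L,
                                           end = 1000L)), genome, 1000L)
  expect_equal(which(occ$matrix[1, ] == 1), 1)
  occ2 <- bin_occupancy(list(f = data.frame(chrom = "chr1", start = 999L,
                                            end = 1001L)), genome, 1000L)
  expect_equal(which(occ2$matrix[1, ] == 1), c(1, 2))
  expect_error(
    bin_occupancy(list(f = data.frame(chrom = "chr1", start = 9500L,
                                      end = 10500L)), genome, 1000L),
    "beyond chromosome end")
  # fuzz against a per-bin scan
  withr::with_seed(17, {
    for (i in 1:100) {
      s <- sample(0:9000, 8)
      bed <- data.frame(chrom = "chr1", start = s,
                        end = s + sample(1:900, 8, replace = TRUE))
      got <- bin_occupancy(list(f = bed), genome, 700L)$matrix[1, ]
      expect_equal(unname(got), oracle_bin_occupancy(bed, 10000L, 700L))
    }
  })
})

test_that("co-occupancy Z matches its hypergeometric closed form and a permutation null", {
  # disjoint equal-size factors in a small genome sit below expectation
  M <- rbind(a = c(1, 1, 0, 0, 0, 0), b = c(0, 0, 1, 1, 0, 0))
  z <- cooccupancy_z(make_occ(M))
  expect_lt(z["a", "b"], 0)
  # identical factors reach the closed-form self-score
  M2 <- rbind(a = c(1, 1, 1, 0, 0, 0), b = c(1, 1, 1, 0, 0, 0))
  z2 <- cooccupancy_z(make_occ(M2))
  N <- 6; m <- 3; E <- m * m / N
  sig <- sqrt(E * (1 - m / N) * (N - m) / (N - 1))
  expect_equal(z2["a", "b"], (m - E) / sig, tolerance = 1e-12)
  expect_equal(z2["a", "a"], z2["a", "b"])

  # N = 20 bins, m_a = 5, m_b = 8, O = 4 vs 20,000 permutation draws
  Ma <- c(rep(1, 5), rep(0, 15))
  Mb <- c(rep(1, 4), 0, rep(1, 4), rep(0, 11))
  z3 <- cooccupancy_z(make_occ(rbind(a = Ma, b = Mb)))
  withr::with_seed(101, {
    O_sim <- vapply(1:20000, function(i) {
      sum(Ma[sample.int(20)] * Mb)
    }, numeric(1))
  })
  z_perm <- (4 - mean(O_sim)) / sd(O_sim)
  expect_equal(z3["a", "b"], z_perm, tolerance = 0.1)

  # degenerate: factor occupying every bin
  M4 <- rbind(a = rep(1, 6), b = c(1, 1, 0, 0, 0, 0))
  expect_warning(z4 <- cooccupancy_z(make_occ(M4)), "all bins")
  expect_equal(z4["a", "a"], 0)
})

test_that("Z matrices are symmetric with the self-score as row maximum", {
  withr::with_seed(23, {
    for (i in 1:25) {
      n_bins <- sample(20:60, 1)
      nf <- sample(3:6, 1)
      M <- t(vapply(seq_len(nf), function(f) {
        m <- sample(1:(n_bins - 1), 1)
        as.integer(seq_len(n_bins) %in% sample.int(n_bins, m))
      }, integer(n_bins)))
      rownames(M) <- paste0("f", seq_len(nf))
      z <- cooccupancy_z(make_occ(M))
      expect_true(isSymmetric(z))
      expect_true(all(diag(z) >= apply(z, 1, max) - 1e-9))
    }
  })
})

test_that("clustering recovers planted classes and is permutation-equivariant", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(seed = 31)
  pk <- gen_peaks(cfg)
  occ <- bin_occupancy(pk$peaks, cfg$genome, cfg$bin_size)
  z <- cooccupancy_z(occ)
  n_cut <- length(cfg$classes) + cfg$n_noise_factors
  cl <- cluster_subclasses(z, n_cut)
  truth <- pk$truth$factor_class
  truth[is.na(truth)] <- names(truth)[is.na(truth)]
  ari <- mclust::adjustedRandIndex(cl$membership[names(truth)], truth)
  expect_gte(ari, 0.9)
  # singleton cut
  cls <- cluster_subclasses(z, nrow(z))
  expect_equal(max(table(cls$membership)), 1)
  # permutation equivariance
  perm <- withr::with_seed(5, sample(rownames(z)))
  cl2 <- cluster_subclasses(z[perm, perm], n_cut)
  expect_equal(mclust::adjustedRandIndex(cl$membership[perm],
                                         cl2$membership[perm]), 1)
  expect_error(cluster_subclasses(z, nrow(z) + 1), "n_clusters")
  zc <- z; zc[1, ] <- zc[, 1] <- 1
  expect_error(cluster_subclasses(zc, 2), "constant")
})

test_that("HDBS extraction merges, counts degree, and thresholds as stated", {
  pk <- list(A = data.frame(chrom = "chr1", start = 0L, end = 100L),
             B = data.frame(chrom = "chr1", start = 50L, end = 150L),
             C = data.frame(chrom = "chr1", start = 400L, end = 500L))
  h <- hdbs_extract(pk, k = 2)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0); expect_equal(h$end, 150)
  expect_equal(h$degree, 2)
  h1 <- hdbs_extract(pk, k = 1)
  expect_equal(h1[, c("start", "end")],
               data.frame(start = c(0L, 400L), end = c(150L, 500L)))
  hn <- hdbs_extract(list(A = pk$A, B = pk$A), k = 2)
  expect_equal(hn[, c("start", "end")], data.frame(start = 0L, end = 100L))
  expect_error(hdbs_extract(pk, k = 4), "exceeds")
  expect_equal(nrow(hdbs_extract(list(A = pk$A[0, ], B = pk$B), k = 1)), 1)
})

test_that("HDBS degrees equal per-base counting and shrink with k", {
  withr::with_seed(71, {
    for (i in 1:200) {
      nf <- sample(2:5, 1)
      pk <- lapply(seq_len(nf), function(f) {
        n <- sample(1:5, 1)
        s <- sample(0:900, n)
        data.frame(chrom = "chrT", start = s,
                   end = s + sample(10:120, n, replace = TRUE))
      })
      names(pk) <- paste0("f", seq_len(nf))
      k <- sample(seq_len(nf), 1)
      got <- hdbs_extract(pk, k = k)
      want <- oracle_hdbs(pk, k = k, limit = 1100L)
      expect_equal(got[c("start", "end", "degree")],
                   want[c("start", "end", "degree")], ignore_attr = TRUE)
      sizes <- vapply(seq_len(nf), function(kk) {
        nrow(hdbs_extract(pk, k = kk))
      }, integer(1))
      expect_true(all(diff(sizes) <= 0))
    }
  })
})

test_that("peak annotation categorizes by promoter, gene body, distance", {
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    tss = c(10000L, 50000L), strand = c("+", "-"),
                    body_start = c(10000L, 45000L),
                    body_end = c(20000L, 50000L))
  at_tss <- annotate_peaks(data.frame(chrom = "chr1", start = 9950L,
                                      end = 10050L), ann)
  expect_equal(at_tss$distance, 0)
  expect_equal(at_tss$category, "promoter")
  up <- annotate_peaks(data.frame(chrom = "chr1", start = 6949L,
                                  end = 7049L), ann)
  expect_equal(up$distance, -3001)
  expect_equal(up$category, "distal_intergenic")
  body <- annotate_peaks(data.frame(chrom = "chr1", start = 15900L,
                                    end = 16100L), ann)
  expect_equal(body$category, "gene_body")
  minus <- annotate_peaks(data.frame(chrom = "chr1", start = 51950L,
                                     end = 52050L), ann)
  expect_equal(minus$distance, -2000)  # upstream of the - strand gene
  expect_error(annotate_peaks(data.frame(chrom = "chr1", start = 1L,
                                         end = 2L), ann[0, ]), "empty")
  # fuzzed nearest-TSS distances match an exhaustive scan
  withr::with_seed(41, {
    for (i in 1:100) {
      ann_f <- data.frame(gene_id = paste0("g", 1:6), chrom = "chr1",
                          tss = sample(0:100000, 6), strand = "+",
                          body_start = 0L, body_end = 0L)
      ann_f$body_start <- ann_f$tss
      ann_f$body_end <- ann_f$tss + 1000L
      iv <- data.frame(chrom = "chr1", start = sample(0:100000, 5), end = 0L)
      iv$end <- iv$start + 200L
      got <- annotate_peaks(iv, ann_f)
      mids <- (iv$start + iv$end) %/% 2
      want <- vapply(mids, function(m) min(abs(m - ann_f$tss)), numeric(1))
      expect_equal(abs(got$distance), want)
    }
  })
})

test_that("coverage profiles average windows with zero-filled truncation", {
  sites <- data.frame(chrom = "chr1", start = c(4000L, 9000L),
                      end = c(4200L, 9200L))
  flat <- list(mk = data.frame(chrom = "chr1", start = 0L, end = 20000L,
                               value = 2.5))
  prof <- histone_profile(flat, sites, flank = 1000L, bin = 100L)
  expect_true(all(abs(prof - 2.5) < 1e-12))
  # delta at each midpoint peaks only at the central bin
  mids <- (sites$start + sites$end) %/% 2L
  delta <- list(mk = data.frame(chrom = "chr1", start = mids,
                                end = mids + 1L, value = 100))
  p2 <- histone_profile(delta, sites, flank = 1000L, bin = 100L)
  expect_equal(sum(p2 > 0), 1)
  expect_equal(unname(which(p2[1, ] > 0)), 11)
  # random coverage equals naive per-site averaging
  withr::with_seed(53, {
    starts <- seq(0L, 19900L, by = 100L)
    cov <- data.frame(chrom = "chr1", start = starts, end = starts + 100L,
                      value = round(runif(length(starts)), 3))
    p3 <- histone_profile(list(mk = cov), sites, flank = 600L, bin = 50L)
    expect_equal(unname(p3[1, ]), oracle_profile(cov, sites, 600L, 50L),
                 tolerance = 1e-12)
  })
  # truncation at the chromosome start counts zeros in the denominator
  edge <- data.frame(chrom = "chr1", start = 100L, end = 300L)
  p4 <- histone_profile(flat, edge, flank = 1000L, bin = 2000L)
  expect_equal(unname(p4[1, 1]), 2.5 * (2000 - 800) / 2000)
})
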