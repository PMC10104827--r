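# Synthetic study generator. Every input the analysis consumes is generated
# here with planted ground truth (essential genes, factor classes, true
# module targets, activity shifts, hazard ratios) so each downstream stage
# can be checked against a known answer.

#' Configuration for a synthetic regulatory-network study
#'
#' Bundles every tunable of the generator. Defaults define the standard
#' simulated study used throughout the test-suite: five knockout screens
#' over 2,000 genes, three planted factor classes of four members each plus
#' three unclustered noise factors, ~50 shared binding sites per class on a
#' two-chromosome 4 Mb genome, three expression sample groups with a 4-fold
#' (log2 effect 2) activity shift for the planted active/repressed group,
#' and an activity-dependent hazard ratio of 3 for survival times.
#'
#' @param seed Integer seed; fixing it makes every generated object
#'   byte-identical across runs.
#' @param n_genes Number of genes in the screen/expression universe.
#' @param n_screens Number of knockout screens (>= 2).
#' @param n_common_essential Genes planted essential in all screens.
#' @param n_specific_essential Extra genes planted essential per screen only.
#' @param essential_shift True log2 fold change of essential genes (< 0).
#' @param sgrnas_per_gene Guides per gene.
#' @param nb_dispersion Negative-binomial dispersion of sgRNA counts.
#' @param mean_count Mean sgRNA read count at day 0.
#' @param libsize_sdlog Log-normal sd of per-sample library-size factors.
#' @param genome Named vector of chromosome lengths (bp).
#' @param bin_size Genome bin size (bp) for occupancy binarization.
#' @param classes Named integer vector: members per planted factor class.
#' @param n_shared_sites Shared binding sites planted per class.
#' @param shared_width,background_width Peak widths (bp).
#' @param n_background_peaks Private background peaks per factor.
#' @param jitter Max absolute peak-center jitter (bp); default
#'   `bin_size / 4` so planted co-binding survives binning.
#' @param n_noise_factors Factors with only background peaks.
#' @param fraction_proximal Fraction of planted sites whose true target is
#'   recoverable by the proximal (TSS +/- window) rule; the rest are distal
#'   and linked by an interaction pair.
#' @param promoter_window Promoter half-width (bp) used when planting.
#' @param n_distractor_pairs Random decoy interaction pairs.
#' @param groups Sample group labels.
#' @param n_samples_per_group Samples per group.
#' @param module_effect Numeric matrix modules x groups of log2 expression
#'   shifts applied to true module targets; default activates the first two
#'   classes and represses the third in the first group.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline expression.
#' @param noise_sdlog Multiplicative log-normal expression noise (0 = none).
#' @param n_histone_marks Histone-mark features per gene.
#' @param n_timepoints Expression time-course features per gene.
#' @param signal_shift Mean feature shift of true-target genes (sd units).
#' @param contamination_rate Fraction of false positives planted among
#'   putative module targets.
#' @param hazard_ratio Hazard ratio between high- and low-activity samples.
#' @param baseline_hazard Baseline exponential hazard.
#' @param censor_max Upper bound of uniform censoring times (`Inf` = none).
#' @param n_patients Patients for survival simulation.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_screens = 5L,
                       n_common_essential = 60L,
                       n_specific_essential = 40L,
                       essential_shift = -3,
                       sgrnas_per_gene = 4L,
                       nb_dispersion = 0.1,
                       mean_count = 300,
                       libsize_sdlog = 0.1,
                       genome = c(chr1 = 2000000L, chr2 = 2000000L),
                       bin_size = 1000L,
                       classes = c(CORE = 4L, MYC = 4L, PRC = 4L),
                       n_shared_sites = 50L,
                       shared_width = 600L,
                       background_width = 300L,
                       n_background_peaks = 100L,
                       jitter = NULL,
                       n_noise_factors = 3L,
                       fraction_proximal = 0.5,
                       promoter_window = 5000L,
                       n_distractor_pairs = 50L,
                       groups = c("ESC", "EB6", "EB12"),
                       n_samples_per_group = 10L,
                       module_effect = NULL,
                       baseline_meanlog = 3,
                       baseline_sdlog = 1,
                       noise_sdlog = 0.4,
                       n_histone_marks = 10L,
                       n_timepoints = 5L,
                       signal_shift = 3,
                       contamination_rate = 0.2,
                       hazard_ratio = 3,
                       baseline_hazard = 0.1,
                       censor_max = 30,
                       n_patients = 200L) {
  if (is.null(jitter)) jitter <- bin_size %/% 4L
  if (is.null(module_effect)) {
    module_effect <- matrix(0, nrow = length(classes), ncol = length(groups),
                            dimnames = list(names(classes), groups))
    if (length(classes) >= 1) module_effect[1, 1] <- 2
    if (length(classes) >= 2) module_effect[2, 1] <- 2
    if (length(classes) >= 3) module_effect[3, 1] <- -2
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_screens = as.integer(n_screens),
              n_common_essential = as.integer(n_common_essential),
              n_specific_essential = as.integer(n_specific_essential),
              essential_shift = essential_shift,
              sgrnas_per_gene = as.integer(sgrnas_per_gene),
              nb_dispersion = nb_dispersion, mean_count = mean_count,
              libsize_sdlog = libsize_sdlog, genome = genome,
              bin_size = as.integer(bin_size), classes = classes,
              n_shared_sites = as.integer(n_shared_sites),
              shared_width = as.integer(shared_width),
              background_width = as.integer(background_width),
              n_background_peaks = as.integer(n_background_peaks),
              jitter = as.integer(jitter),
              n_noise_factors = as.integer(n_noise_factors),
              fraction_proximal = fraction_proximal,
              promoter_window = as.integer(promoter_window),
              n_distractor_pairs = as.integer(n_distractor_pairs),
              groups = groups,
              n_samples_per_group = as.integer(n_samples_per_group),
              module_effect = module_effect,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, noise_sdlog = noise_sdlog,
              n_histone_marks = as.integer(n_histone_marks),
              n_timepoints = as.integer(n_timepoints),
              signal_shift = signal_shift,
              contamination_rate = contamination_rate,
              hazard_ratio = hazard_ratio, baseline_hazard = baseline_hazard,
              censor_max = censor_max, n_patients = as.integer(n_patients))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  check_genome(cfg$genome)
  counts <- c(cfg$n_genes, cfg$n_screens, cfg$sgrnas_per_gene,
              cfg$n_samples_per_group, cfg$n_patients)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (any(cfg$genome < 10 * cfg$bin_size)) {
    stop("chromosome lengths must be >= 10 x bin_size")
  }
  if (cfg$contamination_rate < 0 || cfg$contamination_rate >= 1) {
    stop("contamination_rate must be in [0, 1)")
  }
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (!identical(rownames(cfg$module_effect), names(cfg$classes)) ||
      !identical(colnames(cfg$module_effect), cfg$groups)) {
    stop("module_effect must be a modules x groups matrix matching classes/groups")
  }
  cfg
}

gene_ids <- function(n) sprintf("gene%04d", seq_len(n))

#' Generate synthetic CRISPR-screen result tables
#'
#' Each screen draws per-gene log2 fold changes from a null centred at 0,
#' except planted essential genes which receive `essential_shift`. A common
#' subset is essential in every screen; each screen additionally has its own
#' context-specific essentials. sgRNA read counts (4 guides/gene, two
#' timepoints, two replicates each) are drawn from a negative-binomial model
#' consistent with the gene-level fold change; gene tables (normalized LFC
#' and a negative/positive-selection p-value) are then computed from those
#' counts.
#'
#' @param cfg A [sim_config()].
#' @return List with `gene_tables` (one MAGeCK-style data.frame per screen:
#'   `screen_id`, `gene_id`, `lfc`, `p_neg`, `p_pos`), `counts` (one sgRNA
#'   count data.frame per screen), and `truth` (`essential` per screen,
#'   `common`).
#' @export
gen_screens <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_screens < 2) stop("n_screens must be >= 2")
  withr::with_seed(cfg$seed + 101L, {
    genes <- gene_ids(cfg$n_genes)
    common <- genes[seq_len(cfg$n_common_essential)]
    # disjoint context-specific blocks after the common block
    specific <- lapply(seq_len(cfg$n_screens), function(s) {
      i0 <- cfg$n_common_essential + (s - 1L) * cfg$n_specific_essential
      genes[(i0 + 1L):(i0 + cfg$n_specific_essential)]
    })
    ess <- lapply(specific, function(sp) c(common, sp))

    n_sg <- cfg$sgrnas_per_gene
    sg_gene <- rep(genes, each = n_sg)
    sg_id <- paste0(sg_gene, "_sg", rep(seq_len(n_sg), times = cfg$n_genes))
    samples <- c("t0_r1", "t0_r2", "t14_r1", "t14_r2")
    tps <- c(t0_r1 = "t0", t0_r2 = "t0", t14_r1 = "t14", t14_r2 = "t14")

    gene_tables <- vector("list", cfg$n_screens)
    count_tables <- vector("list", cfg$n_screens)
    for (s in seq_len(cfg$n_screens)) {
      true_lfc <- ifelse(genes %in% ess[[s]], cfg$essential_shift, 0)
      base <- stats::rlnorm(length(sg_id),
                            meanlog = log(cfg$mean_count), sdlog = 0.3)
      lib <- stats::rlnorm(length(samples), 0, cfg$libsize_sdlog)
      names(lib) <- samples
      mu <- cbind(base, base, base * 2^true_lfc[match(sg_gene, genes)],
                  base * 2^true_lfc[match(sg_gene, genes)])
      colnames(mu) <- samples
      counts <- matrix(0L, nrow = length(sg_id), ncol = length(samples),
                       dimnames = list(NULL, samples))
      for (j in samples) {
        counts[, j] <- stats::rnbinom(length(sg_id), mu = mu[, j] * lib[[j]],
                                      size = 1 / cfg$nb_dispersion)
      }
      ct <- data.frame(sgrna_id = sg_id, gene_id = sg_gene,
                       stringsAsFactors = FALSE)
      ct <- cbind(ct, as.data.frame(counts))
      attr(ct, "timepoints") <- tps
      count_tables[[s]] <- ct

      cpm <- normalize_counts(ct)
      lfc_sg <- sgrna_lfc(cpm, timepoints = tps, from = "t0", to = "t14")
      gl <- tapply(lfc_sg$lfc, lfc_sg$gene_id, mean)[genes]
      scale_hat <- stats::mad(gl)
      z <- as.numeric(gl) / scale_hat
      gene_tables[[s]] <- data.frame(
        screen_id = sprintf("screen%d", s), gene_id = genes,
        lfc = as.numeric(gl),
        p_neg = stats::pnorm(z),
        p_pos = stats::pnorm(z, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
    names(gene_tables) <- sprintf("screen%d", seq_len(cfg$n_screens))
    names(count_tables) <- names(gene_tables)
    names(ess) <- names(gene_tables)
    list(gene_tables = gene_tables, counts = count_tables,
         truth = list(essential = ess, common = common))
  })
}

#' Generate factor binding peak sets with planted co-occupancy classes
#'
#' Factors of one planted class share `n_shared_sites` binding sites (each
#' member's peak jittered by at most `jitter` bp around the site centre) on
#' top of private background peaks; classes never share sites; noise factors
#' carry background peaks only.
#'
#' @param cfg A [sim_config()].
#' @return List with `peaks` (named list of sorted interval data.frames, one
#'   per factor, BED convention) and `truth` (`factor_class` map and
#'   `shared_sites` table with class and site centres).
#' @export
gen_peaks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  check_genome(cfg$genome)
  withr::with_seed(cfg$seed + 202L, {
    chroms <- names(cfg$genome)
    margin <- max(2L * cfg$bin_size, cfg$shared_width + 2L * cfg$jitter)
    # sample non-colliding site centres across all classes
    n_total <- cfg$n_shared_sites * length(cfg$classes)
    centers <- data.frame(chrom = character(0), pos = integer(0))
    tries <- 0L
    while (nrow(centers) < n_total) {
      tries <- tries + 1L
      if (tries > 50L * n_total) stop("genome too small to place class sites")
      chr <- sample(chroms, 1L, prob = cfg$genome)
      pos <- sample.int(cfg$genome[[chr]] - 2L * margin, 1L) + margin
      same <- centers$chrom == chr
      if (!any(same) || all(abs(centers$pos[same] - pos) > 2L * margin)) {
        centers <- rbind(centers, data.frame(chrom = chr, pos = pos))
      }
    }
    cls_of_site <- rep(names(cfg$classes), each = cfg$n_shared_sites)
    shared <- data.frame(site_id = sprintf("site%03d", seq_len(n_total)),
                         class = cls_of_site,
                         chrom = centers$chrom, center = centers$pos,
                         stringsAsFactors = FALSE)

    factors <- unlist(lapply(names(cfg$classes), function(cl) {
      sprintf("%s_f%d", cl, seq_len(cfg$classes[[cl]]))
    }))
    factor_class <- rep(names(cfg$classes), times = cfg$classes)
    names(factor_class) <- factors
    if (cfg$n_noise_factors > 0) {
      nf <- sprintf("noise_f%d", seq_len(cfg$n_noise_factors))
      factor_class[nf] <- NA_character_
      factors <- c(factors, nf)
    }

    half <- cfg$shared_width %/% 2L
    bg_half <- cfg$background_width %/% 2L
    peaks <- lapply(factors, function(f) {
      cl <- factor_class[[f]]
      out <- NULL
      if (!is.na(cl)) {
        s <- shared[shared$class == cl, ]
        jit <- if (cfg$jitter > 0) {
          sample.int(2L * cfg$jitter + 1L, nrow(s), replace = TRUE) -
            cfg$jitter - 1L
        } else rep(0L, nrow(s))
        out <- data.frame(chrom = s$chrom,
                          start = s$center + jit - half,
                          end = s$center + jit + half,
                          stringsAsFactors = FALSE)
      }
      chr <- sample(chroms, cfg$n_background_peaks, replace = TRUE,
                    prob = cfg$genome)
      pos <- vapply(chr, function(cc) {
        sample.int(cfg$genome[[cc]] - 2L * cfg$background_width, 1L) +
          cfg$background_width
      }, integer(1))
      bg <- data.frame(chrom = chr, start = pos - bg_half,
                       end = pos + bg_half, stringsAsFactors = FALSE)
      out <- rbind(out, bg)
      out$start <- pmax(out$start, 0L)
      out$end <- pmin(out$end, unname(cfg$genome[out$chrom]))
      rownames(out) <- NULL
      sort_bed(out)
    })
    names(peaks) <- factors
    list(peaks = peaks,
         truth = list(factor_class = factor_class, shared_sites = shared))
  })
}

#' Generate gene annotation and chromatin interaction pairs
#'
#' Each planted class site is given one true target gene. A fraction
#' `fraction_proximal` of sites get their target's TSS planted inside the
#' proximal window around the site, so the proximal rule alone recovers
#' them; the remaining sites are distal: their target's TSS is planted away
#' from every class site and an interaction pair connects the site to the
#' target's promoter window. Filler genes (up to `n_genes`) and random
#' distractor pairs are added.
#'
#' @param cfg A [sim_config()].
#' @param peaks Output of [gen_peaks()].
#' @return List with `annotation` (gene_id, chrom, tss, strand, body
#'   bounds), `interactions` (BEDPE-style data.frame), and `truth`
#'   (`true_targets` per class, per-gene `origin`, site-to-gene map).
#' @export
gen_annotation_and_interactions <- function(cfg, peaks) {
  stopifnot(inherits(cfg, "sim_config"))
  shared <- peaks$truth$shared_sites
  withr::with_seed(cfg$seed + 303L, {
    w <- cfg$promoter_window
    n_sites <- nrow(shared)
    n_prox <- round(cfg$fraction_proximal * n_sites)
    is_prox <- rep(FALSE, n_sites)
    if (n_prox > 0) is_prox[sample.int(n_sites, n_prox)] <- TRUE

    tss <- integer(0); tchr <- character(0)
    taken <- function(chr, pos, min_gap) {
      same <- tchr == chr
      any(same) && any(abs(tss[same] - pos) < min_gap)
    }
    # exclusion zones around all class sites, for distal/filler genes
    near_site <- function(chr, pos) {
      same <- shared$chrom == chr
      any(same) && any(abs(shared$center[same] - pos) <
                         w + cfg$shared_width + 2L * cfg$jitter)
    }
    place <- function(chr = NULL, lo = NULL, hi = NULL, avoid_sites = FALSE) {
      for (i in seq_len(2000L)) {
        cc <- if (is.null(chr)) {
          sample(names(cfg$genome), 1L, prob = cfg$genome)
        } else chr
        span <- if (is.null(lo)) c(2000L, cfg$genome[[cc]] - 2000L)
                else c(max(lo, 2000L), min(hi, cfg$genome[[cc]] - 2000L))
        if (span[2] <= span[1]) next
        pos <- sample.int(span[2] - span[1], 1L) + span[1]
        if (taken(cc, pos, 200L)) next
        if (avoid_sites && near_site(cc, pos)) next
        return(list(chrom = cc, pos = pos))
      }
      stop("genome too small to place genes")
    }

    n_target_genes <- n_sites
    ids <- gene_ids(cfg$n_genes)
    if (cfg$n_genes < n_target_genes) stop("n_genes < number of class sites")
    site_gene <- ids[seq_len(n_target_genes)]
    gchr <- character(cfg$n_genes); gpos <- integer(cfg$n_genes)
    for (i in seq_len(n_sites)) {
      if (is_prox[i]) {
        p <- place(chr = shared$chrom[i],
                   lo = shared$center[i] - (w - 1000L),
                   hi = shared$center[i] + (w - 1000L))
      } else {
        p <- place(avoid_sites = TRUE)
      }
      gchr[i] <- p$chrom; gpos[i] <- p$pos
      tchr <- c(tchr, p$chrom); tss <- c(tss, p$pos)
    }
    if (cfg$n_genes > n_sites) {
      for (i in seq.int(n_sites + 1L, cfg$n_genes)) {
        p <- place(avoid_sites = TRUE)
        gchr[i] <- p$chrom; gpos[i] <- p$pos
        tchr <- c(tchr, p$chrom); tss <- c(tss, p$pos)
      }
    }
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    blen <- sample(2000:10000, cfg$n_genes, replace = TRUE)
    body_start <- ifelse(strand == "+", gpos, pmax(gpos - blen, 0L))
    body_end <- ifelse(strand == "+",
                       pmin(gpos + blen, unname(cfg$genome[gchr])), gpos)
    ann <- data.frame(gene_id = ids, chrom = gchr, tss = gpos,
                      strand = strand, body_start = body_start,
                      body_end = body_end, stringsAsFactors = FALSE)

    # interaction pairs for distal sites: anchor1 on the site, anchor2 on
    # the target promoter (anchor order randomized; both are considered)
    dist_idx <- which(!is_prox)
    pr <- data.frame()
    if (length(dist_idx)) {
      a1 <- data.frame(chrom = shared$chrom[dist_idx],
                       start = shared$center[dist_idx] - 500L,
                       end = shared$center[dist_idx] + 500L)
      g <- match(site_gene[dist_idx], ann$gene_id)
      a2 <- data.frame(chrom = ann$chrom[g],
                       start = pmax(ann$tss[g] - 2000L, 0L),
                       end = ann$tss[g] + 2000L)
      flip <- sample(c(TRUE, FALSE), length(dist_idx), replace = TRUE)
      pr <- data.frame(
        chrom1 = ifelse(flip, a2$chrom, a1$chrom),
        start1 = ifelse(flip, a2$start, a1$start),
        end1 = ifelse(flip, a2$end, a1$end),
        chrom2 = ifelse(flip, a1$chrom, a2$chrom),
        start2 = ifelse(flip, a1$start, a2$start),
        end2 = ifelse(flip, a1$end, a2$end),
        name = sprintf("loop_%s", shared$site_id[dist_idx]),
        stringsAsFactors = FALSE)
    }
    if (cfg$n_distractor_pairs > 0) {
      rnd_anchor <- function(n) {
        chr <- sample(names(cfg$genome), n, replace = TRUE, prob = cfg$genome)
        pos <- vapply(chr, function(cc) {
          sample.int(cfg$genome[[cc]] - 4000L, 1L) + 2000L
        }, integer(1))
        data.frame(chrom = chr, start = pos - 1000L, end = pos + 1000L)
      }
      d1 <- rnd_anchor(cfg$n_distractor_pairs)
      d2 <- rnd_anchor(cfg$n_distractor_pairs)
      pr <- rbind(pr, data.frame(
        chrom1 = d1$chrom, start1 = d1$start, end1 = d1$end,
        chrom2 = d2$chrom, start2 = d2$start, end2 = d2$end,
        name = sprintf("decoy%03d", seq_len(cfg$n_distractor_pairs)),
        stringsAsFactors = FALSE))
    }

    true_targets <- split(site_gene, shared$class)
    origin <- ifelse(is_prox, "proximal", "distal")
    names(origin) <- site_gene
    list(annotation = ann, interactions = pr,
         truth = list(true_targets = true_targets, origin = origin,
                      site_gene = stats::setNames(site_gene, shared$site_id)))
  })
}

#' Generate an expression matrix with planted module activity
#'
#' Log-normal baseline per gene; samples are organized into labelled groups;
#' true targets of module `m` are multiplied by `2^module_effect[m, g]` in
#' group `g`; independent multiplicative log-normal noise is applied.
#'
#' @param cfg A [sim_config()].
#' @param modules Named list of gene sets (true module targets).
#' @return List with `expr` (genes x samples matrix, strictly positive),
#'   `samples` (data.frame sample/group), and `truth` (`group_activity`
#'   sign matrix = sign of `module_effect`).
#' @export
gen_expression <- function(cfg, modules) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 404L, {
    genes <- gene_ids(cfg$n_genes)
    grp <- rep(cfg$groups, each = cfg$n_samples_per_group)
    samp <- sprintf("%s_s%02d", grp,
                    unlist(lapply(cfg$groups, function(g)
                      seq_len(cfg$n_samples_per_group))))
    base <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
    G <- matrix(rep(base, length(samp)), nrow = cfg$n_genes,
                dimnames = list(genes, samp))
    for (m in intersect(names(modules), rownames(cfg$module_effect))) {
      gi <- match(intersect(modules[[m]], genes), genes)
      for (g in cfg$groups) {
        e <- cfg$module_effect[m, g]
        if (e != 0) G[gi, grp == g] <- G[gi, grp == g] * 2^e
      }
    }
    if (cfg$noise_sdlog > 0) {
      G <- G * matrix(stats::rlnorm(length(G), 0, cfg$noise_sdlog),
                      nrow = nrow(G))
    }
    stopifnot(!anyNA(G), all(G > 0))
    list(expr = G,
         samples = data.frame(sample = samp, group = grp,
                              stringsAsFactors = FALSE),
         truth = list(group_activity = sign(cfg$module_effect)))
  })
}

#' Generate per-gene histone-mark and time-course features
#'
#' True targets of transcriptionally activating modules receive elevated
#' active-mark features (and a declining expression time-course); targets of
#' repressed modules receive elevated repressive-mark features (rising
#' time-course); all other genes carry background features. For each module
#' a putative-positive set is constructed as the true targets plus enough
#' background genes that a fraction `contamination_rate` of the putative set
#' is false -- the planted false positives that positive-unlabeled
#' refinement must reject.
#'
#' @param cfg A [sim_config()].
#' @param modules Named list of true target gene sets.
#' @return List with `features` (genes x features matrix, z-scale),
#'   `putative` (named list of putative target sets per module), and
#'   `truth` (`contaminants` per module).
#' @export
gen_histone_features <- function(cfg, modules) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 505L, {
    genes <- gene_ids(cfg$n_genes)
    nf <- cfg$n_histone_marks + cfg$n_timepoints
    fnames <- c(sprintf("mark%02d", seq_len(cfg$n_histone_marks)),
                sprintf("tc%d", seq_len(cfg$n_timepoints)))
    X <- matrix(stats::rnorm(cfg$n_genes * nf), nrow = cfg$n_genes,
                dimnames = list(genes, fnames))
    act_marks <- seq_len(min(4L, cfg$n_histone_marks))
    rep_marks <- seq.int(max(cfg$n_histone_marks - 1L, 1L),
                         cfg$n_histone_marks)
    tc_cols <- cfg$n_histone_marks + seq_len(cfg$n_timepoints)
    decline <- seq(cfg$signal_shift, 0, length.out = cfg$n_timepoints)
    for (m in names(modules)) {
      gi <- match(intersect(modules[[m]], genes), genes)
      activating <- !(m %in% rownames(cfg$module_effect)) ||
        max(cfg$module_effect[m, ]) > 0
      if (activating) {
        X[gi, act_marks] <- X[gi, act_marks] + cfg$signal_shift
        X[gi, tc_cols] <- X[gi, tc_cols] + rep(decline, each = length(gi))
      } else {
        X[gi, rep_marks] <- X[gi, rep_marks] + cfg$signal_shift
        X[gi, tc_cols] <- X[gi, tc_cols] + rep(rev(decline), each = length(gi))
      }
    }
    all_targets <- unique(unlist(modules))
    bg_pool <- setdiff(genes, all_targets)
    putative <- list(); contaminants <- list()
    for (m in names(modules)) {
      tp <- intersect(modules[[m]], genes)
      n_cont <- round(cfg$contamination_rate /
                        (1 - cfg$contamination_rate) * length(tp))
      cont <- if (n_cont > 0) sample(bg_pool, n_cont) else character(0)
      putative[[m]] <- c(tp, cont)
      contaminants[[m]] <- cont
    }
    list(features = X, putative = putative,
         truth = list(contaminants = contaminants))
  })
}

#' Generate survival times driven by module activity
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hazard_ratio^(z > 0)` where `z` is the z-scored
#' per-sample activity; censoring is independent uniform on
#' `[0, censor_max]` (`Inf` disables censoring).
#'
#' @param cfg A [sim_config()].
#' @param activity Named numeric vector of per-sample module activity.
#' @return data.frame with `sample`, `time` (> 0), `event` (0/1) and the
#'   latent `high_activity` indicator.
#' @export
gen_survival <- function(cfg, activity) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  withr::with_seed(cfg$seed + 606L, {
    n <- length(activity)
    z <- as.numeric(scale(activity))
    hi <- z > 0
    rate <- cfg$baseline_hazard * cfg$hazard_ratio^hi
    t_ev <- stats::rexp(n, rate = rate)
    if (is.finite(cfg$censor_max)) {
      t_c <- stats::runif(n, 0, cfg$censor_max)
      time <- pmin(t_ev, t_c)
      event <- as.integer(t_ev <= t_c)
    } else {
      time <- t_ev
      event <- rep(1L, n)
    }
    nm <- if (is.null(names(activity))) sprintf("pat%03d", seq_len(n))
          else names(activity)
    data.frame(sample = nm, time = pmax(time, .Machine$double.eps),
               event = event, high_activity = hi, stringsAsFactors = FALSE)
  })
}

#' Generate the full synthetic study
#'
#' Runs every generator in order (screens, peaks, annotation/interactions,
#' expression, features, survival) and collects all planted ground truth.
#' The latent per-patient activity driving survival is the z-scored mean
#' log2 expression of the first module's true targets, resampled to
#' `n_patients`.
#'
#' @param cfg A [sim_config()].
#' @return List with `screens`, `peaks`, `annotation`, `expression`,
#'   `features`, `survival`, and a merged `truth` list.
#' @export
simulate_study <- function(cfg) {
  scr <- gen_screens(cfg)
  pk <- gen_peaks(cfg)
  ann <- gen_annotation_and_interactions(cfg, pk)
  ex <- gen_expression(cfg, ann$truth$true_targets)
  ft <- gen_histone_features(cfg, ann$truth$true_targets)
  m1 <- ann$truth$true_targets[[1]]
  lat <- colMeans(log2(ex$expr[m1, , drop = FALSE] + 1))
  withr::with_seed(cfg$seed + 707L, {
    act <- stats::setNames(
      lat[sample.int(length(lat), cfg$n_patients, replace = TRUE)] +
        stats::rnorm(cfg$n_patients, 0, 0.05),
      sprintf("pat%03d", seq_len(cfg$n_patients)))
  })
  sv <- gen_survival(cfg, act)
  list(screens = scr, peaks = pk, annotation = ann, expression = ex,
       features = ft, survival = sv, patient_activity = act,
       truth = c(scr["truth"], list(peaks = pk$truth, targets = ann$truth,
                                    expression = ex$truth,
                                    features = ft$truth)))
}

#' Write a synthetic study to disk in standard formats
#'
#' Screens as TSV, peaks as BED (plus a factor manifest), annotation as TSV,
#' interactions as BEDPE, expression/features/survival as TSV, true module
#' gene sets as GMT, and the ground truth as a JSON sidecar.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f, rn = FALSE) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  }
  for (s in names(study$screens$gene_tables)) {
    tsv(study$screens$gene_tables[[s]], sprintf("%s_gene_summary.tsv", s))
    tsv(study$screens$counts[[s]], sprintf("%s_sgrna_counts.tsv", s))
  }
  pk_dir <- file.path(dir, "peaks")
  dir.create(pk_dir, showWarnings = FALSE)
  manifest <- data.frame(factor = names(study$peaks$peaks),
                         path = file.path("peaks",
                                          paste0(names(study$peaks$peaks), ".bed")))
  for (f in names(study$peaks$peaks)) {
    write_bed(study$peaks$peaks[[f]], file.path(pk_dir, paste0(f, ".bed")))
  }
  tsv(manifest, "peak_manifest.tsv")
  tsv(study$annotation$annotation, "annotation.tsv")
  write_bedpe(study$annotation$interactions, file.path(dir, "interactions.bedpe"))
  tsv(study$expression$expr, "expression.tsv", rn = TRUE)
  tsv(study$expression$samples, "samples.tsv")
  tsv(study$features$features, "features.tsv", rn = TRUE)
  tsv(study$survival, "survival.tsv")
  write_gmt(study$annotation$truth$true_targets, file.path(dir, "modules_truth.gmt"))
  truth <- study$truth
  truth$peaks$factor_class <- as.list(truth$peaks$factor_class)
  jsonlite::write_json(
    list(essential = truth$essential, common = truth$common,
         factor_class = truth$peaks$factor_class,
         true_targets = truth$targets$true_targets,
         origin = as.list(truth$targets$origin),
         contaminants = truth$features$contaminants),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
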