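# One-call orchestration of the full analysis over a synthetic study:
# simulate -> integrate screens -> co-occupancy classes -> HDBS ->
# target assignment + PU refinement -> activity -> enrichment -> survival.

#' Run the full module-definition pipeline on a synthetic study
#'
#' Generates a study from `cfg`, integrates the screens into common and
#' context-specific hit sets, clusters factors into sub-classes from
#' binding co-occupancy, extracts each sub-class's high-degree co-occupancy
#' sites, assigns proximal and distal target genes and refines them by
#' positive-unlabeled sampling, scores module activity (matrix chain and
#' rank-AUC), computes per-sample and per-group enrichment patterns, and
#' stratifies the survival cohort by the first module's activity.
#'
#' Sub-class HDBS thresholds default to k = n - 1 members (k = 1 for
#' singleton classes); clustering is cut at the number of planted classes
#' plus noise factors.
#'
#' @param cfg A [sim_config()].
#' @return Nested list with `study`, `screens` (partition, correlation),
#'   `classes` (Z matrix, clustering, HDBS per class), `targets`
#'   (candidates and refined modules), `activity` (E, per-sample, AUC),
#'   `enrichment` (per-sample and per-group patterns), `survival`.
#' @export
run_pipeline <- function(cfg) {
  study <- simulate_study(cfg)

  part <- integrate_screens(study$screens$gene_tables)
  corr <- screen_correlation(study$screens$gene_tables)

  occ <- bin_occupancy(study$peaks$peaks, cfg$genome, cfg$bin_size)
  z <- cooccupancy_z(occ)
  n_cut <- length(cfg$classes) + cfg$n_noise_factors
  cl <- cluster_subclasses(z, n_clusters = n_cut)

  ann <- study$annotation$annotation
  pairs <- study$annotation$interactions
  hdbs <- list(); candidates <- list(); refined <- list()
  multi <- Filter(function(mem) length(mem) >= 2, cl$classes)
  for (nm in names(multi)) {
    members <- multi[[nm]]
    k <- max(length(members) - 1L, 1L)
    h <- hdbs_extract(study$peaks$peaks[members], k = k, name = nm)
    hdbs[[nm]] <- h
    prox <- proximal_targets(h, ann, window = cfg$promoter_window)
    dist <- distal_targets(h, pairs, ann,
                           promoter_window = cfg$promoter_window)
    cand <- candidate_targets(prox, dist)
    candidates[[nm]] <- cand
    if (nrow(cand) >= 10) {
      ref <- adasample_refine(cand$gene_id, study$features$features,
                              seed = cfg$seed + 11L)
      refined[[nm]] <- ref$retained
    } else {
      refined[[nm]] <- cand$gene_id
    }
  }

  S <- standardize_expression(study$expression$expr, pseudocount = 1)
  C <- centralize_expression(S)
  groups <- stats::setNames(study$expression$samples$group,
                            study$expression$samples$sample)
  act <- module_activity(C, refined, groups)
  auc <- auc_activity(study$expression$expr, refined[[1]])

  degs <- call_sample_degs(study$expression$expr)
  cells <- sample_module_pattern(degs, refined)
  gpat <- group_pattern(cells, groups)

  surv <- stratify_survival(study$patient_activity, study$survival)

  list(study = study,
       screens = list(partition = part, correlation = corr),
       classes = list(z = z, clustering = cl, hdbs = hdbs),
       targets = list(candidates = candidates, modules = refined),
       activity = list(E = act$E, per_sample = act$per_sample, auc = auc),
       enrichment = list(cells = cells, groups = gpat),
       survival = surv)
}

#' Write the main pipeline outputs as plain-text tables
#'
#' Z matrix, cluster membership, HDBS BED files (degree in the score
#' column), refined module GMT, activity matrices, enrichment score
#' matrices and KM step tables. Used for reproducibility checks: the same
#' configuration yields byte-identical files.
#'
#' @param res Output of [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f, rn = FALSE) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  }
  tsv(round(res$classes$z, 6), "z_matrix.tsv", rn = TRUE)
  tsv(data.frame(factor = names(res$classes$clustering$membership),
                 cluster = res$classes$clustering$membership),
      "clusters.tsv")
  for (nm in names(res$classes$hdbs)) {
    h <- res$classes$hdbs[[nm]]
    h$name <- nm
    h$score <- h$degree
    write_bed(h, file.path(dir, sprintf("hdbs_%s.bed", nm)))
  }
  write_gmt(res$targets$modules, file.path(dir, "modules.gmt"))
  tsv(data.frame(gene = res$screens$partition$common), "common_genes.tsv")
  tsv(round(res$screens$correlation, 6), "screen_correlation.tsv", rn = TRUE)
  tsv(round(res$activity$E, 6), "module_activity.tsv", rn = TRUE)
  tsv(round(res$activity$per_sample, 6), "activity_per_sample.tsv", rn = TRUE)
  cells <- res$enrichment$cells
  cells[c("p_over", "p_under", "score")] <-
    lapply(cells[c("p_over", "p_under", "score")], round, 6)
  tsv(cells, "enrichment_cells.tsv")
  gp <- res$enrichment$groups
  gp[c("p_over", "p_under", "score")] <-
    lapply(gp[c("p_over", "p_under", "score")], round, 6)
  tsv(gp, "enrichment_groups.tsv")
  km <- res$survival$km
  km$surv <- round(km$surv, 6)
  tsv(km, "km_curves.tsv")
  invisible(dir)
}
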