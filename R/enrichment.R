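# Per-sample over/under-expression calling and hypergeometric module
# enrichment patterns, per sample and per sample group.

#' Call per-sample over- and under-expressed gene sets
#'
#' A gene is over-expressed in a sample iff its value is at least
#' `fold`-fold its cross-sample average, under-expressed iff at most the
#' average divided by `fold` (both boundaries inclusive). Genes with a zero
#' average are excluded from both sets with a warning.
#'
#' @param G Expression matrix (genes x samples).
#' @param fold Fold-change cutoff; default 2.
#' @return List with `over` and `under` (named lists of gene sets per
#'   sample) and `universe` (genes with a positive average).
#' @export
call_sample_degs <- function(G, fold = 2) {
  if (ncol(G) < 2) stop("need >= 2 samples to define the average")
  gbar <- rowMeans(G)
  if (any(gbar == 0)) {
    warning(sum(gbar == 0), " gene(s) with zero average excluded")
  }
  keep <- gbar > 0
  Gk <- G[keep, , drop = FALSE]
  gb <- gbar[keep]
  over <- lapply(seq_len(ncol(Gk)), function(j) {
    rownames(Gk)[Gk[, j] >= fold * gb]
  })
  under <- lapply(seq_len(ncol(Gk)), function(j) {
    rownames(Gk)[Gk[, j] <= gb / fold]
  })
  names(over) <- names(under) <- colnames(G)
  list(over = over, under = under, universe = rownames(Gk))
}

#' Hypergeometric enrichment p-value (upper tail)
#'
#' P[X >= k] for X ~ Hypergeometric(universe_size, |module|, |hit_set|),
#' where k is the overlap between the hit set and the module.
#'
#' @param hit_set Gene set drawn (e.g. a sample's over-expressed genes).
#' @param module Module gene set.
#' @param universe_size Total number of genes in the universe.
#' @return Upper-tail p-value; an empty module returns 1 with a warning.
#' @export
hypergeom_enrich <- function(hit_set, module, universe_size) {
  n <- length(hit_set)
  K <- length(module)
  if (K == 0) {
    warning("empty module; p = 1")
    return(1)
  }
  if (K > universe_size || n > universe_size) {
    stop("set larger than universe")
  }
  k <- length(intersect(hit_set, module))
  stats::phyper(k - 1, K, universe_size - K, n, lower.tail = FALSE)
}

# shared direction-selection rule: both significant -> smaller p (exact
# ties -> over); one significant -> that one; else none, score 0
choose_direction <- function(p_over, p_under, alpha) {
  if (p_over < alpha && p_under < alpha) {
    dir <- if (p_under < p_over) "under" else "over"
  } else if (p_over < alpha) {
    dir <- "over"
  } else if (p_under < alpha) {
    dir <- "under"
  } else {
    return(list(direction = "none", score = 0))
  }
  p <- if (dir == "over") p_over else p_under
  list(direction = dir, score = if (dir == "over") -log2(p) else log2(p))
}

#' Per-sample module enrichment pattern
#'
#' For every (sample, module) the over- and under-expressed gene sets are
#' tested for module enrichment; the significant direction (smaller p when
#' both pass `alpha`) is reported with the signed score
#' `sign * -log2(p)` (+ for over, - for under; 0 when neither passes).
#'
#' @param degs Output of [call_sample_degs()].
#' @param modules Named list of module gene sets.
#' @param alpha Significance threshold; default 0.05.
#' @return data.frame with `sample`, `module`, `p_over`, `p_under`,
#'   `direction`, `score`.
#' @export
sample_module_pattern <- function(degs, modules, alpha = 0.05) {
  N <- length(degs$universe)
  rows <- list()
  for (s in names(degs$over)) {
    for (m in names(modules)) {
      mod <- intersect(modules[[m]], degs$universe)
      p_o <- hypergeom_enrich(degs$over[[s]], mod, N)
      p_u <- hypergeom_enrich(degs$under[[s]], mod, N)
      ch <- choose_direction(p_o, p_u, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, module = m, p_over = p_o, p_under = p_u,
        direction = ch$direction, score = ch$score,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Group-level module enrichment pattern
#'
#' For each (group, module, direction) the number of direction-enriched
#' samples inside the group is tested against the total count of
#' direction-enriched samples over all samples (hypergeometric upper
#' tail); the direction is then chosen by the same smaller-p rule.
#'
#' @param cells Per-sample pattern from [sample_module_pattern()].
#' @param groups Named character vector mapping sample -> group.
#' @param alpha Significance threshold; default 0.05.
#' @return data.frame with `group`, `module`, `p_over`, `p_under`,
#'   `direction`, `score`.
#' @export
group_pattern <- function(cells, groups, alpha = 0.05) {
  if (anyNA(groups[unique(cells$sample)])) {
    stop("every sample must have a group")
  }
  samples <- unique(cells$sample)
  N <- length(samples)
  rows <- list()
  for (m in unique(cells$module)) {
    cm <- cells[cells$module == m, , drop = FALSE]
    enr <- list(over = cm$sample[cm$direction == "over"],
                under = cm$sample[cm$direction == "under"])
    for (g in unique(groups[samples])) {
      gs <- samples[groups[samples] == g]
      p <- vapply(c("over", "under"), function(d) {
        if (!length(enr[[d]])) return(1)  # no enriched samples anywhere
        hypergeom_enrich(gs, enr[[d]], N)
      }, numeric(1))
      ch <- choose_direction(p[["over"]], p[["under"]], alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, module = m, p_over = p[["over"]], p_under = p[["under"]],
        direction = ch$direction, score = ch$score, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
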