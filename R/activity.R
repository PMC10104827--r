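# Module expression activity: standardization against the per-gene mean,
# centering, module x group activity averaging, a rank-AUC per-sample
# activity score, and activity-stratified survival analysis.

#' Standardize expression against the per-gene mean
#'
#' S(i,j) = log2((G(i,j) + pc) / (Gbar(i) + pc)), where Gbar(i) is the
#' arithmetic mean of gene i over *all* samples.
#'
#' @param G Non-negative expression matrix (genes x samples, CPM/RPKM).
#' @param pseudocount Added inside the ratio; default 1. With
#'   `pseudocount = 0`, genes whose mean (or any value) is zero are
#'   rejected.
#' @return Standardized matrix S, finite everywhere.
#' @export
standardize_expression <- function(G, pseudocount = 1) {
  if (ncol(G) < 2) stop("need >= 2 samples")
  if (any(G < 0)) stop("expression must be non-negative")
  gbar <- rowMeans(G)
  if (pseudocount == 0 && any(gbar == 0)) {
    stop("zero row mean with pseudocount 0 for gene(s): ",
         paste(utils::head(rownames(G)[gbar == 0], 5), collapse = ", "))
  }
  S <- log2((G + pseudocount) / (gbar + pseudocount))
  if (any(!is.finite(S))) {
    stop("non-finite standardized values; use a positive pseudocount")
  }
  S
}

#' Center standardized expression per gene
#'
#' C(i,j) = S(i,j) - Sbar(i); positive values mean above-average expression
#' in that sample. Every row of the result has mean 0.
#'
#' @param S Standardized matrix from [standardize_expression()].
#' @return Centered matrix C.
#' @export
centralize_expression <- function(S) {
  if (any(!is.finite(S))) stop("S must be finite")
  C <- S - rowMeans(S)
  stopifnot(max(abs(rowMeans(C))) < 1e-9)
  C
}

#' Module x group expression activity
#'
#' E(x, y) = sum of C over module-x genes and group-y samples, divided by
#' (number of module genes present) x (number of group samples).
#'
#' @param C Centered matrix from [centralize_expression()].
#' @param modules Named list of gene sets. Module genes absent from the
#'   matrix are dropped with a warning and recorded.
#' @param groups Named character vector mapping sample -> group label.
#' @return List with `E` (modules x groups), `per_sample` (modules x
#'   samples mean C), and `n` (genes/samples used per cell).
#' @export
module_activity <- function(C, modules, groups) {
  samples <- colnames(C)
  if (is.null(names(groups))) stop("groups must be named by sample")
  groups <- groups[samples]
  glabs <- unique(groups)
  E <- matrix(NA_real_, length(modules), length(glabs),
              dimnames = list(names(modules), glabs))
  PS <- matrix(NA_real_, length(modules), length(samples),
               dimnames = list(names(modules), samples))
  used <- list()
  for (m in names(modules)) {
    present <- intersect(modules[[m]], rownames(C))
    if (!length(present)) stop("module '", m, "' has no genes in the matrix")
    if (length(present) < length(unique(modules[[m]]))) {
      warning("module '", m, "': ",
              length(unique(modules[[m]])) - length(present),
              " gene(s) absent from matrix, dropped")
    }
    used[[m]] <- present
    sub <- C[present, , drop = FALSE]
    PS[m, ] <- colMeans(sub)
    for (g in glabs) {
      E[m, g] <- mean(sub[, groups == g, drop = FALSE])
    }
  }
  list(E = E, per_sample = PS,
       n = list(genes = lengths(used), samples = table(groups)))
}

#' Rank-AUC module activity score per sample
#'
#' Genes are ranked by descending expression within each sample (ties
#' broken by gene label for determinism). The score is the area under the
#' recovery curve of module genes within the top
#' `ceiling(top_fraction * n)` ranks, normalized so that all module genes
#' at the very top give 1 and none in the top block gives 0.
#'
#' @param expr Expression matrix (genes x samples) or a single named
#'   column.
#' @param module Gene set (must be within the gene universe).
#' @param top_fraction Fraction of top ranks forming the recovery block;
#'   default 0.05.
#' @return Named numeric vector of per-sample scores in `[0, 1]`.
#' @export
auc_activity <- function(expr, module, top_fraction = 0.05) {
  if (is.null(dim(expr))) expr <- cbind(sample1 = expr)
  genes <- rownames(expr)
  module <- unique(module)
  if (length(module) > length(genes)) stop("module larger than gene universe")
  if (!all(module %in% genes)) stop("module gene(s) missing from universe")
  n <- length(genes)
  top <- ceiling(top_fraction * n)
  if (top < 1) stop("top block is empty; increase top_fraction")
  m <- min(length(module), top)
  max_area <- sum(pmin(seq_len(top), m))
  apply(expr, 2, function(x) {
    ord <- order(-x, genes)
    ranks <- match(module, genes[ord])
    inside <- ranks[ranks <= top]
    sum(top - inside + 1) / max_area
  })
}

#' Stratify survival by module activity and run a log-rank test
#'
#' Samples are split at the activity quantile `cut` (ties at the cut value
#' go to the low stratum); the two strata are compared with the log-rank
#' test and summarized by Kaplan-Meier step tables.
#'
#' @param activity Named numeric vector (per sample).
#' @param surv data.frame with `sample`, `time` (> 0), `event` (0/1).
#' @param cut Activity quantile for the split; default 0.5 (median).
#' @return List with `strata` (named factor high/low), `chisq`, `p`, and
#'   `km` (data.frame of per-stratum step functions).
#' @export
stratify_survival <- function(activity, surv, cut = 0.5) {
  act <- activity[surv$sample]
  if (anyNA(act)) stop("activity missing for some samples")
  if (sum(surv$event) < 2) stop("need >= 2 events")
  thr <- stats::quantile(act, cut, names = FALSE)
  strata <- factor(ifelse(act > thr, "high", "low"),
                   levels = c("low", "high"))
  if (any(table(strata) == 0)) stop("empty stratum at this cut")
  sd_ <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ strata)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ strata)
  km <- data.frame(stratum = rep(sub("strata=", "", names(fit$strata)),
                                 fit$strata),
                   time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, surv = fit$surv,
                   stringsAsFactors = FALSE)
  list(strata = stats::setNames(strata, surv$sample),
       chisq = unname(sd_$chisq), p = p, km = km)
}
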