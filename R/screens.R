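# Integration and comparison of CRISPR knockout screens. Gene-level tables
# are MAGeCK-style (one row per gene per screen, normalized LFC plus
# negative/positive selection p-values); sgRNA count tables carry one row
# per guide with one column per sample.

#' Scale sgRNA counts to counts per million
#'
#' Each sample column is scaled to CPM. No pseudocount is added here; the
#' 0.5 pseudocount enters downstream, inside the log of [sgrna_lfc()].
#'
#' @param counts data.frame with `sgrna_id`, `gene_id` and one numeric
#'   column per sample.
#' @return The table with sample columns CPM-scaled; attributes preserved.
#' @export
normalize_counts <- function(counts) {
  samp <- setdiff(names(counts), c("sgrna_id", "gene_id"))
  if (!length(samp)) stop("no sample columns found")
  tot <- vapply(counts[samp], sum, numeric(1))
  if (any(tot <= 0)) {
    stop("all-zero sample(s): ", paste(samp[tot <= 0], collapse = ", "))
  }
  counts[samp] <- Map(function(x, t) x / t * 1e6, counts[samp], tot)
  counts
}

#' Per-sgRNA log2 fold change between two timepoints
#'
#' LFC = log2(mean CPM at `to` + 0.5) - log2(mean CPM at `from` + 0.5),
#' with means taken over the replicate samples of each timepoint.
#'
#' @param counts CPM-normalized count table (see [normalize_counts()]).
#' @param timepoints Named character vector mapping sample column ->
#'   timepoint label; defaults to the table's `timepoints` attribute.
#' @param from,to Timepoint labels.
#' @return data.frame with `sgrna_id`, `gene_id`, `lfc`.
#' @export
sgrna_lfc <- function(counts, timepoints = attr(counts, "timepoints"),
                      from = "t0", to = "t14") {
  if (is.null(timepoints)) stop("no timepoint mapping supplied")
  s_from <- names(timepoints)[timepoints == from]
  s_to <- names(timepoints)[timepoints == to]
  if (!length(s_from)) stop("missing timepoint label: ", from)
  if (!length(s_to)) stop("missing timepoint label: ", to)
  m_from <- rowMeans(counts[, s_from, drop = FALSE])
  m_to <- rowMeans(counts[, s_to, drop = FALSE])
  data.frame(sgrna_id = counts$sgrna_id, gene_id = counts$gene_id,
             lfc = log2(m_to + 0.5) - log2(m_from + 0.5),
             stringsAsFactors = FALSE)
}

#' Compare sgRNA fold changes of two gene sets
#'
#' Wilcoxon signed-rank test against a zero shift (`paired = TRUE`, on the
#' values of `set_a`, or on paired differences when `set_b` is given) or
#' two-sample rank-sum test. Exact enumeration is used for n <= 25 without
#' ties, the normal approximation with continuity correction otherwise.
#'
#' @param lfc data.frame from [sgrna_lfc()] (`gene_id`, `lfc`).
#' @param set_a,set_b Gene sets; `set_b` may be `NULL` in paired mode.
#' @param paired If `TRUE`, signed-rank vs 0; else rank-sum.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return List with `statistic`, `p.value`, `method`.
#' @export
compare_gene_sets <- function(lfc, set_a, set_b = NULL, paired = FALSE,
                              alternative = "two.sided") {
  vals <- function(set) lfc$lfc[lfc$gene_id %in% set]
  a <- vals(set_a)
  if (length(a) < 3) stop("set_a maps to fewer than 3 sgRNA values")
  if (paired) {
    d <- if (is.null(set_b)) a else {
      b <- vals(set_b)
      if (length(b) != length(a)) stop("paired mode requires equal-size value vectors")
      a - b
    }
    if (all(d == 0)) {
      warning("all differences are zero; p set to 1")
      return(list(statistic = 0, p.value = 1, method = "signed-rank"))
    }
    n <- sum(d != 0)
    wt <- suppressWarnings(stats::wilcox.test(
      d, alternative = alternative, exact = n <= 25 && !any(duplicated(abs(d[d != 0]))),
      correct = TRUE))
    return(list(statistic = unname(wt$statistic), p.value = wt$p.value,
                method = "signed-rank"))
  }
  b <- vals(set_b)
  if (length(b) < 3) stop("set_b maps to fewer than 3 sgRNA values")
  exact <- length(a) <= 25 && length(b) <= 25 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = "rank-sum")
}

#' Partition genes by expression level
#'
#' A gene is called expressed iff its mean expression strictly exceeds
#' `threshold` (RPKM-like units); genes at or below the threshold -- and
#' genes absent from the matrix -- form the low/non-expressed set.
#'
#' @param genes Character vector of gene ids.
#' @param expr Expression matrix (genes x samples).
#' @param threshold Expression cutoff; default 0.5.
#' @return List with `expressed` and `low_non_expressed` (exhaustive,
#'   disjoint partition of `genes`).
#' @export
filter_expressed <- function(genes, expr, threshold = 0.5) {
  if (!length(genes)) {
    return(list(expressed = character(0), low_non_expressed = character(0)))
  }
  present <- genes %in% rownames(expr)
  if (any(!present)) {
    warning(sum(!present), " gene(s) absent from matrix; counted as low/non-expressed")
  }
  m <- rowMeans(expr[genes[present], , drop = FALSE])
  expressed <- genes[present][m > threshold]
  list(expressed = expressed,
       low_non_expressed = setdiff(genes, expressed))
}

#' Partition screen hits into common and context-specific sets
#'
#' Per-screen significant set = genes with negative-selection p < `alpha`
#' (strict, uncorrected). The common set is the intersection over all
#' screens; the context-specific set is the union minus the common set.
#' Genes absent from a screen count as non-significant there.
#'
#' @param tables List of screen gene tables (`gene_id`, `p_neg`).
#' @param alpha Significance threshold; default 0.05.
#' @return List with `common`, `context_specific`,
#'   `per_screen_significant`.
#' @export
integrate_screens <- function(tables, alpha = 0.05) {
  if (length(tables) < 2) stop("need >= 2 screens")
  sig <- lapply(tables, function(t) t$gene_id[t$p_neg < alpha])
  common <- Reduce(intersect, sig)
  all_sig <- Reduce(union, sig)
  list(common = common,
       context_specific = setdiff(all_sig, common),
       per_screen_significant = sig)
}

#' Pairwise Pearson correlation of screen fold changes
#'
#' Correlations are computed on genes present in both members of each pair
#' (pairwise-complete). Pairs sharing fewer than 3 genes are returned as
#' `NA` with a warning rather than silently 0.
#'
#' @param tables List of screen gene tables (`gene_id`, `lfc`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
screen_correlation <- function(tables) {
  if (length(tables) < 2) stop("need >= 2 screens")
  n <- length(tables)
  nm <- if (!is.null(names(tables))) names(tables)
        else sprintf("screen%d", seq_len(n))
  r <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  diag(r) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(tables[[i]]$gene_id, tables[[j]]$gene_id)
      if (length(shared) < 3) {
        warning(sprintf("screens %s and %s share < 3 genes; correlation undefined",
                        nm[i], nm[j]))
        next
      }
      xi <- tables[[i]]$lfc[match(shared, tables[[i]]$gene_id)]
      xj <- tables[[j]]$lfc[match(shared, tables[[j]]$gene_id)]
      r[i, j] <- r[j, i] <- stats::cor(xi, xj)
    }
  }
  r
}

#' Read a MAGeCK-style gene summary table
#'
#' @param path TSV path.
#' @param column_map Named vector mapping the standard fields `gene_id`,
#'   `p_neg`, `p_pos`, `lfc` to column names in the file.
#' @param screen_id Screen identifier to attach.
#' @return A screen gene table data.frame.
#' @export
read_gene_summary <- function(path,
                              column_map = c(gene_id = "id",
                                             p_neg = "neg.p.value",
                                             p_pos = "pos.p.value",
                                             lfc = "neg.lfc"),
                              screen_id = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- intersect(names(column_map), c("gene_id", "p_neg", "lfc"))
  missing <- need[!(column_map[need] %in% names(df))]
  if (length(missing)) {
    stop("columns not found: ", paste(column_map[missing], collapse = ", "))
  }
  out <- data.frame(screen_id = screen_id,
                    gene_id = df[[column_map[["gene_id"]]]],
                    lfc = df[[column_map[["lfc"]]]],
                    p_neg = df[[column_map[["p_neg"]]]],
                    stringsAsFactors = FALSE)
  if ("p_pos" %in% names(column_map) && column_map[["p_pos"]] %in% names(df)) {
    out$p_pos <- df[[column_map[["p_pos"]]]]
  }
  out
}
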