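# Assignment of putative proximal and distal target genes to sub-class
# binding sites, and positive-unlabeled refinement of the putative set.

#' Proximal target genes of an HDBS set
#'
#' A gene is a proximal target iff some HDBS interval overlaps the window
#' TSS +/- `window` by at least 1 bp. The window is strand-independent and
#' closed at both ends in base coordinates: an interval starting exactly at
#' TSS + window still touches the window's last base.
#'
#' @param hdbs Interval data.frame (e.g. from [hdbs_extract()]).
#' @param annotation Gene annotation data.frame (`gene_id`, `chrom`, `tss`).
#' @param window Half-width of the promoter window in bp; default 5000.
#' @return Character vector of target gene ids (annotation order).
#' @export
proximal_targets <- function(hdbs, annotation, window = 5000L) {
  if (window <= 0) stop("window must be positive")
  if (!nrow(hdbs)) return(character(0))
  win <- data.frame(chrom = annotation$chrom,
                    start = pmax(annotation$tss - window, 0L),
                    end = annotation$tss + window + 1L)
  annotation$gene_id[bed_count_overlaps(win, hdbs) > 0]
}

#' Distal target genes via chromatin interaction pairs
#'
#' A gene is a distal target iff some interaction pair has one anchor
#' overlapping an HDBS interval and the *other* anchor overlapping the
#' gene's promoter window (TSS +/- `promoter_window`); both anchor
#' orderings are considered.
#'
#' @param hdbs Interval data.frame.
#' @param pairs Interaction data.frame
#'   (`chrom1,start1,end1,chrom2,start2,end2`).
#' @param annotation Gene annotation data.frame.
#' @param promoter_window Promoter half-width in bp; default 5000.
#' @return Character vector of target gene ids (annotation order).
#' @export
distal_targets <- function(hdbs, pairs, annotation, promoter_window = 5000L) {
  if (!nrow(pairs)) stop("no interaction pairs supplied")
  if (!nrow(hdbs)) return(character(0))
  a1 <- data.frame(chrom = pairs$chrom1, start = pairs$start1,
                   end = pairs$end1)
  a2 <- data.frame(chrom = pairs$chrom2, start = pairs$start2,
                   end = pairs$end2)
  h1 <- bed_count_overlaps(a1, hdbs) > 0
  h2 <- bed_count_overlaps(a2, hdbs) > 0
  win <- data.frame(chrom = annotation$chrom,
                    start = pmax(annotation$tss - promoter_window, 0L),
                    end = annotation$tss + promoter_window + 1L)
  p1 <- bed_find_overlaps(win, a1)
  p2 <- bed_find_overlaps(win, a2)
  # promoter on one anchor, HDBS on the opposite anchor of the same pair
  g1 <- S4Vectors::queryHits(p1)[h2[S4Vectors::subjectHits(p1)]]
  g2 <- S4Vectors::queryHits(p2)[h1[S4Vectors::subjectHits(p2)]]
  annotation$gene_id[sort(unique(c(g1, g2)))]
}

#' Combine proximal and distal targets into a candidate table
#'
#' @param proximal,distal Character vectors of gene ids.
#' @return data.frame `gene_id`, `origin` (proximal/distal/both).
#' @export
candidate_targets <- function(proximal, distal) {
  genes <- union(proximal, distal)
  origin <- ifelse(genes %in% proximal & genes %in% distal, "both",
                   ifelse(genes %in% proximal, "proximal", "distal"))
  data.frame(gene_id = genes, origin = origin, stringsAsFactors = FALSE)
}

#' Build a z-scored per-gene feature table
#'
#' Concatenates expression time-course values and histone-mark
#' quantifications over the union gene universe, z-scores every feature,
#' imputes genes missing one source to the feature mean (flagged), and
#' drops zero-variance features with a warning.
#'
#' @param expr_tc Matrix genes x timepoints (expression time-course).
#' @param histone Matrix genes x marks (e.g. RPKM around the TSS).
#' @return List with `features` (z-scored matrix over the union universe)
#'   and `imputed` (logical vector per gene).
#' @export
build_features <- function(expr_tc, histone) {
  universe <- union(rownames(expr_tc), rownames(histone))
  if (!length(intersect(rownames(expr_tc), rownames(histone)))) {
    stop("gene universes do not overlap")
  }
  fill <- function(m) {
    out <- matrix(NA_real_, length(universe), ncol(m),
                  dimnames = list(universe, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  X <- cbind(fill(expr_tc), fill(histone))
  imputed <- rowSums(is.na(X)) > 0
  keep <- rep(TRUE, ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    mu <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- mu
    s <- stats::sd(x)
    if (s == 0) { keep[j] <- FALSE; next }
    X[, j] <- (x - mu) / s
  }
  if (any(!keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  list(features = X[, keep, drop = FALSE], imputed = imputed)
}

# one adaptive-sampling run: iteratively reweight putative positives by a
# classifier's predicted positive probability
ada_single <- function(cand_idx, features, n_rounds, learner, n_train,
                       tol = 1e-3) {
  n <- nrow(features)
  w <- numeric(n)
  w[cand_idx] <- 1
  neg_idx <- setdiff(seq_len(n), cand_idx)
  converged <- FALSE
  for (r in seq_len(n_rounds)) {
    m <- min(length(cand_idx), length(neg_idx), n_train)
    pos_tr <- sample(cand_idx, m, replace = TRUE, prob = w[cand_idx] + 1e-12)
    neg_tr <- sample(neg_idx, m, replace = TRUE,
                     prob = 1 - w[neg_idx] + 1e-12)
    p <- learner(features[c(pos_tr, neg_tr), , drop = FALSE],
                 c(rep(1L, m), rep(0L, m)), features)
    delta <- max(abs(p - w))
    w <- p
    if (delta <= tol) { converged <- TRUE; break }
  }
  list(w = w, converged = converged)
}

learner_knn <- function(k = 5L) {
  function(x_tr, y_tr, x_all) {
    pred <- class::knn(x_tr, x_all, factor(y_tr, levels = c(0, 1)),
                       k = min(k, nrow(x_tr)), prob = TRUE)
    pw <- attr(pred, "prob")
    ifelse(pred == "1", pw, 1 - pw)
  }
}

learner_ridge <- function(lambda = 0.01) {
  function(x_tr, y_tr, x_all) {
    fit <- glmnet::glmnet(x_tr, y_tr, family = "binomial", alpha = 0,
                          lambda = lambda)
    as.numeric(stats::predict(fit, newx = x_all, type = "response"))
  }
}

#' Refine putative targets by positive-unlabeled adaptive sampling
#'
#' Candidates start with positive weight 1 and every other gene with 0.
#' Each round samples a balanced training set (positives drawn from the
#' candidates proportional to their weight, negatives from the
#' non-candidates proportional to one minus their weight), fits a
#' probabilistic classifier, and replaces each gene's weight with the
#' predicted positive probability. The procedure is repeated over an
#' ensemble mixing a k-nearest-neighbour probability estimator and a
#' ridge-regularized logistic model; each member votes positive when its
#' final probability is >= 0.5, and a candidate is retained when the
#' ensemble positive fraction reaches `threshold` (threshold 1 =
#' unanimity, evaluated at 1 - 1e-9). Non-candidates are never promoted.
#'
#' @param candidates Character vector of putative target gene ids.
#' @param features z-scored feature matrix (rownames = gene universe).
#' @param universe Gene universe; default all feature rows.
#' @param threshold Ensemble positive fraction required; default 1.
#' @param n_rounds Adaptive-sampling rounds per member; default 5.
#' @param n_ensemble Ensemble size; default 10.
#' @param n_train Training draws per class and round; default 200.
#' @param seed Integer seed.
#' @return List with `retained` (gene ids), `positive_fraction` (named,
#'   per candidate), and `converged` (per ensemble member).
#' @export
adasample_refine <- function(candidates, features,
                             universe = rownames(features), threshold = 1,
                             n_rounds = 5L, n_ensemble = 10L,
                             n_train = 200L, seed = 1L) {
  features <- features[universe, , drop = FALSE]
  candidates <- intersect(candidates, universe)
  if (length(candidates) < 10) stop("need >= 10 candidate genes")
  if (length(universe) - length(candidates) < 10) {
    stop("need >= 10 non-candidate genes")
  }
  cand_idx <- match(candidates, universe)
  votes <- matrix(0, nrow = length(candidates), ncol = n_ensemble,
                  dimnames = list(candidates, NULL))
  conv <- logical(n_ensemble)
  for (e in seq_len(n_ensemble)) {
    learner <- if (e %% 2L == 1L) learner_knn(5L) else learner_ridge()
    res <- withr::with_seed(seed + e, {
      ada_single(cand_idx, features, n_rounds, learner, n_train)
    })
    votes[, e] <- as.integer(res$w[cand_idx] >= 0.5)
    conv[e] <- res$converged
  }
  frac <- rowMeans(votes)
  retained <- candidates[frac >= threshold - 1e-9]
  list(retained = retained, positive_fraction = frac, converged = conv)
}

#' Pairwise module overlap and exclusive counts
#'
#' @param modules Named list of gene sets.
#' @return List with `intersection` (symmetric count matrix, diagonal =
#'   module sizes) and `exclusive` (genes in exactly one module).
#' @export
module_overlap <- function(modules) {
  if (length(modules) < 2) stop("need >= 2 modules")
  n <- length(modules)
  M <- matrix(0L, n, n, dimnames = list(names(modules), names(modules)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[i, j] <- length(intersect(modules[[i]], modules[[j]]))
    }
  }
  counts <- table(unlist(lapply(modules, unique)))
  excl <- vapply(modules, function(g) {
    sum(counts[unique(g)] == 1L)
  }, integer(1))
  list(intersection = M, exclusive = excl)
}
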