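# Correlation-matrix PCA comprehensive scoring and hierarchical
# clustering of batch fingerprints.

#' Autoscale a matrix
#'
#' Column-wise standardization to mean 0 and unit sample standard
#' deviation (n - 1 denominator) — the prerequisite for correlation-matrix
#' PCA of a peak-area matrix.
#'
#' @param x numeric matrix (samples x variables) or a
#'   `fingerprint_matrix`, in which case its area matrix is used.
#' @param common_only for a `fingerprint_matrix`, restrict to common peaks
#'   (default `TRUE`).
#' @return standardized matrix with the input dimnames.
#' @export
autoscale <- function(x, common_only = TRUE) {
  if (inherits(x, "fingerprint_matrix")) {
    keep <- if (common_only) x$common_mask else rep(TRUE, ncol(x$areas))
    x <- x$areas[, keep, drop = FALSE]
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("autoscaling needs at least two samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  zero <- which(sds == 0)
  if (length(zero)) {
    nm <- colnames(x)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  scale(x, center = TRUE, scale = sds)
}

#' Principal component analysis on the correlation matrix
#'
#' Eigendecomposition of the correlation matrix of the (autoscaled) data.
#' The retained components are those with eigenvalue above
#' `eigen_threshold`. Loadings follow a fixed sign convention — the
#' largest-magnitude element of each loading vector is positive — so
#' scores are reproducible across linear-algebra backends.
#'
#' @param x samples x variables matrix (raw or standardized) or a
#'   `fingerprint_matrix`. Standardization is (re-)applied internally;
#'   autoscaling is idempotent so passing standardized data is harmless.
#' @param eigen_threshold retention threshold on the eigenvalues
#'   (default 0.99).
#' @return object of class `"herb_pca"`: `eigenvalues` (descending),
#'   `contribution` (fractions summing to 1), `loadings`
#'   (variables x PCs), `scores` (samples x PCs), `retained` (count).
#' @export
pca_fingerprint <- function(x, eigen_threshold = 0.99) {
  if (eigen_threshold <= 0) stop("threshold must be positive", call. = FALSE)
  z <- autoscale(x)
  if (nrow(z) < 2) stop("need at least two samples", call. = FALSE)
  p <- ncol(z)
  e <- eigen(stats::cor(z), symmetric = TRUE)
  load <- e$vectors
  # sign convention: largest |element| of each loading positive
  for (k in seq_len(p)) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) load[, k] <- -load[, k]
  }
  dimnames(load) <- list(colnames(z), paste0("PC", seq_len(p)))
  scores <- z %*% load
  structure(list(eigenvalues = e$values,
                 contribution = e$values / sum(e$values),
                 loadings = load,
                 scores = scores,
                 retained = sum(e$values > eigen_threshold),
                 eigen_threshold = eigen_threshold),
            class = "herb_pca")
}

#' @export
print.herb_pca <- function(x, ...) {
  cat("<herb_pca> ", nrow(x$scores), " samples, ", length(x$eigenvalues),
      " PCs; ", x$retained, " retained (eigenvalue > ",
      format(x$eigen_threshold), ")\n", sep = "")
  cat("cumulative contribution of retained PCs: ",
      sprintf("%.1f%%", 100 * sum(x$contribution[seq_len(max(x$retained, 0))])),
      "\n", sep = "")
  invisible(x)
}

#' Comprehensive quality scores and batch ranking
#'
#' Weighted sum of the retained principal-component scores, the weight of
#' PC k being its variance contribution renormalized over the retained
#' components (option `weights = "contribution"` uses the raw
#' contributions instead). Samples are ranked by descending comprehensive
#' score — higher means better quality; ties are broken by sample id.
#'
#' @param p a [pca_fingerprint()] result with at least one retained PC.
#' @param weights `"renormalized"` (default) or `"contribution"`.
#' @return data frame of class `"quality_ranking"`: sample id, the
#'   retained PC scores, `comprehensive_score` and `rank` (1 = best).
#' @export
comprehensive_scores <- function(p, weights = c("renormalized",
                                                "contribution")) {
  stopifnot(inherits(p, "herb_pca"))
  weights <- match.arg(weights)
  k <- p$retained
  if (k < 1) stop("no retained principal components", call. = FALSE)
  w <- p$contribution[seq_len(k)]
  if (weights == "renormalized") w <- w / sum(w)
  sc <- p$scores[, seq_len(k), drop = FALSE]
  comp <- as.numeric(sc %*% w)
  ids <- rownames(sc)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(sc)))
  ord <- order(-comp, ids)
  rk <- integer(length(comp)); rk[ord] <- seq_along(comp)
  out <- data.frame(sample_id = ids, sc, comprehensive_score = comp,
                    rank = rk, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("quality_ranking", "data.frame")
  out
}

#' Hierarchical cluster analysis of batch fingerprints
#'
#' Agglomerative clustering of the autoscaled sample profiles; defaults
#' are Ward linkage on Euclidean distances. Flat cluster labels are
#' obtained by cutting the tree at `k` groups.
#'
#' @param x samples x variables matrix or `fingerprint_matrix`
#'   (autoscaled internally).
#' @param k number of flat clusters to report (optional).
#' @param linkage `"ward"` (Ward's minimum-variance, `hclust`'s
#'   `"ward.D2"`), `"complete"`, `"average"` or `"single"`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return list with `hclust` (the merge tree), and if `k` was given,
#'   `labels` (named integer vector from [stats::cutree()]).
#' @export
hca <- function(x, k = NULL, linkage = "ward", metric = "euclidean") {
  methods <- c(ward = "ward.D2", complete = "complete",
               average = "average", single = "single")
  if (!linkage %in% names(methods))
    stop("unknown linkage '", linkage, "'", call. = FALSE)
  if (!metric %in% c("euclidean", "manhattan"))
    stop("unknown metric '", metric, "'", call. = FALSE)
  z <- autoscale(x)
  hc <- stats::hclust(stats::dist(z, method = metric),
                      method = methods[[linkage]])
  out <- list(hclust = hc)
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` object (or the list returned by [hca()]).
#' @param path optional file to write to.
#' @return the Newick string, invisibly if `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  if (is.list(hc) && !inherits(hc, "hclust") && !is.null(hc$hclust))
    hc <- hc$hclust
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# Agreement between two flat labelings up to relabeling: fraction of
# samples correctly assigned under the best one-to-one label matching
# (exhaustive over permutations; fine for the handful of origins used
# here).
label_agreement <- function(truth, labels) {
  truth <- as.integer(factor(truth))
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  if (length(ks) > 8) stop("too many clusters for exhaustive matching")
  perms <- permutations_of(sort(unique(truth)))
  best <- 0
  for (p in perms) {
    mapped <- p[labels]
    best <- max(best, mean(mapped == truth))
  }
  best
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
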