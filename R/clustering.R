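#' Ward hierarchical clustering of response profiles
#'
#' Agglomerative clustering under Ward's minimum-variance criterion with the
#' squared Euclidean (L2) distance: at every step the pair of clusters whose
#' merge least increases the total within-cluster sum of squares is joined.
#' Traces are z-scored per trace by default (so motif shape, not amplitude,
#' drives the grouping); the tree is cut at `k` clusters and labels are
#' renumbered 1..k in order of first appearance, making the labelling
#' deterministic for a given input order.
#'
#' Merge heights are reported as the exact increase in within-cluster sum of
#' squares at each merge (`delta_ss`), which is nondecreasing along the
#' agglomeration.
#'
#' @param responses A [trace_matrix()] or numeric matrix (traces x time).
#' @param k Number of clusters to cut at (default 4, the number of motif
#'   groups typically seen in looming-responsive populations).
#' @param normalize z-score each trace before clustering (default TRUE).
#' @return Object of class `cluster_result`: list with `labels` (1..k per
#'   trace), `k`, `merge` (hclust-style merge matrix), `delta_ss` (within-SS
#'   increase per merge), `hclust` (the underlying tree, heights =
#'   `delta_ss`), `means` (k x time matrix of per-cluster mean input
#'   traces), `normalize`.
#' @export
ward_cluster <- function(responses, k = 4, normalize = TRUE) {
  X <- unclass(as.matrix(responses))
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of traces")
  if (k < 1) stop("k must be >= 1")
  Z <- X
  if (normalize) {
    sds <- apply(Z, 1, stats::sd)
    if (any(sds == 0)) sds[sds == 0] <- 1
    Z <- (Z - rowMeans(Z)) / sds
  }
  if (n == 1) {
    hc <- NULL
    labels <- 1L
    merge <- matrix(integer(0), 0, 2)
    dss <- numeric(0)
  } else {
    # hclust with ward.D on squared distances implements Ward's criterion;
    # its merge heights are exactly twice the within-SS increase
    d2 <- stats::dist(Z)^2
    hc <- stats::hclust(d2, method = "ward.D")
    dss <- hc$height / 2
    hc$height <- dss
    raw <- stats::cutree(hc, k = k)
    labels <- match(raw, unique(raw))   # renumber by first appearance
    merge <- hc$merge
  }
  means <- t(vapply(seq_len(k), function(g)
    colMeans(X[labels == g, , drop = FALSE]), numeric(ncol(X))))
  if (ncol(X) == 1) means <- matrix(means, nrow = k)
  out <- list(labels = labels, k = as.integer(k), merge = merge,
              delta_ss = dss, hclust = hc, means = means,
              normalize = normalize)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Ward clustering: %d traces in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Per-cluster mean response traces
#'
#' @param result A [ward_cluster()] result.
#' @param traces The clustered traces (traces x time), same order and count
#'   as the clustering input. Defaults to the means computed at clustering
#'   time; pass traces explicitly to average a different representation
#'   (e.g. raw rather than normalised).
#' @return Matrix k x time of arithmetic mean traces per label.
#' @export
cluster_means <- function(result, traces = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(traces)) return(result$means)
  traces <- unclass(as.matrix(traces))
  if (nrow(traces) != length(result$labels))
    stop("labels and traces disagree in length")
  counts <- tabulate(result$labels, result$k)
  if (any(counts == 0)) stop("empty cluster")
  out <- t(vapply(seq_len(result$k), function(g)
    colMeans(traces[result$labels == g, , drop = FALSE]),
    numeric(ncol(traces))))
  if (ncol(traces) == 1) out <- matrix(out, nrow = result$k)
  out
}

#' Export a clustering as CSV / JSON
#'
#' Labels as CSV `(roi_id, cluster)`; the merge tree as JSON with the
#' within-SS increase at each merge so the dendrogram cut is auditable.
#'
#' @param result A [ward_cluster()] result.
#' @param labels_path CSV output for labels (NULL to skip).
#' @param tree_path JSON output for the merge tree (NULL to skip).
#' @param roi_ids Optional ROI identifiers (default 1..n).
#' @export
write_clusters <- function(result, labels_path = NULL, tree_path = NULL,
                           roi_ids = seq_along(result$labels)) {
  if (!is.null(labels_path))
    utils::write.csv(data.frame(roi_id = roi_ids, cluster = result$labels),
                     labels_path, row.names = FALSE)
  if (!is.null(tree_path))
    jsonlite::write_json(
      list(merge = result$merge, delta_ss = result$delta_ss, k = result$k),
      tree_path, digits = NA)
  invisible(result)
}
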