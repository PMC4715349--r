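#' Pairwise L1 (Manhattan) distance matrix
#'
#' `d(i, j) = sum_a |z_ia - z_ja|` over standardized annotations; L1 is less
#' influenced by outliers within the non-SV class than Euclidean distance.
#'
#' @param table An [annotation_table()] of transformed values (no masked
#'   cells), or a plain numeric matrix.
#' @return Symmetric site-by-site distance matrix.
#' @export
l1_distance_matrix <- function(table) {
  x <- if (inherits(table, "annotation_table")) table$values else table
  if (anyNA(x)) stop("l1_distance_matrix: masked cells remain; apply_transform first")
  as.matrix(dist(x, method = "manhattan"))
}

#' Agglomerative Ward clustering on a distance matrix
#'
#' Ward's method applied directly to the provided dissimilarities (the
#' `ward.D` convention, no pre-squaring), as is conventional when pairing
#' Ward linkage with L1 distances.
#'
#' @param distances Distance matrix (e.g. from [l1_distance_matrix()]) or
#'   `dist` object; at least 2 sites.
#' @return An `hclust` tree.
#' @export
ward_cluster <- function(distances) {
  d <- if (inherits(distances, "dist")) distances else as.dist(distances)
  if (attr(d, "Size") < 2L) stop("ward_cluster: need at least 2 sites")
  hclust(d, method = "ward.D")
}

# Left-to-right leaf order with the convention: at every internal node the
# tighter (lower merge height) subtree goes left; ties broken by the smallest
# member index.  Singletons have height 0.
dendrogram_order <- function(tree) {
  n <- length(tree$height) + 1L
  node_height <- function(k) if (k < 0) 0 else tree$height[k]
  node_min <- function(k) if (k < 0) -k else min_idx[k]
  min_idx <- integer(n - 1L)
  for (k in seq_len(n - 1L))
    min_idx[k] <- min(node_min(tree$merge[k, 1]), node_min(tree$merge[k, 2]))
  leaves <- function(k) {
    if (k < 0) return(-k)
    a <- tree$merge[k, 1]; b <- tree$merge[k, 2]
    ha <- node_height(a); hb <- node_height(b)
    if (ha < hb || (ha == hb && node_min(a) <= node_min(b)))
      c(leaves(a), leaves(b)) else c(leaves(b), leaves(a))
  }
  leaves(n - 1L)
}

#' Cut a tree into clusters, numbered left to right
#'
#' Exactly one of `height` / `n_clusters` must be given.  Labels are numbered
#' by left-to-right position in the dendrogram (tighter subtree left), so
#' cluster 1 is the leftmost.
#'
#' @param tree An `hclust` tree from [ward_cluster()].
#' @param height Dissimilarity cut height.
#' @param n_clusters Number of clusters.
#' @return Integer labels, one per site.
#' @export
cut_tree <- function(tree, height = NULL, n_clusters = NULL) {
  if (is.null(height) == is.null(n_clusters))
    stop("give exactly one of height / n_clusters")
  n <- length(tree$height) + 1L
  if (!is.null(n_clusters) && n_clusters > n)
    stop("n_clusters (", n_clusters, ") exceeds number of sites (", n, ")")
  raw <- if (is.null(height)) cutree(tree, k = n_clusters)
         else cutree(tree, h = height)
  ord <- dendrogram_order(tree)
  first_seen <- unique(raw[ord])
  as.integer(match(raw, first_seen))
}

#' Classical (Torgerson) MDS embedding of a distance matrix
#'
#' Double-centered squared distances, eigendecomposition, coordinates ordered
#' by decreasing eigenvalue.  Sign convention: the first coordinate of
#' largest magnitude in each dimension is made positive, so embeddings are
#' reproducible.
#'
#' @param distances Distance matrix.
#' @param k Number of dimensions (default 3, convenient for visualization);
#'   must be below the number of sites.
#' @return `n x k` coordinate matrix.
#' @export
mds_embedding <- function(distances, k = 3) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (k >= n) stop("mds_embedding: k must be < number of sites")
  coords <- cmdscale(d, k = k)
  if (ncol(coords) < k)   # trailing zero-eigenvalue dimensions
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  for (j in seq_len(k)) {
    v <- coords[, j]
    i <- which.max(abs(v))
    if (length(i) && abs(v[i]) > 1e-9 && v[i] < 0) coords[, j] <- -v
  }
  coords
}

#' Per-cluster composition by source call set
#'
#' Counts of sites per (cluster, source) and the proportion of each cluster
#' that is an SV call.
#'
#' @param labels Cluster labels (e.g. from [cut_tree()]).
#' @param sources Call-set label per site.
#' @param is_sv Logical per site; defaults to `sv_type`-style sources being
#'   anything other than `random`/`repeat_element` if not given.
#' @return Data.frame: `cluster`, one count column per source, `n`,
#'   `prop_sv`.
#' @export
cluster_composition <- function(labels, sources,
                                is_sv = !grepl("random|repeat", sources)) {
  stopifnot(length(labels) == length(sources), length(is_sv) == length(labels))
  tab <- table(cluster = labels, source = sources)
  out <- data.frame(cluster = as.integer(rownames(tab)))
  for (s in colnames(tab)) out[[s]] <- as.integer(tab[, s])
  out$n <- as.integer(rowSums(tab))
  out$prop_sv <- as.numeric(tapply(is_sv, labels, mean)[as.character(out$cluster)])
  out
}
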