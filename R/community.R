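#' Bray-Curtis dissimilarity between site communities
#'
#' d(u, v) = 1 - 2 * sum(min(u, v)) / (sum(u) + sum(v)) on copy
#' concentrations, so the dissimilarity uses the quantitative information
#' rather than presence/absence. A pair of two all-zero communities has no
#' defined dissimilarity; it is set to 0 with a warning.
#'
#' @param community Numeric matrix, sites in rows, taxa in columns, values
#'   >= 0 (copies/L).
#' @return A symmetric numeric matrix of class `dissimilarity_matrix` with
#'   values in \[0, 1\] and zero diagonal.
#' @export
bray_curtis <- function(community) {
  stopifnot(is.matrix(community))
  if (any(is.na(community))) stop("community matrix contains NA", call. = FALSE)
  if (any(community < 0)) stop("community values must be non-negative", call. = FALSE)
  d <- as.matrix(suppressWarnings(vegan::vegdist(community, method = "bray")))
  empty <- rowSums(community) == 0
  if (sum(empty) >= 2) {
    warning("dissimilarity between all-zero communities set to 0")
    d[empty, empty] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(community), rownames(community))
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal NMDS (monotone regression of configuration distances on
#' dissimilarity ranks), keeping the lowest-stress configuration over
#' `n_restarts` random starts. Deterministic given `seed`.
#'
#' @param d Dissimilarity matrix (from [bray_curtis()]).
#' @param dims Embedding dimension, default 2.
#' @param n_restarts Number of random starts, default 500.
#' @param seed Integer seed.
#' @return Object of class `edna_ordination`: `points` (n x dims, centred),
#'   `stress` (Kruskal stress-1, in \[0, 1\]), `n_restarts_used`, `seed`.
#' @export
nmds <- function(d, dims = 2, n_restarts = 500, seed = 1L) {
  d <- unclass(d)
  n <- nrow(d)
  if (n <= dims) stop("need more sites than embedding dimensions", call. = FALSE)
  set.seed(seed)
  fit <- suppressWarnings(vegan::metaMDS(
    stats::as.dist(d), k = dims, try = n_restarts, trymax = n_restarts,
    trace = 0, autotransform = FALSE, wascores = FALSE
  ))
  pts <- scale(fit$points, scale = FALSE)  # centre at origin
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("NMDS", seq_len(dims))
  structure(list(points = pts, stress = fit$stress,
                 n_restarts_used = n_restarts, seed = seed),
            class = "edna_ordination")
}

#' @export
print.edna_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d sites in %d dimensions, stress = %.4f (%d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_restarts_used))
  invisible(x)
}

#' @export
plot.edna_ordination <- function(x, ...) {
  graphics::plot(x$points, asp = 1, ...)
  graphics::text(x$points, labels = rownames(x$points), pos = 3, cex = 0.7)
  invisible(x)
}

#' Calinski-Harabasz criterion for a labelling
#'
#' CH(k) = \[B / (k - 1)\] / \[W / (n - k)\], where B and W are the between-
#' and within-cluster sums of squared Euclidean distances to the cluster
#' centroids.
#'
#' @param points Numeric matrix, observations in rows.
#' @param labels Integer cluster labels.
#' @return The CH value (numeric scalar).
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(points)
  W <- 0
  B <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    ctr <- colMeans(points[idx, , drop = FALSE])
    W <- W + sum(sweep(points[idx, , drop = FALSE], 2, ctr)^2)
    B <- B + sum(idx) * sum((ctr - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' K-means clustering with Calinski-Harabasz choice of k
#'
#' For each k in `k_range`, runs best-of-`n_init` k-means (Lloyd, squared
#' Euclidean) and evaluates the Calinski-Harabasz criterion; returns the
#' labelling for the k that maximizes it (smallest k on ties). Typically run
#' on the 2-D NMDS coordinates derived from Bray-Curtis dissimilarities, so
#' the community dissimilarity drives the clustering while k-means operates
#' in a Euclidean space; the raw copy matrix can be passed instead.
#'
#' @param points Numeric matrix, sites in rows (ordination coordinates or a
#'   site x taxon copy matrix).
#' @param k_range Candidate numbers of clusters, default 2:8.
#' @param n_init Random initialisations per k, default 50.
#' @param seed Integer seed.
#' @return Object of class `edna_clustering`: `labels` (integer, 1..k),
#'   `k`, `calinski_by_k` (named numeric), `seed`.
#' @export
choose_k_kmeans <- function(points, k_range = 2:8, n_init = 50, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (any(k_range < 2)) stop("k_range must contain only k >= 2", call. = FALSE)
  k_range <- k_range[k_range < n]
  if (length(k_range) == 0) stop("need more sites than the smallest k", call. = FALSE)
  set.seed(seed)
  ch <- stats::setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- suppressWarnings(stats::kmeans(points, centers = k, nstart = n_init,
                                          iter.max = 100, algorithm = "Lloyd"))
    fits[[i]] <- fit
    ch[i] <- calinski_harabasz(points, fit$cluster)
  }
  best <- which(ch == max(ch, na.rm = TRUE))[1]  # smallest k on ties
  labels <- fits[[best]]$cluster
  # relabel 1..k in order of first appearance for determinism
  labels <- as.integer(factor(labels, levels = unique(labels)))
  names(labels) <- rownames(points)
  structure(list(labels = labels, k = k_range[best], calinski_by_k = ch,
                 seed = seed),
            class = "edna_clustering")
}

#' @export
print.edna_clustering <- function(x, ...) {
  cat(sprintf("k-means clustering: k = %d chosen by Calinski-Harabasz\n", x$k))
  cat("CH by k:", paste(sprintf("%s: %.2f", names(x$calinski_by_k),
                                x$calinski_by_k), collapse = ", "), "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Community-structure stage on a calibrated run
#'
#' Convenience wrapper: drops all-zero sites, computes Bray-Curtis
#' dissimilarities on copies/L, fits the NMDS ordination and clusters its
#' coordinates by k-means with Calinski-Harabasz choice of k.
#'
#' @param copies Site-level copy matrix (taxa x sites), e.g. from
#'   [copies_by_site()].
#' @param dims,n_restarts,k_range,n_init,seed Passed to [nmds()] and
#'   [choose_k_kmeans()].
#' @param transform Optional `"log10"` to use log10(x + 1) copies.
#' @return List with `dissimilarity`, `ordination`, `clustering` and
#'   `dropped_sites` (all-zero sites removed before analysis).
#' @export
community_structure <- function(copies, dims = 2, n_restarts = 500,
                                k_range = 2:8, n_init = 50, seed = 1L,
                                transform = c("none", "log10")) {
  transform <- match.arg(transform)
  comm <- t(copies)  # sites x taxa
  comm[is.na(comm)] <- 0
  dropped <- rownames(comm)[rowSums(comm) == 0]
  if (length(dropped) > 0) {
    comm <- comm[rowSums(comm) > 0, , drop = FALSE]
  }
  if (transform == "log10") comm <- log10(comm + 1)
  d <- bray_curtis(comm)
  ord <- nmds(d, dims = dims, n_restarts = n_restarts, seed = seed)
  cl <- choose_k_kmeans(ord$points, k_range = k_range, n_init = n_init,
                        seed = seed)
  list(dissimilarity = d, ordination = ord, clustering = cl,
       dropped_sites = dropped)
}
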