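# exact k-nearest-neighbour indices (Euclidean), computed block-wise
knn_indices <- function(x, k) {
  n <- nrow(x)
  if (k >= n) stop("need more observations than neighbours")
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, `+`) - 2 * x[idx, , drop = FALSE] %*% t(x)
    for (ii in seq_along(idx)) {
      d2[ii, idx[ii]] <- Inf
      out[idx[ii], ] <- order(d2[ii, ])[seq_len(k)]
    }
  }
  out
}

#' UMAP embedding of PCA scores
#'
#' Two-dimensional UMAP of the top principal components (the conventional
#' single-cell workflow uses the top 50). Deterministic for a fixed seed.
#'
#' @param scores PCA score matrix (cells x components).
#' @param n_components number of leading score columns to use (default 50,
#'   capped at the available columns).
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed integer seed.
#' @return data.frame `cell_id`, `x`, `y`.
#' @export
umap_embed <- function(scores, n_components = 50, n_neighbors = 15,
                       min_dist = 0.1, seed = 0) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("need at least 2 components for a 2-D embedding")
  if (nrow(scores) <= n_neighbors) {
    stop("fewer cells than 'n_neighbors'; reduce n_neighbors")
  }
  use <- scores[, seq_len(min(n_components, ncol(scores))), drop = FALSE]
  emb <- with_seed(derive_seed(seed, "umap"), {
    uwot::umap(use, n_neighbors = n_neighbors, min_dist = min_dist,
      n_threads = 1L, n_sgd_threads = 0L, verbose = FALSE)
  })
  if (any(!is.finite(emb))) stop("UMAP produced non-finite coordinates")
  data.frame(
    cell_id = rownames(scores) %||% sprintf("cell_%04d", seq_len(nrow(scores))),
    x = emb[, 1L], y = emb[, 2L],
    stringsAsFactors = FALSE
  )
}

#' Leiden community detection on a kNN graph of PCA scores
#'
#' Builds an exact k-nearest-neighbour graph (Euclidean metric in PC space),
#' then optimises modularity with the Leiden algorithm at the given
#' resolution (default 0.5). Clusters are relabelled 0..C-1 by decreasing
#' size, so the labelling is deterministic for a fixed seed.
#'
#' @param scores PCA score matrix.
#' @param k_neighbors neighbours per cell (default 15).
#' @param resolution Leiden resolution parameter (default 0.5).
#' @param seed integer seed.
#' @param n_iterations Leiden iterations.
#' @return a `cluster_assignment`: data.frame `cell_id`, `cluster` with
#'   attributes `resolution`, `k_neighbors`, `seed`.
#' @export
leiden_cluster <- function(scores, k_neighbors = 15, resolution = 0.5,
                           seed = 0, n_iterations = 10) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n <= k_neighbors) stop("need more cells than 'k_neighbors'")
  if (all(apply(scores, 2L, function(v) diff(range(v))) < 1e-12)) {
    warning("all spectra identical in PC space; returning a single cluster")
    cl <- rep(0L, n)
  } else {
    nn <- knn_indices(scores, k_neighbors)
    edges <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    comm <- with_seed(derive_seed(seed, "leiden"), {
      igraph::cluster_leiden(g, objective_function = "modularity",
        resolution = resolution, n_iterations = n_iterations)
    })
    memb <- igraph::membership(comm)
    sizes <- sort(table(memb), decreasing = TRUE)
    relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
    cl <- unname(relabel[as.character(memb)])
  }
  structure(data.frame(
    cell_id = rownames(scores) %||% sprintf("cell_%04d", seq_len(n)),
    cluster = as.integer(cl),
    stringsAsFactors = FALSE
  ), resolution = resolution, k_neighbors = k_neighbors, seed = seed,
  class = c("cluster_assignment", "data.frame"))
}

#' Resistance-label composition of each cluster
#'
#' For every (cluster, drug) pair: the proportion of member cells whose
#' sample carries a resistant / sensitive / unknown label for that drug.
#' Unknowns are reported explicitly rather than dropped.
#'
#' @param assignment a `cluster_assignment` from [leiden_cluster()].
#' @param metadata a `cohort_metadata` aligned to the same cells.
#' @param drugs drugs to summarise (default: all annotated).
#' @return data.frame `cluster`, `drug`, `p_resistant`, `p_sensitive`,
#'   `p_unknown`, `n`.
#' @export
cluster_composition <- function(assignment, metadata, drugs = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  drugs <- drugs %||% metadata_drugs(metadata)
  if (length(drugs) == 0L) stop("no drug label columns in metadata")
  m <- match(assignment$cell_id, metadata$cell_id)
  if (anyNA(m)) stop("cluster assignment contains cells absent from metadata")
  rows <- list()
  for (cl in sort(unique(assignment$cluster))) {
    sel <- m[assignment$cluster == cl]
    for (d in drugs) {
      lab <- metadata[[d]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, drug = d,
        p_resistant = mean(lab == "resistant"),
        p_sensitive = mean(lab == "sensitive"),
        p_unknown = mean(lab == "unknown"),
        n = length(lab)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
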