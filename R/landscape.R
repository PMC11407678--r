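#' Size-factor normalization of marker intensities
#'
#' Each particle's size factor is its total marker signal divided by the
#' geometric mean of all totals (so the factors have geometric mean 1, and
#' the normalization is invariant to a global rescaling of the raw
#' intensities). Marker values are divided by the particle's factor and
#' log1p-transformed. Particles with all-zero markers carry no profile and
#' are dropped with a warning.
#'
#' @param table a [particle_table()] (or plain non-negative matrix).
#' @return list: `matrix` (log1p-normalized particles x markers), `factors`
#'   (per kept particle), `kept` (row indices kept), `markers`.
#' @export
size_factor_normalize <- function(table) {
  M <- if (inherits(table, "particle_table")) marker_matrix(table)
       else as.matrix(table)
  if (any(M < 0)) stop("marker intensities must be non-negative")
  totals <- rowSums(M)
  kept <- which(totals > 0)
  if (length(kept) < nrow(M))
    warning("dropping ", nrow(M) - length(kept),
            " particle(s) with all-zero marker intensities")
  M <- M[kept, , drop = FALSE]
  totals <- totals[kept]
  factors <- totals / exp(mean(log(totals)))
  list(matrix = log1p(M / factors), factors = factors, kept = kept,
       markers = colnames(M))
}

#' Embed particle profiles into the 2-D organelle landscape
#'
#' Runs centered PCA on the normalized profiles (all components are kept for
#' the typical 4–8 marker panels), removes batch structure by centering each
#' replicate's PC coordinates on the common origin, and embeds the aligned
#' PCs in two dimensions with UMAP (trained model retained so query data can
#' later be projected into the same space).
#'
#' @param matrix normalized profile matrix (particles x markers), e.g.
#'   `size_factor_normalize(...)$matrix`.
#' @param batch per-particle replicate/batch labels (NULL = single batch).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param n_pcs number of principal components (default: all, capped at 10).
#' @param seed seed fixing the UMAP optimization.
#' @return object of class `landscape_model`: `markers`, PCA `center` and
#'   `rotation`, `batch` labels, `pcs` (aligned PCs), `umap` (trained uwot
#'   model), `embedding` (n x 2), and after [cluster_landscape()] a
#'   `cluster` vector.
#' @export
embed_landscape <- function(matrix, batch = NULL, n_neighbors = 15,
                            min_dist = 0.1, n_pcs = NULL, seed = 0) {
  if (nrow(matrix) < 2) stop("need at least 2 particles to embed")
  if (any(!is.finite(matrix))) stop("non-finite values in profile matrix")
  if (is.null(batch)) batch <- rep(1L, nrow(matrix))
  if (length(batch) != nrow(matrix))
    stop("batch labels must match the number of particles")
  if (is.null(n_pcs)) n_pcs <- min(ncol(matrix), 10L)
  pca <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  pcs <- pca$x[, seq_len(min(n_pcs, ncol(pca$x))), drop = FALSE]
  pcs <- center_batches(pcs, batch)
  # spectral initialization needs a reasonably sized graph; tiny inputs
  # fall back to a seeded random layout
  um <- uwot::umap(pcs, n_neighbors = min(n_neighbors, nrow(pcs) - 1),
                   min_dist = min_dist, metric = "euclidean", seed = seed,
                   init = if (nrow(pcs) < 30) "rand" else "spectral",
                   ret_model = TRUE)
  structure(list(markers = colnames(matrix),
                 center = pca$center, rotation = pca$rotation,
                 n_pcs = ncol(pcs), batch = batch, pcs = pcs,
                 umap = um, embedding = um$embedding,
                 n_neighbors = n_neighbors, min_dist = min_dist,
                 seed = seed, cluster = NULL),
            class = "landscape_model")
}

# subtract each batch's mean in PC space (the default batch aligner)
center_batches <- function(pcs, batch) {
  for (b in unique(batch)) {
    rows <- batch == b
    pcs[rows, ] <- sweep(pcs[rows, , drop = FALSE], 2,
                         colMeans(pcs[rows, , drop = FALSE]))
  }
  pcs
}

#' Cluster the landscape by community detection on the kNN graph
#'
#' Builds the k-nearest-neighbor graph of the 2-D UMAP embedding and
#' partitions it by Leiden modularity optimization. The resolution default
#' was calibrated once on the seven-organelle simulation (so that the seven
#' generative classes are recovered) and frozen.
#'
#' @param model a fitted [embed_landscape()] model.
#' @param k neighbor count of the kNN graph (60 for the organelle
#'   landscape, 20 for the contact-site and endosome analyses).
#' @param resolution Leiden resolution parameter.
#' @param seed seed for the (stochastic) Leiden refinement.
#' @return the model with an integer `cluster` vector added (labels 1..C,
#'   ordered by decreasing cluster size).
#' @export
cluster_landscape <- function(model, k = 60, resolution = 0.01, seed = 0) {
  stopifnot(inherits(model, "landscape_model"))
  n <- nrow(model$embedding)
  if (k >= n) stop("k must be smaller than the number of particles")
  nn <- FNN::get.knn(model$embedding, k = k)$nn.index
  edges <- cbind(rep(seq_len(n), k), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = 10)
  lab <- igraph::membership(comm)
  # relabel 1..C by decreasing size
  sizes <- sort(table(lab), decreasing = TRUE)
  model$cluster <- as.integer(match(lab, as.integer(names(sizes))))
  model$cluster_k <- k
  model$resolution <- resolution
  model
}

#' Merge clusters manually
#'
#' Replaces the listed labels of each group by a single label (the group's
#' name if given, else its first member), leaving all other labels
#' untouched — the programmatic equivalent of manually grouping clusters
#' that carry the same dominant marker.
#'
#' @param labels vector of cluster labels.
#' @param groups list of vectors of labels to merge; optionally named (the
#'   name becomes the merged label).
#' @return relabeled vector of the same length.
#' @export
merge_clusters <- function(labels, groups) {
  if (!length(groups)) return(labels)
  out <- labels
  seen <- c()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    unknown <- setdiff(g, labels)
    if (length(unknown))
      stop("unknown cluster label(s): ", paste(unknown, collapse = ", "))
    if (any(g %in% seen)) stop("groups must not overlap")
    seen <- c(seen, g)
    new <- if (!is.null(names(groups)) && nzchar(names(groups)[gi]))
      names(groups)[gi] else g[1]
    out[labels %in% g] <- new
  }
  out
}

#' Project query particles onto a reference landscape
#'
#' Normalizes the query with its own size factors, pushes it through the
#' reference PCA (reference center and rotation) and the batch aligner
#' (centering each query batch), embeds it with the reference-trained UMAP
#' transform, and transfers cluster labels by majority vote among the 10
#' nearest reference particles in embedding space (ties resolved by the
#' single nearest neighbor). The distance to the nearest reference particle
#' in aligned PC space is reported so novel query populations can be
#' flagged (the UMAP transform itself always lands new points among
#' reference points, so embedding distances carry no novelty signal).
#'
#' @param ref a clustered [landscape_model()].
#' @param query a [particle_table()] whose markers equal the reference's.
#' @param batch per-particle query batch labels (default: the query table's
#'   `replicate` column).
#' @param k_transfer neighbor count for label transfer.
#' @return object of class `query_projection`: `embedding` (m x 2),
#'   `cluster` (transferred labels), `nn_dist` (nearest-reference
#'   distances), and `kept` (query rows retained by normalization).
#' @export
map_query <- function(ref, query, batch = NULL, k_transfer = 10) {
  stopifnot(inherits(ref, "landscape_model"))
  if (is.null(ref$cluster)) stop("reference model has no cluster labels; ",
                                 "run cluster_landscape() first")
  qm <- if (inherits(query, "particle_table")) {
    if (!setequal(markers(query), ref$markers))
      stop("query markers do not match the reference markers")
    marker_matrix(query)[, ref$markers, drop = FALSE]
  } else {
    q <- as.matrix(query)
    if (is.null(colnames(q)) || !all(ref$markers %in% colnames(q)))
      stop("query markers do not match the reference markers")
    q[, ref$markers, drop = FALSE]
  }
  if (is.null(batch)) {
    batch <- if (inherits(query, "particle_table") &&
                 "replicate" %in% names(query)) query$replicate
             else rep(1L, nrow(qm))
  }
  norm <- size_factor_normalize(qm)
  batch <- batch[norm$kept]
  pcs <- sweep(norm$matrix, 2, ref$center) %*%
    ref$rotation[, seq_len(ref$n_pcs), drop = FALSE]
  pcs <- center_batches(pcs, batch)
  emb <- uwot::umap_transform(pcs, ref$umap)
  nn <- FNN::get.knnx(ref$embedding, emb, k = k_transfer)
  votes <- matrix(ref$cluster[nn$nn.index], nrow(emb), k_transfer)
  lab <- apply(votes, 1, function(v) {
    tab <- table(v)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else as.character(v[1])  # tie -> nearest
  })
  # novelty is judged in aligned PC space: the UMAP transform places even
  # out-of-distribution points among reference points, so embedding-space
  # distances cannot flag them
  nn_pc <- FNN::get.knnx(ref$pcs, pcs, k = 1)
  structure(list(embedding = emb,
                 cluster = utils::type.convert(lab, as.is = TRUE),
                 nn_dist = nn_pc$nn.dist[, 1],
                 kept = norm$kept),
            class = "query_projection")
}

#' Fit the full landscape pipeline on a particle table
#'
#' Convenience wrapper: size-factor normalization, PCA, batch alignment,
#' UMAP, and kNN-graph clustering, returning both the fitted model and the
#' input table augmented with `PCA1`/`PCA2`, `UMAP1`/`UMAP2` and `cluster`
#' columns (rows dropped by normalization get NA).
#'
#' @param table a [particle_table()].
#' @param k clustering neighbor count.
#' @param resolution Leiden resolution.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed seed for UMAP and Leiden.
#' @return list: `model` (a clustered `landscape_model`), `table` (augmented
#'   [particle_table()]).
#' @export
fit_landscape <- function(table, k = 60, resolution = 0.01,
                          n_neighbors = 15, min_dist = 0.1, seed = 0) {
  stopifnot(inherits(table, "particle_table"))
  norm <- size_factor_normalize(table)
  batch <- table$replicate[norm$kept]
  model <- embed_landscape(norm$matrix, batch = batch,
                           n_neighbors = n_neighbors, min_dist = min_dist,
                           seed = seed)
  model <- cluster_landscape(model, k = k, resolution = resolution,
                             seed = seed)
  df <- as.data.frame(table)
  df$PCA1 <- df$PCA2 <- df$UMAP1 <- df$UMAP2 <- NA_real_
  df$cluster <- NA_integer_
  df$PCA1[norm$kept] <- model$pcs[, 1]
  df$PCA2[norm$kept] <- model$pcs[, 2]
  df$UMAP1[norm$kept] <- model$embedding[, 1]
  df$UMAP2[norm$kept] <- model$embedding[, 2]
  df$cluster[norm$kept] <- model$cluster
  list(model = model, table = particle_table(df, markers = markers(table)))
}
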