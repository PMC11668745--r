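#' Mapper cover/cluster configuration
#'
#' @param n_intervals number of cover intervals per axis (default 10).
#' @param overlap_fraction fractional overlap between adjacent intervals,
#'   strictly inside (0, 1) (default 0.3).
#' @param clusterer `"single_linkage"` (hclust cut at a distance cutoff) or
#'   `"density"` (connected components of the epsilon-ball graph at the
#'   same cutoff).
#' @param cluster_cutoff distance cutoff; `NULL` means the median
#'   nearest-neighbor distance of the embedding, recomputed per call.
#' @param min_cluster_size smallest cluster kept as a node (default 1, so
#'   no point is discarded and the cover property holds exactly).
#' @return object of class `mapper_config`.
#' @export
mapper_config <- function(n_intervals = 10L, overlap_fraction = 0.3,
                          clusterer = c("single_linkage", "density"),
                          cluster_cutoff = NULL, min_cluster_size = 1L) {
  clusterer <- match.arg(clusterer)
  stopifnot(n_intervals >= 1L, overlap_fraction > 0, overlap_fraction < 1,
            min_cluster_size >= 1L,
            is.null(cluster_cutoff) || cluster_cutoff > 0)
  structure(list(n_intervals = as.integer(n_intervals),
                 overlap_fraction = overlap_fraction, clusterer = clusterer,
                 cluster_cutoff = cluster_cutoff,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "mapper_config")
}

#' Binary functional connectivity network
#'
#' @param adjacency binary symmetric matrix with zero diagonal.
#' @param roi_names labels in row order.
#' @param provenance free-form list describing how the graph was built.
#' @return object of class `fcn`.
#' @export
fcn <- function(adjacency, roi_names = rownames(adjacency),
                provenance = list()) {
  adjacency <- as.matrix(adjacency)
  if (is.null(roi_names)) roi_names <- roi_labels(nrow(adjacency))
  stopifnot(nrow(adjacency) == ncol(adjacency),
            all(adjacency %in% c(0, 1)),
            identical(adjacency, t(adjacency)),
            all(diag(adjacency) == 0),
            length(roi_names) == nrow(adjacency))
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(roi_names, roi_names)
  structure(list(adjacency = adjacency, roi_labels = roi_names,
                 provenance = provenance),
            class = "fcn")
}

#' @export
print.fcn <- function(x, ...) {
  cat(sprintf("<fcn> %d ROIs, %d edges\n", nrow(x$adjacency),
              sum(x$adjacency) / 2))
  invisible(x)
}

#' Build an FCN from a 2-D embedding with the Mapper algorithm
#'
#' Covers the embedding with `n_intervals^2` overlapping axis-aligned
#' rectangles, clusters the points inside each rectangle, treats each
#' sub-cluster as a nerve node, and maps the nerve back to ROI level: two
#' ROIs are connected iff they co-occur in one sub-cluster, or (when
#' `link_overlap` is on) they lie in two sub-clusters that share at least
#' one member. The cover is built from interval endpoints stretched so
#' every point falls in at least one rectangle by construction.
#'
#' @param emb a [roi_embedding()] (or bare `n x 2` coordinate matrix).
#' @param cfg a [mapper_config()].
#' @param link_overlap connect ROIs across overlapping sub-clusters
#'   (default `TRUE`).
#' @return an [fcn()]; its `provenance` records the config and the list of
#'   sub-clusters (`clusters`, member indices per nerve node).
#' @export
mapper_fcn <- function(emb, cfg = mapper_config(), link_overlap = TRUE) {
  coords <- if (inherits(emb, "roi_embedding")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (n == 0L) stop("empty embedding")
  labels <- rownames(coords)
  if (is.null(labels)) labels <- roi_labels(n)
  stopifnot(inherits(cfg, "mapper_config"), ncol(coords) == 2L)

  cutoff <- cfg$cluster_cutoff %||% .median_nn_dist(coords)
  bins <- lapply(1:2, function(ax)
    .cover_intervals(coords[, ax], cfg$n_intervals, cfg$overlap_fraction))

  clusters <- list()
  for (i in seq_len(cfg$n_intervals)) {
    in_x <- coords[, 1] >= bins[[1]]$lo[i] & coords[, 1] <= bins[[1]]$hi[i]
    for (j in seq_len(cfg$n_intervals)) {
      idx <- which(in_x &
                   coords[, 2] >= bins[[2]]$lo[j] &
                   coords[, 2] <= bins[[2]]$hi[j])
      if (!length(idx)) next
      for (cl in .cluster_bin(coords[idx, , drop = FALSE], cfg, cutoff)) {
        if (length(cl) >= cfg$min_cluster_size)
          clusters[[length(clusters) + 1L]] <- idx[cl]
      }
    }
  }
  # overlapping bins rediscover sub-clusters wholly contained in a
  # neighboring bin's cluster; keep only the maximal ones so the nerve
  # reflects the cover's geometry, not bin bookkeeping
  clusters <- unique(lapply(clusters, sort))
  if (length(clusters) > 1L) {
    sets <- lapply(clusters, as.integer)
    maximal <- vapply(seq_along(sets), function(i)
      !any(vapply(seq_along(sets), function(j)
        i != j && length(sets[[i]]) <= length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]]) &&
          !identical(sets[[i]], sets[[j]]), logical(1))), logical(1))
    clusters <- clusters[maximal]
  }
  covered <- sort(unique(unlist(clusters)))
  stopifnot(identical(covered, seq_len(n))) # cover property, by construction

  adj <- matrix(0, n, n)
  for (cl in clusters) adj[cl, cl] <- 1
  if (link_overlap && length(clusters) > 1L) {
    memb <- matrix(0L, n, length(clusters))
    for (k in seq_along(clusters)) memb[clusters[[k]], k] <- 1L
    share <- crossprod(memb) # cluster x cluster overlap counts
    for (k1 in seq_len(ncol(memb) - 1L)) for (k2 in (k1 + 1L):ncol(memb)) {
      if (share[k1, k2] > 0)
        adj[clusters[[k1]], clusters[[k2]]] <- 1
    }
    adj <- pmax(adj, t(adj))
  }
  diag(adj) <- 0
  rownames(adj) <- colnames(adj) <- labels
  fcn(adj, labels,
      provenance = list(method = "mapper", config = cfg, cutoff = cutoff,
                        clusters = clusters,
                        embedding_method =
                          if (inherits(emb, "roi_embedding")) emb$method))
}

# overlapping cover of one axis: n equal base intervals over the data
# range, each stretched by overlap_fraction of its length on both sides
.cover_intervals <- function(v, n_intervals, overlap) {
  r <- range(v)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  len <- diff(r) / n_intervals
  lo <- r[1] + (seq_len(n_intervals) - 1L) * len - overlap * len
  hi <- r[1] + seq_len(n_intervals) * len + overlap * len
  list(lo = lo, hi = hi)
}

.median_nn_dist <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) return(1)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  m <- stats::median(apply(d, 1, min))
  if (m == 0) m <- mean(d[is.finite(d)]) / n
  max(m, .Machine$double.eps)
}

# cluster the points of one cover bin; returns list of index vectors
# (local indices into the bin)
.cluster_bin <- function(pts, cfg, cutoff) {
  m <- nrow(pts)
  if (m == 1L) return(list(1L))
  d <- stats::dist(pts)
  if (cfg$clusterer == "single_linkage") {
    if (all(d == 0)) return(list(seq_len(m)))
    hc <- stats::hclust(d, method = "single")
    # slack keeps merges at exactly the cutoff (knife-edge distances)
    split(seq_len(m), stats::cutree(hc, h = cutoff * (1 + 1e-8)))
  } else {
    g <- igraph::graph_from_adjacency_matrix(
      as.matrix(d) <= cutoff, mode = "undirected", diag = FALSE)
    split(seq_len(m), igraph::components(g)$membership)
  }
}

#' Nerve graph of a Mapper FCN
#'
#' One node per Mapper sub-cluster; two nodes are joined when their
#' clusters share at least one ROI. This is the simplicial-complex
#' 1-skeleton underlying the ROI-level adjacency.
#'
#' @param net an [fcn()] produced by [mapper_fcn()].
#' @return an igraph object whose vertices carry a `members` attribute
#'   (comma-separated ROI labels).
#' @export
mapper_nerve <- function(net) {
  stopifnot(inherits(net, "fcn"))
  clusters <- net$provenance$clusters
  if (is.null(clusters)) stop("no Mapper clusters recorded on this FCN")
  k <- length(clusters)
  memb <- matrix(0L, nrow(net$adjacency), k)
  for (i in seq_len(k)) memb[clusters[[i]], i] <- 1L
  share <- crossprod(memb)
  diag(share) <- 0
  g <- igraph::graph_from_adjacency_matrix(share > 0, mode = "undirected")
  igraph::V(g)$members <- vapply(clusters, function(cl)
    paste(net$roi_labels[cl], collapse = ","), character(1))
  g
}

#' Export an FCN (or any igraph-convertible adjacency) to GraphML / edge list
#'
#' @param net an [fcn()] or [summary_fcn()].
#' @param graphml_path,edgelist_path output paths (`NULL` to skip either).
#' @return invisibly, the igraph object.
#' @export
export_network <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  adj <- if (inherits(net, "summary_fcn")) net$ratio else net$adjacency
  mode <- "undirected"
  g <- igraph::graph_from_adjacency_matrix(adj, mode = mode, weighted = TRUE,
                                           diag = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el) <- c("roi_from", "roi_to", "weight")[seq_len(ncol(el))]
    utils::write.csv(el, edgelist_path, row.names = FALSE)
  }
  invisible(g)
}
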