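#' Phi coefficient of two binary series
#'
#' Pearson correlation specialized to binary data, computed from the 2x2
#' contingency table:
#' `phi = (n11*n00 - n10*n01) / sqrt((n11+n10)(n01+n00)(n11+n01)(n10+n00))`.
#' Any zero marginal (a constant series) makes the denominator vanish; phi
#' is then defined as 0.
#'
#' @param a,b equal-length binary (0/1) series.
#' @return Scalar in `[-1, 1]`.
#' @export
phi_coef <- function(a, b) {
  a <- if (inherits(a, "event_raster")) a$active else as.integer(a)
  b <- if (inherits(b, "event_raster")) b$active else as.integer(b)
  if (length(a) != length(b) || length(a) < 2L)
    stop_calwave("calwave_invalid", "series must have equal length >= 2")
  n11 <- sum(a == 1L & b == 1L); n10 <- sum(a == 1L & b == 0L)
  n01 <- sum(a == 0L & b == 1L); n00 <- sum(a == 0L & b == 0L)
  den <- sqrt(n11 + n10) * sqrt(n01 + n00) * sqrt(n11 + n01) * sqrt(n10 + n00)
  if (den == 0) return(0)
  (n11 * n00 - n10 * n01) / den
}

#' Phi-coefficient functional connectivity matrix
#'
#' Computes pairwise phi coefficients between ROI rasters and binarizes at
#' the threshold: an (undirected, unweighted) edge exists iff
#' `phi >= threshold` (the boundary value keeps the edge). The diagonal is
#' zero.
#'
#' @param rasters list of rasters (`"event_raster"` or 0/1 vectors) or a 0/1
#'   matrix (frames x ROIs); at least 2 ROIs.
#' @param threshold phi threshold (default 0.2).
#' @return A `"connectivity"`: list with `phi` (symmetric matrix),
#'   `adjacency` (0/1 matrix), `threshold`.
#' @export
build_network <- function(rasters, threshold = 0.2) {
  m <- if (is.matrix(rasters)) rasters
       else do.call(cbind, lapply(rasters, function(r)
         if (inherits(r, "event_raster")) r$active else as.integer(r)))
  k <- ncol(m)
  if (k < 2L) stop_calwave("calwave_invalid", "need at least 2 rasters")
  phi <- diag(0, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    phi[i, j] <- phi[j, i] <- phi_coef(m[, i], m[, j])
  }
  adj <- (phi >= threshold) * 1L
  diag(adj) <- 0L
  dimnames(phi) <- dimnames(adj) <- list(colnames(m), colnames(m))
  structure(list(phi = phi, adjacency = adj, threshold = threshold),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("Connectivity: %d ROIs, %d edge(s) at phi >= %g\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$threshold))
  invisible(x)
}

#' Binary-graph measures of a functional network
#'
#' Computes six standard measures on the unweighted undirected graph:
#' density `2E/(n(n-1))`; global clustering as the mean over nodes of the
#' local clustering coefficient (nodes of degree < 2 contribute 0); degree
#' assortativity (Newman; `NA` when degenerate); Newman modularity of a
#' Louvain partition under a fixed seed; characteristic path length as the
#' mean *finite* shortest-path distance over ordered node pairs (the count
#' of disconnected pairs is reported alongside); and global efficiency as
#' the mean of inverse distances with `1/Inf = 0`. The prose shorthand
#' "efficiency = 1 / characteristic path length" is additionally reported
#' as `efficiency_inverse_cpl` for comparability.
#'
#' @param adjacency 0/1 symmetric matrix, or a `"connectivity"`.
#' @param seed seed fixing the Louvain run (default 1).
#' @return A `"network_measures"` list: `density`, `global_clustering`,
#'   `assortativity`, `modularity`, `characteristic_path_length`,
#'   `global_efficiency`, `efficiency_inverse_cpl`, `disconnected_pairs`,
#'   `n_nodes`, `n_edges`.
#' @export
graph_measures <- function(adjacency, seed = 1) {
  if (inherits(adjacency, "connectivity")) adjacency <- adjacency$adjacency
  n <- nrow(adjacency)
  if (is.null(n) || n < 2L) stop_calwave("calwave_invalid", "need at least 2 nodes")
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop_calwave("calwave_invalid", "adjacency must be symmetric")
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0, mode = "undirected",
                                           diag = FALSE)
  n_edges <- igraph::ecount(g)
  density <- 2 * n_edges / (n * (n - 1))
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[!is.finite(loc)] <- 0
  global_clustering <- mean(loc)
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  if (!is.finite(assort)) assort <- NA_real_
  modularity <- if (n_edges == 0L) NA_real_ else {
    comm <- with_local_seed(seed, igraph::cluster_louvain(g))
    igraph::modularity(comm)
  }
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  cpl <- if (any(finite)) mean(off[finite]) else NA_real_
  eff <- mean(ifelse(finite, 1 / off, 0))
  structure(list(density = density, global_clustering = global_clustering,
                 assortativity = assort, modularity = modularity,
                 characteristic_path_length = cpl, global_efficiency = eff,
                 efficiency_inverse_cpl = if (is.na(cpl)) NA_real_ else 1 / cpl,
                 disconnected_pairs = sum(!finite), n_nodes = n,
                 n_edges = n_edges),
            class = "network_measures")
}

#' @export
print.network_measures <- function(x, ...) {
  cat(sprintf("Network (%d nodes, %d edges): density %.3f, clustering %.3f, assortativity %s,\n",
              x$n_nodes, x$n_edges, x$density, x$global_clustering,
              format(x$assortativity, digits = 3)))
  cat(sprintf("  modularity %s, path length %s (%d disconnected pairs), efficiency %.3f\n",
              format(x$modularity, digits = 3),
              format(x$characteristic_path_length, digits = 3),
              x$disconnected_pairs, x$global_efficiency))
  invisible(x)
}
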