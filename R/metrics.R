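#' All-pairs geodesic distances (BFS, compiled)
#'
#' @param A symmetric 0/1 matrix with zero diagonal.
#' @return integer matrix of shortest-path lengths, `NA` between
#'   components.
#' @export
geodesic_distances <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  bfs_distances_cpp(A)
}

#' Betweenness centrality (Brandes accumulation, compiled)
#'
#' Fractional credit for tied geodesics, unnormalised raw pair counts; on
#' disconnected graphs only reachable pairs contribute.
#'
#' @param A symmetric 0/1 matrix with zero diagonal.
#' @return numeric vector of B_c values.
#' @export
betweenness_centrality <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  brandes_betweenness_cpp(A)
}

#' Per-node clustering coefficients
#'
#' C_i is the fraction of a node's neighbour pairs that are themselves
#' connected: (number of triangles through i) / (k_i choose 2). Nodes of
#' degree < 2 get C_i = 0 by default (`undefined = "zero"`), keeping the
#' network mean defined on sparse graphs; `undefined = "exclude"` drops
#' them from [global_metrics()]'s mean instead.
#'
#' @param A symmetric 0/1 adjacency matrix, zero diagonal.
#' @return numeric vector of C_i.
#' @export
clustering_coefficients <- function(A) {
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2  # triangles through each node
  ci <- ifelse(k >= 2, tri / (k * (k - 1) / 2), 0)
  as.numeric(ci)
}

check_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (nrow(A) < 2) stop("graph must have at least 2 nodes")
  if (any(A != t(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero")
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary")
  A
}

#' Global architecture of one binary network
#'
#' Mean degree `<k> = 2|E|/R`, average shortest path length `L_p` (mean
#' over all unordered node pairs) and mean clustering coefficient `C_p`.
#' Disconnected or empty graphs are an error: the threshold grid is
#' constructed so that every analysed network is connected.
#'
#' @param A symmetric 0/1 adjacency matrix, zero diagonal.
#' @param clustering_undefined `"zero"` (count degree<2 nodes as C_i = 0)
#'   or `"exclude"` (drop them from the mean).
#' @return list with `mean_degree`, `path_length`, `clustering`.
#' @export
global_metrics <- function(A, clustering_undefined = c("zero", "exclude")) {
  clustering_undefined <- match.arg(clustering_undefined)
  A <- check_adjacency(A)
  if (sum(A) == 0) stop("empty graph: no edges")
  if (!is_connected(A)) stop("graph is disconnected; restrict the threshold grid")
  n <- nrow(A)
  D <- geodesic_distances(A)
  lp <- mean(D[upper.tri(D)])
  ci <- clustering_coefficients(A)
  cp <- if (clustering_undefined == "zero") mean(ci)
        else mean(ci[rowSums(A) >= 2])
  list(mean_degree = sum(A) / n, path_length = lp, clustering = cp)
}

#' Eigenvector centrality by Perron-shifted power iteration
#'
#' Iterates `x <- (A + I) x` (the identity shift makes the dominant
#' eigenvalue strictly largest in modulus on connected graphs, so the
#' iteration converges even on bipartite graphs) from a deterministic
#' uniform start, to a max-norm tolerance of 1e-12, then scales so the
#' maximum entry is exactly 1 (ties broken by lowest region index).
#'
#' @param A symmetric 0/1 adjacency matrix of a connected graph.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @keywords internal
eigenvector_centrality <- function(A, tol = 1e-12, max_iter = 1e5) {
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) { x <- y; break }
    x <- y
  }
  x / x[which.max(x)]
}

#' Regional centrality profile of one binary network
#'
#' Degree (k_i, row sums), betweenness (B_c, fractional tie credit,
#' unnormalised) and eigenvector centrality (E_c, principal eigenvector of
#' the adjacency scaled to max 1).
#'
#' @param A symmetric 0/1 adjacency matrix of a connected graph.
#' @return data.frame with columns `region`, `degree`, `betweenness`,
#'   `eigenvector`.
#' @export
centrality <- function(A) {
  A <- check_adjacency(A)
  if (!is_connected(A)) stop("graph is disconnected; centrality undefined here")
  data.frame(
    region = colnames(A) %||% sprintf("n%d", seq_len(nrow(A))),
    degree = as.numeric(rowSums(A)),
    betweenness = betweenness_centrality(A),
    eigenvector = eigenvector_centrality(A),
    stringsAsFactors = FALSE
  )
}

#' Global metrics and centrality across a network's threshold grid
#'
#' @param network a thresholded `group_network`.
#' @return list with `global` (data.frame: threshold, mean_degree,
#'   path_length, clustering, plus an across-threshold mean row) and
#'   `centrality` (long data.frame: region x threshold x the three
#'   metrics).
#' @export
network_metrics <- function(network) {
  stopifnot(inherits(network, "group_network"))
  if (is.null(network$A)) stop("network has no adjacency stack; threshold it first")
  glb <- do.call(rbind, Map(function(t, A) {
    g <- global_metrics(A)
    data.frame(threshold = t, mean_degree = g$mean_degree,
               path_length = g$path_length, clustering = g$clustering)
  }, network$thresholds, network$A))
  glb <- rbind(glb, data.frame(threshold = NA,
                               mean_degree = mean(glb$mean_degree),
                               path_length = mean(glb$path_length),
                               clustering = mean(glb$clustering)))
  cen <- do.call(rbind, Map(function(t, A) {
    cbind(threshold = t, centrality(A))
  }, network$thresholds, network$A))
  rownames(glb) <- rownames(cen) <- NULL
  list(global = glb, centrality = cen)
}
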