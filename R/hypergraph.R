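#' Construct a hypergraph from an incidence matrix
#'
#' A hypergraph over N vertices is stored as a binary N x Ne incidence
#' matrix H (H\[v, e\] = 1 iff vertex v belongs to hyperedge e) together
#' with non-negative hyperedge weights w(e). The vertex degree
#' d(v) = sum_e w(e) H(v, e) and the hyperedge degree (cardinality)
#' delta(e) = sum_v H(v, e) are derived and cached.
#'
#' @param incidence binary N x Ne matrix.
#' @param edge_weights non-negative numeric vector of length Ne (default:
#'   all ones).
#' @return an object of class `hypergraph` with fields `incidence`,
#'   `edge_weights`, `vertex_degrees`, `edge_degrees`.
#' @seealso [knn_hypergraph()], [hypergraph_laplacian()]
#' @export
hypergraph <- function(incidence, edge_weights = NULL) {
  incidence <- as.matrix(incidence)
  if (!all(incidence %in% c(0, 1))) {
    abort("incidence entries must be 0 or 1")
  }
  ne <- ncol(incidence)
  edge_weights <- edge_weights %||% rep(1, ne)
  if (length(edge_weights) != ne || any(edge_weights < 0) ||
      !all(is.finite(edge_weights))) {
    abort("`edge_weights` must be a non-negative finite vector, one per hyperedge")
  }
  edge_degrees <- colSums(incidence)
  if (any(edge_degrees == 0)) abort("empty hyperedge")
  vertex_degrees <- as.vector(incidence %*% edge_weights)
  if (any(vertex_degrees <= 0)) abort("isolated vertex")
  structure(
    list(incidence = incidence, edge_weights = as.numeric(edge_weights),
         vertex_degrees = vertex_degrees,
         edge_degrees = as.integer(edge_degrees)),
    class = "hypergraph"
  )
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> %d vertices, %d hyperedges (cardinality %d..%d)\n",
              nrow(x$incidence), ncol(x$incidence),
              min(x$edge_degrees), max(x$edge_degrees)))
  invisible(x)
}

#' Build a KNN hypergraph over subjects
#'
#' Each of the N subjects (rows of `features`) becomes a vertex, and one
#' hyperedge is centred on every vertex: the edge contains the centre plus
#' its `k` nearest neighbours by Euclidean distance, so there are exactly N
#' hyperedges of cardinality k + 1, all with weight 1. Distance ties are
#' broken towards the lower subject index, making the construction
#' deterministic; duplicated subjects (zero distance) are allowed.
#'
#' Euclidean KNN is scale-sensitive, so each feature is z-scored (on the
#' supplied data, i.e. the training statistics when called inside a
#' cross-validation fold) before distances are computed; set
#' `scale = FALSE` to use raw distances.
#'
#' @param features numeric N x d matrix of subjects by features.
#' @param k number of nearest neighbours per hyperedge centre
#'   (`1 <= k <= N - 1`).
#' @param scale z-score features before computing distances (default TRUE).
#' @return a [hypergraph()].
#' @examples
#' hg <- knn_hypergraph(matrix(rnorm(30), 10, 3), k = 2)
#' hg$edge_degrees  # all 3
#' @export
knn_hypergraph <- function(features, k, scale = TRUE) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) abort("non-finite feature values")
  n <- nrow(features)
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be a positive integer")
  if (n <= k) abort("k exceeds available neighbors")
  if (isTRUE(scale)) {
    scl <- apply(features, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    features <- sweep(sweep(features, 2, colMeans(features), "-"), 2, scl, "/")
  }
  dmat <- as.matrix(dist(features))
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    # order() with the index as the second key breaks ties deterministically
    nn <- cand[order(dmat[i, cand], cand)][seq_len(k)]
    H[c(i, nn), i] <- 1
  }
  hypergraph(H)
}

#' Normalized hypergraph Laplacian
#'
#' Computes `Lh = I - Theta` with
#' `Theta = Dv^(-1/2) H W De^(-1) H' Dv^(-1/2)`, where Dv, De and W are the
#' diagonal vertex-degree, edge-degree and edge-weight matrices. Lh is
#' symmetric positive semidefinite and annihilates the vector with entries
#' `sqrt(d(v))`. When every hyperedge has exactly two vertices (a simple
#' graph), Lh equals one half of the standard normalized graph Laplacian.
#'
#' @param hg a [hypergraph()].
#' @return an object of class `hypergraph_laplacian` wrapping the N x N
#'   `matrix`.
#' @export
hypergraph_laplacian <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  if (any(hg$vertex_degrees <= 0)) abort("isolated vertex")
  n <- nrow(hg$incidence)
  Hn <- hg$incidence / sqrt(hg$vertex_degrees)      # rows scaled by Dv^(-1/2)
  theta <- Hn %*% (t(Hn) * (hg$edge_weights / hg$edge_degrees))
  lap <- diag(n) - theta
  lap <- (lap + t(lap)) / 2
  structure(list(matrix = lap, vertex_degrees = hg$vertex_degrees),
            class = "hypergraph_laplacian")
}

#' @export
print.hypergraph_laplacian <- function(x, ...) {
  cat(sprintf("<hypergraph_laplacian> %d x %d\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Laplacian quadratic form
#'
#' Evaluates `s' Lh s` for a score vector s (for the regularizer this is
#' s = X w, the fitted scores of the training subjects). The value is
#' non-negative up to numerical round-off and measures how much co-members
#' of hyperedges disagree.
#'
#' @param lap a [hypergraph_laplacian()].
#' @param scores numeric vector of length N.
#' @return a scalar.
#' @export
laplacian_quadform <- function(lap, scores) {
  stopifnot(inherits(lap, "hypergraph_laplacian"))
  scores <- as.numeric(scores)
  if (length(scores) != nrow(lap$matrix)) {
    abort("dimension mismatch between Laplacian and scores")
  }
  drop(crossprod(scores, lap$matrix %*% scores))
}

#' Write a hypergraph incidence matrix as a dense 0/1 CSV
#'
#' Debug helper: vertices are rows, hyperedges columns.
#'
#' @param hg a [hypergraph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(hg, path) {
  stopifnot(inherits(hg, "hypergraph"))
  write.csv(hg$incidence, path, row.names = FALSE)
  invisible(path)
}
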