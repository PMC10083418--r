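#' Generate an Erdos-Renyi network layer
#'
#' Draws a simple undirected \eqn{G(n, p)} graph (each unordered pair of
#' nodes connected independently with probability \eqn{p}) and computes
#' its Laplacian in the sign convention used throughout this package,
#' \eqn{L = A - \mathrm{diag}(k)}, which is negative semidefinite: all
#' eigenvalues satisfy \eqn{\Lambda \le 0} with \eqn{\Lambda_1 = 0}.
#' The graph may be disconnected -- at the small connection
#' probabilities of interest (down to \eqn{p = 0.001}) it usually is --
#' and no connectivity is enforced.
#'
#' @param n number of nodes (>= 2).
#' @param p connection probability in \[0, 1\].
#' @param seed integer seed; the draw is deterministic given the seed
#'   and does not disturb the caller's RNG state.
#' @return An object of class \code{"layer_graph"}: list with
#'   \code{n}, \code{p}, \code{seed}, \code{adjacency} (dense 0/1
#'   matrix), \code{degrees}, \code{laplacian} and \code{eigenvalues}
#'   (sorted descending, so the leading entry is 0).
#' @examples
#' g <- generate_layer(20, 0.1, seed = 42)
#' max(g$eigenvalues)   # 0 up to round-off
#' @export
generate_layer <- function(n, p, seed = 1L) {
  if (!is.numeric(n) || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("'p' must be a probability in [0, 1]", call. = FALSE)
  g <- with_seed(seed, igraph::sample_gnp(n, p, directed = FALSE))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  storage.mode(A) <- "double"
  new_layer_graph(A, p = p, seed = as.integer(seed))
}

#' Load a network layer from a plain-text file
#'
#' Two formats are supported. \code{"edge-list"}: whitespace-separated
#' 0-based node-index pairs, one edge per line, \code{#} comments
#' allowed; isolated trailing nodes can be included by giving \code{n}.
#' \code{"adjacency-csv"}: a square numeric 0/1 matrix, no header. The
#' adjacency must be symmetric with a zero diagonal; violations raise
#' an error naming the offending entry.
#'
#' @param path file path.
#' @param format \code{"edge-list"} or \code{"adjacency-csv"}.
#' @param n node count for edge lists (default: 1 + largest index seen).
#' @return A \code{"layer_graph"} (see \code{\link{generate_layer}});
#'   its \code{seed} and \code{p} are \code{NA}.
#' @export
load_layer <- function(path, format = c("edge-list", "adjacency-csv"), n = NULL) {
  format <- match.arg(format)
  if (format == "edge-list") {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines)) {
      idx <- lapply(strsplit(lines, "[[:space:]]+"), as.integer)
      bad <- which(vapply(idx, length, integer(1)) != 2L)
      if (length(bad))
        stop("edge-list line ", bad[1], " does not have two node indices",
             call. = FALSE)
      e <- do.call(rbind, idx)
      if (anyNA(e) || any(e < 0))
        stop("edge list contains a non-integer or negative node index",
             call. = FALSE)
      loops <- which(e[, 1] == e[, 2])
      if (length(loops))
        stop("self-loop on node ", e[loops[1], 1], " (edge-list line ",
             loops[1], ")", call. = FALSE)
    } else e <- matrix(integer(0), 0, 2)
    if (is.null(n)) n <- if (nrow(e)) max(e) + 1L else 0L
    if (n < 2) stop("layer needs at least 2 nodes", call. = FALSE)
    A <- matrix(0, n, n)
    for (i in seq_len(nrow(e))) {
      A[e[i, 1] + 1L, e[i, 2] + 1L] <- 1
      A[e[i, 2] + 1L, e[i, 1] + 1L] <- 1
    }
  } else {
    A <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(A) <- NULL
    if (nrow(A) != ncol(A))
      stop("adjacency matrix is not square: ", nrow(A), "x", ncol(A),
           call. = FALSE)
    bad <- which(A != t(A), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("adjacency is asymmetric at entry [%d, %d]",
                   bad[1, 1], bad[1, 2]), call. = FALSE)
    dg <- which(diag(A) != 0)
    if (length(dg))
      stop("adjacency has nonzero diagonal at node ", dg[1], call. = FALSE)
    if (!all(A %in% c(0, 1)))
      stop("adjacency entries must be 0 or 1", call. = FALSE)
  }
  new_layer_graph(A, p = NA_real_, seed = NA_integer_)
}

new_layer_graph <- function(A, p, seed) {
  k <- rowSums(A)
  L <- A - diag(k, nrow(A))
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  structure(list(n = nrow(A), p = p, seed = seed, adjacency = A,
                 degrees = k, laplacian = L, eigenvalues = ev),
            class = "layer_graph")
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("network layer: %d nodes, %d edges", x$n,
              sum(x$adjacency) / 2))
  if (!is.na(x$p)) cat(sprintf(" (G(n, p), p = %g, seed = %d)", x$p, x$seed))
  cat(sprintf("\n  Laplacian eigenvalues in [%.4g, %.4g]\n",
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Eigenvalue grid of a Cartesian-product network
#'
#' The Cartesian product \eqn{R \Box E} of two layers has Laplacian
#' \eqn{L^{R \Box E} = L^R \otimes I_{n_e} + I_{n_r} \otimes L^E} (a
#' Kronecker sum), whose eigenvalues are exactly all pairwise sums
#' \eqn{\Lambda_\alpha^R + \Lambda_\beta^E} of the layer eigenvalues.
#' This function enumerates that grid; the assembled operator itself is
#' available via \code{\link{product_laplacian}}.
#'
#' @param R,E \code{"layer_graph"} objects.
#' @return An object of class \code{"product_spectrum"}: list with
#'   \code{pairs} (data frame \code{alpha}, \code{beta},
#'   \code{lambda_R}, \code{lambda_E}, \code{lambda_sum}) and
#'   \code{layers}.
#' @examples
#' R <- generate_layer(4, 0.5, seed = 1)
#' E <- generate_layer(3, 0.5, seed = 2)
#' ps <- product_spectrum(R, E)
#' nrow(ps$pairs)  # 12
#' @export
product_spectrum <- function(R, E) {
  stopifnot(inherits(R, "layer_graph"), inherits(E, "layer_graph"))
  grid <- expand.grid(beta = seq_len(E$n), alpha = seq_len(R$n))
  pairs <- data.frame(
    alpha = grid$alpha, beta = grid$beta,
    lambda_R = R$eigenvalues[grid$alpha],
    lambda_E = E$eigenvalues[grid$beta])
  pairs$lambda_sum <- pairs$lambda_R + pairs$lambda_E
  structure(list(pairs = pairs, layers = list(R = R, E = E)),
            class = "product_spectrum")
}

#' @export
print.product_spectrum <- function(x, ...) {
  cat(sprintf("Cartesian-product spectrum: %d x %d = %d modes\n",
              x$layers$R$n, x$layers$E$n, nrow(x$pairs)))
  cat(sprintf("  eigenvalue sums in [%.4g, %.4g]\n",
              min(x$pairs$lambda_sum), max(x$pairs$lambda_sum)))
  invisible(x)
}

#' Assembled Kronecker-sum Laplacian of a product network
#'
#' Returns \eqn{c_R\, L^R \otimes I_{n_e} + c_E\, I_{n_r} \otimes L^E}
#' as a sparse matrix, with per-layer diffusion weights \code{coef_R},
#' \code{coef_E}. Node ordering is row-major: product node
#' \eqn{(r, e)} maps to row \eqn{(r-1) n_e + e}.
#'
#' @param R,E \code{"layer_graph"} objects.
#' @param coef_R,coef_E diffusion coefficients multiplying the two
#'   layer Laplacians (default 1, the unweighted Kronecker sum).
#' @return A sparse \code{\link[Matrix]{Matrix}} of dimension
#'   \eqn{n_r n_e \times n_r n_e}.
#' @export
product_laplacian <- function(R, E, coef_R = 1, coef_E = 1) {
  LR <- Matrix::Matrix(R$laplacian, sparse = TRUE)
  LE <- Matrix::Matrix(E$laplacian, sparse = TRUE)
  coef_R * Matrix::kronecker(LR, Matrix::Diagonal(E$n)) +
    coef_E * Matrix::kronecker(Matrix::Diagonal(R$n), LE)
}

#' Export a product spectrum as CSV
#'
#' Writes the eigenvalue grid with columns \code{alpha}, \code{beta},
#' \code{lambda_R}, \code{lambda_E}, \code{lambda_sum} at 12
#' significant digits.
#'
#' @param spec a \code{"product_spectrum"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "product_spectrum"))
  df <- spec$pairs
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring
# the caller's stream afterwards; keeps graph draws, perturbations and
# noise on documented independent substreams.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# documented substream allocation: one base seed per run, fixed offsets
# per purpose so e.g. changing t_end never alters the generated graphs
substream_seed <- function(seed, stream = c("graph_R", "graph_E",
                                            "perturb", "noise", "extra")) {
  stream <- match.arg(stream)
  off <- c(graph_R = 0L, graph_E = 1L, perturb = 2L, noise = 3L, extra = 4L)
  (as.integer(seed) %% 214748357L) * 10L + off[[stream]]
}
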