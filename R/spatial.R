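#' Spatial connection network among sampled individuals
#'
#' Symmetric k-nearest-neighbour graph on individual coordinates (cell
#' centres in km), binary weights, row-standardised. Ties in distance are
#' broken by index order; the default k = 8 mirrors the Queen's-case
#' neighbourhood of the dispersal model.
#'
#' @param coords Two-column matrix or data frame of coordinates (x, y).
#' @param k_neighbors Number of nearest neighbours before symmetrisation.
#' @return A `tort_network`: row-standardised weight matrix `W`, symmetric
#'   binary adjacency `A`, and the coordinates.
#' @export
build_network <- function(coords, k_neighbors = 8L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < k_neighbors + 1L) abort("need at least k + 1 points")
  D <- as.matrix(stats::dist(coords))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i]
    A[i, ord[seq_len(k_neighbors)]] <- 1
  }
  A <- pmax(A, t(A))            # symmetrise (union of neighbourhoods)
  rs <- rowSums(A)
  if (any(rs == 0)) abort("isolated node in connection network")
  W <- A / rs
  structure(list(W = W, A = A, coords = coords, k = k_neighbors),
            class = "tort_network")
}

#' Moran's I spatial autocorrelation
#'
#' Standard Moran's I with the network's row-standardised weights:
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values (S0 = n for row-standardised weights).
#'
#' @param values Numeric vector, one value per network node.
#' @param network A `tort_network`.
#' @return Moran's I (single numeric).
#' @export
morans_I <- function(values, network) {
  W <- network$W
  n <- nrow(W)
  if (length(values) != n) abort("values length must equal node count")
  z <- values - mean(values)
  if (all(z == 0)) abort("zero-variance input")
  s0 <- sum(W)
  (n / s0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

# individual x allele frequency matrix (0 / 0.5 / 1), optionally centred
allele_freq_matrix <- function(sample, center = TRUE, drop_constant = TRUE) {
  G <- sample$G
  cols <- list(); nm <- character(0)
  for (l in seq_len(sample$n_loci)) {
    a1 <- G[, 2L * l - 1L]; a2 <- G[, 2L * l]
    for (u in sort(unique(c(a1, a2)))) {
      cols[[length(cols) + 1L]] <- ((a1 == u) + (a2 == u)) / 2
      nm <- c(nm, paste0("L", l, ".", u))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  if (drop_constant) {
    keep <- apply(X, 2, function(x) var(x) > 0)
    X <- X[, keep, drop = FALSE]
  }
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  X
}

#' Spatial principal components analysis
#'
#' Eigen-decomposition of `(1/n) X' L X`, where `X` is the column-centred
#' individual allele-frequency matrix and `L = (W + W') / 2` the symmetrised
#' row-standardised connection weights. Each axis maximises the product of
#' the score variance and its Moran's I; positive eigenvalues indicate
#' global (cline/patch) structure, negative ones local (repulsion)
#' structure, and for every axis `lambda = var(scores) * I(scores)` exactly.
#'
#' @param sample A `tort_sample`.
#' @param network A `tort_network` built on the same individuals.
#' @param tol Eigenvalues with absolute value below `tol * max(|lambda|)`
#'   are dropped as numerically null.
#' @return A `tort_spca`: `eigenvalues`, `scores` (individuals x axes),
#'   `loadings`, and per-axis `var` and `moran`.
#' @export
spca <- function(sample, network, tol = 1e-9) {
  X <- allele_freq_matrix(sample)
  n <- nrow(X)
  if (nrow(network$W) != n) abort("network and sample sizes differ")
  L <- (network$W + t(network$W)) / 2
  M <- crossprod(X, L %*% X) / n
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  keep <- abs(eig$values) > tol * max(abs(eig$values))
  values <- eig$values[keep]
  vectors <- eig$vectors[, keep, drop = FALSE]
  scores <- X %*% vectors
  axis_var <- colSums(scores^2) / n
  axis_moran <- apply(scores, 2, function(s) morans_I(s, network))
  structure(list(eigenvalues = values, scores = scores, loadings = vectors,
                 var = axis_var, moran = axis_moran, n = n),
            class = "tort_spca")
}

#' @export
print.tort_spca <- function(x, ...) {
  cat("<tort_spca> ", length(x$eigenvalues), " axes; leading global eigenvalue ",
      signif(max(x$eigenvalues), 3), ", leading local ",
      signif(min(x$eigenvalues), 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.tort_spca <- function(x, ...) {
  tibble(axis = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         var = x$var, moran = x$moran)
}

#' @export
autoplot.tort_spca <- function(object, axes = c(1, 2), ...) {
  df <- tibble(s1 = object$scores[, axes[1]], s2 = object$scores[, axes[2]])
  ggplot2::ggplot(df, ggplot2::aes(.data$s1, .data$s2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = paste("axis", axes[1]), y = paste("axis", axes[2]))
}

#' Global and local Monte-Carlo tests for spatial genetic structure
#'
#' Permutes individual locations (rows of the allele-frequency matrix
#' relative to the network) and recomputes the sum of positive (global) and
#' negative (local) eigenvalue mass of the spatial PCA operator;
#' `p = (1 + #(perm >= obs)) / (1 + n_perm)`.
#'
#' @param sample A `tort_sample`.
#' @param network A `tort_network`.
#' @param n_perm Number of permutations (999 to match the analysis design).
#' @param seed Optional integer seed.
#' @return Tibble with `test` ("global"/"local"), `statistic`, `p`.
#' @export
global_local_test <- function(sample, network, n_perm = 999L, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  X <- allele_freq_matrix(sample)
  n <- nrow(X)
  L <- (network$W + t(network$W)) / 2
  mass <- function(Xp) {
    M <- crossprod(Xp, L %*% Xp) / n
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    c(global = sum(ev[ev > 0]), local = -sum(ev[ev < 0]))
  }
  obs <- mass(X)
  perm <- matrix(0, n_perm, 2)
  for (b in seq_len(n_perm)) {
    perm[b, ] <- mass(X[sample.int(n), , drop = FALSE])
  }
  tibble(test = c("global", "local"),
         statistic = as.numeric(obs),
         p = c((1 + sum(perm[, 1] >= obs[1])) / (1 + n_perm),
               (1 + sum(perm[, 2] >= obs[2])) / (1 + n_perm)))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with a permutation
#' p-value obtained by jointly shuffling the row/column order of the second
#' matrix; `p = (1 + #(perm >= obs)) / (1 + n_perm)` (one-sided, positive
#' association).
#'
#' @param dist_gen,dist_geo Square symmetric matrices (or `dist` objects) of
#'   equal size.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return Tibble with `r` and `p`.
#' @export
mantel <- function(dist_gen, dist_geo, n_perm = 999L, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  A <- as.matrix(dist_gen); B <- as.matrix(dist_geo)
  if (!all(dim(A) == dim(B))) abort("distance matrices differ in size")
  n <- nrow(A)
  lt <- lower.tri(A)
  r_obs <- cor(A[lt], B[lt])
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (cor(A[lt], B[p, p][lt]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  tibble(r = r_obs, p = (1 + hits) / (1 + n_perm))
}

#' Individual coordinates for spatial analyses
#'
#' Cell-centre coordinates in km for each individual in a sample;
#' individuals sharing a cell are jittered uniformly within the cell so the
#' connection network has no coincident points.
#'
#' @param sample A `tort_sample`.
#' @param jitter Jitter co-located individuals within their cell.
#' @param seed Optional integer seed for the jitter.
#' @return A two-column matrix (x = column, y = row, km).
#' @export
sample_coords <- function(sample, jitter = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- sample$n_cols
  x <- cell_col(sample$cell, nc) - 0.5
  y <- cell_row(sample$cell, nc) - 0.5
  if (jitter) {
    x <- x + runif(length(x), -0.45, 0.45)
    y <- y + runif(length(y), -0.45, 0.45)
  }
  cbind(x = x, y = y)
}

#' Euclidean genetic distance between individuals
#'
#' Distance on the individual allele-frequency vectors (0 / 0.5 / 1 per
#' allele column); symmetric, non-negative, and zero only for identical
#' genotypes.
#'
#' @param sample A `tort_sample`.
#' @return A `dist` object.
#' @export
genetic_dist <- function(sample) {
  stats::dist(allele_freq_matrix(sample, center = FALSE, drop_constant = FALSE))
}
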