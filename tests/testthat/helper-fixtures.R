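# shared fixtures: everything is generated in code, nothing is stored on disk

# a small calibrated frequency panel + founder pool, built once per test run
fixture_freqs <- function(seed = 101) {
  generate_frequencies(20, target_he = 0.81, target_ar = 13, seed = seed)
}

fixture_founders <- local({
  cache <- NULL
  function(n = 4000, seed = 102) {
    if (is.null(cache) || cache$n < n) {
      cache <<- sample_founders(fixture_freqs(), max(n, 4000), seed = seed)
    }
    cache
  }
})

# build a tort_sample directly from a genotype matrix (bypassing the
# simulator) -- used to feed hand-constructed cases into the statistics
make_sample <- function(G, group = NULL, cell = NULL, n_cols = 25L) {
  n <- nrow(G)
  group <- group %||% rep("A", n)
  structure(list(G = G, group = factor(group, levels = unique(group)),
                 cell = cell %||% rep(1L, n), n = n,
                 n_loci = ncol(G) %/% 2L, n_cols = n_cols),
            class = "tort_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw a diploid sample of size n from explicit allele frequencies
# (list of per-locus frequency vectors), under HWE
hwe_sample <- function(freq_list, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(0L, n, 2L * length(freq_list))
  for (l in seq_along(freq_list)) {
    p <- freq_list[[l]]
    G[, 2L * l - 1L] <- sample.int(length(p), n, TRUE, prob = p)
    G[, 2L * l] <- sample.int(length(p), n, TRUE, prob = p)
  }
  G
}

# 8-connected component count over habitable cells (independent flood fill,
# used as the oracle for surface connectivity)
n_components <- function(surface) {
  open <- surface$resistance < 1
  nr <- nrow(open); nc <- ncol(open)
  seen <- matrix(FALSE, nr, nc)
  comps <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!open[r0, c0] || seen[r0, c0]) next
    comps <- comps + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            open[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  comps
}

# independent Weir & Cockerham (1984) theta, computed locus by locus from
# genotype tables with scalar arithmetic (oracle for pairwise_fst)
wc_theta_oracle <- function(G, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  n_loci <- ncol(G) %/% 2L
  num <- den <- 0
  r <- 2
  n_i <- as.numeric(table(group))
  nbar <- mean(n_i)
  nc_ <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  for (l in seq_len(n_loci)) {
    a1 <- G[, 2 * l - 1]; a2 <- G[, 2 * l]
    for (u in unique(c(a1, a2))) {
      if (length(unique(c(a1, a2))) < 2) next
      p_i <- h_i <- numeric(2)
      for (g in 1:2) {
        rows <- which(group == levels(group)[g])
        p_i[g] <- (sum(a1[rows] == u) + sum(a2[rows] == u)) / (2 * n_i[g])
        h_i[g] <- sum((a1[rows] == u) + (a2[rows] == u) == 1) / n_i[g]
      }
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc_) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}
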