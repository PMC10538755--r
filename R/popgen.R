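#' Subsample a genotype snapshot for analysis
#'
#' Draws a uniform sample without replacement from a population state (or
#' returns the whole population with a warning when it is smaller than `n`),
#' and labels each sampled individual with its side of the (real or virtual)
#' central barrier column: `"A"` (west), `"B"` (east). Individuals sitting
#' exactly on the barrier column (culvert occupants) are assigned a side at
#' random.
#'
#' @param state A `tort_state` (or `tort_sample`, which is passed through
#'   after resampling).
#' @param n Sample size (750 by default, past the pairwise-FST convergence
#'   point on these landscapes).
#' @param seed Optional integer seed.
#' @param n_cols Grid width used to locate the central column.
#' @return A `tort_sample`: genotype matrix, `group` factor, cell locations.
#' @export
subsample <- function(state, n = 750, seed = NULL, n_cols = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_cols <- n_cols %||% attr(state, "n_cols") %||% 25L
  total <- state$n
  if (total < n) {
    warn(sprintf("snapshot holds %d < %d individuals; taking all", total, n))
    take <- seq_len(total)
  } else {
    take <- sample.int(total, n)
  }
  cells <- state$cell[take]
  bc <- barrier_column(n_cols)
  cols <- cell_col(cells, n_cols)
  side <- ifelse(cols < bc, "A", ifelse(cols > bc, "B", NA))
  on_bar <- is.na(side)
  if (any(on_bar)) side[on_bar] <- sample(c("A", "B"), sum(on_bar), replace = TRUE)
  structure(list(G = state$G[take, , drop = FALSE],
                 group = factor(side, levels = c("A", "B")),
                 cell = cells, n = length(take),
                 n_loci = ncol(state$G) %/% 2L, n_cols = n_cols),
            class = "tort_sample")
}

#' @export
print.tort_sample <- function(x, ...) {
  cat("<tort_sample> ", x$n, " individuals, ", x$n_loci, " loci, groups: ",
      paste(table(x$group), collapse = " / "), "\n", sep = "")
  invisible(x)
}

# allele counts per locus as a list of named count vectors
locus_alleles <- function(G, n_loci) {
  lapply(seq_len(n_loci), function(l) {
    a <- c(G[, 2L * l - 1L], G[, 2L * l])
    tabulate(a, max(a))
  })
}

#' Per-locus genetic diversity
#'
#' Observed heterozygosity (fraction of heterozygous individuals), unbiased
#' expected heterozygosity (Nei's gene diversity with the small-sample
#' correction `2n / (2n - 1)`), and allelic richness (raw count of distinct
#' alleles) at each locus.
#'
#' @param sample A `tort_sample` (groups are pooled).
#' @return Tibble of class `tort_diversity` with columns `locus`, `ho`,
#'   `he`, `ar`.
#' @export
diversity <- function(sample) {
  stopifnot(sample$n >= 1)
  G <- sample$G
  n <- sample$n
  out <- purrr::map_dfr(seq_len(sample$n_loci), function(l) {
    a1 <- G[, 2L * l - 1L]; a2 <- G[, 2L * l]
    ho <- mean(a1 != a2)
    cnt <- tabulate(c(a1, a2))
    p <- cnt[cnt > 0] / (2 * n)
    he_raw <- 1 - sum(p^2)
    he <- if (n > 1) (2 * n / (2 * n - 1)) * he_raw else he_raw
    tibble(locus = l, ho = ho, he = he, ar = sum(cnt > 0))
  })
  class(out) <- c("tort_diversity", class(out))
  out
}

#' @export
glance.tort_diversity <- function(x, ...) {
  tibble(ho = mean(x$ho), ho_sd = sd(x$ho),
         he = mean(x$he), he_sd = sd(x$he),
         ar = mean(x$ar), ar_sd = sd(x$ar))
}

#' Pairwise Weir-Cockerham FST between the two barrier sides
#'
#' Multilocus theta of Weir & Cockerham (1984): per allele and locus, the
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components are computed from sample sizes,
#' allele frequencies and heterozygote frequencies in the two groups; theta
#' is the ratio of summed `a` to summed `a + b + c` over all alleles and
#' loci.
#'
#' @param sample A `tort_sample` with both groups represented by at least two
#'   individuals.
#' @return A single numeric value (can be slightly negative for panmictic
#'   data).
#' @export
pairwise_fst <- function(sample) {
  g <- sample$group
  if (nlevels(g) != 2L || any(table(g) < 2L)) {
    abort("pairwise FST requires two groups with >= 2 individuals each")
  }
  comp <- wc_components(sample)
  den <- sum(comp$a + comp$b + comp$c)
  if (den == 0) return(0)  # no polymorphic locus: no differentiation
  sum(comp$a) / den
}

# Weir & Cockerham (1984) variance components for every allele x locus
wc_components <- function(sample) {
  G <- sample$G
  idx <- split(seq_len(sample$n), sample$group)
  r <- 2L
  n_i <- lengths(idx)
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  a_all <- b_all <- c_all <- numeric(0)
  for (l in seq_len(sample$n_loci)) {
    a1 <- G[, 2L * l - 1L]; a2 <- G[, 2L * l]
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2L) next
    for (u in alleles) {
      p_i <- vapply(idx, function(ii) {
        (sum(a1[ii] == u) + sum(a2[ii] == u)) / (2 * length(ii))
      }, numeric(1))
      h_i <- vapply(idx, function(ii) {
        mean((a1[ii] == u) != (a2[ii] == u))
      }, numeric(1))
      p_bar <- sum(n_i * p_i) / (r * n_bar)
      s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
      h_bar <- sum(n_i * h_i) / (r * n_bar)
      a <- (n_bar / n_c) *
        (s2 - (1 / (n_bar - 1)) *
           (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4))
      b <- (n_bar / (n_bar - 1)) *
        (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
           h_bar * (2 * n_bar - 1) / (4 * n_bar))
      cc <- h_bar / 2
      a_all <- c(a_all, a); b_all <- c(b_all, b); c_all <- c(c_all, cc)
    }
  }
  list(a = a_all, b = b_all, c = c_all)
}

#' Hardy-Weinberg exact test per locus
#'
#' Monte-Carlo exact test: the observed genotype table's conditional
#' probability (given allele counts) is compared against tables generated by
#' randomly re-pairing the alleles of the locus; the p-value is the
#' proportion of permuted tables at most as probable as the observed one
#' (with the +1 correction). A Bonferroni verdict at `0.05 / n_loci` is
#' attached.
#'
#' @param sample A `tort_sample` (groups pooled), at least 5 individuals.
#' @param n_perm Number of Monte-Carlo shuffles (>= 1e4 by default).
#' @param seed Optional integer seed.
#' @return Tibble with `locus`, `p`, and attribute `bonferroni` (the
#'   threshold); monomorphic loci get `p = 1`.
#' @export
hwe_test <- function(sample, n_perm = 10000L, seed = NULL) {
  stopifnot(sample$n >= 5)
  if (!is.null(seed)) set.seed(seed)
  G <- sample$G
  n <- sample$n
  res <- purrr::map_dfr(seq_len(sample$n_loci), function(l) {
    a1 <- G[, 2L * l - 1L]; a2 <- G[, 2L * l]
    al <- c(a1, a2)
    k <- max(al)
    if (length(unique(al)) < 2L) return(tibble(locus = l, p = 1))
    stat_obs <- hwe_stat(a1, a2, k)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(al)
      if (hwe_stat(perm[seq_len(n)], perm[n + seq_len(n)], k) <=
          stat_obs + 1e-12) hits <- hits + 1L
    }
    tibble(locus = l, p = (1 + hits) / (1 + n_perm))
  })
  attr(res, "bonferroni") <- 0.05 / sample$n_loci
  res
}

# log conditional probability of a genotype table given allele counts, up to
# a constant: h * log(2) - sum(lgamma(n_gg + 1))
hwe_stat <- function(a1, a2, k) {
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  code <- (lo - 1L) * k + hi
  cnt <- tabulate(code, k * k)
  cnt <- cnt[cnt > 0L]
  sum(a1 != a2) * log(2) - sum(lgamma(cnt + 1))
}

#' Paired comparison of per-locus statistics
#'
#' Two-sided paired t-test across loci (df = number of loci - 1), used to
#' compare a per-locus diversity statistic between two conditions (e.g. the
#' same loci at two generations or in two scenarios).
#'
#' @param stats_a,stats_b Numeric vectors of equal length (one value per
#'   locus).
#' @return Tibble with `t`, `p`, `df`, `degenerate`.
#' @export
compare_across_loci <- function(stats_a, stats_b) {
  if (length(stats_a) != length(stats_b)) {
    abort("per-locus vectors differ in length")
  }
  d <- stats_a - stats_b
  n <- length(d)
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(t = 0, p = 1, df = n - 1L, degenerate = FALSE))
    }
    warn("zero variance of paired differences with nonzero mean; t undefined")
    return(tibble(t = NA_real_, p = NA_real_, df = n - 1L, degenerate = TRUE))
  }
  t <- mean(d) / (sd(d) / sqrt(n))
  tibble(t = t, p = 2 * pt(-abs(t), n - 1L), df = n - 1L, degenerate = FALSE)
}
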