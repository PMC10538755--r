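#' Effective population size from linkage disequilibrium
#'
#' Single-sample Ne estimate from Burrows' composite disequilibrium among
#' unlinked loci, under the random-mating model. Alleles with frequency below
#' `pcrit` are screened out; for each remaining cross-locus allele pair the
#' squared composite correlation `r^2` is computed, averaged, and corrected
#' for the sample-size expectation under linkage equilibrium
#' (`E[r^2 | S] = 1/S + 3.19/S^2` for S >= 30). The corrected `r^2'` maps to
#' Ne via `Ne = (1/3 + sqrt(1/9 - 2.76 r^2')) / (2 r^2')`; non-positive
#' `r^2'` yields an infinite estimate. Parametric 95% confidence limits come
#' from a chi-square on the number of locus-pair comparisons (allele pairs
#' within a locus pair share the same individuals and are far from
#' independent; using their count would understate the uncertainty).
#'
#' Biallelic loci contribute one allele; loci with three or more retained
#' alleles contribute all of them. Loci with fewer than two retained alleles
#' are dropped. Missing genotypes are not supported and are rejected.
#'
#' @param sample A `tort_sample` (groups pooled).
#' @param pcrit Lowest allele frequency retained (0.05).
#' @return A `tort_ne` object: `ne`, `ci_lo`, `ci_hi`, `r2`, `r2_exp`,
#'   `r2_prime`, `S`, `n_comparisons`.
#' @export
ld_ne <- function(sample, pcrit = 0.05) {
  G <- sample$G
  if (any(is.na(G))) abort("missing genotypes are not supported")
  S <- sample$n
  n_loci <- sample$n_loci
  # per-locus allele-count columns (0/1/2 copies per individual)
  cols <- list(); locus_of <- integer(0)
  for (l in seq_len(n_loci)) {
    a1 <- G[, 2L * l - 1L]; a2 <- G[, 2L * l]
    alleles <- sort(unique(c(a1, a2)))
    freq <- vapply(alleles, function(u) (sum(a1 == u) + sum(a2 == u)), numeric(1)) / (2 * S)
    keep <- alleles[freq >= pcrit & freq <= 1 - pcrit]
    if (length(keep) < 2L) next
    if (length(keep) == 2L) keep <- keep[1L]   # biallelic: one allele carries all information
    for (u in keep) {
      cols[[length(cols) + 1L]] <- (a1 == u) + (a2 == u)
      locus_of <- c(locus_of, l)
    }
  }
  if (length(unique(locus_of)) < 2L) {
    abort("fewer than two usable polymorphic loci after allele screening")
  }
  X <- do.call(cbind, cols)
  p <- colMeans(X) / 2
  # Burrows composite disequilibrium for every column pair:
  # Delta = S/(S-1) * (sum(x y)/(2 S) - 2 p q)
  M <- crossprod(X) / (2 * S)
  Delta <- (S / (S - 1)) * (M - 2 * outer(p, p))
  denom <- outer(p * (1 - p), p * (1 - p))
  r2 <- Delta^2 / denom
  cross <- outer(locus_of, locus_of, "!=") & upper.tri(r2)
  n_comp <- sum(cross)
  used <- unique(locus_of)
  n_pairs <- choose(length(used), 2)
  r2_mean <- mean(r2[cross])
  r2_exp <- expected_r2(S)
  r2_prime <- r2_mean - r2_exp
  ne <- ne_from_r2(r2_prime, S)
  # parametric CI: chi-square on the locus-pair count, applied to mean r^2
  r2_lo <- n_pairs * r2_mean / qchisq(0.975, n_pairs)
  r2_hi <- n_pairs * r2_mean / qchisq(0.025, n_pairs)
  ci_hi <- ne_from_r2(r2_lo - r2_exp, S)
  ci_lo <- ne_from_r2(r2_hi - r2_exp, S)
  structure(list(ne = ne, ci_lo = min(ci_lo, ne), ci_hi = max(ci_hi, ne),
                 r2 = r2_mean, r2_exp = r2_exp, r2_prime = r2_prime,
                 S = S, n_comparisons = n_comp, n_locus_pairs = n_pairs,
                 pcrit = pcrit),
            class = "tort_ne")
}

expected_r2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

ne_from_r2 <- function(r2_prime, S) {
  if (!is.finite(r2_prime) || r2_prime <= 0) return(Inf)
  if (S >= 30) {
    (1 / 3 + sqrt(max(0, 1 / 9 - 2.76 * r2_prime))) / (2 * r2_prime)
  } else {
    (0.618 + sqrt(max(0, 0.618^2 - 5.24 * r2_prime))) / (2 * r2_prime)
  }
}

#' @export
print.tort_ne <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "∞" else format(round(v, 1))
  cat("<tort_ne> Ne = ", fmt(x$ne), " (95% CI ", fmt(x$ci_lo), "-",
      fmt(x$ci_hi), "), S = ", x$S, ", ", x$n_comparisons,
      " allele-pair comparisons\n", sep = "")
  invisible(x)
}

#' @export
glance.tort_ne <- function(x, ...) {
  tibble(ne = x$ne, ci_lo = x$ci_lo, ci_hi = x$ci_hi, r2 = x$r2,
         r2_exp = x$r2_exp, r2_prime = x$r2_prime, S = x$S,
         n_comparisons = x$n_comparisons, n_locus_pairs = x$n_locus_pairs)
}
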