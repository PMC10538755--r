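#' Generate synthetic microsatellite allele-frequency tables
#'
#' Builds per-locus allele frequency distributions statistically matched to an
#' empirical microsatellite panel: mean expected heterozygosity (He) and mean
#' number of alleles per locus (allelic richness, Ar) are calibrated to the
#' requested targets. Allele states are abstract integers `1..A` per locus.
#'
#' Per-locus allele counts are drawn around `target_ar` (truncated normal,
#' sd = `target_ar / 3`, minimum 2 when `target_he > 0`) and then shifted so
#' their mean is within 1 of the target. Frequencies are drawn from a
#' symmetric Dirichlet whose concentration matches the target He in
#' expectation, then tempered (`p^t`, renormalised) with `t` tuned by
#' bisection so the realised locus-mean He hits `target_he` to within 1e-4.
#'
#' @param n_loci Number of loci (20 for the tortoise panel).
#' @param target_he Target mean expected heterozygosity in \[0, 1).
#' @param target_ar Target mean number of alleles per locus.
#' @param seed Optional integer seed (all randomness local to the call).
#' @return A tibble of class `tort_freqs` with columns `locus`, `allele`,
#'   `freq`; frequencies sum to 1 within each locus.
#' @examples
#' fr <- generate_frequencies(20, target_he = 0.81, target_ar = 13, seed = 1)
#' glance(fr)
#' @export
generate_frequencies <- function(n_loci, target_he = 0.81, target_ar = 13,
                                 seed = NULL) {
  stopifnot(n_loci >= 1, target_ar >= 1)
  if (target_he < 0 || target_he >= 1) {
    abort("`target_he` must lie in [0, 1)")
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  if (target_he == 0) {
    k <- rep(1L, n_loci)
  } else {
    k <- pmax(2L, as.integer(round(rnorm(n_loci, target_ar, target_ar / 3))))
    k <- pmax(2L, k - as.integer(round(mean(k) - target_ar)))
  }
  # feasibility: max attainable mean He with these allele counts
  he_max <- mean(1 - 1 / k)
  if (target_he > he_max + 1e-12) {
    abort(sprintf(
      "target He %.3f infeasible with mean allele count %.1f (max He %.3f)",
      target_he, mean(k), he_max))
  }
  if (target_he == 0) {
    freqs <- lapply(k, function(ki) 1)
  } else {
    # symmetric Dirichlet: E[1 - sum p^2] = 1 - (a + 1) / (k a + 1);
    # use the closed form at the mean allele count for the initial draw
    km <- mean(k)
    m <- 1 - target_he
    alpha <- if (m * km > 1) (1 - m) / (m * km - 1) else 50
    raw <- lapply(k, function(ki) {
      g <- stats::rgamma(ki, shape = alpha)
      if (all(g == 0)) g <- rep(1, ki)
      g / sum(g)
    })
    # temper p^t / sum(p^t): He is continuous and decreasing in t, with
    # t -> 0 giving the uniform (max He); bisect to the target mean He
    mean_he <- function(t) {
      mean(vapply(raw, function(p) {
        q <- p^t; q <- q / sum(q); 1 - sum(q^2)
      }, numeric(1)))
    }
    lo <- 1e-9; hi <- 1
    while (mean_he(hi) > target_he && hi < 1024) hi <- hi * 2
    if (mean_he(hi) > target_he) {
      abort("could not temper frequencies down to the target He")
    }
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (mean_he(mid) > target_he) lo <- mid else hi <- mid
    }
    t_star <- (lo + hi) / 2
    freqs <- lapply(raw, function(p) {
      q <- p^t_star
      q / sum(q)
    })
  }
  out <- tibble(
    locus = rep(seq_len(n_loci), lengths(freqs)),
    allele = unlist(lapply(freqs, seq_along)),
    freq = unlist(freqs))
  class(out) <- c("tort_freqs", class(out))
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

freqs_as_list <- function(freqs) {
  split(freqs$freq, freqs$locus)
}

#' @export
glance.tort_freqs <- function(x, ...) {
  per_locus <- x %>%
    group_by(.data$locus) %>%
    summarise(he = 1 - sum(.data$freq^2), n_alleles = dplyr::n())
  tibble(n_loci = nrow(per_locus),
         mean_he = mean(per_locus$he),
         mean_ar = mean(per_locus$n_alleles))
}

#' Sample a panmictic founder panel from allele frequencies
#'
#' Draws `n` diploid genotypes with two independent allele copies per locus
#' (Hardy-Weinberg proportions by construction), with no spatial coordinates:
#' the panel emulates an empirical sample randomised to remove any signal of
#' isolation by distance.
#'
#' @param freqs A `tort_freqs` tibble from [generate_frequencies()].
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return A `tort_founders` object holding an `n x 2L` integer genotype
#'   matrix (columns `locus1_a1, locus1_a2, locus2_a1, ...`).
#' @export
sample_founders <- function(freqs, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  fl <- freqs_as_list(freqs)
  n_loci <- length(fl)
  G <- matrix(0L, n, 2L * n_loci)
  for (l in seq_len(n_loci)) {
    p <- fl[[l]]
    draws <- sample.int(length(p), 2L * n, replace = TRUE, prob = p)
    G[, 2L * l - 1L] <- draws[seq_len(n)]
    G[, 2L * l] <- draws[n + seq_len(n)]
  }
  new_founders(G, allele_states = lapply(fl, seq_along))
}

new_founders <- function(G, allele_states) {
  structure(list(G = G, n = nrow(G), n_loci = length(allele_states),
                 allele_states = allele_states),
            class = "tort_founders")
}

#' @export
print.tort_founders <- function(x, ...) {
  cat("<tort_founders> ", x$n, " individuals, ", x$n_loci, " loci\n", sep = "")
  invisible(x)
}

#' Tidy a founder panel into long format
#'
#' @param x A `tort_founders` object.
#' @param ... Unused.
#' @return A tibble with columns `id`, `locus`, `allele1`, `allele2`.
#' @export
as_tibble.tort_founders <- function(x, ...) {
  n <- x$n
  odd <- x$G[, 2L * seq_len(x$n_loci) - 1L, drop = FALSE]
  even <- x$G[, 2L * seq_len(x$n_loci), drop = FALSE]
  tibble(
    id = rep(seq_len(n), times = x$n_loci),
    locus = rep(seq_len(x$n_loci), each = n),
    allele1 = as.integer(odd),
    allele2 = as.integer(even))
}

#' Burn in a founder panel on a uniform landscape
#'
#' Runs the forward simulator on a no-barrier surface for a number of
#' generations starting from a founder panel, and returns the final
#' population state; used to let the panel equilibrate spatially before
#' experiments.
#'
#' @param founders A `tort_founders` panel.
#' @param generations Number of burn-in generations (0 returns the founders
#'   placed on the landscape unchanged).
#' @param config A [sim_config()].
#' @param density Density class of the uniform surface.
#' @param seed Integer seed.
#' @return A `tort_state` population state.
#' @export
burn_in <- function(founders, generations = 100, config = sim_config(),
                    density = "moderate", seed = 1L) {
  surface <- build_scenario_surface("no_barrier", density = density)
  state <- initialize_population(surface, density, founders, seed = seed)
  if (generations == 0) return(state)
  for (g in seq_len(generations)) {
    state <- step_generation(state, surface, config)
    if (state$extinct) break
  }
  state
}
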