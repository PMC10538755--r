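#' Specify a scenario x density experiment
#'
#' @param scenario `"no_barrier"`, `"barrier"` or `"culverts"`.
#' @param density `"low"`, `"moderate"` or `"high"`.
#' @param n_replicates,n_generations,sample_interval,seed Run-control
#'   overrides passed to [sim_config()].
#' @param subsample_n Analysis subsample size per snapshot (750).
#' @param founders Optional `tort_founders` panel; generated from the default
#'   frequency targets (20 loci, He 0.81, Ar 13) when omitted.
#' @param ... Further overrides for [sim_config()].
#' @return A `tort_spec` list.
#' @export
experiment_spec <- function(scenario, density, n_replicates = 30L,
                            n_generations = 200L, sample_interval = 5L,
                            seed = 42L, subsample_n = 750L,
                            founders = NULL, ...) {
  structure(list(scenario = scenario, density = density,
                 config = sim_config(n_replicates = n_replicates,
                                     n_generations = n_generations,
                                     sample_interval = sample_interval,
                                     seed = seed, ...),
                 subsample_n = subsample_n, founders = founders),
            class = "tort_spec")
}

#' Run a full scenario x density experiment
#'
#' Builds the surface and founder panel, runs the replicated simulation, and
#' computes per-snapshot genetic statistics (Ho, He, Ar and -- when both
#' barrier sides are populated -- pairwise Weir-Cockerham FST) on subsamples
#' of up to `subsample_n` individuals. Effective population size is estimated
#' at the first and final generation of each replicate.
#'
#' @param spec A [experiment_spec()].
#' @return A `tort_experiment`: the `tort_runs` object plus `stats` (per
#'   replicate x sampled generation tibble), `ne` (per replicate, first/final
#'   generation), and the surface/founders used.
#' @export
run_experiment <- function(spec) {
  if (spec$config$n_replicates < 1) abort("need at least one replicate")
  surface <- build_scenario_surface(spec$scenario, density = spec$density)
  founders <- spec$founders
  if (is.null(founders)) {
    freqs <- generate_frequencies(20, target_he = 0.81, target_ar = 13,
                                  seed = spec$config$seed)
    need <- sum(as.integer(as.vector(surface$carrying_capacity) > 0)) * 20L
    founders <- sample_founders(freqs, max(need, 12500L),
                                seed = spec$config$seed + 1L)
  }
  snap_fun <- function(state, surface) {
    smp <- subsample(state, spec$subsample_n, n_cols = surface$n_cols)
    div <- glance(diversity(smp))
    fst <- if (all(table(smp$group) >= 2)) pairwise_fst(smp) else NA_real_
    dplyr::bind_cols(div, tibble(fst = fst, n_sampled = smp$n))
  }
  runs <- run_replicates(spec$config, surface, founders,
                         density = spec$density, snapshot_fun = snap_fun)
  ne <- purrr::map_dfr(seq_along(runs$snapshots), function(r) {
    purrr::map_dfr(runs$snapshots[[r]], function(st) {
      smp <- suppressWarnings(subsample(st, spec$subsample_n,
                                        n_cols = surface$n_cols))
      est <- glance(ld_ne(smp))
      dplyr::bind_cols(tibble(replicate = r, generation = st$generation), est)
    })
  })
  structure(list(runs = runs, stats = runs$stats, ne = ne,
                 census = runs$census, surface = surface,
                 founders = founders, spec = spec),
            class = "tort_experiment")
}

#' @export
print.tort_experiment <- function(x, ...) {
  cat("<tort_experiment> ", x$spec$scenario, " / ", x$spec$density, ", ",
      x$spec$config$n_replicates, " replicates x ",
      x$spec$config$n_generations, " generations\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Final-generation summary of an experiment
#'
#' Cross-replicate means (and SDs) of the census and the genetic statistics
#' at the final simulated generation -- one row in the style of the scenario
#' comparison tables.
#'
#' @param x A `tort_experiment`.
#' @param ... Unused.
#' @export
glance.tort_experiment <- function(x, ...) {
  gmax <- max(x$census$generation)
  fin <- x$census %>% filter(.data$generation == gmax)
  st <- x$stats %>% filter(.data$generation == gmax)
  ne <- x$ne %>% filter(.data$generation == gmax)
  tibble(scenario = x$spec$scenario, density = x$spec$density,
         generation = gmax,
         n = mean(fin$n), n_sd = sd(fin$n),
         ne = mean(ne$ne), ar = mean(st$ar), ho = mean(st$ho),
         he = mean(st$he), fst = mean(st$fst))
}

#' Per-generation time series of an experiment
#'
#' @param x A `tort_experiment`.
#' @param ... Unused.
#' @return Tibble with cross-replicate mean and SD of census, Ho, He, Ar and
#'   FST at each sampled generation.
#' @export
tidy.tort_experiment <- function(x, ...) {
  cen <- x$census %>% group_by(.data$generation) %>%
    summarise(n_mean = mean(.data$n), n_sd = sd(.data$n), .groups = "drop")
  st <- x$stats %>% group_by(.data$generation) %>%
    summarise(dplyr::across(c("ho", "he", "ar", "fst"),
                            list(mean = ~mean(.x), sd = ~sd(.x))),
              .groups = "drop")
  left_join(cen, st, by = "generation")
}

#' Time-series plot of heterozygosity and differentiation
#'
#' @param object A `tort_experiment`.
#' @param years_per_generation Axis conversion (17 years per tortoise
#'   generation).
#' @param ... Unused.
#' @export
autoplot.tort_experiment <- function(object, years_per_generation = 17, ...) {
  ts <- tidy(object) %>%
    select("generation", "ho_mean", "fst_mean") %>%
    tidyr::pivot_longer(c("ho_mean", "fst_mean"),
                        names_to = "statistic", values_to = "value") %>%
    mutate(statistic = dplyr::recode(.data$statistic,
                                     ho_mean = "Ho", fst_mean = "FST"),
           years = .data$generation * years_per_generation)
  ggplot2::ggplot(ts, ggplot2::aes(.data$years, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$statistic, scales = "free_y") +
    ggplot2::labs(x = "years", y = NULL)
}

#' Pick the replicate snapshot best representing the mean FST
#'
#' @param fst_by_replicate Tibble with columns `replicate` and `fst` (one row
#'   per replicate at the target generation).
#' @return The replicate id whose FST is nearest the cross-replicate mean;
#'   ties go to the lowest replicate index.
#' @export
select_representative_snapshot <- function(fst_by_replicate) {
  stopifnot(nrow(fst_by_replicate) >= 1)
  m <- mean(fst_by_replicate$fst)
  d <- round(abs(fst_by_replicate$fst - m), 12)  # guard float ties
  fst_by_replicate$replicate[order(d, fst_by_replicate$replicate)][1]
}

#' Pairwise-FST convergence check over subsample sizes
#'
#' Recomputes pairwise FST on subsamples of increasing size from one
#' snapshot and flags the smallest size after which successive estimates
#' change by less than 10% relative (reproducing the design check that led
#' to the n = 750 analysis sample).
#'
#' @param state A `tort_state` snapshot (at least `max(sizes)` individuals).
#' @param sizes Subsample sizes to scan.
#' @param seed Optional integer seed.
#' @return Tibble `n`, `fst`, with attribute `converged_at`.
#' @export
convergence_check <- function(state, sizes = seq(100L, 1200L, by = 100L),
                              seed = NULL) {
  if (state$n < max(sizes)) abort("snapshot smaller than the largest size")
  if (!is.null(seed)) set.seed(seed)
  fst <- vapply(sizes, function(s) {
    pairwise_fst(subsample(state, s))
  }, numeric(1))
  # successive change under 10% relative (or 1e-3 absolute, so near-zero
  # estimates are not held to a relative standard) counts as stable
  stable <- abs(diff(fst)) < pmax(0.10 * abs(fst[-length(fst)]), 1e-3)
  conv <- NA_integer_
  for (i in seq_along(stable)) {
    if (all(stable[i:length(stable)])) { conv <- sizes[i + 1L]; break }
  }
  if (all(abs(fst) < 1e-12)) conv <- sizes[1L]
  out <- tibble(n = sizes, fst = fst)
  attr(out, "converged_at") <- conv
  out
}
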