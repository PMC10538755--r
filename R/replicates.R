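#' Run replicated simulations on a surface
#'
#' Runs `config$n_replicates` independent replicates of the forward
#' simulation. Replicate seeds are derived from the master seed by one
#' `sample.int()` draw under `set.seed(config$seed)`, and each replicate's
#' stochastic stream flows through a single generator seeded with its derived
#' seed, so runs are reproducible bit-for-bit.
#'
#' @param config A [sim_config()].
#' @param surface A `tort_surface`.
#' @param founders A `tort_founders` panel.
#' @param density Density class used to seed the population (defaults to the
#'   surface's own class).
#' @param snapshot_fun Optional `function(state, surface)` returning a
#'   one-row tibble of per-snapshot statistics, evaluated every
#'   `sample_interval` generations (and at generations 0 and the final one).
#' @param keep_generations Generations whose full genotype snapshots are
#'   retained in the result (default: first and last).
#' @return A `tort_runs` object: `census` tibble (per replicate x generation
#'   census, per-side counts, culvert crossings, mutation counts), `stats`
#'   tibble from `snapshot_fun`, and `snapshots` (nested list,
#'   `snapshots[[replicate]][[as.character(generation)]]`; the entry
#'   `"last"` always holds the most recent living state, which matters for
#'   replicates that go extinct before the final generation).
#' @export
run_replicates <- function(config, surface, founders,
                           density = surface$density,
                           snapshot_fun = NULL,
                           keep_generations = c(0L, config$n_generations)) {
  tables <- dispersal_tables(surface, config$max_dispersal_cells, config$dispersal_kernel)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  census <- vector("list", config$n_replicates)
  stats <- vector("list", config$n_replicates)
  snapshots <- vector("list", config$n_replicates)
  bc <- barrier_column(surface$n_cols)
  for (r in seq_len(config$n_replicates)) {
    set.seed(rep_seeds[r])
    state <- initialize_population(surface, density, founders)
    crows <- list(); srows <- list(); snaps <- list()
    record <- function(state) {
      g <- state$generation
      cols <- cell_col(state$cell, surface$n_cols)
      crows[[length(crows) + 1L]] <<- tibble(
        replicate = r, generation = g, n = state$n,
        n_left = sum(cols < bc), n_right = sum(cols > bc),
        crossings = sum(state$crossings), mutations = state$n_mutations,
        extinct = state$extinct)
      if (g %% config$sample_interval == 0L || g == config$n_generations) {
        if (!is.null(snapshot_fun) && state$n > 0L) {
          row <- snapshot_fun(state, surface)
          srows[[length(srows) + 1L]] <<-
            dplyr::bind_cols(tibble(replicate = r, generation = g), row)
        }
      }
      if (g %in% keep_generations) {
        snaps[[as.character(g)]] <<- state
      }
      if (state$n > 0L) snaps[["last"]] <<- state
    }
    record(state)
    for (g in seq_len(config$n_generations)) {
      state <- step_generation(state, surface, config, tables)
      record(state)
      if (state$extinct) break
    }
    census[[r]] <- dplyr::bind_rows(crows)
    stats[[r]] <- dplyr::bind_rows(srows)
    snapshots[[r]] <- snaps
  }
  structure(list(census = dplyr::bind_rows(census),
                 stats = dplyr::bind_rows(stats),
                 snapshots = snapshots,
                 config = config, surface = surface,
                 replicate_seeds = rep_seeds),
            class = "tort_runs")
}

#' @export
print.tort_runs <- function(x, ...) {
  fin <- x$census %>% group_by(.data$replicate) %>%
    summarise(n = .data$n[which.max(.data$generation)])
  cat("<tort_runs> ", length(x$snapshots), " replicates, scenario: ",
      x$surface$scenario, ", final census mean ", round(mean(fin$n), 1),
      " (sd ", round(sd(fin$n), 1), ")\n", sep = "")
  invisible(x)
}

#' Cross-replicate census summary
#'
#' @param x A `tort_runs` object.
#' @param ... Unused.
#' @return Per-generation tibble with replicate mean and SD of the census.
#' @export
tidy.tort_runs <- function(x, ...) {
  x$census %>%
    group_by(.data$generation) %>%
    summarise(n_mean = mean(.data$n), n_sd = sd(.data$n),
              n_replicates = dplyr::n(), .groups = "drop")
}
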