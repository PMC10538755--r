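#' Simulation configuration
#'
#' Collects the life-history and run-control parameters of the forward
#' simulation. Defaults are the desert-tortoise values: dispersal probability
#' 0.5 per individual per generation, maximum dispersal distance 10 cells
#' (about 14 km), intrinsic per-generation growth rate 0.48 (an annual rate of
#' 1% compounded additively over 48 breeding years), microsatellite mutation
#' rate 5e-4 per locus per generation, 200 non-overlapping generations
#' (about 3400 years at 17 years/generation), genotype sampling every 5
#' generations, and 30 replicate runs.
#'
#' @param dispersal_probability Probability an individual disperses.
#' @param max_dispersal_cells Maximum dispersal distance in cells (Queen's
#'   case / Chebyshev metric).
#' @param dispersal_kernel How a disperser's destination is chosen.
#'   `"random_walk"` (default): the individual takes `max_dispersal_cells`
#'   successive moves, each to a uniformly chosen traversable neighbour
#'   (8-neighbourhood); displacement is at most `max_dispersal_cells` cells.
#'   `"max_ring"`: the destination is drawn uniformly among habitable cells
#'   at the largest reachable geodesic Chebyshev distance `<=
#'   max_dispersal_cells`.
#' @param growth_rate Intrinsic logistic growth rate per generation.
#' @param mutation_rate Mutation probability per allele copy per generation.
#' @param mutation_model `"kam"` (uniform to a different founder allele
#'   state) or `"smm"` (single-step, reflected at the state-space edges).
#' @param n_generations Number of generations to simulate.
#' @param sample_interval Generations between genotype snapshots.
#' @param n_replicates Number of replicate runs.
#' @param seed Master RNG seed; replicate seeds are derived from it.
#' @return A list of class `tort_config`.
#' @export
sim_config <- function(dispersal_probability = 0.5,
                       max_dispersal_cells = 10L,
                       dispersal_kernel = c("random_walk", "max_ring"),
                       growth_rate = 0.48,
                       mutation_rate = 0.0005,
                       mutation_model = c("kam", "smm"),
                       n_generations = 200L,
                       sample_interval = 5L,
                       n_replicates = 30L,
                       seed = 42L) {
  stopifnot(dispersal_probability >= 0, dispersal_probability <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            max_dispersal_cells >= 1, n_generations >= 0,
            sample_interval >= 1, n_replicates >= 1)
  structure(list(
    dispersal_probability = dispersal_probability,
    max_dispersal_cells = as.integer(max_dispersal_cells),
    dispersal_kernel = match.arg(dispersal_kernel),
    growth_rate = growth_rate,
    mutation_rate = mutation_rate,
    mutation_model = match.arg(mutation_model),
    n_generations = as.integer(n_generations),
    sample_interval = as.integer(sample_interval),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)), class = "tort_config")
}

new_state <- function(cell, female, G, allele_states, generation = 0L,
                      extinct = FALSE) {
  structure(list(cell = as.integer(cell), female = female, G = G,
                 allele_states = allele_states,
                 n = length(cell), generation = as.integer(generation),
                 extinct = extinct,
                 crossings = integer(0), n_mutations = 0L),
            class = "tort_state")
}

#' @export
print.tort_state <- function(x, ...) {
  cat("<tort_state> generation ", x$generation, ", ", x$n, " individuals",
      if (x$extinct) " (EXTINCT)", "\n", sep = "")
  invisible(x)
}

#' Tidy a population state into a tibble of individuals
#'
#' @param x A `tort_state`.
#' @param ... Unused.
#' @return Tibble with `id`, `sex`, `row`, `col`, `cell` and one pair of
#'   columns per locus (`locus<l>_a1`, `locus<l>_a2`).
#' @export
as_tibble.tort_state <- function(x, ...) {
  nc <- attr(x, "n_cols") %||% 25L
  base <- tibble(id = seq_len(x$n),
                 sex = ifelse(x$female, "female", "male"),
                 row = cell_row(x$cell, nc), col = cell_col(x$cell, nc),
                 cell = x$cell)
  G <- as.data.frame(x$G)
  nl <- ncol(x$G) / 2L
  names(G) <- paste0("locus", rep(seq_len(nl), each = 2), "_a", 1:2)
  dplyr::bind_cols(base, G)
}

#' Seed a population on a resistance surface
#'
#' Every habitable cell (resistance < 1) is seeded with a density-dependent
#' number of individuals: 3 (low), 14 (moderate), 20 (high) or the cell's own
#' carrying capacity (`"variable"`). Culvert cells are seeded at most to
#' their carrying capacity (3). Genotypes are drawn from the founder panel
#' (without replacement when the panel is large enough) and sexes are i.i.d.
#' 1:1. On the 625-cell open landscape this gives the canonical initial
#' population sizes 1875 / 8750 / 12500.
#'
#' @param surface A `tort_surface`.
#' @param density `"low"`, `"moderate"`, `"high"` or `"variable"`.
#' @param founders A `tort_founders` panel.
#' @param seed Optional integer seed.
#' @return A `tort_state`.
#' @export
initialize_population <- function(surface, density = surface$density,
                                  founders, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.na(density) || !density %in% c("low", "moderate", "high", "variable")) {
    abort("unknown density class")
  }
  res <- as.vector(t(surface$resistance))   # cell-id order (row-major)
  K <- as.vector(t(surface$carrying_capacity))
  habitable <- which(res < 1)
  if (!length(habitable)) abort("surface has no habitable cells")
  counts <- if (density == "variable") K[habitable] else {
    per <- c(low = 3L, moderate = 14L, high = 20L)[[density]]
    cnt <- rep(per, length(habitable))
    is_cul <- habitable %in% surface$culvert_cells
    cnt[is_cul] <- pmin(per, K[habitable][is_cul])
    cnt
  }
  counts <- as.integer(counts)
  cells <- rep(habitable, counts)
  n <- length(cells)
  if (founders$n >= n) {
    rows <- sample.int(founders$n, n)
  } else {
    rows <- sample.int(founders$n, n, replace = TRUE)
  }
  st <- new_state(cells, runif(n) < 0.5, founders$G[rows, , drop = FALSE],
                  founders$allele_states)
  attr(st, "n_cols") <- surface$n_cols
  st
}

# ---------------------------------------------------------------------------
# dispersal tables.
# random_walk kernel: per-cell lists of traversable neighbours.
# max_ring kernel: for every habitable origin cell, the destination cells at
# the largest feasible geodesic (8-connected, Chebyshev) distance <= max_d,
# plus -- on culvert surfaces -- the culvert each destination routes through
# (0 = none), so per-generation transit quotas can be enforced.

dispersal_tables <- function(surface, max_d = 10L, kernel = "random_walk") {
  out <- if (kernel == "random_walk") {
    neighbour_tables(surface)
  } else if (length(surface$culvert_cells)) {
    culvert_tables(surface, max_d)
  } else {
    bfs_tables(surface, max_d)
  }
  out$kernel <- kernel
  out
}

neighbour_tables <- function(surface) {
  nr <- surface$n_rows; nc <- surface$n_cols
  res <- as.vector(t(surface$resistance))
  ids <- seq_len(nr * nc)
  rows <- cell_row(ids, nc); cols <- cell_col(ids, nc)
  nbr <- vector("list", nr * nc)
  shifts <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                  dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  for (id in which(res < 1)) {
    rr <- rows[id] + shifts[, 1]; cc <- cols[id] + shifts[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    cand <- cell_id(as.integer(rr[ok]), as.integer(cc[ok]), nc)
    nbr[[id]] <- cand[res[cand] < 1]
  }
  len <- integer(nr * nc)
  nonnull <- !vapply(nbr, is.null, logical(1))
  len[nonnull] <- lengths(nbr[nonnull])
  off <- c(0L, cumsum(len))
  list(nbr = unlist(nbr[nonnull]) %||% integer(0),
       off = off[ids], len = len,
       n_culverts = length(surface$culvert_cells),
       culverts = as.integer(surface$culvert_cells))
}

# generic geodesic rings by layered frontier expansion on the traversable grid
bfs_tables <- function(surface, max_d) {
  trav <- surface$resistance < 1
  nr <- surface$n_rows; nc <- surface$n_cols
  ids <- which(t(trav))  # habitable cell ids
  dest <- vector("list", nr * nc)
  for (id in ids) {
    r0 <- cell_row(id, nc); c0 <- cell_col(id, nc)
    reached <- matrix(FALSE, nr, nc)
    reached[r0, c0] <- TRUE
    ring <- NULL
    for (d in seq_len(max_d)) {
      new_layer <- dilate8(reached) & trav & !reached
      if (!any(new_layer)) break
      ring <- new_layer
      reached <- reached | new_layer
    }
    dest[[id]] <- if (is.null(ring)) integer(0) else which(t(ring))
  }
  flatten_tables(dest, tag = NULL, n_culverts = 0L)
}

dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- p[1:nr, 1:nc] | p[1:nr, 2:(nc + 1L)] | p[1:nr, 3:(nc + 2L)] |
    p[2:(nr + 1L), 1:nc] | p[2:(nr + 1L), 3:(nc + 2L)] |
    p[3:(nr + 2L), 1:nc] | p[3:(nr + 2L), 2:(nc + 1L)] | p[3:(nr + 2L), 3:(nc + 2L)]
  out
}

# analytic tables for the barrier-with-culverts geometry: each side of the
# barrier is a rectangle, in which geodesic distance equals Chebyshev
# distance; the other side is only reachable through a culvert cell.
culvert_tables <- function(surface, max_d, avail = NULL) {
  geom <- culvert_geometry(surface)
  n_cul <- length(geom$culverts)
  if (is.null(avail)) avail <- rep(TRUE, n_cul)
  dest <- vector("list", length(geom$res))
  tag <- vector("list", length(geom$res))
  for (id in geom$habitable) {
    opt <- origin_ring(geom, id, max_d, avail)
    dest[[id]] <- opt$dest; tag[[id]] <- opt$tag
  }
  out <- flatten_tables(dest, tag, n_cul)
  out$geom <- geom
  out
}

culvert_geometry <- function(surface) {
  nr <- surface$n_rows; nc <- surface$n_cols
  bc <- barrier_column(nc)
  culverts <- surface$culvert_cells
  ids <- seq_len(nr * nc)
  rows <- cell_row(ids, nc); cols <- cell_col(ids, nc)
  res <- as.vector(t(surface$resistance))
  side <- ifelse(cols < bc, 1L, ifelse(cols > bc, 2L, 0L))
  cul_rows <- cell_row(culverts, nc)
  Dcul <- vapply(seq_along(culverts), function(k) {
    pmax(abs(rows - cul_rows[k]), abs(cols - bc))
  }, numeric(nr * nc))
  list(rows = rows, cols = cols, res = res, side = side,
       culverts = as.integer(culverts), Dcul = Dcul,
       habitable = which(res < 1))
}

# exact-distance destination ring (and culvert tags) for one origin cell
origin_ring <- function(geom, id, max_d, avail) {
  rows <- geom$rows; cols <- geom$cols; res <- geom$res; side <- geom$side
  culverts <- geom$culverts
  r0 <- rows[id]; c0 <- cols[id]; s <- side[id]
  cheb <- pmax(abs(rows - r0), abs(cols - c0))
  for (d in seq(max_d, 1L)) {
    if (s == 0L) {
      base <- which(side != 0L & res < 1 & cheb == d)
      cul_ok <- which(avail & culverts != id & cheb[culverts] == d)
      dd <- c(base, culverts[cul_ok])
      tt <- c(rep(0L, length(base)), cul_ok)
    } else {
      base <- which(side == s & cheb == d)
      cul_ok <- which(avail & cheb[culverts] == d)
      other <- which(side == 3L - s)
      dd <- c(base, culverts[cul_ok]); tt <- c(rep(0L, length(base)), cul_ok)
      if (any(avail)) {
        through <- sweep(geom$Dcul[other, avail, drop = FALSE], 2,
                         cheb[culverts[avail]], "+")
        geo <- apply(through, 1, min)
        hit <- geo == d
        if (any(hit)) {
          kk <- which(avail)[apply(through[hit, , drop = FALSE], 1, which.min)]
          dd <- c(dd, other[hit]); tt <- c(tt, kk)
        }
      }
    }
    if (length(dd)) return(list(dest = dd, tag = tt))
  }
  list(dest = integer(0), tag = integer(0))
}

flatten_tables <- function(dest, tag, n_culverts) {
  len <- integer(length(dest))
  nonnull <- !vapply(dest, is.null, logical(1))
  len[nonnull] <- lengths(dest[nonnull])
  off <- c(0L, cumsum(len))
  out <- list(dest = unlist(dest[nonnull]) %||% integer(0),
              off = off[seq_along(dest)], len = len,
              n_culverts = n_culverts)
  if (!is.null(tag)) {
    out$tag <- unlist(tag[vapply(tag, length, integer(1)) > 0]) %||% integer(0)
    out$has_tag <- vapply(seq_along(dest), function(i) {
      !is.null(tag[[i]]) && any(tag[[i]] > 0L)
    }, logical(1))
  }
  out
}

#' Dispersal phase
#'
#' Each individual independently disperses with the configured probability.
#' Under the default `"random_walk"` kernel a disperser performs
#' `max_dispersal_cells` successive Queen's-case moves, each to a uniformly
#' chosen traversable neighbour (resistance < 1); under `"max_ring"` it jumps
#' to a cell drawn uniformly among habitable cells at the largest geodesic
#' Chebyshev distance `d <= max_dispersal_cells` reachable through
#' traversable cells. In either case a one-cell-wide barrier is impassable,
#' and a culvert cell admits at most its carrying capacity (3) of distinct
#' individuals entering or passing through per generation; individuals
#' blocked everywhere stay put.
#'
#' @param state A `tort_state`.
#' @param surface The `tort_surface` the population lives on.
#' @param config A [sim_config()].
#' @param tables Precomputed dispersal tables (internal; computed when
#'   missing).
#' @return The state after movement, with per-culvert entry counts in
#'   `$crossings`.
#' @export
disperse <- function(state, surface, config, tables = NULL) {
  if (state$n == 0L) return(state)
  if (is.null(tables)) {
    tables <- dispersal_tables(surface, config$max_dispersal_cells,
                               config$dispersal_kernel)
  }
  n <- state$n
  moving <- which(runif(n) < config$dispersal_probability)
  crossings <- integer(tables$n_culverts)
  if (!length(moving)) { state$crossings <- crossings; return(state) }
  cell <- state$cell
  if (tables$kernel == "random_walk") {
    quota <- if (tables$n_culverts) {
      as.vector(t(surface$carrying_capacity))[tables$culverts]
    } else integer(0)
    walk <- walk_dispersers(cell[moving], tables, config$max_dispersal_cells,
                            quota)
    cell[moving] <- walk$cell
    crossings <- walk$crossings
    state$cell <- cell
    state$crossings <- crossings
    return(state)
  }
  if (tables$n_culverts == 0L) {
    ocell <- cell[moving]
    ln <- tables$len[ocell]
    can <- ln > 0L
    pick <- tables$off[ocell[can]] + ceiling(runif(sum(can)) * ln[can])
    cell[moving[can]] <- tables$dest[pick]
  } else {
    quota <- as.vector(t(surface$carrying_capacity))[surface$culvert_cells]
    # split movers into those whose option set can involve a culvert
    # (processed sequentially so quotas bind in arrival order) and the rest
    involved <- tables$has_tag[cell[moving]]
    plain <- moving[!involved]
    if (length(plain)) {
      ocell <- cell[plain]
      ln <- tables$len[ocell]
      can <- ln > 0L
      pick <- tables$off[ocell[can]] + ceiling(runif(sum(can)) * ln[can])
      cell[plain[can]] <- tables$dest[pick]
    }
    seq_movers <- moving[involved][sample.int(sum(involved))]
    cache <- new.env(parent = emptyenv())
    epoch <- 0L
    avail <- rep(TRUE, tables$n_culverts)
    for (i in seq_movers) {
      o <- cell[i]
      key <- as.character(o)
      ent <- get0(key, cache)
      if (is.null(ent) || ent$epoch != epoch) {
        ent <- origin_options(o, surface, config$max_dispersal_cells,
                              tables, avail, epoch)
        assign(key, ent, cache)
      }
      if (!length(ent$dest)) next
      j <- ceiling(runif(1) * length(ent$dest))
      cell[i] <- ent$dest[j]
      k <- ent$tag[j]
      if (k > 0L) {
        crossings[k] <- crossings[k] + 1L
        if (crossings[k] >= quota[k]) {
          avail[k] <- FALSE
          epoch <- epoch + 1L
        }
      }
    }
  }
  state$cell <- cell
  state$crossings <- crossings
  state
}

# stepwise Queen's-case walk for all dispersers, with per-generation entry
# quotas on culvert cells (each distinct walker entering a culvert consumes
# one unit; a blocked walker re-chooses among its remaining neighbours)
walk_dispersers <- function(cur, tables, steps, quota) {
  m <- length(cur)
  culverts <- tables$culverts %||% integer(0)
  counted <- rep(list(integer(0)), length(culverts))
  for (s in seq_len(steps)) {
    ln <- tables$len[cur]
    can <- ln > 0L
    prop <- cur
    j <- ceiling(runif(m) * ln)
    prop[can] <- tables$nbr[tables$off[cur[can]] + j[can]]
    if (length(culverts)) {
      hits <- which(prop != cur & prop %in% culverts)
      for (i in hits[sample.int(length(hits))]) {
        k <- match(prop[i], culverts)
        if (i %in% counted[[k]]) next
        if (length(counted[[k]]) < quota[k]) {
          counted[[k]] <- c(counted[[k]], i)
          next
        }
        # quota exhausted: re-choose among the walker's other neighbours,
        # excluding culverts this walker cannot enter
        opts <- tables$nbr[tables$off[cur[i]] + seq_len(tables$len[cur[i]])]
        blocked <- culverts[lengths(counted) >= quota &
                              !vapply(counted, function(v) i %in% v, logical(1))]
        opts <- opts[!opts %in% blocked]
        if (!length(opts)) { prop[i] <- cur[i]; next }
        pick <- opts[ceiling(runif(1) * length(opts))]
        kk <- match(pick, culverts)
        if (!is.na(kk) && !(i %in% counted[[kk]])) {
          counted[[kk]] <- c(counted[[kk]], i)
        }
        prop[i] <- pick
      }
    }
    cur <- prop
  }
  list(cell = cur, crossings = lengths(counted))
}

origin_options <- function(o, surface, max_d, tables, avail, epoch) {
  if (all(avail)) {
    idx <- tables$off[o] + seq_len(tables$len[o])
    return(list(dest = tables$dest[idx], tag = tables$tag[idx], epoch = epoch))
  }
  opt <- origin_ring(tables$geom, o, max_d, avail)
  list(dest = opt$dest, tag = opt$tag, epoch = epoch)
}

#' Reproduction phase
#'
#' Within every occupied cell holding at least two individuals including at
#' least one male and one female, the expected number of recruits follows the
#' discrete logistic map `E = N + r N (1 - N / K)` (floored at zero); the
#' realised number is `floor(E)` plus a Bernoulli draw on the fractional
#' remainder. Each recruit draws a mother and a father uniformly at random
#' (with replacement) from the cell's females and males, inherits one
#' uniformly chosen allele per parent at each locus, and is male or female
#' with probability 1/2. Cells without a mating pair produce no recruits.
#'
#' @inheritParams disperse
#' @return A `tort_state` holding the offspring cohort (previous adults are
#'   not included; they die at the end of the step).
#' @export
reproduce <- function(state, surface, config) {
  n_cells <- surface$n_rows * surface$n_cols
  K <- as.vector(t(surface$carrying_capacity))
  if (state$n && any(K[unique(state$cell)] == 0L)) {
    abort("occupied cell with zero carrying capacity: dispersal violated the surface")
  }
  Ncell <- tabulate(state$cell, n_cells)
  Fcell <- tabulate(state$cell[state$female], n_cells)
  Mcell <- Ncell - Fcell
  eligible <- which(Ncell >= 2L & Fcell >= 1L & Mcell >= 1L & K > 0L)
  if (!length(eligible)) {
    return(empty_cohort(state))
  }
  N <- Ncell[eligible]
  E <- pmax(0, N + config$growth_rate * N * (1 - N / K[eligible]))
  recruits <- floor(E) + (runif(length(E)) < (E - floor(E)))
  recruits <- as.integer(recruits)
  keep <- recruits > 0L
  eligible <- eligible[keep]; recruits <- recruits[keep]
  if (!length(eligible)) return(empty_cohort(state))
  m <- sum(recruits)
  child_cell <- rep(eligible, recruits)
  # index females/males by cell for uniform within-cell parent draws
  f_idx <- which(state$female); m_idx <- which(!state$female)
  f_sorted <- f_idx[order(state$cell[f_idx])]
  m_sorted <- m_idx[order(state$cell[m_idx])]
  f_off <- c(0L, cumsum(tabulate(state$cell[f_idx], n_cells)))
  m_off <- c(0L, cumsum(tabulate(state$cell[m_idx], n_cells)))
  nf <- Fcell[child_cell]; nm <- Mcell[child_cell]
  mothers <- f_sorted[f_off[child_cell] + ceiling(runif(m) * nf)]
  fathers <- m_sorted[m_off[child_cell] + ceiling(runif(m) * nm)]
  n_loci <- ncol(state$G) %/% 2L
  childG <- matrix(0L, m, 2L * n_loci)
  bm <- matrix(as.integer(runif(m * n_loci) < 0.5), m, n_loci)
  bf <- matrix(as.integer(runif(m * n_loci) < 0.5), m, n_loci)
  loci2 <- rep(2L * seq_len(n_loci), each = m)
  childG[, 2L * seq_len(n_loci) - 1L] <-
    state$G[cbind(rep(mothers, n_loci), loci2 - 1L + as.vector(bm))]
  childG[, 2L * seq_len(n_loci)] <-
    state$G[cbind(rep(fathers, n_loci), loci2 - 1L + as.vector(bf))]
  out <- new_state(child_cell, runif(m) < 0.5, childG, state$allele_states,
                   generation = state$generation)
  attr(out, "n_cols") <- attr(state, "n_cols")
  out$crossings <- state$crossings
  out
}

empty_cohort <- function(state) {
  out <- new_state(integer(0), logical(0),
                   matrix(0L, 0L, ncol(state$G)), state$allele_states,
                   generation = state$generation, extinct = TRUE)
  attr(out, "n_cols") <- attr(state, "n_cols")
  out$crossings <- state$crossings
  out
}

#' Mutation phase
#'
#' Every allele copy mutates independently with probability `mutation_rate`.
#' Under the k-allele model (`"kam"`, the default) a mutation replaces the
#' allele with a uniformly chosen different state from the locus's founder
#' state space; under `"smm"` it steps one state up or down, reflecting at
#' the edges. Loci with a single state cannot mutate and are skipped.
#'
#' @param state A `tort_state` (typically the offspring cohort).
#' @param config A [sim_config()].
#' @return The state with mutated genotypes; `$n_mutations` records the count.
#' @export
mutate_genotypes <- function(state, config) {
  mu <- config$mutation_rate
  state$n_mutations <- 0L
  if (mu == 0 || state$n == 0L) return(state)
  G <- state$G
  n_entries <- length(G)
  hits <- which(runif(n_entries) < mu)
  if (!length(hits)) return(state)
  n <- nrow(G)
  locus <- ((hits - 1L) %/% (2L * n)) + 1L
  k <- lengths(state$allele_states)[locus]
  ok <- k > 1L
  hits <- hits[ok]; locus <- locus[ok]; k <- k[ok]
  if (!length(hits)) return(state)
  cur <- G[hits]
  if (config$mutation_model == "kam") {
    draw <- ceiling(runif(length(hits)) * (k - 1L))
    new <- ifelse(draw >= cur, draw + 1L, draw)
  } else {
    stp <- ifelse(runif(length(hits)) < 0.5, -1L, 1L)
    new <- cur + stp
    new <- ifelse(new < 1L, 2L, ifelse(new > k, k - 1L, new))
  }
  G[hits] <- as.integer(new)
  state$G <- G
  state$n_mutations <- length(hits)
  state
}

#' Advance the simulation one generation
#'
#' Applies the phases in the fixed order dispersal, reproduction, mutation of
#' the recruits, then complete adult mortality: the offspring cohort becomes
#' the next generation. A population that produces no recruits is recorded as
#' extinct and the state flagged.
#'
#' @inheritParams disperse
#' @return The next-generation `tort_state`.
#' @export
step_generation <- function(state, surface, config, tables = NULL) {
  if (state$extinct || state$n == 0L) {
    state$extinct <- TRUE
    state$generation <- state$generation + 1L
    return(state)
  }
  if (is.null(tables)) tables <- dispersal_tables(surface, config$max_dispersal_cells, config$dispersal_kernel)
  moved <- disperse(state, surface, config, tables)
  cohort <- reproduce(moved, surface, config)
  cohort <- mutate_genotypes(cohort, config)
  cohort$generation <- state$generation + 1L
  cohort
}
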