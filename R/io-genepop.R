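#' Write genotypes in GENEPOP format
#'
#' Two-allele, three-digit codes per locus (`001002` etc.); one `Pop` block
#' per group (barrier side), or a single block for ungrouped data such as a
#' founder panel.
#'
#' @param x A `tort_sample`, `tort_state` or `tort_founders`.
#' @param path Output path.
#' @param title Header line.
#' @export
write_genepop <- function(x, path, title = "tortsim genotypes") {
  parts <- as_genotype_parts(x)
  n_loci <- ncol(parts$G) %/% 2L
  lines <- c(title, paste0("locus", seq_len(n_loci)))
  enc <- function(rows, label) {
    body <- apply(parts$G[rows, , drop = FALSE], 1, function(g) {
      paste(sprintf("%03d%03d", g[2L * seq_len(n_loci) - 1L],
                    g[2L * seq_len(n_loci)]), collapse = " ")
    })
    paste0(label, "_", rows, " ,  ", body)
  }
  for (grp in levels(parts$group)) {
    rows <- which(parts$group == grp)
    if (!length(rows)) next
    lines <- c(lines, "Pop", enc(rows, grp))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a GENEPOP file
#'
#' Supports the 3-digit (and 2-digit) two-allele-per-locus encoding written
#' by [write_genepop()]; `Pop` blocks become groups `A`, `B`, ...
#'
#' @param path Path to a GENEPOP file.
#' @return A `tort_sample` (without spatial coordinates).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3) abort("malformed GENEPOP file")
  loci <- unlist(strsplit(paste(lines[2:(first_pop - 1)], collapse = ","), ","))
  loci <- trimws(loci[nzchar(trimws(loci))])
  n_loci <- length(loci)
  group <- integer(0); rows <- list()
  gi <- 0L
  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) { gi <- gi + 1L; next }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2) abort("malformed GENEPOP genotype line")
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(codes) != n_loci) abort("locus count mismatch in GENEPOP file")
    w <- nchar(codes[1]) / 2
    a1 <- as.integer(substr(codes, 1, w))
    a2 <- as.integer(substr(codes, w + 1, 2 * w))
    rows[[length(rows) + 1L]] <- as.integer(rbind(a1, a2))
    group <- c(group, gi)
  }
  G <- do.call(rbind, lapply(rows, function(r) {
    out <- integer(2L * n_loci)
    out[2L * seq_len(n_loci) - 1L] <- r[2L * seq_len(n_loci) - 1L]
    out[2L * seq_len(n_loci)] <- r[2L * seq_len(n_loci)]
    out
  }))
  structure(list(G = G, group = factor(LETTERS[group]),
                 cell = rep(NA_integer_, nrow(G)), n = nrow(G),
                 n_loci = n_loci, n_cols = NA_integer_),
            class = "tort_sample")
}

#' Write genotypes in Structure format
#'
#' One row per individual: id, group index, then two columns per locus.
#'
#' @inheritParams write_genepop
#' @export
write_structure <- function(x, path) {
  parts <- as_genotype_parts(x)
  n_loci <- ncol(parts$G) %/% 2L
  header <- paste(paste0("locus", seq_len(n_loci)), collapse = "\t")
  body <- vapply(seq_len(nrow(parts$G)), function(i) {
    paste(c(paste0("ind", i), as.integer(parts$group[i]),
            parts$G[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a snapshot to CSV (long format)
#'
#' Columns: `id`, `sex`/`group`, `row`, `col`, `locus`, `allele1`, `allele2`.
#'
#' @param x A `tort_state` or `tort_sample`.
#' @param path Output path.
#' @export
write_snapshot_csv <- function(x, path) {
  parts <- as_genotype_parts(x)
  n <- nrow(parts$G); n_loci <- ncol(parts$G) %/% 2L
  nc <- parts$n_cols %||% 25L
  df <- tibble(
    id = rep(seq_len(n), times = n_loci),
    group = rep(as.character(parts$group), times = n_loci),
    row = rep(if (all(is.na(parts$cell))) NA_integer_ else
      cell_row(parts$cell, nc), times = n_loci),
    col = rep(if (all(is.na(parts$cell))) NA_integer_ else
      cell_col(parts$cell, nc), times = n_loci),
    locus = rep(seq_len(n_loci), each = n),
    allele1 = as.integer(parts$G[, 2L * seq_len(n_loci) - 1L]),
    allele2 = as.integer(parts$G[, 2L * seq_len(n_loci)]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

as_genotype_parts <- function(x) {
  if (inherits(x, "tort_sample")) {
    list(G = x$G, group = x$group, cell = x$cell, n_cols = x$n_cols)
  } else if (inherits(x, "tort_state")) {
    list(G = x$G, group = factor(rep("A", x$n)), cell = x$cell,
         n_cols = attr(x, "n_cols"))
  } else if (inherits(x, "tort_founders")) {
    list(G = x$G, group = factor(rep("A", x$n)),
         cell = rep(NA_integer_, x$n), n_cols = NA_integer_)
  } else {
    abort("unsupported genotype container")
  }
}
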