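# Independent oracles and fixture builders shared across tests.

# Connected-component sizes via igraph on the lattice adjacency graph --
# an implementation path independent of label_components().
oracle_component_sizes <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(mask)
  if (!length(cells)) return(integer(0))
  id <- integer(nr * nc); id[cells] <- seq_along(cells)
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  rs <- ((cells - 1) %% nr) + 1
  cs <- ((cells - 1) %/% nr) + 1
  edges <- lapply(offs, function(o) {
    r2 <- rs + o[1]; c2 <- cs + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    w <- (c2[ok] - 1) * nr + r2[ok]
    keep <- mask[w]
    rbind(id[cells[ok]][keep], id[w[keep]])
  })
  e <- do.call(cbind, edges)
  g <- igraph::make_graph(as.vector(e), n = length(cells), directed = FALSE)
  sort(igraph::components(g)$csize)
}

# Naive per-pair per-bin double loop JID (probability-mass normalised).
oracle_jid_matrix <- function(pairs, grid) {
  nb <- grid$n_bins
  m <- matrix(0, nb, nb)
  for (p in seq_len(nrow(pairs))) {
    lx <- log10(pairs[p, 1]); ly <- log10(pairs[p, 2])
    for (i in seq_len(nb)) for (j in seq_len(nb))
      m[i, j] <- m[i, j] +
        stats::dnorm(grid$centers[i], lx, grid$bandwidth) *
        stats::dnorm(grid$centers[j], ly, grid$bandwidth)
  }
  m <- m / nrow(pairs)
  m / sum(m)
}

# A JID object with a given matrix (for constructed-group tests).
manual_jid <- function(mat, grid = jid_grid(),
                       normalization = "probability_mass") {
  structure(list(grid = grid, matrix = mat, n_pairs = 1L,
                 normalization = normalization, out_of_grid = 0),
            class = "jid")
}

# Random probability-mass JID (dirichlet-ish noise around uniform).
random_jid <- function(grid = jid_grid(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rexp(grid$n_bins^2), grid$n_bins, grid$n_bins)
  manual_jid(m / sum(m), grid)
}

# A small, fast synthetic config (short periods, light days) for tests
# that exercise structure rather than statistical power.
small_config <- function(seed = 1L, ...) {
  synth_config(n_pre = 8L, n_taper = 4L, n_post = 8L,
               daily_count_law = list(name = "lognormal",
                                      meanlog = log(400), sdlog = 0.3),
               seed = seed, ...)
}

# Daily JIDs drawn straight from the generator for one condition.
gen_condition_jids <- function(cfg, condition, n, seed0,
                               grid = jid_grid()) {
  lapply(seq_len(n), function(i) {
    s <- generate_day(cfg, condition, day_index = i - 1L, seed = seed0 + i)
    compute_jid(make_pairs(diff(s$timestamps) / 1000), grid)
  })
}

# One default-scale study, generated once and cached for the session.
.fixture_env <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- generate_study(synth_config(seed = 20260926 %% 99991))
  .fixture_env$study
}
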