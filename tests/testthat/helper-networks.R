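# Shared fixtures and independent oracles.

# A -> B -> C chain with hand-picked CPTs (used for hand-checked joints).
chain3_network <- function() {
  bn_network(
    bn_stochastic("A", cpt(c(0.3, 0.7))),
    bn_stochastic("B", cpt(array(c(0.9, 0.2, 0.1, 0.8), c(2, 2))),
                  parents = "A"),
    bn_stochastic("C", cpt(array(c(0.6, 0.5, 0.4, 0.5), c(2, 2))),
                  parents = "B")
  )
}

# Brute-force conditional marginal: enumerate every complete assignment of
# the stochastic nodes, resolve the deterministic nodes, and sum
# joint_probability().  Independent of the factor-algebra code path.
# Evidence must have positive probability (used on generated networks).
brute_force_marginal <- function(network, ev, query) {
  ord <- topological_order(network)
  stoch <- intersect(ord, adbn:::stochastic_names(network))
  free <- setdiff(stoch, names(ev))
  num <- 0
  den <- 0
  grid <- if (length(free)) {
    as.matrix(expand.grid(rep(list(1:2), length(free))))
  } else {
    matrix(integer(), nrow = 1L, ncol = 0L)
  }
  for (r in seq_len(nrow(grid))) {
    st <- stats::setNames(integer(length(ord)), ord)
    for (v in names(ev)) st[v] <- ev[[v]]
    if (length(free)) st[free] <- grid[r, ]
    for (nm in ord) {
      node <- network$nodes[[nm]]
      if (node$kind == "deterministic_max") st[nm] <- max(st[node$members])
    }
    p <- joint_probability(network, st)
    den <- den + p
    if (st[[query]] == 2L) num <- num + p
  }
  num / den
}

# fixtures are loaded repeatedly across test files; cache them
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(id, corrected = TRUE) {
  key <- paste0(id, if (corrected) "c" else "p")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- load_example(id, corrected = corrected,
                                         quiet = TRUE)
  }
  fixture_cache[[key]]
}

# random data-list document generator for round-trip property tests
random_datalist <- function(seed) {
  set.seed(seed)
  doc <- list(scalars = stats::setNames(numeric(), character()),
              vectors = list(), arrays = list())
  n <- sample(0:6, 1)
  for (i in seq_len(n)) {
    nm <- paste0("s", i)
    doc$scalars[nm] <- round(stats::runif(1, -10, 10), sample(0:6, 1))
  }
  for (i in seq_len(sample(0:4, 1))) {
    doc$vectors[[paste0("v", i)]] <-
      stats::runif(sample(1:6, 1), -1, 1) * 10^sample(-8:3, 1)
  }
  for (i in seq_len(sample(0:4, 1))) {
    dims <- sample(1:3, sample(1:3, 1), replace = TRUE)
    doc$arrays[[paste0("a", i)]] <-
      list(data = stats::runif(prod(dims)), dim = as.integer(dims))
  }
  structure(doc, class = "bn_datalist")
}
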