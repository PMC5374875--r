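#' Generate a random network fixture
#'
#' Draws a random DAG over binary stochastic nodes with Dirichlet-sampled
#' CPT rows, optionally topped by deterministic max aggregators, and emits
#' it both as an in-memory network and as a (config, data list) text pair
#' that round-trips through [read_network_config()] and
#' [bind_parameters()].  Used as the fixture generator for property tests
#' of the inference engines; all randomness is controlled by `seed`.
#'
#' @param n_nodes number of stochastic nodes (>= 1).
#' @param max_parents maximum in-degree (<= 3).
#' @param seed integer seed.
#' @param max_nodes number of deterministic max aggregators to add on top
#'   (members drawn among the stochastic nodes; default 0).
#' @return `list(network, config, data_list)` where `config` and
#'   `data_list` are document texts.
#' @export
simulate_network <- function(n_nodes, max_parents = 3L, seed = 1L,
                             max_nodes = 0L) {
  stopifnot(n_nodes >= 1L, max_parents <= 3L, max_parents >= 0L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  nms <- sprintf("N%02d", seq_len(n_nodes))
  nodes <- list()
  doc <- structure(list(scalars = stats::setNames(numeric(), character()),
                        vectors = list(), arrays = list()),
                   class = "bn_datalist")
  for (i in seq_len(n_nodes)) {
    k <- sample(0:min(max_parents, i - 1L), 1L)
    parents <- if (k > 0L) sort(sample(nms[seq_len(i - 1L)], k)) else character()
    n_rows <- 2L^k
    g <- matrix(stats::rgamma(2L * n_rows, shape = 1), ncol = 2L)
    rows <- g / rowSums(g)
    a <- array(0, dim = rep(2L, k + 1L))
    if (k == 0L) {
      a[] <- rows[1L, ]
    } else {
      combos <- as.matrix(expand.grid(rep(list(1:2), k),
                                      KEEP.OUT.ATTRS = FALSE))
      for (r in seq_len(n_rows)) {
        a[rbind(c(combos[r, ], 1L))] <- rows[r, 1L]
        a[rbind(c(combos[r, ], 2L))] <- rows[r, 2L]
      }
    }
    nodes[[nms[i]]] <- bn_stochastic(nms[i], cpt = cpt(a), parents = parents)
    if (k == 0L) {
      doc$vectors[[paste0("p.", nms[i])]] <- as.vector(a)
    } else {
      doc$arrays[[paste0("p.", nms[i])]] <- list(data = row_major_flatten(a),
                                                 dim = rep(2L, k + 1L))
    }
  }
  if (max_nodes > 0L) {
    for (j in seq_len(max_nodes)) {
      nm <- sprintf("M%02d", j)
      members <- sort(sample(nms, sample(1:min(3L, n_nodes), 1L)))
      nodes[[nm]] <- bn_max(nm, members)
    }
  }
  net <- bn_network(nodes)
  list(network = net,
       config = write_network_config(net),
       data_list = write_data_list(doc))
}
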