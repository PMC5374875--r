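#' Exact posterior marginal of a binary node
#'
#' Computes `P(query = True | evidence)` by summing the joint distribution
#' over all completions of the evidence, either by direct enumeration of the
#' free stochastic nodes or by variable elimination on the factor graph
#' (min-degree ordering).  Deterministic max nodes are evaluated per
#' assignment (enumeration) or carried as indicator factors (elimination);
#' both routes return identical values.
#'
#' Conditioning follows the BUGS convention for observed nodes: factors that
#' are constant under the evidence (an observed node whose parents are all
#' observed) cancel between numerator and denominator and are dropped, so
#' clamping a root to a state its own prior excludes is tolerated.  Evidence
#' is reported impossible only when the free nodes cannot produce it, i.e.
#' the remaining normalizer is zero.
#'
#' @param network a valid [bn_network()].
#' @param ev an [evidence()] object (possibly empty).
#' @param query name of the node whose probability of being present (state
#'   2) is requested; may be deterministic.
#' @param method `"auto"` (enumeration up to 14 free stochastic nodes,
#'   variable elimination beyond), `"enumeration"`, or `"elimination"`.
#' @return `P(query = 2 | evidence)`, a number in \[0,1\].
#' @examples
#' net <- bn_network(
#'   bn_stochastic("Ab", cpt(c(0.5, 0.5))),
#'   bn_stochastic("LewyBodies", cpt(c(0.884, 0.116))),
#'   bn_max("ProdromalAD", c("Ab", "LewyBodies"))
#' )
#' exact_marginal(net, evidence(), "ProdromalAD")  # 1 - 0.5*0.884 = 0.558
#' @export
exact_marginal <- function(network, ev = evidence(), query,
                           method = c("auto", "enumeration", "elimination")) {
  method <- match.arg(method)
  stop_on_diagnostics(network)
  check_evidence(network, ev)
  if (!query %in% node_names(network)) {
    stop("unknown query node: ", query, call. = FALSE)
  }
  if (query %in% names(ev)) {
    return(as.numeric(ev[[query]] == 2L))
  }
  n_free <- length(setdiff(stochastic_names(network), names(ev)))
  if (method == "auto") {
    method <- if (n_free <= 14L) "enumeration" else "elimination"
  }
  if (method == "enumeration") {
    if (n_free > 22L) {
      stop("too many free stochastic nodes (", n_free,
           ") for enumeration; use method = \"elimination\"", call. = FALSE)
    }
    marginal_enumeration(network, ev, query)
  } else {
    marginal_elimination(network, ev, query)
  }
}

marginal_elimination <- function(network, ev, query) {
  factors <- network_factors(network, ev)
  res <- ve_eliminate(factors, keep = query)
  if (!identical(res$vars, query)) {
    # query variable untouched by any factor can only happen on invalid input
    stop("internal error: query '", query, "' lost during elimination")
  }
  z <- sum(res$values)
  if (z <= 0) stop("impossible evidence", call. = FALSE)
  as.numeric(res$values[2L] / z)
}

# Enumerate all assignments of the free stochastic nodes; deterministic
# nodes are resolved per assignment; constant (fully clamped) factors are
# skipped so they cancel exactly as in marginal_elimination().
marginal_enumeration <- function(network, ev, query) {
  st <- complete_states(network, ev)
  w <- st$weights
  z <- sum(w)
  if (z <= 0) stop("impossible evidence", call. = FALSE)
  sum(w[st$states[, query] == 2L]) / z
}

# All completions of the evidence: a matrix of states (rows = assignments,
# cols = every node) plus the unnormalized weight of each row.
complete_states <- function(network, ev) {
  order <- topological_order(network, strict = FALSE)
  free <- setdiff(stochastic_names(network), names(ev))
  free <- order[order %in% free]
  nrows <- 2L^length(free)
  states <- matrix(0L, nrow = nrows, ncol = length(order),
                   dimnames = list(NULL, order))
  for (v in names(ev)) states[, v] <- ev[[v]]
  if (length(free)) {
    grid <- as.matrix(expand.grid(rep(list(1:2), length(free)),
                                  KEEP.OUT.ATTRS = FALSE))
    states[, free] <- grid
  }
  w <- rep(1, nrows)
  for (nm in order) {
    node <- network$nodes[[nm]]
    if (node$kind == "deterministic_max") {
      cols <- states[, node$members, drop = FALSE]
      states[, nm] <- do.call(pmax, as.data.frame(cols))
    } else if (!all(c(node$parents, nm) %in% names(ev))) {
      w <- w * cpt_prob(node$cpt, states[, node$parents, drop = FALSE],
                        states[, nm])
    }
  }
  list(states = states, weights = w)
}

#' Convert a 1/2-coded posterior mean to a probability
#'
#' Under the state coding 1 = absent, 2 = present, the posterior mean of an
#' indicator node satisfies `E = 2 p + 1 (1 - p)`, so `p = E - 1`.
#'
#' @param mean posterior mean(s) in \[1,2\].
#' @return probability of the present state.
#' @examples
#' mean_to_probability(1.999)  # 0.999
#' @export
mean_to_probability <- function(mean) {
  if (!is.numeric(mean) || any(!is.finite(mean)) ||
      any(mean < 1) || any(mean > 2)) {
    stop("a 1/2-coded posterior mean must lie in [1, 2]", call. = FALSE)
  }
  mean - 1
}

#' Probabilities of the eight Alzheimer's disease categories
#'
#' Evaluates `P(category = True | evidence)` for the eight diagnostic
#' category nodes (Prodromal AD through Mild Cognitive Impairment), either
#' exactly or from an MCMC chain.
#'
#' @param network a network containing the eight category nodes (see
#'   [build_ad_network()]).
#' @param ev an [evidence()] object.
#' @param mode `"exact"` (default) or `"mcmc"`.
#' @param iterations,seed,burn_in,batches MCMC settings, see
#'   [sample_posterior()] and [posterior_summary()].
#' @param method exact-inference method, see [exact_marginal()].
#' @return a data frame of class `bn_category_report` with columns
#'   `category` (node name), `label` (table heading used in the original
#'   report) and `probability`; in MCMC mode also `mean`, `sd`, `mc_error`.
#' @export
category_probabilities <- function(network, ev = evidence(),
                                   mode = c("exact", "mcmc"),
                                   iterations = 10000L, seed = 20170331L,
                                   burn_in = 0L, batches = 50L,
                                   method = "auto") {
  mode <- match.arg(mode)
  cats <- ad_categories()
  missing <- setdiff(names(cats), node_names(network))
  if (length(missing)) {
    stop("network is missing category node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (mode == "exact") {
    p <- vapply(names(cats), function(q) {
      exact_marginal(network, ev, q, method = method)
    }, numeric(1L))
    out <- data.frame(category = names(cats), label = unname(cats),
                      probability = unname(p), stringsAsFactors = FALSE)
  } else {
    chain <- sample_posterior(network, ev, iterations = iterations,
                              seed = seed, burn_in = burn_in,
                              monitor = names(cats))
    s <- posterior_summary(chain, batches = batches)
    out <- data.frame(category = names(cats), label = unname(cats),
                      probability = mean_to_probability(s$mean),
                      mean = s$mean, sd = s$sd, mc_error = s$mc_error,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("bn_category_report", "data.frame")
  out
}

#' @export
print.bn_category_report <- function(x, digits = 4, ...) {
  cat("Alzheimer's disease category probabilities\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
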