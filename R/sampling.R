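#' Posterior sampling for a discrete network
#'
#' Draws a chain of network states conditional on the evidence.  When the
#' evidence is *ancestral-closed* (every ancestor of an observed node is
#' itself observed - true whenever only root nodes are clamped, as in all
#' bundled case studies) the sampler draws each free node after its parents
#' in topological order, which yields independent joint samples.  Otherwise
#' a single-site Gibbs sampler resamples each free stochastic node from its
#' full conditional; deterministic max nodes are recomputed every sweep.
#'
#' Each node consumes its own deterministically derived substream of the
#' root seed, so adding or removing monitored nodes does not perturb the
#' draws of the others.
#'
#' @param network a valid [bn_network()].
#' @param ev an [evidence()] object.
#' @param iterations number of retained sweeps (> 0).
#' @param seed integer root seed.
#' @param burn_in sweeps discarded before retention (default 0; ancestral
#'   draws are independent so burn-in is unnecessary there).
#' @param sampler `"auto"` (default), `"ancestral"`, or `"gibbs"`.
#' @param monitor node names to record (default: all nodes).
#' @return an object of class `bn_chain`: a list with `states` (an
#'   `iterations` x `length(monitor)` integer matrix of 1/2 states),
#'   `iterations`, `seed`, `burn_in`, `sampler`, `monitor`.
#' @export
sample_posterior <- function(network, ev = evidence(), iterations = 10000L,
                             seed = 20170331L, burn_in = 0L,
                             sampler = c("auto", "ancestral", "gibbs"),
                             monitor = NULL) {
  sampler <- match.arg(sampler)
  stop_on_diagnostics(network)
  check_evidence(network, ev)
  if (!is.numeric(iterations) || iterations <= 0) {
    stop("iterations must be a positive count", call. = FALSE)
  }
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  order <- topological_order(network)
  if (is.null(monitor)) monitor <- order
  unknown <- setdiff(monitor, order)
  if (length(unknown)) {
    stop("unknown monitored node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  closed <- evidence_is_ancestral_closed(network, ev, order)
  if (sampler == "auto") sampler <- if (closed) "ancestral" else "gibbs"
  if (sampler == "ancestral" && !closed) {
    stop("ancestral sampling requires ancestral-closed evidence; ",
         "use sampler = \"gibbs\"", call. = FALSE)
  }
  states <- switch(sampler,
    ancestral = sample_ancestral(network, ev, iterations + burn_in, seed, order),
    gibbs = sample_gibbs(network, ev, iterations + burn_in, seed, order)
  )
  if (burn_in > 0L) states <- states[-seq_len(burn_in), , drop = FALSE]
  structure(
    list(states = states[, monitor, drop = FALSE], iterations = iterations,
         seed = as.integer(seed), burn_in = burn_in, sampler = sampler,
         monitor = monitor),
    class = "bn_chain"
  )
}

#' @export
print.bn_chain <- function(x, ...) {
  cat("<bn_chain> ", x$iterations, " iterations (", x$sampler,
      " sampler, seed ", x$seed, ", burn-in ", x$burn_in, "), ",
      length(x$monitor), " monitored node(s)\n", sep = "")
  invisible(x)
}

evidence_is_ancestral_closed <- function(network, ev, order) {
  if (length(ev) == 0L) return(TRUE)
  anc <- list()
  for (nm in order) {
    deps <- node_deps(network$nodes[[nm]])
    anc[[nm]] <- unique(c(deps, unlist(anc[deps], use.names = FALSE)))
  }
  all(vapply(names(ev), function(v) all(anc[[v]] %in% names(ev)),
             logical(1L)))
}

# deterministic per-node substream: a polynomial hash of the node name mixed
# into the root seed; all arithmetic stays exact in doubles (< 2^53)
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1009871
  s <- (as.double(seed) %% 2147483647) * 69069 + h   # < 2^53, exact
  as.integer(s %% 2147483647)
}

node_uniforms <- function(seed, name, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, name))
  stats::runif(n)
}

sample_ancestral <- function(network, ev, n, seed, order) {
  states <- matrix(0L, nrow = n, ncol = length(order),
                   dimnames = list(NULL, order))
  for (nm in order) {
    node <- network$nodes[[nm]]
    if (nm %in% names(ev)) {
      states[, nm] <- ev[[nm]]
    } else if (node$kind == "stochastic") {
      p2 <- cpt_prob(node$cpt, states[, node$parents, drop = FALSE], 2L)
      u <- node_uniforms(seed, nm, n)
      states[, nm] <- 1L + (u < p2)
    } else {
      cols <- states[, node$members, drop = FALSE]
      states[, nm] <- do.call(pmax, as.data.frame(cols))
    }
  }
  states
}

sample_gibbs <- function(network, ev, n, seed, order) {
  stoch <- stochastic_names(network)
  free <- order[order %in% setdiff(stoch, names(ev))]
  det <- order[!(order %in% stoch)]
  # stochastic children indexed by parent, for the full conditionals
  children <- stats::setNames(vector("list", length(order)), order)
  for (nm in stoch) {
    for (p in network$nodes[[nm]]$parents) {
      children[[p]] <- c(children[[p]], nm)
    }
  }
  # initial state: one forward draw (evidence overwritten afterwards)
  cur <- sample_ancestral(network, evidence(), 1L, stream_seed(seed, ".init"),
                          order)[1L, ]
  for (v in names(ev)) cur[v] <- ev[[v]]
  u <- vapply(free, function(nm) node_uniforms(seed, nm, n), numeric(n))
  states <- matrix(0L, nrow = n, ncol = length(order),
                   dimnames = list(NULL, order))
  for (t in seq_len(n)) {
    for (j in seq_along(free)) {
      nm <- free[j]
      node <- network$nodes[[nm]]
      w <- numeric(2L)
      for (k in 1:2) {
        cur[nm] <- k
        p <- cpt_prob(node$cpt, cur[node$parents], k)
        for (ch in children[[nm]]) {
          chn <- network$nodes[[ch]]
          p <- p * cpt_prob(chn$cpt, cur[chn$parents], cur[[ch]])
          if (p == 0) break
        }
        w[k] <- p
      }
      if (sum(w) == 0) stop("impossible evidence", call. = FALSE)
      cur[nm] <- 1L + (u[t, j] < w[2L] / sum(w))
    }
    for (nm in det) {
      cur[nm] <- max(cur[network$nodes[[nm]]$members])
    }
    states[t, ] <- cur
  }
  states
}

#' WinBUGS-style posterior summary of a chain
#'
#' For each monitored node reports the sample mean of the 1/2 state codes,
#' the population standard deviation, and the batch-means Monte Carlo error:
#' the chain is cut into `batches` consecutive batches of
#' `floor(iterations / batches)` draws (any remainder is dropped) and the
#' MC error is the standard deviation of the batch means divided by
#' `sqrt(batches)`.
#'
#' @param chain a [sample_posterior()] result.
#' @param batches number of batches (>= 2, default 50).
#' @return a data frame of class `bn_posterior` with columns `node`,
#'   `mean`, `sd`, `mc_error`, `iterations`.
#' @export
posterior_summary <- function(chain, batches = 50L) {
  stopifnot(inherits(chain, "bn_chain"))
  x <- chain$states
  n <- nrow(x)
  if (is.null(x) || n == 0L) stop("empty chain", call. = FALSE)
  if (!is.numeric(batches) || batches < 2L) {
    stop("batches must be at least 2", call. = FALSE)
  }
  batches <- as.integer(batches)
  bsize <- n %/% batches
  if (bsize < 1L) {
    stop("chain too short: ", n, " iterations cannot fill ", batches,
         " batches", call. = FALSE)
  }
  m <- colMeans(x)
  sdev <- sqrt(colMeans(x^2) - m^2)  # population (divide-by-n) convention
  used <- bsize * batches
  mc <- vapply(seq_len(ncol(x)), function(j) {
    bm <- colMeans(matrix(x[seq_len(used), j], nrow = bsize, ncol = batches))
    stats::sd(bm) / sqrt(batches)
  }, numeric(1L))
  out <- data.frame(node = colnames(x), mean = unname(m), sd = unname(sdev),
                    mc_error = mc, iterations = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bn_posterior", "data.frame")
  out
}

#' @export
summary.bn_chain <- function(object, batches = 50L, ...) {
  posterior_summary(object, batches = batches)
}

#' @export
print.bn_posterior <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
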