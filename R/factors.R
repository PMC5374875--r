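# Internal factor algebra over binary variables (states 1/2).
# A factor is list(vars = character k, values = array dim rep(2, k));
# a scalar factor has vars = character(0) and a length-1 values vector.

f_new <- function(vars, values) {
  vars <- as.character(vars)
  if (length(vars) == 0L) {
    return(list(vars = character(), values = as.numeric(values)[1L]))
  }
  list(vars = vars, values = array(as.numeric(values), dim = rep(2L, length(vars))))
}

# condition on var = state, dropping the axis
f_reduce <- function(f, var, state) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  n <- length(f$vars)
  idx <- rep(list(TRUE), n)
  idx[[k]] <- state
  vals <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  f_new(f$vars[-k], as.vector(vals))
}

# sum out one variable
f_marginalize <- function(f, var) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  a <- f_reduce(f, var, 1L)
  b <- f_reduce(f, var, 2L)
  f_new(a$vars, a$values + b$values)
}

f_multiply <- function(f, g) {
  if (length(f$vars) == 0L) return(f_new(g$vars, g$values * f$values))
  if (length(g$vars) == 0L) return(f_new(f$vars, f$values * g$values))
  u <- union(f$vars, g$vars)
  grid <- as.matrix(expand.grid(rep(list(1:2), length(u)), KEEP.OUT.ATTRS = FALSE))
  fv <- f$values[grid[, match(f$vars, u), drop = FALSE]]
  gv <- g$values[grid[, match(g$vars, u), drop = FALSE]]
  f_new(u, fv * gv)
}

f_product <- function(factors) {
  Reduce(f_multiply, factors, f_new(character(), 1))
}

# indicator factor of node = max(members); vars = c(members, node).
# Repeated members are allowed (max is idempotent).
f_max_indicator <- function(members, node) {
  u <- unique(members)
  vars <- c(u, node)
  grid <- as.matrix(expand.grid(rep(list(1:2), length(vars)), KEEP.OUT.ATTRS = FALSE))
  m <- grid[, seq_along(u), drop = FALSE]
  ok <- grid[, length(vars)] == apply(m, 1L, max)
  f_new(vars, as.numeric(ok))
}

# Factor representation of a network conditioned on evidence.
# Factors whose scope becomes empty under the evidence are dropped: their
# value is constant in the free variables, so it cancels between numerator
# and denominator of any conditional query.  This matches the Gibbs-sampler
# semantics of observed nodes (which are never resampled and whose constant
# likelihood never enters a free node's full conditional) and tolerates the
# common BUGS practice of clamping a root to a state its own prior excludes.
network_factors <- function(network, ev = evidence()) {
  factors <- list()
  for (node in network$nodes) {
    f <- if (node$kind == "stochastic") {
      f_new(c(node$parents, node$name), as.vector(unclass(node$cpt)))
    } else {
      f_max_indicator(node$members, node$name)
    }
    for (v in intersect(names(ev), f$vars)) {
      f <- f_reduce(f, v, ev[[v]])
    }
    if (length(f$vars) > 0L) factors[[length(factors) + 1L]] <- f
  }
  factors
}

# Sum out `elim_vars` from `factors` (min-degree greedy ordering), keeping
# `keep` variables.  Returns a single factor over (a subset of) `keep`.
ve_eliminate <- function(factors, keep) {
  all_vars <- unique(unlist(lapply(factors, `[[`, "vars")))
  elim <- setdiff(all_vars, keep)
  while (length(elim)) {
    # degree of a candidate = size of the union scope of the factors touching it
    deg <- vapply(elim, function(v) {
      touch <- vapply(factors, function(f) v %in% f$vars, logical(1L))
      length(unique(unlist(lapply(factors[touch], `[[`, "vars"))))
    }, numeric(1L))
    v <- elim[order(deg, elim, method = "radix")][1L]
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1L))
    prod_f <- f_product(factors[touch])
    factors <- c(factors[!touch], list(f_marginalize(prod_f, v)))
    elim <- setdiff(elim, v)
  }
  f_product(factors)
}
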