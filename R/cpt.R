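#' Conditional probability table for a binary node
#'
#' Builds the CPT of a binary (absent/present) node from a numeric vector or
#' array.  States are coded 1 = absent/False and 2 = present/True, matching
#' the BUGS `dcat` convention, so a category's probability of being present
#' equals its posterior mean minus 1.  The outcome is the *last* axis; parent
#' axes precede it in the declared parent order, mirroring the
#' `p.Node[parent, 1:2]` indexing of BUGS data lists.
#'
#' @param values numeric vector of length 2 (root node) or array with all
#'   extents equal to 2; the last axis is the node's own state.
#' @param n_parents expected number of parents; checked against the shape
#'   when supplied.
#' @return an object of class `bn_cpt` (a numeric array).
#' @examples
#' cpt(c(0.884, 0.116))                      # root prior: P(True) = 0.116
#' cpt(array(c(1, 1, 0, 0), c(2, 2)))        # one parent, always False
#' @export
cpt <- function(values, n_parents = NULL) {
  if (!is.numeric(values)) {
    stop("CPT values must be numeric", call. = FALSE)
  }
  if (is.null(dim(values))) {
    if (length(values) != 2L) {
      stop("only binary nodes are supported: a root CPT must have exactly ",
           "2 entries, got ", length(values), call. = FALSE)
    }
    values <- array(as.numeric(values), dim = 2L)
  }
  d <- dim(values)
  if (any(d != 2L)) {
    stop("only binary nodes are supported: every CPT axis must have extent ",
         "2, got (", paste(d, collapse = ","), ")", call. = FALSE)
  }
  if (!is.null(n_parents) && length(d) != n_parents + 1L) {
    stop("CPT dimension mismatch: expected ", n_parents + 1L,
         " axes (", n_parents, " parent(s) + outcome), got ", length(d),
         call. = FALSE)
  }
  structure(array(as.numeric(values), dim = d), class = "bn_cpt")
}

#' @export
print.bn_cpt <- function(x, ...) {
  k <- length(dim(x)) - 1L
  cat("<bn_cpt> ", k, " parent(s); rows = P(False), P(True)\n", sep = "")
  print(cpt_rows(x))
  invisible(x)
}

# CPT as a (parent-combination x outcome) matrix; parent combinations are
# enumerated with the FIRST parent varying slowest (row-major reading order).
cpt_rows <- function(x) {
  d <- dim(x)
  k <- length(d) - 1L
  if (k == 0L) {
    m <- matrix(as.numeric(x), nrow = 1L)
    rownames(m) <- ""
  } else {
    flat <- as.vector(aperm(unclass(x), c(rev(seq_len(k)), k + 1L)))
    m <- matrix(flat, ncol = 2L)
    combos <- as.matrix(expand.grid(rep(list(1:2), k)))[, seq_len(k), drop = FALSE]
    rownames(m) <- apply(combos, 1L, paste, collapse = ",")
  }
  colnames(m) <- c("False", "True")
  m
}

n_parents_cpt <- function(x) length(dim(x)) - 1L

as_cpt <- function(x, n_parents = NULL) {
  if (inherits(x, "bn_cpt")) {
    if (!is.null(n_parents) && n_parents_cpt(x) != n_parents) {
      stop("CPT dimension mismatch: expected ", n_parents,
           " parent axis/axes, got ", n_parents_cpt(x), call. = FALSE)
    }
    x
  } else {
    cpt(x, n_parents = n_parents)
  }
}

# P(node = state | parents = pa_states) for one or many assignments.
# pa_states: integer matrix (rows = draws, cols = parents in declared order)
# or a plain vector for a single assignment.
cpt_prob <- function(x, pa_states, state) {
  k <- n_parents_cpt(x)
  if (k == 0L) {
    return(as.numeric(unclass(x)[state]))
  }
  if (is.null(dim(pa_states))) pa_states <- matrix(pa_states, nrow = 1L)
  idx <- cbind(pa_states, state)
  as.numeric(unclass(x)[idx])
}
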