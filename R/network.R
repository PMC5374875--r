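#' Nodes of a discrete Bayesian network
#'
#' Two node kinds are supported, mirroring the BUGS formulation of
#' diagnostic networks: *stochastic* nodes drawn from a categorical
#' distribution (`dcat`) conditional on their parents, and *deterministic
#' max* nodes whose state is the maximum of their members' states - a
#' logical OR under the 1 = False / 2 = True coding.  Deterministic nodes
#' are read-outs: they may aggregate other deterministic nodes, but must
#' never appear as parents of stochastic nodes.
#'
#' @param name node name (unique within a network).
#' @param cpt a [cpt()] (or values coercible by it) whose parent axes follow
#'   the order of `parents`.
#' @param parents character vector of parent node names (stochastic nodes).
#' @param members character vector of member node names (max nodes).
#' @param param optional data-list parameter slot this node's CPT binds to
#'   (defaults to `name`); see [bind_parameters()].
#' @return an object of class `bn_node`.
#' @examples
#' bn_stochastic("LewyBodies", parents = "Age_Inheritance",
#'               cpt = cpt(array(c(0.884, 0.884, 0.116, 0.116), c(2, 2))))
#' bn_max("ADdementia", members = c("Ab", "Vascular"))
#' @export
bn_stochastic <- function(name, cpt = NULL, parents = character(), param = name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(cpt)) cpt <- as_cpt(cpt)
  structure(
    list(name = name, kind = "stochastic", parents = as.character(parents),
         cpt = cpt, members = NULL, param = param),
    class = "bn_node"
  )
}

#' @rdname bn_stochastic
#' @export
bn_max <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(
    list(name = name, kind = "deterministic_max", parents = character(),
         cpt = NULL, members = as.character(members), param = name),
    class = "bn_node"
  )
}

#' @export
print.bn_node <- function(x, ...) {
  if (x$kind == "stochastic") {
    cat("<bn_node> ", x$name, " ~ dcat(",
        if (length(x$parents)) paste(x$parents, collapse = ", ") else "",
        ")\n", sep = "")
  } else {
    cat("<bn_node> ", x$name, " <- max(",
        paste(x$members, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Assemble a discrete Bayesian network
#'
#' @param ... `bn_node` objects, or a single list of them.
#' @return an object of class `bn_network`: a named list of nodes.  The
#'   network is *not* validated on construction so that [validate_network()]
#'   can report problems as diagnostics; inference functions validate first.
#' @examples
#' net <- bn_network(
#'   bn_stochastic("A", cpt(c(0.76, 0.24))),
#'   bn_stochastic("B", cpt(array(c(1, 0.5, 0, 0.5), c(2, 2))), parents = "A")
#' )
#' topological_order(net)
#' @export
bn_network <- function(...) {
  nodes <- list(...)
  if (length(nodes) == 1L && !inherits(nodes[[1L]], "bn_node")) {
    nodes <- nodes[[1L]]
  }
  ok <- vapply(nodes, inherits, logical(1L), what = "bn_node")
  if (!all(ok)) stop("all arguments must be bn_node objects", call. = FALSE)
  nms <- vapply(nodes, `[[`, character(1L), "name")
  names(nodes) <- nms          # duplicates reported by validate_network()
  structure(list(nodes = nodes), class = "bn_network")
}

#' @export
print.bn_network <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, character(1L), "kind")
  cat("<bn_network> ", length(x$nodes), " nodes (",
      sum(kinds == "stochastic"), " stochastic, ",
      sum(kinds == "deterministic_max"), " deterministic max)\n", sep = "")
  invisible(x)
}

node_names <- function(network) {
  vapply(network$nodes, `[[`, character(1L), "name")
}

stochastic_names <- function(network) {
  nm <- node_names(network)
  nm[vapply(network$nodes, `[[`, character(1L), "kind") == "stochastic"]
}

deterministic_names <- function(network) {
  setdiff(node_names(network), stochastic_names(network))
}

# dependencies (parents or members) of a node
node_deps <- function(node) {
  if (node$kind == "stochastic") node$parents else node$members
}

#' Validate a network
#'
#' Checks every structural and numerical invariant of the data model and
#' returns one human-readable diagnostic per violation instead of throwing:
#' duplicate names, dangling parent/member references, cycles, CPTs of the
#' wrong dimensionality, probabilities outside \[0,1\], rows not summing to
#' one (tolerance 1e-9), all-zero rows, max nodes without members, and
#' deterministic nodes used as parents of stochastic nodes.
#'
#' @param network a [bn_network()].
#' @return character vector of diagnostics; empty when the network is valid.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "bn_network"))
  diags <- character()
  nms <- node_names(network)
  dup <- unique(nms[duplicated(nms)])
  for (d in dup) diags <- c(diags, paste0("duplicate name: node '", d,
                                          "' declared more than once"))
  det <- deterministic_names(network)
  for (node in network$nodes) {
    deps <- node_deps(node)
    missing <- setdiff(deps, nms)
    for (m in missing) {
      diags <- c(diags, paste0("dangling reference: node '", node$name,
                               "' refers to undeclared node '", m, "'"))
    }
    if (node$kind == "stochastic") {
      bad_par <- intersect(node$parents, det)
      for (b in bad_par) {
        diags <- c(diags, paste0("deterministic parent: stochastic node '",
                                 node$name, "' has deterministic node '", b,
                                 "' as a parent (deterministic nodes are read-outs)"))
      }
      if (is.null(node$cpt)) {
        diags <- c(diags, paste0("missing CPT: stochastic node '",
                                 node$name, "' has no CPT"))
      } else {
        k <- n_parents_cpt(node$cpt)
        if (k != length(node$parents)) {
          diags <- c(diags, paste0("CPT dimension mismatch: node '", node$name,
                                   "' declares ", length(node$parents),
                                   " parent(s) but its CPT has ", k,
                                   " parent axis/axes"))
        } else {
          diags <- c(diags, check_cpt_rows(node))
        }
      }
    } else {
      if (length(node$members) < 1L) {
        diags <- c(diags, paste0("empty aggregator: max node '", node$name,
                                 "' has no members"))
      }
      if (!is.null(node$cpt)) {
        diags <- c(diags, paste0("unexpected CPT: max node '", node$name,
                                 "' must not carry a CPT"))
      }
    }
  }
  # cycle detection on the declared-dependency graph (restricted to
  # declared nodes so dangling references do not mask it)
  ord <- try(topological_order(network, strict = FALSE), silent = TRUE)
  if (inherits(ord, "try-error")) {
    diags <- c(diags, "cycle: the dependency graph is not acyclic")
  }
  diags
}

check_cpt_rows <- function(node) {
  diags <- character()
  rows <- cpt_rows(node$cpt)
  vals <- as.numeric(rows)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    diags <- c(diags, paste0("probability out of range: node '", node$name,
                             "' has CPT entries outside [0,1]"))
  }
  s <- rowSums(rows)
  bad <- which(is.finite(s) & abs(s - 1) > 1e-9)
  for (b in bad) {
    if (s[b] == 0) next  # reported as the more specific all-zero diagnostic
    diags <- c(diags, paste0("unnormalized row: node '", node$name,
                             "' parent combination (", rownames(rows)[b],
                             ") sums to ", format(s[b])))
  }
  zero <- which(rowSums(rows == 0) == 2L)
  for (z in zero) {
    diags <- c(diags, paste0("all-zero row: node '", node$name,
                             "' parent combination (", rownames(rows)[z],
                             ") assigns probability 0 to both states"))
  }
  diags
}

#' Topological order of a network
#'
#' Kahn's algorithm with a deterministic tie-break: among the nodes whose
#' dependencies are all placed, the lexicographically smallest name (C
#' locale) goes next, so the order is reproducible across platforms.
#'
#' @param network a [bn_network()].
#' @param strict validate first and stop on any diagnostic (default `TRUE`).
#' @return character vector of node names; every node appears after all of
#'   its parents/members.
#' @export
topological_order <- function(network, strict = TRUE) {
  stopifnot(inherits(network, "bn_network"))
  if (strict) stop_on_diagnostics(network)
  nms <- unique(node_names(network))
  deps <- lapply(network$nodes[!duplicated(node_names(network))], function(n) {
    intersect(node_deps(n), nms)
  })
  names(deps) <- nms
  placed <- character()
  remaining <- nms
  while (length(remaining)) {
    ready <- remaining[vapply(deps[remaining], function(d) {
      all(d %in% placed)
    }, logical(1L))]
    if (!length(ready)) {
      stop("cycle detected among nodes: ",
           paste(sort(remaining, method = "radix"), collapse = ", "),
           call. = FALSE)
    }
    nxt <- sort(ready, method = "radix")[1L]
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  placed
}

stop_on_diagnostics <- function(network) {
  diags <- validate_network(network)
  if (length(diags)) {
    stop("invalid network:\n  - ", paste(diags, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(network)
}

#' Joint probability of a complete assignment
#'
#' Computes \eqn{P(N) = \prod_{n \in N} p(n \mid pa(n))} over the stochastic
#' nodes.  A deterministic max node contributes factor 1 when its state
#' equals the maximum of its members' states and 0 otherwise, so assignments
#' inconsistent with the aggregators have probability 0.
#'
#' @param network a valid [bn_network()].
#' @param assignment named integer vector (states 1 or 2) covering every
#'   node in the network.
#' @return the joint probability, a number in \[0,1\].
#' @export
joint_probability <- function(network, assignment) {
  stop_on_diagnostics(network)
  nms <- node_names(network)
  missing <- setdiff(nms, names(assignment))
  if (length(missing)) {
    stop("incomplete assignment: missing state(s) for ",
         paste(sort(missing, method = "radix"), collapse = ", "),
         call. = FALSE)
  }
  st <- assignment[nms]
  if (!all(st %in% c(1L, 2L))) {
    stop("assignment states must be 1 (False) or 2 (True)", call. = FALSE)
  }
  p <- 1
  for (node in network$nodes) {
    x <- st[[node$name]]
    if (node$kind == "stochastic") {
      p <- p * cpt_prob(node$cpt, unlist(st[node$parents], use.names = FALSE), x)
    } else {
      if (x != max(unlist(st[node$members]))) return(0)
    }
    if (p == 0) return(0)
  }
  p
}

#' Evidence: clamped node states
#'
#' @param ... named states (`Age_Inheritance = 2, ...`) or a single named
#'   vector/list.
#' @return a named integer vector of class `bn_evidence`.
#' @export
evidence <- function(...) {
  ev <- c(...)
  if (length(ev) == 0L) {
    return(structure(integer(), class = "bn_evidence"))
  }
  if (is.list(ev)) ev <- unlist(ev)
  if (is.null(names(ev)) || any(names(ev) == "")) {
    stop("evidence entries must be named", call. = FALSE)
  }
  if (!all(ev %in% c(1, 2))) {
    stop("evidence states must be 1 (False) or 2 (True); got ",
         paste(ev[!ev %in% c(1, 2)], collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(as.integer(ev), names(ev)), class = "bn_evidence")
}

check_evidence <- function(network, ev) {
  if (length(ev) == 0L) return(invisible(ev))
  nms <- node_names(network)
  unknown <- setdiff(names(ev), nms)
  if (length(unknown)) {
    stop("evidence refers to unknown node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  nonstoch <- setdiff(names(ev), stochastic_names(network))
  if (length(nonstoch)) {
    stop("evidence may only clamp stochastic nodes; deterministic: ",
         paste(nonstoch, collapse = ", "), call. = FALSE)
  }
  invisible(ev)
}
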