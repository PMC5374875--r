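#' Read a network structure configuration
#'
#' User-defined networks are declared as a YAML (or JSON, a YAML subset)
#' document listing the nodes:
#'
#' ```yaml
#' nodes:
#'   - name: Exposure
#'     kind: stochastic
#'     parents: []
#'   - name: Lesion
#'     kind: stochastic
#'     parents: [Exposure]
#'   - name: Risk
#'     kind: deterministic_max
#'     members: [Exposure, Lesion]
#' ```
#'
#' Structure and parameters are deliberately separate: the CPTs arrive via
#' a data-list document (`p.<name>` entries) bound with
#' [bind_parameters()].  A stochastic node may carry an optional `param`
#' key when its parameter-table name differs from the node name.
#'
#' @param source path to a config file, or the document text itself.
#' @return a [bn_network()] template (stochastic nodes carry `NULL` CPTs).
#' @export
read_network_config <- function(source) {
  text <- if (length(source) == 1L && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  conf <- tryCatch(yaml::yaml.load(text), error = function(e) {
    stop("malformed network config: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(conf) || is.null(conf$nodes)) {
    stop("network config must have a top-level 'nodes' list", call. = FALSE)
  }
  nodes <- lapply(conf$nodes, function(spec) {
    if (is.null(spec$name)) {
      stop("every config node needs a 'name'", call. = FALSE)
    }
    kind <- if (is.null(spec$kind)) "stochastic" else spec$kind
    if (kind == "stochastic") {
      bn_stochastic(spec$name, cpt = NULL,
                    parents = as.character(unlist(spec$parents)),
                    param = if (is.null(spec$param)) spec$name else spec$param)
    } else if (kind == "deterministic_max") {
      bn_max(spec$name, members = as.character(unlist(spec$members)))
    } else {
      stop("unknown node kind '", kind, "' for node '", spec$name, "'",
           call. = FALSE)
    }
  })
  bn_network(nodes)
}

#' Write a network structure configuration
#'
#' @param network a [bn_network()].
#' @param path optional output file.
#' @return the YAML text (invisibly when `path` is given).
#' @export
write_network_config <- function(network, path = NULL) {
  stopifnot(inherits(network, "bn_network"))
  nodes <- lapply(network$nodes, function(n) {
    if (n$kind == "stochastic") {
      spec <- list(name = n$name, kind = "stochastic",
                   parents = as.list(n$parents))
      if (!identical(n$param, n$name)) spec$param <- n$param
      spec
    } else {
      list(name = n$name, kind = "deterministic_max",
           members = as.list(n$members))
    }
  })
  text <- yaml::as.yaml(list(nodes = unname(nodes)))
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Attach bound CPTs to a structural template
#'
#' @param network a [bn_network()] template.
#' @param params named list of CPTs keyed by parameter slot, e.g. from
#'   [bind_parameters()].
#' @return the network with CPTs attached to its stochastic nodes.
#' @export
set_network_cpts <- function(network, params) {
  stopifnot(inherits(network, "bn_network"))
  names(params) <- gsub("-", "_", names(params), fixed = TRUE)
  for (nm in node_names(network)) {
    node <- network$nodes[[nm]]
    if (node$kind != "stochastic") next
    slot <- gsub("-", "_", node$param, fixed = TRUE)
    if (!is.null(params[[slot]])) {
      network$nodes[[nm]]$cpt <- as_cpt(params[[slot]],
                                        n_parents = length(node$parents))
    }
  }
  network
}
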