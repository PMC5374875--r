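#' Parse a WinBUGS-style data list
#'
#' Reads the `list(name = value, name = c(...), name = structure(.Data =
#' c(...), .Dim = c(...)))` documents WinBUGS uses to supply constants,
#' parameters and observations.  Whitespace and newlines are arbitrary and
#' trailing commas are tolerated.  Array values fill the declared
#' dimensions in ROW-MAJOR order (last index varies fastest) - the
#' WinBUGS/S-plus convention, *not* R's column-major one.  So
#' `.Data = c(1,2,3,4), .Dim = c(2,2)` yields `x[1,1] = 1`, `x[1,2] = 2`,
#' `x[2,1] = 3`, `x[2,2] = 4`.
#'
#' @param text the document as a single string or character vector of lines.
#' @return an object of class `bn_datalist`: a list with `scalars` (named
#'   numeric vector), `vectors` (named list of numeric vectors) and
#'   `arrays` (named list of `list(data = <row-major values>, dim =
#'   <extents>)`).
#' @examples
#' doc <- parse_data_list("list(MetalIons = 2, p.MetalIons = c(0.76, 0.24))")
#' doc$scalars
#' @export
parse_data_list <- function(text) {
  text <- paste(text, collapse = "\n")
  text <- gsub(",(\\s*)\\)", "\\1)", text)  # tolerate trailing commas
  exprs <- tryCatch(
    parse(text = text, keep.source = TRUE),
    error = function(e) {
      stop("malformed data list: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(exprs) != 1L) {
    stop("malformed data list: expected a single list(...) expression, got ",
         length(exprs), call. = FALSE)
  }
  e <- exprs[[1L]]
  if (!is.call(e) || !identical(e[[1L]], as.name("list"))) {
    stop("malformed data list: the document must be a single list(...) call",
         call. = FALSE)
  }
  args <- as.list(e)[-1L]
  nms <- names(args)
  if (length(args) && (is.null(nms) || any(nms == ""))) {
    stop("malformed data list: every entry must be named", call. = FALSE)
  }
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    stop("duplicate entry name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  doc <- list(scalars = stats::setNames(numeric(), character()),
              vectors = list(), arrays = list())
  for (i in seq_along(args)) {
    val <- args[[i]]
    nm <- nms[i]
    if (is_structure_call(val)) {
      doc$arrays[[nm]] <- eval_structure(val, nm)
    } else if (is.call(val) && identical(val[[1L]], as.name("c"))) {
      doc$vectors[[nm]] <- eval_numeric(val, nm)
    } else {
      v <- eval_numeric(val, nm)
      if (length(v) != 1L) {
        stop("entry '", nm, "': expected a scalar", call. = FALSE)
      }
      doc$scalars[nm] <- v
    }
  }
  structure(doc, class = "bn_datalist")
}

is_structure_call <- function(x) {
  is.call(x) && identical(x[[1L]], as.name("structure"))
}

# numbers, unary +/- and c(...) of those; anything else is rejected
eval_numeric <- function(x, nm) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.call(x)) {
    op <- x[[1L]]
    if (identical(op, as.name("-")) && length(x) == 2L) {
      return(-eval_numeric(x[[2L]], nm))
    }
    if (identical(op, as.name("+")) && length(x) == 2L) {
      return(eval_numeric(x[[2L]], nm))
    }
    if (identical(op, as.name("c"))) {
      parts <- as.list(x)[-1L]
      return(unlist(lapply(parts, eval_numeric, nm = nm), use.names = FALSE))
    }
  }
  stop("entry '", nm, "': only numbers and c(...) are allowed, found '",
       paste(deparse(x), collapse = " "), "'", call. = FALSE)
}

eval_structure <- function(x, nm) {
  args <- as.list(x)[-1L]
  if (is.null(names(args)) || !all(c(".Data", ".Dim") %in% names(args))) {
    stop("entry '", nm,
         "': structure(...) needs .Data and .Dim arguments", call. = FALSE)
  }
  data <- eval_numeric(args[[".Data"]], nm)
  dims <- eval_numeric(args[[".Dim"]], nm)
  if (any(dims != as.integer(dims)) || any(dims < 1)) {
    stop("entry '", nm, "': .Dim must be positive integers", call. = FALSE)
  }
  dims <- as.integer(dims)
  if (length(data) != prod(dims)) {
    stop("entry '", nm, "': .Data has ", length(data),
         " values but .Dim = c(", paste(dims, collapse = ","),
         ") requires ", prod(dims), call. = FALSE)
  }
  list(data = data, dim = dims)
}

#' @export
print.bn_datalist <- function(x, ...) {
  cat("<bn_datalist> ", length(x$scalars), " scalar(s), ",
      length(x$vectors), " vector(s), ", length(x$arrays), " array(s)\n",
      sep = "")
  invisible(x)
}

#' Materialize a data-list array as an R array (row-major fill)
#'
#' @param entry an element of the `arrays` field of a [parse_data_list()]
#'   document.
#' @return an R array with the declared extents, filled so that the last
#'   index varies fastest over the flat `.Data` values.
#' @export
datalist_array <- function(entry) {
  d <- entry$dim
  if (length(d) == 1L) return(array(entry$data, dim = d))
  aperm(array(entry$data, dim = rev(d)), rev(seq_along(d)))
}

# inverse of datalist_array(): flatten an R array in row-major order
row_major_flatten <- function(a) {
  d <- dim(a)
  if (is.null(d) || length(d) == 1L) return(as.vector(a))
  as.vector(aperm(a, rev(seq_along(d))))
}

#' Write a data list back to text
#'
#' Produces the normal form `list(name = ..., name = c(...), name =
#' structure(.Data = c(...), .Dim = c(...)))` with one entry per line.
#' Values round-trip exactly: `parse_data_list(write_data_list(doc))`
#' reproduces `doc` bit for bit, and write-parse-write is idempotent on the
#' emitted text.
#'
#' @param doc a [parse_data_list()] document.
#' @param path optional file to write to.
#' @return the document text, invisibly when `path` is given.
#' @export
write_data_list <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "bn_datalist"))
  entries <- character()
  for (nm in names(doc$scalars)) {
    entries <- c(entries, paste0(nm, " = ", fmt_num(doc$scalars[[nm]])))
  }
  for (nm in names(doc$vectors)) {
    entries <- c(entries, paste0(nm, " = c(",
                                 paste(fmt_num(doc$vectors[[nm]]),
                                       collapse = ", "), ")"))
  }
  for (nm in names(doc$arrays)) {
    a <- doc$arrays[[nm]]
    entries <- c(entries, paste0(
      nm, " = structure(.Data = c(",
      paste(fmt_num(a$data), collapse = ", "),
      "), .Dim = c(", paste(a$dim, collapse = ","), "))"))
  }
  text <- if (length(entries)) {
    paste0("list(\n  ", paste(entries, collapse = ",\n  "), "\n)")
  } else {
    "list()"
  }
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

# shortest decimal representation that parses back to the identical double
fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- as.character(v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1L))
}

#' Read a data-list file
#'
#' @param path file containing a single `list(...)` document.
#' @return a [parse_data_list()] document.
#' @export
read_data_list <- function(path) {
  parse_data_list(readLines(path, warn = FALSE))
}

#' Bind a data list to a network template
#'
#' Matches the document's entries to a network: `p.`-prefixed vectors and
#' arrays become CPTs for the node whose parameter slot has that name, and
#' bare scalar assignments become clamped evidence (the WinBUGS reading of
#' data-list entries as observations).  Hyphens and underscores in names
#' are treated as equivalent (the published model mixes `PS1-2`/`PS1_2`).
#'
#' @param doc a [parse_data_list()] document.
#' @param network a [bn_network()]; its stochastic nodes may carry `NULL`
#'   CPTs (a structural template) or existing ones (to be replaced).
#' @return `list(params = <named list of [cpt()] keyed by parameter slot>,
#'   evidence = <[evidence()]>)`.
#' @export
bind_parameters <- function(doc, network) {
  stopifnot(inherits(doc, "bn_datalist"), inherits(network, "bn_network"))
  norm <- function(x) gsub("-", "_", x, fixed = TRUE)
  slots <- vapply(network$nodes, function(n) norm(n$param), character(1L))
  kinds <- vapply(network$nodes, `[[`, character(1L), "kind")
  nparents <- vapply(network$nodes, function(n) length(n$parents), integer(1L))
  nms <- node_names(network)

  params <- list()
  unmatched <- character()

  bind_one <- function(nm, values, dims) {
    slot <- norm(sub("^p\\.", "", nm))
    hit <- which(slots == slot & kinds == "stochastic")
    if (!length(hit)) {
      unmatched <<- c(unmatched, nm)
      return(invisible(NULL))
    }
    k <- nparents[[hit[1L]]]
    if (length(dims) != k + 1L || any(dims != 2L)) {
      stop("entry '", nm, "': node '", nms[[hit[1L]]], "' has ", k,
           " parent(s), expected .Dim = c(", paste(rep(2L, k + 1L),
           collapse = ","), "), got (", paste(dims, collapse = ","), ")",
           call. = FALSE)
    }
    a <- datalist_array(list(data = values, dim = dims))
    params[[sub("^p\\.", "", nm)]] <<- cpt(a, n_parents = k)
  }

  for (nm in names(doc$vectors)) {
    if (grepl("^p\\.", nm)) {
      bind_one(nm, doc$vectors[[nm]], length(doc$vectors[[nm]]))
    } else {
      unmatched <- c(unmatched, nm)
    }
  }
  for (nm in names(doc$arrays)) {
    if (grepl("^p\\.", nm)) {
      bind_one(nm, doc$arrays[[nm]]$data, doc$arrays[[nm]]$dim)
    } else {
      unmatched <- c(unmatched, nm)
    }
  }

  ev_names <- character()
  ev_states <- integer()
  for (nm in names(doc$scalars)) {
    target <- nms[match(norm(nm), norm(nms))]
    if (is.na(target) ||
        network$nodes[[target]]$kind != "stochastic") {
      unmatched <- c(unmatched, nm)
      next
    }
    v <- doc$scalars[[nm]]
    if (!v %in% c(1, 2)) {
      stop("entry '", nm, "': observed state must be 1 or 2 for a binary ",
           "node, got ", v, call. = FALSE)
    }
    ev_names <- c(ev_names, target)
    ev_states <- c(ev_states, as.integer(v))
  }
  if (length(unmatched)) {
    stop("data-list entries with no matching node or parameter slot: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  list(params = params,
       evidence = evidence(stats::setNames(ev_states, ev_names)))
}

#' Write a posterior/category report
#'
#' @param summaries a [posterior_summary()] data frame, or `NULL`.
#' @param categories a [category_probabilities()] report, or `NULL`.
#' @param format `"tsv"` (tab-separated, 4 significant digits, matching the
#'   precision of the published tables) or `"json"` (lossless).
#' @param path optional output file.
#' @return the report text (invisibly when `path` is given).
#' @export
write_report <- function(summaries = NULL, categories = NULL,
                         format = c("tsv", "json"), path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    blocks <- character()
    if (!is.null(summaries)) {
      lines <- c("node\tmean\tsd\tmc_error",
                 sprintf("%s\t%s\t%s\t%s", summaries$node,
                         fmt_sig4(summaries$mean), fmt_sig4(summaries$sd),
                         fmt_sig4(summaries$mc_error)))
      blocks <- c(blocks, paste(lines, collapse = "\n"))
    }
    if (!is.null(categories)) {
      lines <- c("category\tprobability",
                 sprintf("%s\t%s", categories$category,
                         fmt_sig4(categories$probability)))
      blocks <- c(blocks, paste(lines, collapse = "\n"))
    }
    text <- paste(blocks, collapse = "\n\n")
  } else {
    payload <- list()
    if (!is.null(summaries)) payload$summaries <- as.data.frame(summaries)
    if (!is.null(categories)) payload$categories <- as.data.frame(categories)
    text <- as.character(jsonlite::toJSON(payload, dataframe = "rows",
                                          digits = NA, auto_unbox = TRUE,
                                          pretty = TRUE))
  }
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

fmt_sig4 <- function(x) {
  vapply(signif(x, 4), function(v) format(v, scientific = v != 0 && abs(v) < 1e-4),
         character(1L))
}
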