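# Graph representation, degree-class summaries, network statistics and file
# I/O. Graphs are igraph objects: simple (no self-loops, no parallel edges),
# undirected, unweighted. Node labels are opaque strings kept in the "name"
# vertex attribute; all internal indexing is an implementation detail.

#' Validate a population-structure graph
#'
#' Checks that \code{g} is a simple undirected igraph object, and optionally
#' that it is connected. All evolutionary operations in this package require
#' connectedness: a mutant lineage cannot reach nodes in another component, so
#' fixation is not defined on disconnected graphs.
#'
#' @param g An igraph object.
#' @param require_connected Error if the graph is disconnected (default TRUE).
#' @return \code{g}, invisibly, with a "name" vertex attribute guaranteed.
#' @export
validate_graph <- function(g, require_connected = TRUE) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("graph must be undirected", call. = FALSE)
  if (igraph::any_loop(g)) stop("graph must not contain self-loops", call. = FALSE)
  if (igraph::any_multiple(g)) stop("graph must not contain parallel edges", call. = FALSE)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  if (require_connected && !igraph::is_connected(g)) {
    comp <- igraph::components(g)
    stop(sprintf(
      "graph is disconnected: %d components with sizes %s",
      comp$no, paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(g)
}

#' Degree-class summary of a graph
#'
#' Reduces a graph to the state space used by the degree-class diffusion
#' approximation: the ordered set of distinct degrees D, the number of nodes
#' N_i in each class, class frequencies p_i = N_i / N, and the row-stochastic
#' degree mixing matrix p_ij, the probability that an edge endpoint attached
#' to a degree-d_i node leads to a degree-d_j node. p_ij is computed from the
#' realized graph by counting ordered edge endpoints per degree pair and
#' normalizing rows.
#'
#' The summary satisfies the edge-balance identity
#' \eqn{p_i d_i p_{ij} = p_j d_j p_{ji}} for all class pairs.
#'
#' @param g A connected simple undirected igraph object with at least 2 nodes.
#' @param bin_width Optional positive width used to pool degrees into bins for
#'   graphs with very many distinct degrees. Default \code{NULL} (exact
#'   degrees, no binning); the diffusion theory indexes by exact degree, so
#'   binning is an approximation and each bin is represented by its
#'   node-weighted mean degree.
#' @return An object of class \code{"eg_degree_classes"}: a list with elements
#'   \code{D} (distinct degrees, ascending), \code{N_i}, \code{p_i},
#'   \code{p_ij} (row-stochastic matrix with dimnames = degrees), and \code{N}.
#' @examples
#' s <- degree_class_summary(igraph::make_star(4, mode = "undirected"))
#' s$D    # 1 3
#' s$p_ij # leaves connect only to the hub and vice versa
#' @export
degree_class_summary <- function(g, bin_width = NULL) {
  validate_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) stop("graph must have at least 2 nodes", call. = FALSE)
  deg <- igraph::degree(g)

  if (is.null(bin_width)) {
    cls <- deg
  } else {
    stopifnot(is.numeric(bin_width), bin_width > 0)
    cls <- floor(deg / bin_width)
  }
  levels_cls <- sort(unique(cls))
  idx <- match(cls, levels_cls)
  k <- length(levels_cls)
  n_i <- tabulate(idx, nbins = k)
  # class degree: exact degree, or node-weighted mean degree within a bin
  d_i <- as.numeric(vapply(seq_len(k), function(i) mean(deg[idx == i]), 0.0))

  el <- igraph::as_edgelist(g, names = FALSE)
  from <- c(idx[el[, 1]], idx[el[, 2]])
  to <- c(idx[el[, 2]], idx[el[, 1]])
  counts <- unname(as.matrix(table(factor(from, levels = seq_len(k)),
                                   factor(to, levels = seq_len(k)))))
  p_ij <- counts / rowSums(counts)
  dimnames(p_ij) <- list(format(d_i, trim = TRUE), format(d_i, trim = TRUE))

  structure(
    list(
      D = d_i,
      N_i = n_i,
      p_i = n_i / n,
      p_ij = p_ij,
      N = n,
      binned = !is.null(bin_width)
    ),
    class = "eg_degree_classes"
  )
}

#' @export
print.eg_degree_classes <- function(x, ...) {
  cat(sprintf(
    "Degree-class summary: N = %d, %d degree class%s (%s)\n",
    x$N, length(x$D), if (length(x$D) == 1) "" else "es",
    paste(format(x$D, trim = TRUE), collapse = ", ")
  ))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a degree-class summary into a tibble
#'
#' @param x An \code{eg_degree_classes} object.
#' @param ... Unused.
#' @return A tibble with one row per degree class: degree, size, frequency.
#' @export
tidy.eg_degree_classes <- function(x, ...) {
  tibble::tibble(degree = x$D, size = x$N_i, frequency = x$p_i)
}

#' Descriptive network statistics
#'
#' Computes the degree-sequence moments and the global wiring descriptors used
#' to characterize graph families: mean degree, degree variance, third central
#' moment, second raw moment, first inverse moment, degree Pearson correlation
#' (assortativity) r, average local clustering coefficient, and the modularity
#' of a greedy community partition. Modularity is descriptive only; the
#' evolutionary theory never uses it.
#'
#' For regular graphs the endpoint degree variance is zero and r is undefined;
#' it is reported as \code{NA}, never silently 0.
#'
#' @param g A connected simple undirected igraph object.
#' @return A one-row tibble.
#' @export
graph_statistics <- function(g) {
  validate_graph(g)
  deg <- igraph::degree(g)
  r <- suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  if (is.nan(r)) r <- NA_real_
  mod <- igraph::modularity(igraph::cluster_fast_greedy(g))
  tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    mean_degree = mean(deg),
    degree_variance = mean((deg - mean(deg))^2),
    degree_third_central = mean((deg - mean(deg))^3),
    degree_second_raw = mean(deg^2),
    degree_inverse_moment = mean(1 / deg),
    assortativity = r,
    clustering = igraph::transitivity(g, type = "localaverage", isolates = "zero"),
    modularity = mod
  )
}

#' Read a graph from a file
#'
#' Supported formats: whitespace-delimited edge lists ("u v" per line, blank
#' lines and \code{#} comments allowed, labels are opaque strings) and
#' GraphML. Self-loops and duplicate edges are rejected; for edge lists the
#' offending line number is reported.
#'
#' @param path Path to the file.
#' @param format "edgelist" or "graphml".
#' @return A simple undirected igraph object with named vertices.
#' @export
read_graph_file <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "each")
    if (igraph::any_loop(g)) stop("GraphML file contains a self-loop", call. = FALSE)
    if (igraph::any_multiple(g)) stop("GraphML file contains a duplicate edge", call. = FALSE)
    if (is.null(igraph::V(g)$name)) {
      idattr <- igraph::vertex_attr(g, "id")
      igraph::V(g)$name <- if (!is.null(idattr)) as.character(idattr) else as.character(seq_len(igraph::vcount(g)))
    }
    return(g)
  }
  lines <- readLines(path)
  stripped <- sub("#.*$", "", lines)
  keep <- which(trimws(stripped) != "")
  if (length(keep) == 0) stop("edge list contains no edges", call. = FALSE)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  from <- character(length(keep)); to <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    parts <- strsplit(trimws(stripped[ln]), "[[:space:]]+")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("line %d: expected two node labels, got %d fields", ln, length(parts)), call. = FALSE)
    }
    if (parts[1] == parts[2]) {
      stop(sprintf("line %d: self-loop '%s %s' is not allowed", ln, parts[1], parts[2]), call. = FALSE)
    }
    key <- paste(sort(parts), collapse = "\r")
    if (!is.null(seen[[key]])) {
      stop(sprintf("line %d: duplicate edge '%s %s' (first seen at line %d)",
                   ln, parts[1], parts[2], seen[[key]]), call. = FALSE)
    }
    seen[[key]] <- ln
    from[i] <- parts[1]; to[i] <- parts[2]
  }
  nodes <- unique(c(from, to))
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g
}

#' Write a graph to a file
#'
#' @param g A simple undirected igraph object.
#' @param path Output path.
#' @param format "edgelist" or "graphml".
#' @return \code{path}, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  validate_graph(g, require_connected = FALSE)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    writeLines(paste(el[, 1], el[, 2]), path)
  }
  invisible(path)
}
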