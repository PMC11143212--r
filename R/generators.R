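# Graph family generators. Every generator returns a connected simple
# undirected igraph with exactly N nodes, is reproducible given `seed`, and
# records its parameters as graph attributes. Stochastic families that can
# come out disconnected (Erdos-Renyi, geometric, Waxman, power-law cluster)
# are regenerated with an incremented sub-seed up to `max_attempts` times;
# exhausting the retries is an error, because the evolutionary process is
# undefined on disconnected graphs.

eg_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a graph from a named family
#'
#' Constructs connected simple undirected graphs from the families used to
#' study amplification and suppression of selection. Family-specific
#' parameters are passed through \code{...}:
#'
#' \describe{
#'   \item{complete}{\code{n}.}
#'   \item{ring_regular}{\code{n}, even \code{k}: ring lattice, each node tied
#'     to its k/2 nearest neighbours on each side.}
#'   \item{erdos_renyi}{\code{n}, \code{p}: each pair connected independently
#'     with probability p.}
#'   \item{preferential_attachment}{\code{n}, \code{m}, \code{beta}: growth
#'     from a clique of m nodes; each new node attaches to m distinct existing
#'     nodes sampled without replacement with weight degree^beta. beta = 0
#'     gives an exponential-tailed degree distribution, beta = 1 a power law.}
#'   \item{random_geometric}{\code{n}, \code{radius}, \code{density}
#'     ("uniform" or "normal"), \code{dim} (2 or 3), \code{sd} (for normal
#'     density, same coordinate units): points in the unit box, edge iff
#'     distance < radius.}
#'   \item{waxman}{\code{n}, \code{decay}, \code{density}, \code{dim},
#'     \code{sd}: points as above, edge with probability exp(-distance/decay).}
#'   \item{small_world}{\code{n}, \code{k}, \code{p_rewire}: Watts-Strogatz.}
#'   \item{power_law_cluster}{\code{n}, \code{m}, \code{p_triad}: Holme-Kim
#'     growth with triad formation.}
#'   \item{detour}{\code{n1} (>= 3), \code{n2} (>= 1): complete graph on n1
#'     nodes with one edge replaced by a path through n2 new nodes; total size
#'     n1 + n2. The removed edge joins the two lowest-labelled cluster nodes
#'     (isomorphism class is unaffected).}
#'   \item{star}{\code{n}: one hub connected to n - 1 leaves.}
#' }
#'
#' @param family Family name (see Details).
#' @param ... Family parameters.
#' @param seed Integer seed; same seed, same graph.
#' @param max_attempts Connectivity retry budget for stochastic families.
#' @return A connected simple undirected igraph object with graph attributes
#'   \code{family}, \code{params} (named list) and \code{seed}.
#' @examples
#' g <- generate_graph("detour", n1 = 4, n2 = 2)
#' sort(igraph::degree(g))  # 2 2 3 3 3 3
#' @export
generate_graph <- function(family = c("complete", "ring_regular", "erdos_renyi",
                                      "preferential_attachment",
                                      "random_geometric", "waxman",
                                      "small_world", "power_law_cluster",
                                      "detour", "star"),
                           ..., seed = NULL, max_attempts = 100L) {
  family <- match.arg(family)
  params <- list(...)
  stochastic <- family %in% c("erdos_renyi", "random_geometric", "waxman",
                              "power_law_cluster", "small_world",
                              "preferential_attachment")
  build <- function(sub_seed) {
    eg_with_seed(sub_seed, do.call(paste0("eg_gen_", family), params))
  }
  if (!stochastic) {
    g <- build(seed)
  } else {
    g <- NULL
    for (attempt in seq_len(max_attempts)) {
      sub_seed <- if (is.null(seed)) NULL else (seed + attempt - 1L) %% .Machine$integer.max
      cand <- build(sub_seed)
      if (igraph::is_connected(cand)) { g <- cand; break }
      if (is.null(seed)) next
    }
    if (is.null(g)) {
      stop(sprintf(
        "family '%s' did not yield a connected graph in %d regeneration attempts (incremented sub-seed policy); increase density parameters",
        family, max_attempts
      ), call. = FALSE)
    }
  }
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g <- igraph::set_graph_attr(g, "family", family)
  g <- igraph::set_graph_attr(g, "params", params)
  g <- igraph::set_graph_attr(g, "seed", if (is.null(seed)) NA_integer_ else as.integer(seed))
  validate_graph(g)
  g
}

eg_gen_complete <- function(n) {
  stopifnot(n >= 2)
  igraph::make_full_graph(n)
}

eg_gen_star <- function(n) {
  stopifnot(n >= 2)
  igraph::make_star(n, mode = "undirected", center = 1)
}

eg_gen_ring_regular <- function(n, k) {
  stopifnot(n >= 3, k >= 2, k %% 2 == 0, k < n)
  igraph::sample_smallworld(1, n, k / 2, 0)
}

eg_gen_small_world <- function(n, k, p_rewire) {
  stopifnot(n >= 3, k >= 2, k %% 2 == 0, p_rewire >= 0, p_rewire <= 1)
  igraph::sample_smallworld(1, n, k / 2, p_rewire)
}

eg_gen_erdos_renyi <- function(n, p) {
  stopifnot(n >= 2, p > 0, p <= 1)
  igraph::sample_gnp(n, p)
}

eg_gen_detour <- function(n1, n2) {
  stopifnot(n1 >= 3, n2 >= 1)
  g <- igraph::make_full_graph(n1)
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(1, 2)))
  g <- igraph::add_vertices(g, n2)
  path_nodes <- c(1, n1 + seq_len(n2), 2)
  g <- igraph::add_edges(g, as.vector(rbind(path_nodes[-length(path_nodes)], path_nodes[-1])))
  g
}

# Growth with clique-of-m bootstrap: every new node can always attach to m
# distinct targets. Attachment weight degree^beta on current degrees, sampled
# without replacement per new node. With m = 1 the bootstrap node has degree 0
# and 0^beta = 0 for beta > 0; the first attachment falls back to uniform.
eg_gen_preferential_attachment <- function(n, m, beta = 1) {
  stopifnot(n >= 2, m >= 1, m < n)
  deg <- integer(n)
  edges <- vector("list", n)
  if (m >= 2) {
    clique <- utils::combn(m, 2)
    edges[[1]] <- as.vector(clique)
    deg[seq_len(m)] <- m - 1L
  }
  for (v in (m + 1L):n) {
    cand <- seq_len(v - 1L)
    w <- deg[cand]^beta
    if (!any(w > 0)) w <- rep(1, length(cand))
    targets <- sample(cand, m, replace = FALSE, prob = w)
    edges[[v]] <- as.vector(rbind(v, targets))
    deg[targets] <- deg[targets] + 1L
    deg[v] <- deg[v] + m
  }
  igraph::make_graph(unlist(edges), n = n, directed = FALSE)
}

# Holme-Kim power-law cluster growth: linear preferential attachment with a
# triad-formation step taken with probability p_triad after each PA step.
eg_gen_power_law_cluster <- function(n, m, p_triad) {
  stopifnot(n >= 2, m >= 1, m < n, p_triad >= 0, p_triad <= 1)
  # repeated-nodes list implements linear preferential attachment
  repeated <- integer(0)
  adj <- vector("list", n)
  edges_from <- integer(0); edges_to <- integer(0)
  add_edge <- function(u, v) {
    edges_from <<- c(edges_from, u); edges_to <<- c(edges_to, v)
    adj[[u]] <<- c(adj[[u]], v); adj[[v]] <<- c(adj[[v]], u)
    repeated <<- c(repeated, u, v)
  }
  seed_nodes <- seq_len(m)
  for (v in (m + 1L):n) {
    targets <- integer(0)
    prev <- NA_integer_
    while (length(targets) < m) {
      do_triad <- !is.na(prev) && stats::runif(1) < p_triad
      if (do_triad) {
        nbr <- setdiff(adj[[prev]], c(v, targets))
        if (length(nbr) > 0) {
          t <- nbr[sample.int(length(nbr), 1)]
          targets <- c(targets, t); prev <- t
          next
        }
      }
      pool <- if (length(repeated) > 0) repeated else seed_nodes
      t <- pool[sample.int(length(pool), 1)]
      if (t != v && !(t %in% targets)) {
        targets <- c(targets, t); prev <- t
      }
    }
    for (t in targets) add_edge(v, t)
  }
  igraph::make_graph(rbind(edges_from, edges_to), n = n, directed = FALSE)
}

eg_points_in_box <- function(n, density, dim, sd) {
  if (density == "uniform") {
    matrix(stats::runif(n * dim), ncol = dim)
  } else {
    # isotropic Gaussian centred in the unit box, truncated to the box
    pts <- matrix(NA_real_, n, dim)
    filled <- 0L
    while (filled < n) {
      need <- n - filled
      cand <- matrix(stats::rnorm(2 * need * dim, mean = 0.5, sd = sd), ncol = dim)
      ok <- rowSums(cand >= 0 & cand <= 1) == dim
      cand <- cand[ok, , drop = FALSE]
      take <- min(nrow(cand), need)
      if (take > 0) {
        pts[filled + seq_len(take), ] <- cand[seq_len(take), , drop = FALSE]
        filled <- filled + take
      }
    }
    pts
  }
}

eg_gen_random_geometric <- function(n, radius, density = c("uniform", "normal"),
                                    dim = 2, sd = 0.2) {
  density <- match.arg(density)
  stopifnot(n >= 2, radius > 0, dim %in% c(2, 3))
  pts <- eg_points_in_box(n, density, dim, sd)
  dmat <- as.matrix(stats::dist(pts))
  am <- (dmat < radius) & upper.tri(dmat)
  el <- which(am, arr.ind = TRUE)
  g <- igraph::make_graph(rbind(el[, 1], el[, 2]), n = n, directed = FALSE)
  igraph::V(g)$x <- pts[, 1]; igraph::V(g)$y <- pts[, 2]
  if (dim == 3) igraph::V(g)$z <- pts[, 3]
  g
}

eg_gen_waxman <- function(n, decay, density = c("uniform", "normal"),
                          dim = 2, sd = 0.2) {
  density <- match.arg(density)
  stopifnot(n >= 2, decay > 0, dim %in% c(2, 3))
  pts <- eg_points_in_box(n, density, dim, sd)
  dmat <- as.matrix(stats::dist(pts))
  pe <- exp(-dmat / decay)
  u <- matrix(stats::runif(n * n), n, n)
  am <- (u < pe) & upper.tri(pe)
  el <- which(am, arr.ind = TRUE)
  g <- igraph::make_graph(rbind(el[, 1], el[, 2]), n = n, directed = FALSE)
  igraph::V(g)$x <- pts[, 1]; igraph::V(g)$y <- pts[, 2]
  if (dim == 3) igraph::V(g)$z <- pts[, 3]
  g
}
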