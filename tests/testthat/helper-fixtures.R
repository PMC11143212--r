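# Small graph fixtures and independent reference formulas used across tests.

# closed-form fixation probability of one mutant in the complete-graph Moran
# chain with relative fitness r = 1 + s
moran_closed_form <- function(N, s) {
  if (s == 0) return(1 / N)
  r <- 1 + s
  (1 - 1 / r) / (1 - r^(-N))
}

# degree Pearson correlation computed from first principles: correlation of
# degrees over edge endpoints, both orientations of every edge
assortativity_by_hand <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  x <- c(deg[el[, 1]], deg[el[, 2]])
  y <- c(deg[el[, 2]], deg[el[, 1]])
  suppressWarnings(stats::cor(x, y))
}

path_graph <- function(n) {
  igraph::make_graph(rbind(seq_len(n - 1), 2:n), n = n, directed = FALSE)
}

# a handful of small connected graphs for oracle comparisons
small_graph_suite <- function() {
  list(
    er1 = generate_graph("erdos_renyi", n = 8, p = 0.4, seed = 21),
    er2 = generate_graph("erdos_renyi", n = 9, p = 0.35, seed = 22),
    er3 = generate_graph("erdos_renyi", n = 10, p = 0.3, seed = 23),
    star9 = generate_graph("star", n = 9),
    star10 = generate_graph("star", n = 10),
    path7 = path_graph(7),
    path9 = path_graph(9),
    detour53 = generate_graph("detour", n1 = 5, n2 = 3),
    detour62 = generate_graph("detour", n1 = 6, n2 = 2),
    pa10 = generate_graph("preferential_attachment", n = 10, m = 2, beta = 1, seed = 24)
  )
}

expect_simple_connected <- function(g, n = NULL) {
  expect_false(igraph::is_directed(g))
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  expect_true(igraph::is_connected(g))
  if (!is.null(n)) expect_equal(igraph::vcount(g), n)
}
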