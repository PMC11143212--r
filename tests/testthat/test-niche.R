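test_that("mean nearest-neighbour distance matches hand geometry", {
  collinear <- data.frame(x = c(0, 1, 2), y = 0)
  expect_equal(mean_nn_distance(collinear), 1)
  expect_equal(mean_nn_distance(data.frame(x = c(0, 5), y = 0)), 5)
  grid <- expand.grid(x = (0:4) * 3.5, y = (0:4) * 3.5)
  expect_equal(mean_nn_distance(grid), 3.5)
  expect_warning(mean_nn_distance(data.frame(x = c(0, 0, 1), y = 0)),
                 "zero nearest-neighbour")
  expect_error(mean_nn_distance(data.frame(x = 1, y = 1)), "at least 2")
  expect_error(mean_nn_distance(data.frame(x = c(0, Inf), y = 0)), "finite")
})

test_that("threshold graphs recover expected topologies", {
  collinear <- data.frame(id = letters[1:5], x = 0:4, y = 0)
  g <- build_spatial_graph(collinear, 1.5)
  expect_simple_connected(g, n = 5)
  expect_equal(sort(igraph::degree(g)), c(1, 1, 2, 2, 2), ignore_attr = TRUE)
  expect_equal(sort(igraph::V(g)$name), letters[1:5])
  expect_error(build_spatial_graph(collinear, 0.5), "no pair of cells")
  # huge cutoff: complete graph
  expect_equal(igraph::ecount(build_spatial_graph(collinear, 100)), 10)
})

test_that("cutoff graphs are invariant to rescaling all coordinates", {
  pts <- synth_points(80, seed = 4)
  g1 <- build_spatial_graph(pts, 3)
  scaled <- pts
  scaled$x <- scaled$x * 1000; scaled$y <- scaled$y * 1000
  g2 <- build_spatial_graph(scaled, 3)
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(canon(g1), canon(g2))
})

test_that("disconnected point clouds reduce to the giant component with a count", {
  two_islands <- data.frame(
    x = c(0, 1, 2, 100, 101), y = 0
  )
  g <- build_spatial_graph(two_islands, 2)  # unit ~ mean NN ~ 1.2
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::vcount(g) + igraph::graph_attr(g, "discarded"), 5)
})

test_that("probabilistic connection mode is seed-reproducible", {
  pts <- synth_points(60, seed = 9)
  g1 <- build_spatial_graph(pts, 3, mode = "exponential", seed = 5)
  g2 <- build_spatial_graph(pts, 3, mode = "exponential", seed = 5)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("synthetic point clouds respect their box, seed and metadata contract", {
  p <- synth_points(200, box = c(500, 800), seed = 11)
  expect_s3_class(p, "tbl_df")
  expect_equal(nrow(p), 200)
  expect_true(all(p$x >= 0 & p$x <= 500))
  expect_true(all(p$y >= 0 & p$y <= 800))
  expect_identical(p$x, synth_points(200, box = c(500, 800), seed = 11)$x)
  expect_false(identical(p$x, synth_points(200, box = c(500, 800), seed = 12)$x))
  expect_named(attr(p, "params"), c("n", "box", "n_components", "weights",
                                    "centers", "sd", "seed"))
  expect_equal(nrow(synth_points(2, seed = 1)), 2)
  p3 <- synth_points(50, box = c(300, 300, 100), seed = 2)
  expect_true("z" %in% names(p3))
  expect_error(synth_points(10, box = c(0, 100)), "degenerate box")
  expect_error(synth_points(10, weights = c(0.5, 0.2)), "sum to 1")
})

test_that("density heterogeneity drives assortativity of the cutoff graph", {
  r_broad <- r_clustered <- numeric(6)
  for (i in 1:6) {
    # one very broad component is nearly uniform over the box
    broad <- synth_points(250, n_components = 1, sd = 5000, seed = 40 + i)
    tight <- synth_points(250, n_components = 3, sd = 250, seed = 40 + i)
    r_broad[i] <- assortativity_by_hand(build_spatial_graph(broad, 3))
    r_clustered[i] <- assortativity_by_hand(build_spatial_graph(tight, 3))
  }
  expect_true(all(r_clustered > 0))
  expect_gt(mean(r_clustered), mean(r_broad))
})

test_that("two overlapping clusters of unequal weight give a bimodal degree distribution", {
  # overlapping components keep the cloud in one connected blob; degree then
  # tracks local density, so the heavy cluster's mode sits well above the
  # light cluster's
  for (seed in 1:3) {
    p <- synth_points(300, n_components = 2, weights = c(0.75, 0.25),
                      centers = rbind(c(900, 900), c(1350, 1350)),
                      sd = 250, seed = seed)
    g <- build_spatial_graph(p, 2.5)
    xy <- cbind(igraph::V(g)$x, igraph::V(g)$y)
    cl <- ifelse((xy[, 1] - 900)^2 + (xy[, 2] - 900)^2 <
                 (xy[, 1] - 1350)^2 + (xy[, 2] - 1350)^2, 1, 2)
    d <- igraph::degree(g)
    expect_gt(sum(cl == 2), 20)
    expect_gt(mean(d[cl == 1]), 1.3 * mean(d[cl == 2]))
  }
})

test_that("a complete-graph control shows no spurious suppression", {
  pts <- synth_points(60, seed = 21)
  scan <- suppression_scan(pts, cutoffs = 1000, rule = "Bd", s = 0.05,
                           reps = 30000, seed = 5)
  expect_equal(scan$N, 60)
  # Bd on the complete graph is exactly the well-mixed Moran chain
  expect_lt(abs(scan$difference), 3 * scan$p_se)
  expect_equal(scan$difference, scan$p_fix - scan$p_wellmixed)
})

test_that("suppression scan emits one labelled row per sample-cutoff pair", {
  samples <- synth_samples(c(60, 80), seed = 2)
  scan <- suppression_scan(samples, cutoffs = c(3, 5), rule = "dB", s = 0.01,
                           reps = 500, seed = 9)
  expect_equal(nrow(scan), 4)
  expect_setequal(unique(scan$sample), names(samples))
  expect_true(all(scan$N <= c(60, 60, 80, 80)))
  expect_s3_class(autoplot(scan), "ggplot")
})

test_that("trend statistics match hand-computed regression anchors", {
  exact_line <- tibble::tibble(N = c(10, 20, 30), difference = c(-0.01, -0.02, -0.03))
  ts <- trend_stats(exact_line)
  expect_equal(ts$pearson_r, -1)
  expect_equal(ts$slope, -0.001)
  expect_lt(ts$p_value, 1e-6)

  flat <- tibble::tibble(N = c(10, 20, 30, 40), difference = rep(-0.005, 4))
  ts2 <- trend_stats(flat)
  expect_equal(ts2$slope, 0)
  expect_equal(ts2$p_value, 1)

  expect_error(trend_stats(tibble::tibble(N = c(1, 2), difference = c(0, 0))),
               "at least 3 rows")
  expect_error(trend_stats(tibble::tibble(N = rep(5, 4), difference = 1:4)),
               "zero variance")
})

test_that("a planted negative size trend is recovered", {
  set.seed(14)
  tab <- tibble::tibble(
    N = rep(seq(100, 1000, by = 100), 3),
    difference = -2e-5 * N + stats::rnorm(30, sd = 1e-3)
  )
  ts <- trend_stats(tab)
  expect_lt(ts$slope, 0)
  expect_lt(ts$pearson_r, -0.9)
  expect_lt(ts$p_value, 1e-4)
})

test_that("interaction-range calibration reproduces the published cutoff", {
  expect_equal(cutoff_from_range(1028, 62.72), 16.4, tolerance = 0.01)
  expect_error(cutoff_from_range(-1, 60))
})

test_that("point tables round-trip through delimited files", {
  p <- synth_points(25, seed = 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(p, f, sep = "\t", row.names = FALSE, quote = FALSE)
  p2 <- read_points(f)
  expect_equal(p2$x, p$x, tolerance = 1e-9)
  expect_equal(nrow(p2), 25)
})
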