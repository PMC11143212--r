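test_that("transition rates vanish at absorption and match the symmetric midpoint", {
  s <- degree_class_summary(generate_graph("detour", n1 = 6, n2 = 3))
  k <- length(s$D)
  r0 <- transition_rates(s, 0.1, rep(0, k))
  r1 <- transition_rates(s, 0.1, rep(1, k))
  expect_equal(r0$T_plus, rep(0, k))
  expect_equal(r0$T_minus, rep(0, k))
  expect_equal(r1$T_plus, rep(0, k))
  expect_equal(r1$T_minus, rep(0, k))

  ring <- degree_class_summary(igraph::make_ring(8))
  mid <- transition_rates(ring, 0, 0.5)
  expect_equal(mid$T_plus, 0.25)   # W = 1 at s = 0
  expect_equal(mid$T_minus, 0.25)
  expect_error(transition_rates(s, 0.1, c(0.5)), "one entry per degree class")
})

test_that("quadratic system reduces to A = 2s/(2+s) for a single degree class", {
  for (s in c(0.02, 0.1, 0.3)) {
    for (rule in c("Bd", "dB")) {
      su <- degree_class_summary(generate_graph("ring_regular", n = 30, k = 4))
      amp <- solve_amplification(su, s, rule)
      expect_equal(unname(amp$A), 2 * s / (2 + s), tolerance = 1e-10)
      expect_equal(amp$alpha, 1, tolerance = 1e-10)
      expect_lt(amp$residual, 1e-10)
    }
  }
  expect_error(solve_amplification(
    degree_class_summary(igraph::make_ring(6)), 0, "Bd"), "s != 0")
})

test_that("Bd and dB quadratic systems coincide on symmetric mixing and differ on the star", {
  # a regular graph has a symmetric one-class summary: rules must agree exactly
  su <- degree_class_summary(generate_graph("ring_regular", n = 40, k = 6))
  expect_equal(solve_amplification(su, 0.1, "Bd")$A,
               solve_amplification(su, 0.1, "dB")$A, tolerance = 1e-12)
  star <- degree_class_summary(generate_graph("star", n = 50))
  a_bd <- solve_amplification(star, 0.1, "Bd")$alpha
  a_db <- solve_amplification(star, 0.1, "dB")$alpha
  expect_gt(a_bd, 1)  # star amplifies under Bd
  expect_lt(a_db, 1)  # and suppresses under dB
})

test_that("diffusion solution on regular graphs equals the well-mixed diffusion form", {
  su <- degree_class_summary(generate_graph("ring_regular", n = 100, k = 4))
  for (s in c(0.01, 0.05)) {
    p <- fixation_prob_diffusion(su, s)
    sp <- s / (1 + s / 2)
    expect_equal(p, (1 - exp(-sp)) / (1 - exp(-100 * sp)), tolerance = 1e-12)
  }
})

test_that("star exponent from the quadratic system is consistent with closed-form alpha_Bd", {
  su <- degree_class_summary(generate_graph("star", n = 100))
  s <- 0.01
  amp <- solve_amplification(su, s, "Bd")
  exponent_quadratic <- su$N * sum(su$p_i * amp$A)
  exponent_closed <- alpha_Bd(su)$alpha * su$N * s / (1 + s / 2)
  expect_equal(exponent_quadratic, exponent_closed, tolerance = 0.02)
})

test_that("diffusion approximation tracks the exact chain under weak selection", {
  suite <- small_graph_suite()[c("er1", "er2", "er3", "pa10", "star9")]
  for (g in suite) {
    su <- degree_class_summary(g)
    s <- 0.1  # N s <= 1 on this suite
    for (rule in c("Bd", "dB")) {
      pd <- fixation_prob_diffusion(su, s, rule = rule)
      pe <- exact_fixation(g, rule, s)$average
      expect_lt(abs(pd - pe) / pe, 0.10)
    }
  }
})

test_that("diffusion prediction matches simulation on a preferential-attachment graph", {
  g <- generate_graph("preferential_attachment", n = 100, m = 3, beta = 1, seed = 8)
  su <- degree_class_summary(g)
  s <- 0.05  # N s = 5
  est <- simulate_fixation(g, "dB", s, reps = 2e5, seed = 31)
  pd <- fixation_prob_diffusion(su, s, rule = "dB")
  expect_lt(abs(pd - est$p_fix), 3 * est$p_se)
})

test_that("closed-form alpha factors match hand-evaluated moments", {
  star <- degree_class_summary(generate_graph("star", n = 100))
  # <d> = 2*99/100, <d^2> = (99 + 99^2)/100
  expect_equal(alpha_dB(star)$alpha, (2 * 99 / 100)^2 / ((99 + 99^2) / 100),
               tolerance = 1e-12)
  expect_equal(alpha_dB(star)$alpha, 0.0396, tolerance = 1e-10)
  # star alpha_Bd = 2(1 + 99^2)/100^2
  ab <- alpha_Bd(star)
  expect_equal(ab$alpha, 2 * (1 + 99^2) / 100^2, tolerance = 1e-12)
  expect_equal(ab$alpha, 1.9604, tolerance = 1e-10)
  # term-by-term mu sums for the star
  expect_equal(ab$mu1, 2 / 100, tolerance = 1e-12)
  expect_equal(ab$mu2, 100 / 9900, tolerance = 1e-12)
  # regular graphs are isothermal under both factors
  ring <- degree_class_summary(generate_graph("ring_regular", n = 60, k = 4))
  expect_equal(alpha_dB(ring)$alpha, 1, tolerance = 1e-12)
  expect_equal(alpha_Bd(ring)$alpha, 1, tolerance = 1e-12)
})

test_that("alpha_dB never exceeds 1 and is invariant under double edge swaps", {
  g <- generate_graph("preferential_attachment", n = 120, m = 2, beta = 1, seed = 12)
  a0 <- alpha_dB(degree_class_summary(g))$alpha
  expect_lte(a0, 1)
  set.seed(3)
  gg <- g
  accepted <- 0
  while (accepted < 5) {
    sw <- double_edge_swap(gg)
    if (sw$accepted) {
      accepted <- accepted + 1
      gg <- sw$graph
      expect_equal(alpha_dB(degree_class_summary(gg))$alpha, a0, tolerance = 1e-12)
    }
  }
})

test_that("swap-effect predictor is zero at equal degrees and positive at the minimum degree", {
  g <- generate_graph("preferential_attachment", n = 150, m = 2, beta = 1, seed = 6)
  su <- degree_class_summary(g)
  d <- su$D
  expect_equal(swap_effect_alpha_Bd(su, d[2], d[2])$value, 0)
  dmin <- min(d)
  for (dj in d[d != dmin][1:3]) {
    expect_gt(swap_effect_alpha_Bd(su, dmin, dj)$value, 0)
  }
  expect_error(swap_effect_alpha_Bd(su, max(d) + 1, dmin), "present in the summary")
})

test_that("regular perturbation is anchored at the complete graph and sizes its system by |D|", {
  for (n in c(20, 50)) {
    su <- degree_class_summary(generate_graph("complete", n = n))
    rp <- solve_regular_perturbation(su, s = 0.01)
    expect_equal(rp$n_unknowns, 1)
    expect_equal(unname(rp$A[1, 1]), n / 2, tolerance = 1e-10)
    expect_equal(rp$difference, 0, tolerance = 1e-12)
  }
  su <- degree_class_summary(generate_graph("detour", n1 = 20, n2 = 10))
  expect_equal(solve_regular_perturbation(su, s = 0.002)$n_unknowns, 3)
})

test_that("detour sweep has an interior suppression minimum that deepens with N", {
  minima <- vapply(c(100, 200, 400), function(N) {
    n2 <- seq(2, N - 10, by = max(2, floor(N / 25)))
    diffs <- vapply(n2, function(l) {
      su <- degree_class_summary(generate_graph("detour", n1 = N - l, n2 = l))
      solve_regular_perturbation(su, N = N, s = 0.002)$difference
    }, 0)
    expect_true(all(diffs < 0))
    imin <- which.min(diffs)
    expect_gt(imin, 1)                 # interior, not at the complete end
    expect_lt(imin, length(diffs))     # rises again toward the ring end
    min(diffs)
  }, 0)
  expect_true(all(diff(minima) < 0))   # deeper at larger N
})

test_that("alpha classification thresholds at 1", {
  expect_equal(classify_alpha(1), "isothermal")
  expect_equal(classify_alpha(1 + 1e-12), "isothermal")
  expect_equal(classify_alpha(alpha_Bd(degree_class_summary(generate_graph("star", n = 100)))),
               "amplifier")
  expect_equal(classify_alpha(alpha_dB(degree_class_summary(generate_graph("star", n = 100)))),
               "suppressor")
  expect_error(classify_alpha(-0.5))
})
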