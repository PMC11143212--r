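# Moran birth-death dynamics on graphs: Monte Carlo simulation, the exact
# absorbing-chain solver over all 2^N mutant sets (tractable only for small
# graphs; used as an oracle), and the classical well-mixed baselines.

eg_graph_csr <- function(g) {
  adj <- igraph::as_adj_list(g)
  offsets <- c(0L, cumsum(vapply(adj, length, 0L)))
  list(offsets = offsets,
       neighbors = unlist(lapply(adj, function(x) as.integer(x) - 1L), use.names = FALSE))
}

#' Simulate fixation of a single invading mutant
#'
#' Runs replicate Moran processes on a connected graph until the mutant
#' lineage (fitness 1 + s; wild type fitness 1) fixes or is lost, under either
#' update rule:
#' \describe{
#'   \item{Bd (Birth-death)}{the reproducer is chosen from the whole
#'     population with probability proportional to fitness, then one of its
#'     neighbours is chosen uniformly to die and is replaced by the offspring.}
#'   \item{dB (death-Birth)}{a node is chosen uniformly to be vacated, then
#'     one of its neighbours reproduces into it with probability proportional
#'     to fitness.}
#' }
#'
#' Each replicate uses an independent RNG stream derived from
#' \code{(seed, replicate index)}, so any replicate is reproducible in
#' isolation and the simulation does not consume R's global RNG.
#'
#' @param g A connected simple undirected igraph object.
#' @param rule "Bd" or "dB".
#' @param s Selection coefficient, s > -1. The mutant has fitness 1 + s.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer master seed.
#' @param placement Initial mutant placement: "uniform" (a uniformly random
#'   node, the default), "fixed_node" (use \code{node}), or "degree_class"
#'   (a uniformly random node of degree \code{degree}).
#' @param node,degree Placement parameters (see \code{placement}).
#' @param step_cap Safety bound on update steps per replicate. Absorption is
#'   certain on a connected graph, so capped replicates indicate a cap that is
#'   too low; they are excluded with a warning.
#' @return A one-row tibble (class \code{eg_fixation}): fixation probability
#'   estimate with binomial standard error, conditional mean fixation time in
#'   update steps and in steps/N ("generations") with standard errors,
#'   replicate counts, and the configuration.
#' @examples
#' est <- simulate_fixation(generate_graph("complete", n = 3), "Bd",
#'                          s = 0, reps = 2000, seed = 1)
#' est$p_fix  # close to 1/3: neutral symmetry
#' @export
simulate_fixation <- function(g, rule = c("Bd", "dB"), s, reps, seed = 1L,
                              placement = c("uniform", "fixed_node", "degree_class"),
                              node = NULL, degree = NULL, step_cap = 1e9) {
  rule <- match.arg(rule)
  placement <- match.arg(placement)
  validate_graph(g)
  stopifnot(s > -1, reps >= 1, step_cap >= 1)
  n <- igraph::vcount(g)

  init_nodes <- switch(placement,
    uniform = seq_len(n) - 1L,
    fixed_node = {
      if (is.null(node)) stop("placement 'fixed_node' requires `node`", call. = FALSE)
      idx <- if (is.character(node)) match(node, igraph::V(g)$name) else as.integer(node)
      if (is.na(idx) || idx < 1 || idx > n) stop("`node` not found in graph", call. = FALSE)
      idx - 1L
    },
    degree_class = {
      if (is.null(degree)) stop("placement 'degree_class' requires `degree`", call. = FALSE)
      idx <- which(igraph::degree(g) == degree)
      if (length(idx) == 0) stop(sprintf("no node has degree %s", degree), call. = FALSE)
      idx - 1L
    }
  )

  csr <- eg_graph_csr(g)
  res <- cpp_simulate_fixation(csr$offsets, csr$neighbors,
                               ifelse(rule == "Bd", 0L, 1L),
                               as.numeric(s), as.integer(reps),
                               as.numeric(seed), as.integer(init_nodes),
                               as.numeric(step_cap))
  if (res$n_capped > 0) {
    warning(sprintf("%d replicate(s) hit the step cap (%g) and were excluded; absorption is certain, so raise the cap",
                    res$n_capped, step_cap))
  }
  n_eff <- res$n_fixed + res$n_lost
  p_hat <- if (n_eff > 0) res$n_fixed / n_eff else NA_real_
  t_fix <- res$steps_fixed
  out <- tibble::tibble(
    rule = rule, s = s, n = n,
    p_fix = p_hat,
    p_se = if (n_eff > 0) sqrt(p_hat * (1 - p_hat) / n_eff) else NA_real_,
    t_fix_steps = if (length(t_fix) > 0) mean(t_fix) else NA_real_,
    t_fix_steps_se = if (length(t_fix) > 1) stats::sd(t_fix) / sqrt(length(t_fix)) else NA_real_,
    t_fix_generations = if (length(t_fix) > 0) mean(t_fix) / n else NA_real_,
    n_fixed = res$n_fixed, n_lost = res$n_lost, n_capped = res$n_capped,
    reps = reps, placement = placement, seed = as.integer(seed)
  )
  class(out) <- c("eg_fixation", class(out))
  out
}

#' Exact fixation probabilities on a small graph
#'
#' Solves the absorbing Markov chain over all 2^N mutant-occupancy states
#' exactly (up to linear-solver tolerance). The state space grows
#' exponentially, so this is enforced for N <= 14 and intended as an oracle
#' for validating simulations and approximations on small graphs.
#'
#' @inheritParams simulate_fixation
#' @return A list with \code{per_node}, a tibble of fixation probability from
#'   each single-mutant start, and \code{average}, the uniform placement
#'   average.
#' @export
exact_fixation <- function(g, rule = c("Bd", "dB"), s) {
  rule <- match.arg(rule)
  validate_graph(g)
  stopifnot(s > -1)
  n <- igraph::vcount(g)
  if (n > 14) {
    stop("exact_fixation is limited to N <= 14 (2^N chain states); use simulate_fixation",
         call. = FALSE)
  }
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  # both orientations: parent u -> victim v
  us <- c(el[, 1], el[, 2]); vs <- c(el[, 2], el[, 1])
  n_states <- 2L^n
  masks <- 0:(n_states - 1L)
  bits <- 2L^(0:(n - 1L))
  popcount <- rowSums(outer(masks, bits, function(mm, b) bitwAnd(mm, b) > 0L))
  fm <- 1 + s

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- numeric(n_states)     # P(state -> all-mutant)
  rowchange <- numeric(n_states)
  full <- n_states - 1L

  for (t in seq_along(us)) {
    u <- us[t]; v <- vs[t]
    mu <- bitwAnd(masks, bits[u]) > 0L
    mv <- bitwAnd(masks, bits[v]) > 0L
    differs <- xor(mu, mv)
    if (rule == "Bd") {
      W <- n - popcount + fm * popcount
      pr <- ifelse(mu, fm, 1) / W / deg[u]
    } else {
      nb <- igraph::neighbors(g, v)
      nbmask <- sum(bits[as.integer(nb)])
      kmut <- rowSums(outer(bitwAnd(masks, nbmask), bits, function(mm, bb) bitwAnd(mm, bb) > 0L))
      wtot <- fm * kmut + (deg[v] - kmut)
      pr <- (1 / n) * ifelse(mu, fm, 1) / wtot
    }
    sel <- which(differs)
    if (length(sel) == 0) next
    target <- bitwXor(masks[sel], bits[v])
    p_sel <- pr[sel]
    rowchange[sel] <- rowchange[sel] + p_sel
    is_full <- target == full
    b[sel[is_full]] <- b[sel[is_full]] + p_sel[is_full]
    keep <- !is_full & target != 0L
    ii <- c(ii, masks[sel][keep]); jj <- c(jj, target[keep]); xx <- c(xx, p_sel[keep])
  }

  transient <- 2:(n_states - 1L)  # masks 1 .. 2^n - 2
  tmap <- integer(n_states); tmap[transient] <- seq_along(transient)
  # Steps that leave the state unchanged sit on the diagonal with probability
  # 1 - rowchange, so (I - P) restricted to transient states has diagonal
  # entries equal to rowchange.
  A <- Matrix::sparseMatrix(
    i = c(tmap[ii + 1L], seq_along(transient)),
    j = c(tmap[jj + 1L], seq_along(transient)),
    x = c(-xx, rowchange[transient]),
    dims = c(length(transient), length(transient))
  )
  p <- as.numeric(Matrix::solve(A, b[transient]))

  single <- tmap[bits + 1L]
  per_node <- tibble::tibble(
    node = igraph::V(g)$name,
    degree = deg,
    p_fix = p[single]
  )
  list(per_node = per_node, average = mean(per_node$p_fix), rule = rule, s = s)
}

#' Well-mixed Moran baselines
#'
#' Reference values for a well-mixed population of size N (the complete
#' graph): the exact fixation probability of a single mutant from the
#' absorbing birth-death chain,
#' \eqn{\rho = (1 - (1+s)^{-1}) / (1 - (1+s)^{-N})} (neutral limit 1/N), the
#' weak-selection diffusion form \eqn{(1 - e^{-s})/(1 - e^{-Ns})}, and the
#' conditional mean fixation time from the standard sojourn-time relations of
#' the same chain (in update steps, and in steps/N "generations").
#'
#' @param N Population size (>= 2).
#' @param s Selection coefficient (> -1); s = 0 is handled by the analytic
#'   limit.
#' @return A one-row tibble with columns \code{p_fix_exact},
#'   \code{p_fix_diffusion}, \code{t_fix_steps}, \code{t_fix_generations}.
#' @export
wellmixed_baseline <- function(N, s) {
  stopifnot(N >= 2, s > -1)
  if (s == 0) {
    p_exact <- 1 / N
    p_diff <- 1 / N
  } else {
    r <- 1 + s
    p_exact <- (1 - 1 / r) / (1 - r^(-N))
    p_diff <- (1 - exp(-s)) / (1 - exp(-N * s))
  }
  # Conditional fixation time: on K_N with k mutants, a Bd step changes k with
  # T_k^+ = k(1+s)(N-k) / (W (N-1)), T_k^- = (N-k) k / (W (N-1)), W = N + ks.
  # Solve h_k = phi_k t_k from the one-step relation; t_1 = h_1 / phi_1.
  k <- 1:(N - 1)
  W <- N + k * s
  Tp <- k * (1 + s) * (N - k) / (W * (N - 1))
  Tm <- (N - k) * k / (W * (N - 1))
  # fixation probabilities phi_k
  if (s == 0) phi <- k / N else phi <- (1 - (1 + s)^(-k)) / (1 - (1 + s)^(-N))
  # (Tp + Tm) h_k - Tp h_{k+1} - Tm h_{k-1} = phi_k, h_0 = h_N-boundary:
  # h_N = phi_N * t_N = 0 since t_N = 0.
  A <- Matrix::bandSparse(N - 1, N - 1,
                          k = c(-1, 0, 1),
                          diagonals = list(-Tm[-1], Tp + Tm, -Tp[-(N - 1)]))
  h <- as.numeric(Matrix::solve(A, phi))
  t1 <- h[1] / phi[1]
  tibble::tibble(N = N, s = s,
                 p_fix_exact = p_exact, p_fix_diffusion = p_diff,
                 t_fix_steps = t1, t_fix_generations = t1 / N)
}
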