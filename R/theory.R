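# Degree-class diffusion machinery: per-class transition rates, the
# singular-perturbation quadratic system and its fixation-probability formula,
# closed-form amplification factors alpha_dB and alpha_Bd, the edge-swap
# effect predictor, and the regular-perturbation linear system used for
# strongly assortative (detour-like) graphs.

eg_check_summary <- function(summary) {
  if (!inherits(summary, "eg_degree_classes")) {
    stop("`summary` must come from degree_class_summary()", call. = FALSE)
  }
  summary
}

# U_ij = p_i * p_ij; its transpose gives p_j * p_ji.
eg_U <- function(summary) summary$p_i * summary$p_ij

#' Per-class transition rates of the degree-class Moran model
#'
#' At class state x (x_i = mutant frequency among the N_i nodes of degree
#' d_i), the frequency x_i increases by 1/N_i with probability T_i^+ and
#' decreases with T_i^-:
#' \deqn{T_i^+ = \frac{1+s}{W} \sum_j p_j p_{ji} x_j (1 - x_i), \quad
#'       T_i^- = \frac{1}{W} \sum_j p_j p_{ji} (1 - x_j) x_i,}
#' where W = 1 + s * sum_i p_i x_i is the population mean fitness.
#'
#' @param summary An \code{eg_degree_classes} object.
#' @param s Selection coefficient.
#' @param x Numeric vector of per-class mutant frequencies in [0,1], one per
#'   degree class.
#' @return A tibble with columns degree, x, T_plus, T_minus.
#' @export
transition_rates <- function(summary, s, x) {
  eg_check_summary(summary)
  if (length(x) != length(summary$D)) {
    stop(sprintf("`x` must have one entry per degree class (%d)", length(summary$D)),
         call. = FALSE)
  }
  stopifnot(all(x >= 0 & x <= 1))
  W <- 1 + s * sum(summary$p_i * x)
  Ut <- t(eg_U(summary))          # Ut[i, j] = p_j * p_ji
  inflow <- as.numeric(Ut %*% x)  # sum_j p_j p_ji x_j
  outflow <- as.numeric(Ut %*% (1 - x))
  tibble::tibble(
    degree = summary$D, x = x,
    T_plus = (1 + s) / W * inflow * (1 - x),
    T_minus = (1 / W) * outflow * x
  )
}

#' Solve the singular-perturbation quadratic system for the class coefficients
#'
#' The diffusion approximation writes the fixation probability from class
#' state x as
#' \deqn{P(x) = \frac{1 - \exp\{-N \sum_i p_i A_i x_i\}}
#'                   {1 - \exp\{-N \sum_i p_i A_i\}},}
#' where the per-class coefficients A_i solve, for every class i (Bd rule),
#' \deqn{\sum_j [(1+s) A_j^2 p_i p_{ij} + A_i^2 p_j p_{ji}
#'       - 2 (1+s) A_j p_i p_{ij} + 2 A_i p_j p_{ji}] = 0,}
#' and the dB system is identical with \eqn{p_i p_{ij}} and \eqn{p_j p_{ji}}
#' transposed. A = 0 is always a spurious root, so a damped Newton iteration
#' starts from the exact single-class solution A_i = 2s/(2+s) and converges to
#' the nontrivial root.
#'
#' @inheritParams transition_rates
#' @param rule "Bd" or "dB".
#' @param tol Residual norm requirement (default 1e-12, must reach < 1e-10).
#' @param max_iter Newton iteration cap.
#' @return An object of class \code{eg_amplification}: list with \code{A}
#'   (per-class coefficients named by degree), \code{alpha} (effective
#'   amplification factor \eqn{\sum_i p_i A_i / (s / (1 + s/2))}, the exponent
#'   rescaling relative to a well-mixed population), \code{method}
#'   ("quadratic-system"), \code{rule}, \code{s} and \code{residual}.
#' @export
solve_amplification <- function(summary, s, rule = c("Bd", "dB"),
                                tol = 1e-12, max_iter = 200L) {
  rule <- match.arg(rule)
  eg_check_summary(summary)
  if (s == 0) {
    stop("the quadratic system is defined for s != 0 (at s = 0 only the trivial root A = 0 exists)",
         call. = FALSE)
  }
  U <- eg_U(summary)
  if (rule == "dB") U <- t(U)
  cs <- colSums(U)          # sum_j U_ji (orientation-dependent counterpart)
  k <- length(summary$D)
  fn <- function(A) {
    (1 + s) * as.numeric(U %*% (A^2 - 2 * A)) + (A^2 + 2 * A) * cs
  }
  jac <- function(A) {
    J <- (1 + s) * U * rep(2 * A - 2, each = k)
    diag(J) <- diag(J) + (2 * A + 2) * cs
    J
  }
  A <- rep(2 * s / (2 + s), k)
  res <- fn(A)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(res^2)) < tol) break
    step <- tryCatch(solve(jac(A), res), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      A_new <- A - lambda * step
      res_new <- fn(A_new)
      if (sum(res_new^2) < sum(res^2) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    A <- A_new; res <- res_new
  }
  resid <- sqrt(sum(res^2))
  if (resid >= 1e-10) {
    stop(sprintf(
      "quadratic system did not converge (residual %.3e); for weakly coupled sub-populations use solve_regular_perturbation()",
      resid
    ), call. = FALSE)
  }
  names(A) <- format(summary$D, trim = TRUE)
  structure(
    list(A = A,
         alpha = sum(summary$p_i * A) / (s / (1 + s / 2)),
         method = "quadratic-system", rule = rule, s = s,
         residual = resid, D = summary$D, p_i = summary$p_i),
    class = "eg_amplification"
  )
}

#' @export
print.eg_amplification <- function(x, ...) {
  cat(sprintf("Amplification result (%s, rule %s): alpha = %.6g -> %s\n",
              x$method, x$rule, x$alpha, classify_alpha(x$alpha)))
  if (!is.null(x$A)) {
    cat("Per-class coefficients A_i:\n")
    print(x$A)
  }
  invisible(x)
}

#' Tidy an amplification result
#'
#' @param x An \code{eg_amplification} object.
#' @param ... Unused.
#' @return Tibble with one row per degree class (or a single row for
#'   closed-form factors without per-class coefficients).
#' @export
tidy.eg_amplification <- function(x, ...) {
  if (is.null(x$A)) {
    return(tibble::tibble(alpha = x$alpha, method = x$method, rule = x$rule))
  }
  tibble::tibble(degree = x$D, A = unname(x$A), alpha = x$alpha,
                 method = x$method, rule = x$rule)
}

#' One-row summary of an amplification result
#'
#' @param x An \code{eg_amplification} object.
#' @param ... Unused.
#' @return A one-row tibble: alpha, classification, method, rule.
#' @export
glance.eg_amplification <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, classification = classify_alpha(x$alpha),
                 method = x$method, rule = x$rule)
}

#' One-row summary of a regular-perturbation result
#'
#' @param x An \code{eg_regular_perturbation} object.
#' @param ... Unused.
#' @return A one-row tibble: p_fix, the same-order well-mixed value, their
#'   difference, system size and conditioning.
#' @export
glance.eg_regular_perturbation <- function(x, ...) {
  tibble::tibble(p_fix = x$p_fix, p_fix_wellmixed = x$p_fix_wellmixed,
                 difference = x$difference, n_unknowns = x$n_unknowns,
                 rcond = x$rcond, N = x$N, s = x$s)
}

#' Fixation probability from the degree-class diffusion approximation
#'
#' Evaluates the singular-perturbation solution at a single-mutant start. A
#' mutant placed in class i corresponds to x_i = 1/N_i (other classes 0), so
#' the class exponent is exactly A_i; "uniform" placement averages the class
#' probabilities with weights p_i. If every A_i is numerically zero the
#' formula is degenerate and the neutral value 1/N is returned with a message.
#'
#' @inheritParams solve_amplification
#' @param N Population size used in the denominator exponent (defaults to the
#'   summary's N).
#' @param placement "uniform" or "class".
#' @param class_degree Degree of the starting class when
#'   \code{placement = "class"}.
#' @param A Optional precomputed \code{eg_amplification} object; solved with
#'   \code{solve_amplification} when omitted.
#' @return Fixation probability (scalar).
#' @export
fixation_prob_diffusion <- function(summary, s, N = summary$N,
                                    rule = c("Bd", "dB"),
                                    placement = c("uniform", "class"),
                                    class_degree = NULL, A = NULL) {
  rule <- match.arg(rule)
  placement <- match.arg(placement)
  eg_check_summary(summary)
  if (is.null(A)) A <- solve_amplification(summary, s, rule)
  Ai <- unname(A$A)
  denom_exp <- N * sum(summary$p_i * Ai)
  if (max(abs(Ai)) < 1e-14) {
    message("all class coefficients are ~0; returning the neutral value 1/N")
    return(1 / N)
  }
  p_class <- (1 - exp(-Ai)) / (1 - exp(-denom_exp))
  if (placement == "class") {
    if (is.null(class_degree)) stop("placement 'class' requires `class_degree`", call. = FALSE)
    i <- match(class_degree, summary$D)
    if (is.na(i)) stop(sprintf("no degree class %s in summary", class_degree), call. = FALSE)
    return(p_class[i])
  }
  sum(summary$p_i * p_class)
}

#' Closed-form amplification factor for the death-Birth rule
#'
#' \deqn{\alpha_{dB} = \langle d \rangle^2 / \langle d^2 \rangle,} the squared
#' mean degree over the second raw moment of the degree distribution. By
#' Jensen's inequality this lies in (0, 1]: under death-Birth updating no
#' degree-heterogeneous graph amplifies selection at this order, and equality
#' holds only for regular graphs. It depends on the degree distribution alone,
#' so it is invariant under degree-preserving rewiring.
#'
#' @param summary An \code{eg_degree_classes} object.
#' @return An \code{eg_amplification} object with method "closed-form-dB".
#' @export
alpha_dB <- function(summary) {
  eg_check_summary(summary)
  d1 <- sum(summary$p_i * summary$D)
  d2 <- sum(summary$p_i * summary$D^2)
  structure(
    list(A = NULL, alpha = d1^2 / d2, method = "closed-form-dB", rule = "dB",
         D = summary$D, p_i = summary$p_i),
    class = "eg_amplification"
  )
}

#' Closed-form amplification factor for the Birth-death rule
#'
#' \deqn{\alpha_{Bd} = \frac{\langle d^{-1} \rangle \,\mu_1}{\mu_2}, \quad
#'   \mu_1 = \sum_{i,j} p_j p_{ji} d_i^{-1}, \quad
#'   \mu_2 = \sum_{i,j} p_j p_{ji} d_i^{-2}.}
#' Unlike the death-Birth factor, this depends on the mixing matrix as well as
#' the degree distribution: at fixed degree sequence, disassortative wiring
#' raises it (the star graph is the extreme case) and assortative wiring
#' lowers it.
#'
#' @param summary An \code{eg_degree_classes} object.
#' @return An \code{eg_amplification} object with method "closed-form-Bd" and
#'   auxiliary sums \code{mu1}, \code{mu2}.
#' @export
alpha_Bd <- function(summary) {
  eg_check_summary(summary)
  cs <- colSums(eg_U(summary))   # sum_j p_j p_ji, indexed by i
  mu1 <- sum(cs / summary$D)
  mu2 <- sum(cs / summary$D^2)
  dinv <- sum(summary$p_i / summary$D)
  structure(
    list(A = NULL, alpha = dinv * mu1 / mu2, mu1 = mu1, mu2 = mu2,
         method = "closed-form-Bd", rule = "Bd",
         D = summary$D, p_i = summary$p_i),
    class = "eg_amplification"
  )
}

#' Predicted effect of one double edge swap on alpha_Bd
#'
#' For a swap that removes an edge between two degree-d_i nodes and one
#' between two degree-d_j nodes and creates two d_i--d_j edges (a
#' disassortativity-increasing move when the degrees differ), the change in
#' the Birth-death amplification factor scales as
#' \deqn{\Delta\alpha_{Bd} \sim (d_i^{-1} - d_j^{-1})^2
#'       (d_i^{-1} + d_j^{-1} - \mu_2/\mu_1).}
#' Because \eqn{\mu_2/\mu_1 \le 1/d_{min}}, swaps involving the lowest degree
#' always increase alpha_Bd. This is a sign/magnitude predictor; the exact
#' change is always available by recomputing \code{\link{alpha_Bd}} on the
#' swapped graph.
#'
#' @param summary An \code{eg_degree_classes} object.
#' @param d_i,d_j Degrees of the two edge classes involved in the swap; must
#'   be degrees present in the graph.
#' @return A list with \code{value} (the expression above) and \code{sign}.
#' @export
swap_effect_alpha_Bd <- function(summary, d_i, d_j) {
  eg_check_summary(summary)
  if (!(d_i %in% summary$D) || !(d_j %in% summary$D)) {
    stop("d_i and d_j must be degrees present in the summary", call. = FALSE)
  }
  ab <- alpha_Bd(summary)
  value <- (1 / d_i - 1 / d_j)^2 * (1 / d_i + 1 / d_j - ab$mu2 / ab$mu1)
  list(value = value, sign = sign(value))
}

#' Regular-perturbation fixation probability (weak-coupling expansion)
#'
#' The singular-perturbation system misplaces the suppression minimum when
#' exchange of individuals between sub-populations is weak (detour-like
#' graphs). This solver instead expands the fixation probability to first
#' order in s using symmetric pair coefficients A_ij that satisfy a linear
#' system of |D|(|D|+1)/2 equations (one per unordered class pair):
#' \deqn{p_j p_{ji}(-\tfrac{1}{\langle d^{-1}\rangle d_i} + \tfrac{2A_{ii}}{N})
#'  - 2\sum_k p_i p_j p_{jk} A_{ki} + 2\sum_k p_j p_k p_{ki} A_{ij}
#'  + p_i p_{ij}(-\tfrac{1}{\langle d^{-1}\rangle d_j} + \tfrac{2A_{jj}}{N})
#'  - 2\sum_k p_j p_i p_{ik} A_{kj} + 2\sum_k p_i p_k p_{kj} A_{ij} = 0.}
#' The Birth-death fixation probability is then
#' \eqn{P \approx 1/N + (s/N) \sum_{ij} p_i p_j A_{ij}}. The normalization of
#' the pair coefficients is pinned by the complete graph: a single degree
#' class gives A = N/2, so the expansion becomes 1/N + s/2, the first-order
#' well-mixed value (the residual s/(2N) is second order under s ~ 1/N), and
#' the reported \code{difference} from the same-order well-mixed value,
#' \eqn{(s/N) (\sum_{ij} p_i p_j A_{ij} - N/2)}, is exactly zero on the
#' complete graph.
#'
#' @param summary An \code{eg_degree_classes} object.
#' @param N Population size (defaults to the summary's N).
#' @param s Selection coefficient.
#' @return An object of class \code{eg_regular_perturbation}: list with the
#'   symmetric coefficient matrix \code{A}, \code{p_fix}, \code{difference}
#'   (from the same-order well-mixed value), \code{n_unknowns} and the
#'   system's reciprocal condition number.
#' @export
solve_regular_perturbation <- function(summary, N = summary$N, s) {
  eg_check_summary(summary)
  k <- length(summary$D)
  p <- summary$p_i
  pij <- summary$p_ij
  h <- sum(p / summary$D)       # <d^-1>
  U <- eg_U(summary)            # p_i p_ij
  cs <- colSums(U)              # sum_k p_k p_ki
  n_unk <- k * (k + 1) / 2
  idx <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    (a - 1) * k - (a - 1) * a / 2 + b
  }
  M <- matrix(0, n_unk, n_unk)
  rhs <- numeric(n_unk)
  row <- 0L
  for (i in seq_len(k)) for (j in i:k) {
    row <- row + 1L
    # constants -> RHS
    rhs[row] <- U[j, i] / (h * summary$D[i]) + U[i, j] / (h * summary$D[j])
    M[row, idx(i, i)] <- M[row, idx(i, i)] + 2 * U[j, i] / N
    M[row, idx(j, j)] <- M[row, idx(j, j)] + 2 * U[i, j] / N
    M[row, idx(i, j)] <- M[row, idx(i, j)] + 2 * (p[j] * cs[i] + p[i] * cs[j])
    for (kk in seq_len(k)) {
      M[row, idx(kk, i)] <- M[row, idx(kk, i)] - 2 * p[i] * U[j, kk]
      M[row, idx(kk, j)] <- M[row, idx(kk, j)] - 2 * p[j] * U[i, kk]
    }
  }
  rc <- rcond(M)
  if (rc < .Machine$double.eps * 10) {
    stop(sprintf("regular-perturbation system is numerically singular (rcond = %.3e)", rc),
         call. = FALSE)
  }
  a_flat <- solve(M, rhs)
  A <- matrix(0, k, k, dimnames = dimnames(pij))
  for (i in seq_len(k)) for (j in i:k) {
    A[i, j] <- a_flat[idx(i, j)]; A[j, i] <- A[i, j]
  }
  pair_sum <- as.numeric(t(p) %*% A %*% p)
  p_fix <- 1 / N + (s / N) * pair_sum
  difference <- (s / N) * (pair_sum - N / 2)
  structure(
    list(A = A, p_fix = p_fix,
         p_fix_wellmixed = 1 / N + s / 2,
         difference = difference,
         n_unknowns = n_unk, rcond = rc,
         method = "regular-perturbation", rule = "Bd", s = s, N = N),
    class = "eg_regular_perturbation"
  )
}

#' @export
print.eg_regular_perturbation <- function(x, ...) {
  cat(sprintf(
    "Regular-perturbation result (Bd, s = %g, N = %d): P = %.6g, difference from well-mixed = %.6g (%d unknowns)\n",
    x$s, x$N, x$p_fix, x$difference, x$n_unknowns
  ))
  invisible(x)
}

#' Classify a graph by its amplification factor
#'
#' alpha > 1: amplifier of selection; alpha < 1: suppressor; alpha = 1 (within
#' tolerance): isothermal, i.e. fixation matches the well-mixed population.
#'
#' @param alpha Positive scalar, or an \code{eg_amplification} object.
#' @param tol Tolerance around 1 (default 1e-9).
#' @return "suppressor", "isothermal" or "amplifier".
#' @export
classify_alpha <- function(alpha, tol = 1e-9) {
  if (inherits(alpha, "eg_amplification")) alpha <- alpha$alpha
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  if (abs(alpha - 1) <= tol) "isothermal" else if (alpha > 1) "amplifier" else "suppressor"
}
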