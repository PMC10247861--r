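#' @title Fixation probabilities under death-Birth updating
#'
#' @description A uniformly random individual dies; one of its neighbors is
#' chosen to give birth with probability proportional to fitness (residents
#' have fitness 1, mutants fitness `r`) and fills the vacancy with its type.
#' With uniform initialization the fixation probability
#' \eqn{\varrho_G(r)} is the average, over all starting vertices, of the
#' probability that a single mutant takes over the whole graph. Comparing
#' \eqn{\varrho_G} with the complete-graph curve \eqn{\varrho_N} classifies a
#' graph as amplifier (\eqn{\varrho_G > \varrho_N} for all `r > 1` and
#' `<` for `r < 1`), suppressor (the reverse), or transient amplifier
#' (\eqn{\varrho_G > \varrho_N} only on a bounded window
#' \eqn{1 < r < r_{\max}}).
#' @name fixation
NULL

#' Exact fixation probability (absorbing-chain solve)
#'
#' Solves the linear system over all \eqn{2^N} mutant-set configurations;
#' feasible up to `size_limit` vertices (the default 13 means at most 8192
#' states, solved sparsely).
#'
#' @inheritParams graph_degrees
#' @param r Mutant fitness (> 0).
#' @param size_limit Refuse graphs with more vertices than this.
#' @return The fixation probability \eqn{\varrho_G(r)}.
#' @examples
#' fixation_exact(igraph::make_full_graph(4), 1) # 0.25
#' @export
fixation_exact <- function(g, r, size_limit = 13) {
  check_graph(g)
  if (r <= 0) abort("`r` must be positive")
  n <- igraph::vcount(g)
  if (n > size_limit)
    abort(sprintf("graph has %d vertices (> %d): use fixation_mc()", n,
                  size_limit))
  if (!is_connected_graph(g)) abort("graph must be connected")
  A <- adj_matrix(g)
  deg <- rowSums(A)
  nstates <- 2^n
  full <- nstates - 1
  states <- 0:(nstates - 1)
  popcount <- integer(nstates)
  for (v in seq_len(n) - 1)
    popcount <- popcount + bitwAnd(bitwShiftR(states, v), 1L)

  nbr_mask <- vapply(seq_len(n), function(v)
    sum(2^(which(A[v, ] > 0) - 1)), numeric(1))

  ti <- list(); tj <- list(); tx <- list()
  bfull <- numeric(nstates)
  for (v in seq_len(n)) {
    bit <- 2^(v - 1)
    mut_nbrs <- popcount[bitwAnd(states, nbr_mask[v]) + 1]
    p_mut <- (r * mut_nbrs) / (r * mut_nbrs + (deg[v] - mut_nbrs))
    up <- bitwOr(states, bit)      # v becomes mutant
    down <- states - bitwAnd(states, bit) # v becomes resident
    ti[[length(ti) + 1]] <- states + 1
    tj[[length(tj) + 1]] <- up + 1
    tx[[length(tx) + 1]] <- p_mut / n
    ti[[length(ti) + 1]] <- states + 1
    tj[[length(tj) + 1]] <- down + 1
    tx[[length(tx) + 1]] <- (1 - p_mut) / n
  }
  i <- unlist(ti); j <- unlist(tj); x <- unlist(tx)
  # drop transitions out of the two absorbing states and split off the
  # inflow into the full-mutant state as the right-hand side
  keep_from <- i != 1 & i != full + 1
  i <- i[keep_from]; j <- j[keep_from]; x <- x[keep_from]
  to_full <- j == full + 1
  for (idx in which(to_full)) bfull[i[idx]] <- bfull[i[idx]] + x[idx]
  keep <- !to_full & j != 1
  # aggregate duplicate transitions sparsely, then solve densely: the state
  # graph is hypercube-like, so sparse LU suffers massive fill-in while a
  # dense LAPACK solve is fast and exact at these sizes
  Q <- Matrix::sparseMatrix(i = i[keep] - 1, j = j[keep] - 1, x = x[keep],
                            dims = c(nstates - 2, nstates - 2))
  M <- diag(nstates - 2) - as.matrix(Q)
  sol <- solve(M, bfull[2:(nstates - 1)])
  singles <- 2^(seq_len(n) - 1)
  mean(sol[singles]) # state index within transient block = S (since S >= 1)
}

#' Closed-form fixation probability on the complete graph
#'
#' The death-Birth process on \eqn{K_N} lumps to a birth-death chain on the
#' mutant count; the standard ratio formula gives \eqn{\varrho_N(r)} exactly.
#'
#' @param n Number of vertices.
#' @param r Mutant fitness.
#' @export
fixation_complete <- function(n, r) {
  m <- seq_len(n - 1)
  gamma <- (r * m + n - 1 - m) / (r * (r * (m - 1) + n - m))
  1 / (1 + sum(cumprod(gamma)))
}

#' Monte-Carlo fixation probability
#'
#' Simulates independent death-Birth trajectories from a uniformly random
#' single mutant. Reproducible for a given `seed`.
#'
#' @inheritParams fixation_exact
#' @param replicates Number of independent runs.
#' @param seed Optional integer passed to [set.seed()].
#' @return A list with `estimate`, `se` (binomial standard error),
#'   `replicates` and `fixed`.
#' @export
fixation_mc <- function(g, r, replicates = 10000, seed = NULL) {
  check_graph(g)
  if (replicates < 1) abort("`replicates` must be at least 1")
  if (!is_connected_graph(g)) abort("graph must be connected")
  if (!is.null(seed)) set.seed(seed)
  fixed <- cpp_fixation_mc(adj_matrix(g), r, as.integer(replicates))
  p <- fixed / replicates
  list(estimate = p, se = sqrt(p * (1 - p) / replicates),
       replicates = replicates, fixed = fixed)
}

default_r_grid <- function(points = 41) {
  exp(seq(log(0.25), log(4), length.out = points))
}

#' Classify a graph against the complete-graph baseline
#'
#' Computes \eqn{\varrho_G} exactly on a fitness grid spanning both sides of
#' `r = 1`, compares with the complete-graph closed form, and reports the
#' classification together with (when applicable) the bracket of the
#' transient window's upper end \eqn{r_{\max}}. Sign changes above `r = 1`
#' are refined by a few bisection steps. The classification is reported,
#' never enforced.
#'
#' @inheritParams fixation_exact
#' @param r_grid Fitness grid (must span both sides of 1); default 41
#'   geometric points on `[0.25, 4]`.
#' @param tol Tolerance on \eqn{\varrho} differences.
#' @param refine Bisection refinement steps per detected sign change.
#' @return An object of class `fixation_result`: list with `r_grid`,
#'   `rho_graph`, `rho_complete`, `classification` (one of `"amplifier"`,
#'   `"suppressor"`, `"transient_amplifier"`, `"other"`) and `window`
#'   (`c(r_min, r_max)` bracket midpoints, `NA` when not applicable).
#' @export
classify <- function(g, r_grid = default_r_grid(), tol = 1e-10, refine = 2) {
  check_graph(g)
  n <- igraph::vcount(g)
  if (min(r_grid) >= 1 || max(r_grid) <= 1)
    abort("`r_grid` must span both sides of r = 1")
  r_grid <- sort(unique(r_grid))
  rho_g <- vapply(r_grid, function(r) fixation_exact(g, r), numeric(1))

  # refine around sign changes of the difference for r > 1
  for (pass in seq_len(refine)) {
    rho_n <- vapply(r_grid, function(r) fixation_complete(n, r), numeric(1))
    dd <- rho_g - rho_n
    above <- which(r_grid > 1)
    flips <- above[which(diff(sign(dd[above])) != 0)]
    new_r <- setdiff(vapply(flips, function(i)
      (r_grid[i] + r_grid[i + 1]) / 2, numeric(1)), r_grid)
    if (length(new_r) == 0) break
    new_rho <- vapply(new_r, function(r) fixation_exact(g, r), numeric(1))
    ord <- order(c(r_grid, new_r))
    rho_g <- c(rho_g, new_rho)[ord]
    r_grid <- c(r_grid, new_r)[ord]
  }
  rho_n <- vapply(r_grid, function(r) fixation_complete(n, r), numeric(1))
  dd <- rho_g - rho_n
  below <- r_grid < 1 - 1e-12
  above <- r_grid > 1 + 1e-12
  sgn <- function(x) ifelse(x > tol, 1L, ifelse(x < -tol, -1L, 0L))
  s <- sgn(dd)

  classification <- "other"
  window <- c(NA_real_, NA_real_)
  if (all(s[below] <= 0) && all(s[above] >= 0) && any(s[above] > 0) &&
      any(s[below] < 0)) {
    classification <- "amplifier"
  } else if (all(s[below] >= 0) && all(s[above] <= 0) && any(s[above] < 0) &&
             any(s[below] > 0)) {
    classification <- "suppressor"
  } else {
    sa <- s[above]
    ra <- r_grid[above]
    pos <- which(sa > 0)
    if (length(pos) > 0 && pos[1] == 1 && all(diff(pos) == 1) &&
        max(pos) < length(sa) && all(sa[(max(pos) + 1):length(sa)] <= 0)) {
      # positive just above 1, then nonpositive: transient window
      classification <- "transient_amplifier"
      r_max <- (ra[max(pos)] + ra[max(pos) + 1]) / 2
      neg_below <- which(s[below] < 0)
      r_min <- if (length(neg_below)) min(r_grid[below][neg_below]) else NA_real_
      window <- c(r_min, r_max)
    }
  }
  structure(list(r_grid = r_grid, rho_graph = rho_g, rho_complete = rho_n,
                 classification = classification, window = window, n = n),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("<fixation_result>  N = %d, classification: %s\n", x$n,
              x$classification))
  if (!all(is.na(x$window)))
    cat(sprintf("  transient window bracket: r_min ~ %.4g, r_max ~ %.4g\n",
                x$window[1], x$window[2]))
  invisible(x)
}

#' @export
tidy.fixation_result <- function(x, ...) {
  tibble(r = x$r_grid, rho_graph = x$rho_graph, rho_complete = x$rho_complete,
         difference = x$rho_graph - x$rho_complete)
}

#' @export
glance.fixation_result <- function(x, ...) {
  tibble(n = x$n, classification = x$classification,
         r_min = x$window[1], r_max = x$window[2])
}

#' @export
autoplot.fixation_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$r, y = .data$difference)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_vline(xintercept = 1, linetype = "dotted") +
    scale_x_log10() +
    labs(x = "mutant fitness r",
         y = expression(varrho[G](r) - varrho[N](r)))
}
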