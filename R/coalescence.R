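#' @title Coalescing random walks and the weak-selection amplifier test
#'
#' @description Two coalescing random walkers on a connected graph meet in
#' expected time \eqn{\tau_{ij}} when started on vertices \eqn{i, j}; at each
#' step one of the two walkers (chosen with probability 1/2) moves to a
#' uniformly random neighbor. The \eqn{\tau_{ij}} solve a linear system over
#' the \eqn{\binom{N}{2}} unordered pairs,
#' \deqn{\tau_{ij} = 1 + \tfrac12 \sum_k (p_{ik}\tau_{jk} + p_{jk}\tau_{ik}),
#'   \quad \tau_{ii} = 0,}
#' with step probabilities \eqn{p_{ij} = 1/k_i} along edges. The remeeting
#' time of vertex \eqn{i} is \eqn{\tau_i = 1 + \sum_j p_{ij}\tau_{ij}}, the
#' relative degree is \eqn{\pi_i = k_i / \sum_j k_j}, and the effective
#' population size is \eqn{N_{\mathrm{eff}} = \sum_i \pi_i \tau_i}. A graph is
#' an amplifier of weak selection under death-Birth updating iff
#' \eqn{N_{\mathrm{eff}} > N}; regular graphs satisfy
#' \eqn{N_{\mathrm{eff}} = N} exactly (isothermal theorem), so only
#' non-regular graphs can amplify. The remeeting times always obey the
#' identity \eqn{\sum_i \pi_i^2 \tau_i = 1}.
#' @name coalescence
NULL

# C(N,2) beyond which the dense LAPACK path gives way to a sparse LU solve
.coalescence_dense_limit <- 1500

#' Pairwise coalescence times
#'
#' @inheritParams graph_degrees
#' @return A symmetric `N x N` matrix with zero diagonal and positive
#'   off-diagonal entries (expected meeting times in steps).
#' @examples
#' coalescence_times(igraph::make_ring(3))
#' @export
coalescence_times <- function(g) {
  check_graph(g)
  coalescence_result(g)$tau_pair
}

#' Per-vertex remeeting times
#'
#' @inheritParams graph_degrees
#' @param tau_pair Optional matrix from [coalescence_times()]; recomputed if
#'   missing.
#' @return A numeric vector of remeeting times, all at least 1.
#' @export
remeeting_times <- function(g, tau_pair = NULL) {
  check_graph(g)
  if (is.null(tau_pair)) return(coalescence_result(g)$tau_remeet)
  A <- adj_matrix(g)
  as.numeric(1 + rowSums(A * tau_pair) / rowSums(A))
}

# full coalescence bundle for one graph
coalescence_result <- function(g) {
  A <- adj_matrix(g)
  n <- nrow(A)
  if (n < 2) abort("need at least 2 vertices")
  if (!cpp_connected(A)) abort("graph is disconnected: coalescence times undefined")
  res <- if (n * (n - 1) / 2 <= .coalescence_dense_limit) {
    cpp_coalescence(A)
  } else {
    coalescence_sparse(A)
  }
  structure(
    list(tau_pair = res$tau_pair, tau_remeet = as.numeric(res$tau_remeet),
         pi = as.numeric(res$pi), n_eff = res$n_eff, n = n),
    class = "coalescence_result")
}

# sparse assembly + LU for large pair systems (each row has <= k_i + k_j + 1
# nonzeros, so sparsity pays off quickly)
coalescence_sparse <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  pidx <- matrix(0L, n, n)
  pidx[lower.tri(pidx)] <- seq_len(n * (n - 1) / 2)
  pidx <- pidx + t(pidx)
  m <- n * (n - 1) / 2
  nbr <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  ri <- rj <- rx <- vector("list", m)
  pos <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pos <- pos + 1
      row <- pidx[i, j]
      ki <- nbr[[i]]; kj <- nbr[[j]]
      ki <- ki[ki != j]; kj <- kj[kj != i]
      cols <- c(row, pidx[cbind(ki, j)], pidx[cbind(i, kj)])
      vals <- c(1, rep(-0.5 / deg[i], length(ki)), rep(-0.5 / deg[j], length(kj)))
      ri[[pos]] <- rep.int(row, length(cols))
      rj[[pos]] <- cols
      rx[[pos]] <- vals
    }
  }
  M <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(rj), x = unlist(rx),
                            dims = c(m, m))
  x <- as.numeric(Matrix::solve(M, rep(1, m)))
  tau <- matrix(0, n, n)
  tau[lower.tri(tau)] <- x
  tau <- tau + t(tau)
  tau_i <- 1 + rowSums(A * tau) / deg
  pi <- deg / sum(deg)
  list(tau_pair = tau, tau_remeet = tau_i, pi = pi,
       n_eff = sum(pi * tau_i))
}

#' Effective population size of a graph
#'
#' @inheritParams graph_degrees
#' @return A list with `n_eff` and the full `coalescence_result` object
#'   (fields `tau_pair`, `tau_remeet`, `pi`, `n_eff`, `n`).
#' @examples
#' effective_population_size(igraph::make_full_graph(5))$n_eff # exactly 5
#' @export
effective_population_size <- function(g) {
  res <- coalescence_result(g)
  list(n_eff = res$n_eff, result = res)
}

#' Weak-selection amplifier test
#'
#' `TRUE` iff \eqn{N_{\mathrm{eff}} - N > } `tol`. The default tolerance is
#' far below the margins of genuine amplifiers (the smallest observed margins
#' are of order 1e-3) and far above solver noise.
#'
#' @inheritParams graph_degrees
#' @param tol Amplification margin.
#' @export
is_weak_selection_amplifier <- function(g, tol = 1e-9) {
  res <- coalescence_result(g)
  res$n_eff - res$n > tol
}

#' @export
tidy.coalescence_result <- function(x, ...) {
  tibble(vertex = seq_len(x$n), pi = x$pi, tau_remeet = x$tau_remeet)
}

#' @export
glance.coalescence_result <- function(x, ...) {
  tibble(n = x$n, n_eff = x$n_eff,
         identity_sum = sum(x$pi^2 * x$tau_remeet),
         amplifier = x$n_eff - x$n > 1e-9)
}

#' @export
print.coalescence_result <- function(x, ...) {
  cat(sprintf("<coalescence_result>  N = %d, N_eff = %.6f (%s)\n", x$n, x$n_eff,
              if (x$n_eff - x$n > 1e-9) "amplifier of weak selection"
              else "not an amplifier"))
  invisible(x)
}
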