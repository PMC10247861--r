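#' @title Remeeting-time histories and perturbation-guided vertex selection
#'
#' @description Along a lineage of edge removals, each candidate graph keeps
#' the full history of its per-vertex remeeting times
#' \eqn{\tau_i(0), \tau_i(1), \ldots}. The vertex from which the next edge is
#' removed is the argmax of the moving difference
#' \eqn{\Delta^j \tau_i = \tau_i(j) - \tau_i(j-1)} (the remeeting time itself
#' at \eqn{j = 0}). The moving difference was found to outperform the exact
#' forward difference \eqn{\sum_p (-1)^{j-p} \binom{j}{p} \tau_i(p)} as a
#' guide, but the forward difference is available via
#' `difference = "forward"` for experimentation.
#' @name guidance
NULL

#' Create a remeeting-time history
#'
#' @param tau0 Remeeting times of the (regular) input graph.
#' @return An object of class `tau_history`: list with `tau` (an
#'   `N x (removals + 1)` matrix, columns indexed by removal count) and
#'   `removed_from` (integer vector of vertices an edge was removed from).
#' @export
tau_history <- function(tau0) {
  structure(list(tau = matrix(as.numeric(tau0), ncol = 1),
                 removed_from = integer(0)),
            class = "tau_history")
}

# extend a history by one removal step
extend_history <- function(history, tau_new, vertex) {
  history$tau <- cbind(history$tau, as.numeric(tau_new))
  history$removed_from <- c(history$removed_from, vertex)
  history
}

#' Moving (or forward) difference of remeeting times
#'
#' @param history A `tau_history`.
#' @param j Removal index; `j = 0` returns \eqn{\tau_i(0)} itself.
#' @param difference `"moving"` (default): \eqn{\tau_i(j) - \tau_i(j-1)};
#'   `"forward"`: \eqn{\sum_{p=0}^{j} (-1)^{j-p} \binom{j}{p} \tau_i(p)}.
#' @return Per-vertex numeric vector \eqn{\Delta^j \tau_i}.
#' @export
moving_difference <- function(history, j, difference = c("moving", "forward")) {
  difference <- match.arg(difference)
  if (j < 0) abort("`j` must be nonnegative")
  if (ncol(history$tau) < j + 1)
    abort(sprintf("history holds %d entries but j = %d needs %d",
                  ncol(history$tau), j, j + 1))
  if (j == 0) return(history$tau[, 1])
  if (difference == "moving") {
    history$tau[, j + 1] - history$tau[, j]
  } else {
    p <- 0:j
    as.numeric(history$tau[, p + 1, drop = FALSE] %*%
                 ((-1)^(j - p) * choose(j, p)))
  }
}

#' Select the vertex for the next edge removal
#'
#' The argmax of \eqn{\Delta^j \tau_i} over all vertices, ties broken by the
#' lowest vertex index. Values within `tie_tol` of the maximum count as tied,
#' so that symmetric graphs (where remeeting times are equal up to eigensolver
#' noise) select reproducibly. A pure function of its inputs: identical
#' histories give identical selections.
#'
#' @param history A `tau_history` consistent with `g`.
#' @param g Current graph of the lineage.
#' @param j Removal index (number of removals already performed).
#' @param tie_tol Absolute slack under the maximum treated as a tie.
#' @inheritParams moving_difference
#' @return A single vertex index.
#' @export
select_vertex <- function(history, g, j = ncol(history$tau) - 1,
                          difference = c("moving", "forward"),
                          tie_tol = 1e-9) {
  d <- moving_difference(history, j, difference)
  which(d >= max(d) - tie_tol)[1] # lowest-index tie-break
}
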