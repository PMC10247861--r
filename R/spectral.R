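#' @title Laplacian spectra, densities and the spectral pseudometric
#'
#' @description The standard Laplacian is \eqn{L = D - A}, the normalized
#' Laplacian \eqn{\Lambda = I - D^{-1/2} A D^{-1/2}}; their sorted spectra are
#' \eqn{0 = \mu_1 \le \dots \le \mu_N} and
#' \eqn{0 = \lambda_1 \le \dots \le \lambda_N \le 2}. The second-smallest
#' eigenvalues \eqn{\mu_2, \lambda_2} (algebraic connectivities) govern the
#' filtering of the guided search. A smoothed spectral density convolves the
#' eigenvalues with a Gaussian kernel of width \eqn{\sigma} (default
#' \eqn{1/(3N)}), and the L1 distance between two densities on \eqn{[0, 2]}
#' is a pseudometric on graphs.
#' @name spectral
NULL

#' Standard and normalized Laplacian matrices
#'
#' @inheritParams graph_degrees
#' @return A list with matrices `standard` (\eqn{D - A}) and `normalized`
#'   (\eqn{I - D^{-1/2} A D^{-1/2}}).
#' @export
laplacians <- function(g) {
  check_graph(g)
  A <- adj_matrix(g)
  k <- rowSums(A)
  if (any(k == 0)) abort("graph has an isolated vertex")
  dinv <- 1 / sqrt(k)
  list(standard = diag(k) - A,
       normalized = diag(nrow(A)) - A * outer(dinv, dinv))
}

#' Sorted Laplacian spectra and algebraic connectivities
#'
#' @inheritParams graph_degrees
#' @return An object of class `spectral_summary`: list with `mu`, `lam`
#'   (sorted spectra), `mu2`, `lam2` (algebraic connectivities) and `n`.
#'   Normalized eigenvalues within 1e-9 of 0 or 2 are clipped to the bound.
#' @export
spectral_summary <- function(g) {
  check_graph(g)
  sp <- cpp_lap_spectra(adj_matrix(g))
  lam <- sp$lam
  lam[abs(lam) < 1e-9] <- 0
  lam[abs(lam - 2) < 1e-9] <- 2
  mu <- sp$mu
  mu[abs(mu) < 1e-9] <- 0
  structure(list(mu = sort(mu), lam = sort(lam),
                 mu2 = sort(mu)[2], lam2 = sort(lam)[2],
                 n = igraph::vcount(g)),
            class = "spectral_summary")
}

#' @export
tidy.spectral_summary <- function(x, ...) {
  tibble(index = seq_len(x$n), mu = x$mu, lam = x$lam)
}

#' @export
glance.spectral_summary <- function(x, ...) {
  tibble(n = x$n, mu2 = x$mu2, lam2 = x$lam2,
         mu_sum = sum(x$mu), lam_sum = sum(x$lam))
}

#' Interlacing check for a single edge removal
#'
#' Standard Laplacian: \eqn{\mu_{i-1}(G) \le \mu_i(G - e) \le \mu_i(G)} for
#' \eqn{i = 2..N}. Normalized Laplacian:
#' \eqn{\lambda_{i-1}(G) \le \lambda_i(G - e) \le \lambda_{i+1}(G)} for
#' \eqn{i = 2..N-1}. Both are theorems, so the checks should always pass;
#' they exist as assertion hooks for the search.
#'
#' @inheritParams graph_degrees
#' @param edge Length-2 vector of vertex indices of an existing edge.
#' @param tol Numerical slack on the inequalities.
#' @return A list with logicals `standard_ok` and `normalized_ok`.
#' @export
interlacing_check <- function(g, edge, tol = 1e-9) {
  check_graph(g)
  s0 <- spectral_summary(g)
  s1 <- spectral_summary(remove_edge(g, edge[1], edge[2]))
  n <- s0$n
  i <- 2:n
  standard_ok <- all(s0$mu[i - 1] <= s1$mu[i] + tol) &&
    all(s1$mu[i] <= s0$mu[i] + tol)
  i <- 2:(n - 1)
  normalized_ok <- all(s0$lam[i - 1] <= s1$lam[i] + tol) &&
    all(s1$lam[i] <= s0$lam[i + 1] + tol)
  list(standard_ok = standard_ok, normalized_ok = normalized_ok)
}

#' Default density grid: 2001 uniform points on [0, 2]
#' @param upper Upper end of the grid (2 for normalized spectra; use
#'   `2 * max(degree)` for standard spectra).
#' @param points Number of grid points.
#' @export
density_grid <- function(upper = 2, points = 2001) {
  seq(0, upper, length.out = points)
}

#' Smoothed spectral density
#'
#' \deqn{\varphi(x) = \frac{1}{N} \sum_i \frac{1}{\sqrt{2\pi\sigma^2}}
#'   \exp\!\left(-\frac{(x - \lambda_i)^2}{2\sigma^2}\right)}
#' with default kernel width \eqn{\sigma = 1/(3N)}.
#'
#' @param spectrum Sorted eigenvalues.
#' @param sigma Gaussian kernel width; default `1 / (3 * length(spectrum))`.
#' @param grid Evaluation grid (strictly increasing), default
#'   [density_grid()].
#' @return An object of class `spectral_density`: list with `grid`, `values`,
#'   `sigma`.
#' @export
spectral_density <- function(spectrum, sigma = 1 / (3 * length(spectrum)),
                             grid = density_grid()) {
  if (sigma <= 0) abort("`sigma` must be positive")
  vals <- rowMeans(exp(-outer(grid, spectrum, "-")^2 / (2 * sigma^2))) /
    sqrt(2 * pi * sigma^2)
  structure(list(grid = grid, values = vals, sigma = sigma),
            class = "spectral_density")
}

# trapezoidal quadrature on the density grid
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Spectral pseudometric distance between two graphs
#'
#' \eqn{d(G, G') = \int_0^2 |\varphi_G(x) - \varphi_{G'}(x)|\, dx},
#' computed by trapezoidal quadrature on a shared grid of normalized-Laplacian
#' densities.
#'
#' @param g,g2 Graphs, or `spectral_density` objects on a shared grid.
#' @param grid Shared evaluation grid.
#' @return A nonnegative number.
#' @export
spectral_distance <- function(g, g2, grid = density_grid()) {
  d1 <- if (inherits(g, "spectral_density")) g
        else spectral_density(spectral_summary(g)$lam, grid = grid)
  d2 <- if (inherits(g2, "spectral_density")) g2
        else spectral_density(spectral_summary(g2)$lam, grid = grid)
  if (length(d1$grid) != length(d2$grid) || any(d1$grid != d2$grid))
    abort("densities must share a grid")
  trapz(d1$grid, abs(d1$values - d2$values))
}

#' Ensemble spectral density of a set of graphs
#'
#' Arithmetic mean of the member densities on a common grid; each member's
#' kernel width follows `sigma_rule(N)`.
#'
#' @param graphs Nonempty list of igraph objects, or a list of spectra
#'   (numeric vectors).
#' @param sigma_rule Function of the spectrum length giving \eqn{\sigma}.
#' @param grid Common evaluation grid.
#' @return A `spectral_density` object.
#' @export
ensemble_density <- function(graphs, sigma_rule = function(n) 1 / (3 * n),
                             grid = density_grid()) {
  if (length(graphs) == 0) abort("`graphs` must be nonempty")
  spectra <- lapply(graphs, function(g)
    if (is.numeric(g)) g else spectral_summary(g)$lam)
  dens <- vapply(spectra, function(s)
    spectral_density(s, sigma = sigma_rule(length(s)), grid = grid)$values,
    numeric(length(grid)))
  structure(list(grid = grid, values = rowMeans(dens),
                 sigma = sigma_rule(length(spectra[[1]]))),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("<spectral_density>  %d grid points on [%g, %g], sigma = %g\n",
              length(x$grid), min(x$grid), max(x$grid), x$sigma))
  invisible(x)
}

#' @export
autoplot.spectral_density <- function(object, ...) {
  ggplot(tibble(x = object$grid, density = object$values),
         aes(x = .data$x, y = .data$density)) +
    geom_line() +
    labs(x = expression(lambda), y = expression(phi(lambda)))
}
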