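#' @title Guided iterative edge-removal search for transient amplifiers
#'
#' @description Starting from a connected k-regular graph, edges are removed
#' one at a time. At each step every candidate graph selects the vertex with
#' the largest moving difference of remeeting times (see [select_vertex()])
#' and spawns one child per edge incident to that vertex. Children that become
#' disconnected are discarded; the pooled children of the step are
#' deduplicated by their normalized-Laplacian cospectral key (a cheap proxy
#' for isomorphism); in greedy mode only the `filter_size` children with the
#' smallest algebraic connectivity \eqn{\lambda_2} pass the filter. Every
#' retained child is tested with the effective-population-size criterion
#' \eqn{N_{\mathrm{eff}} > N}; hits are recorded as transient-amplifier
#' candidates and continue to be expanded (consecutive amplifiers occur).
#' The search stops when the pool empties or after
#' `max_removals = 1 + (k-2)N/2` steps, the connectivity bound on how many
#' edges a connected graph can lose.
#' @name search
NULL

#' Search configuration
#'
#' @param mode `"greedy"` (spectral filter, default) or `"enumerative"`
#'   (exhaustive; no filter).
#' @param filter_size Maximum pool size passed to the next step (greedy mode);
#'   `Inf` makes greedy identical to enumerative.
#' @param filter_measure `"lambda2"` (normalized Laplacian, default) or
#'   `"mu2"` (standard Laplacian; kept for comparison runs -- it is not
#'   expected to find amplifiers).
#' @param max_removals Total edge-removal bound; `NULL` (default) uses
#'   `1 + (k-2)*N/2`.
#' @param amplifier_tol Margin on `n_eff - N` for recording an amplifier.
#' @param cospectral_decimals Rounding of eigenvalues in the dedup key.
#' @param record_dynamics Record per-member spectra for
#'   [spectral_dynamics()].
#' @param difference Vertex-guidance difference, see [moving_difference()].
#' @param stop_at_first_amplifier Stop expanding a lineage once it records an
#'   amplifier (speed option; default expands further).
#' @param check_interlacing Assert Laplacian interlacing for every executed
#'   edge removal (test hook).
#' @return A list of class `search_config`.
#' @export
search_config <- function(mode = c("greedy", "enumerative"),
                          filter_size = 500,
                          filter_measure = c("lambda2", "mu2"),
                          max_removals = NULL,
                          amplifier_tol = 1e-9,
                          cospectral_decimals = 9,
                          record_dynamics = FALSE,
                          difference = c("moving", "forward"),
                          stop_at_first_amplifier = FALSE,
                          check_interlacing = FALSE) {
  mode <- match.arg(mode)
  filter_measure <- match.arg(filter_measure)
  difference <- match.arg(difference)
  if (filter_size < 1) abort("`filter_size` must be at least 1")
  if (!is.null(max_removals) && max_removals < 1)
    abort("`max_removals` must be at least 1")
  structure(list(mode = mode, filter_size = filter_size,
                 filter_measure = filter_measure, max_removals = max_removals,
                 amplifier_tol = amplifier_tol,
                 cospectral_decimals = cospectral_decimals,
                 record_dynamics = record_dynamics, difference = difference,
                 stop_at_first_amplifier = stop_at_first_amplifier,
                 check_interlacing = check_interlacing),
            class = "search_config")
}

assert_interlacing <- function(mu0, lam0, mu1, lam1) {
  n <- length(mu0)
  tol <- 1e-9
  i <- 2:n
  ok_s <- all(mu0[i - 1] <= mu1[i] + tol) && all(mu1[i] <= mu0[i] + tol)
  i <- 2:(n - 1)
  ok_n <- all(lam0[i - 1] <= lam1[i] + tol) && all(lam1[i] <= lam0[i + 1] + tol)
  if (!(ok_s && ok_n)) abort("Laplacian interlacing violated by an edge removal")
  invisible(TRUE)
}

#' Run the guided edge-removal search from one regular input graph
#'
#' @param g_in A connected k-regular igraph object, `k >= 3`.
#' @param config A [search_config()].
#' @param input_id Label carried into the amplifier records.
#' @return An object of class `search_result`: list with `amplifiers` (list of
#'   records: `graph`, `n_eff`, `removals`, `lineage`, `input_id`), `steps`
#'   (tibble of per-step pool statistics), `trace` (member-level records when
#'   `record_dynamics`), `n`, `k`, `config`.
#' @export
run_search <- function(g_in, config = search_config(), input_id = "input") {
  check_graph(g_in)
  A0 <- adj_matrix(g_in)
  n <- nrow(A0)
  deg <- rowSums(A0)
  k <- deg[1]
  if (any(deg != k) || k < 3)
    abort("input must be k-regular with k >= 3")
  if (!cpp_connected(A0)) abort("input must be connected")
  max_removals <- config$max_removals %||% (1 + (k - 2) * n / 2)

  res0 <- cpp_coalescence(A0)
  sp0 <- cpp_lap_spectra(A0)
  root <- list(A = A0, hist = tau_history(res0$tau_remeet),
               lineage = matrix(integer(0), 0, 2), id = 1L, parent = NA_integer_,
               lam = sp0$lam, mu = sp0$mu, n_eff = res0$n_eff)
  pool <- list(root)
  next_id <- 2L
  amplifiers <- list()
  steps <- list()
  trace <- if (config$record_dynamics) {
    list(list(ell = 0L, id = 1L, parent = NA_integer_, lam = sp0$lam,
              n_eff = res0$n_eff, amplifier = FALSE))
  } else NULL
  use_mu2 <- config$filter_measure == "mu2"

  for (ell in seq_len(max_removals)) {
    children <- vector("list", length(pool) * k)
    nc <- 0L
    for (member in pool) {
      v <- select_vertex(member$hist, j = ell - 1L,
                         difference = config$difference)
      kids <- cpp_eval_children(member$A, v)
      for (kid in kids) {
        if (!kid$connected) next
        childA <- member$A
        childA[v, kid$u] <- 0
        childA[kid$u, v] <- 0
        mu <- NULL
        if (use_mu2 || config$check_interlacing)
          mu <- cpp_lap_spectra(childA)$mu
        if (config$check_interlacing)
          assert_interlacing(member$mu %||% cpp_lap_spectra(member$A)$mu,
                             member$lam, mu, kid$lam)
        nc <- nc + 1L
        children[[nc]] <- list(
          A = childA, lam = kid$lam, mu = mu,
          key = spectrum_key(kid$lam, config$cospectral_decimals),
          parent = member, edge = c(v, kid$u))
      }
    }
    if (nc == 0L) break
    children <- children[seq_len(nc)]

    keys <- vapply(children, `[[`, character(1), "key")
    children <- children[!duplicated(keys)]

    # the pool is always kept sorted by the filter measure (ties by the
    # cospectral key, which is unique after dedup), so the greedy filter is a
    # plain truncation and the processing order -- which decides first-wins
    # lineage retention on later cospectral collisions -- is deterministic
    measure <- vapply(children, function(ch)
      if (use_mu2) ch$mu[2] else ch$lam[2], numeric(1))
    ord <- order(measure, vapply(children, `[[`, character(1), "key"))
    children <- children[ord]
    if (config$mode == "greedy" && is.finite(config$filter_size) &&
        length(children) > config$filter_size) {
      children <- children[seq_len(config$filter_size)]
    }

    new_pool <- vector("list", length(children))
    lam2s <- numeric(length(children))
    for (i in seq_along(children)) {
      ch <- children[[i]]
      res <- cpp_coalescence(ch$A)
      member <- list(
        A = ch$A,
        hist = extend_history(ch$parent$hist, res$tau_remeet, ch$edge[1]),
        lineage = rbind(ch$parent$lineage, ch$edge),
        id = next_id, parent = ch$parent$id,
        lam = ch$lam, mu = ch$mu, n_eff = res$n_eff)
      next_id <- next_id + 1L
      lam2s[i] <- ch$lam[2]
      is_amp <- res$n_eff - n > config$amplifier_tol
      if (is_amp) {
        amplifiers[[length(amplifiers) + 1]] <- list(
          graph = graph_from_adj(ch$A), n_eff = res$n_eff, removals = ell,
          lineage = member$lineage, input_id = input_id,
          key = spectrum_key(ch$lam, config$cospectral_decimals),
          lam2 = ch$lam[2], member_id = member$id)
      }
      if (config$record_dynamics)
        trace[[length(trace) + 1]] <- list(ell = ell, id = member$id,
                                           parent = member$parent,
                                           lam = ch$lam, n_eff = res$n_eff,
                                           amplifier = is_amp)
      member$is_amp <- is_amp
      new_pool[[i]] <- member
    }
    n_amp_step <- sum(vapply(new_pool, `[[`, logical(1), "is_amp"))
    if (config$stop_at_first_amplifier)
      new_pool <- new_pool[!vapply(new_pool, `[[`, logical(1), "is_amp")]
    steps[[ell]] <- tibble(
      ell = ell, pool_size = length(new_pool),
      lam2_min = if (length(lam2s)) min(lam2s) else NA_real_,
      lam2_mean = if (length(lam2s)) mean(lam2s) else NA_real_,
      lam2_max = if (length(lam2s)) max(lam2s) else NA_real_,
      amplifiers = n_amp_step)
    pool <- new_pool
    if (length(pool) == 0L) break
  }

  structure(list(amplifiers = amplifiers,
                 steps = dplyr::bind_rows(steps),
                 trace = trace, n = n, k = k,
                 input_id = input_id, config = config),
            class = "search_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result>  input %s (N = %d, k = %d): %d amplifier record(s)\n",
              x$input_id, x$n, x$k, length(x$amplifiers)))
  invisible(x)
}

#' @export
tidy.search_result <- function(x, ...) {
  if (length(x$amplifiers) == 0)
    return(tibble(input_id = character(0), n_eff = numeric(0),
                  removals = integer(0), lam2 = numeric(0),
                  k_max = numeric(0), k_min = numeric(0), k_mean = numeric(0)))
  dplyr::bind_rows(lapply(x$amplifiers, function(a) {
    d <- graph_degrees(a$graph)
    tibble(input_id = a$input_id, n_eff = a$n_eff, removals = a$removals,
           lam2 = a$lam2, k_max = d$k_max, k_min = d$k_min, k_mean = d$k_mean)
  }))
}

#' @export
glance.search_result <- function(x, ...) {
  keys <- vapply(x$amplifiers, `[[`, character(1), "key")
  tibble(n = x$n, k = x$k, total_amplifiers = length(unique(keys)),
         found_any = length(x$amplifiers) > 0,
         steps_run = nrow(x$steps))
}

#' Run a campaign over a set of regular input graphs
#'
#' Applies [run_search()] to every input and aggregates: `A_k` counts inputs
#' yielding at least one amplifier, `#_tot` counts amplifier records after
#' per-run cospectral dedup, `#_noniso` counts canonically distinct amplifier
#' graphs pooled across the campaign, and the mean degree is averaged over
#' the non-isomorphic set.
#'
#' @param inputs List of connected k-regular igraph objects on a common
#'   vertex count (names become input ids).
#' @param config A [search_config()].
#' @param progress Emit a message per input.
#' @return An object of class `campaign_result`: list with `runs` (the
#'   `search_result`s), `amplifiers` (pooled non-isomorphic graphs), and
#'   `stats` (one-row tibble: `n`, `k`, `inputs`, `inputs_with_amplifier`,
#'   `total_amplifiers`, `nonisomorphic_amplifiers`, `mean_degree_noniso`).
#' @export
run_campaign <- function(inputs, config = search_config(), progress = FALSE) {
  if (length(inputs) == 0) abort("`inputs` must be nonempty")
  ids <- names(inputs) %||% as.character(seq_along(inputs))
  if (is.null(names(inputs))) names(inputs) <- ids
  ns <- vapply(inputs, igraph::vcount, numeric(1))
  if (length(unique(ns)) != 1) abort("all inputs must share the same N")
  runs <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    if (progress) inform(sprintf("searching input %s (%d/%d)", ids[i], i,
                                 length(inputs)))
    runs[[i]] <- run_search(inputs[[i]], config, input_id = ids[i])
  }
  names(runs) <- ids

  per_run_tot <- vapply(runs, function(r)
    length(unique(vapply(r$amplifiers, `[[`, character(1), "key"))),
    numeric(1))
  all_amp <- unlist(lapply(runs, `[[`, "amplifiers"), recursive = FALSE)
  noniso <- list()
  if (length(all_amp) > 0) {
    canon <- vapply(all_amp, function(a) canonical_key(a$graph), character(1))
    noniso <- all_amp[!duplicated(canon)]
  }
  kbar <- if (length(noniso)) {
    mean(vapply(noniso, function(a) graph_degrees(a$graph)$k_mean, numeric(1)))
  } else NA_real_
  stats <- tibble(
    n = unique(ns), k = runs[[1]]$k, inputs = length(inputs),
    inputs_with_amplifier = sum(vapply(runs, function(r)
      length(r$amplifiers) > 0, logical(1))),
    total_amplifiers = sum(per_run_tot),
    nonisomorphic_amplifiers = length(noniso),
    mean_degree_noniso = kbar)
  structure(list(runs = runs, amplifiers = noniso, stats = stats,
                 config = config),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("<campaign_result>  N = %d, k = %d: %d/%d inputs yield ",
                     "amplifiers; %d records, %d non-isomorphic\n"),
              s$n, s$k, s$inputs_with_amplifier, s$inputs,
              s$total_amplifiers, s$nonisomorphic_amplifiers))
  invisible(x)
}

#' @export
tidy.campaign_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$runs, tidy))
}

#' @export
glance.campaign_result <- function(x, ...) {
  x$stats
}

#' Spectral dynamics of a recorded search
#'
#' Splits the candidate pool at every removal step \eqn{\ell} into graphs
#' that eventually lead to a transient amplifier (the graph itself or some
#' descendant is one) and graphs that do not, forms the ensemble spectral
#' density of each set, and measures their pseudometric distance. Steps where
#' either set is empty are omitted (with a note).
#'
#' @param x A `search_result` or `campaign_result` whose config had
#'   `record_dynamics = TRUE`.
#' @param grid Density evaluation grid.
#' @return An object of class `spectral_dynamics`: list with `summary` (tibble
#'   of `ell`, `n_amp`, `n_non`, `distance`), `phi_amp`, `phi_non` (lists of
#'   `spectral_density` per kept `ell`) and `omitted` (steps left out).
#' @export
spectral_dynamics <- function(x, grid = density_grid()) {
  traces <- if (inherits(x, "campaign_result")) {
    lapply(x$runs, `[[`, "trace")
  } else if (inherits(x, "search_result")) {
    list(x$trace)
  } else abort("`x` must be a search_result or campaign_result")
  if (any(vapply(traces, is.null, logical(1))))
    abort("search was run without `record_dynamics = TRUE`")

  # retrospective amplifier-bound labels per run: walk parent pointers up
  # from every amplifier member
  labelled <- lapply(traces, function(tr) {
    ids <- vapply(tr, `[[`, integer(1), "id")
    parents <- vapply(tr, `[[`, integer(1), "parent")
    amp <- vapply(tr, `[[`, logical(1), "amplifier")
    bound <- amp
    idx <- stats::setNames(seq_along(ids), ids)
    for (i in which(amp)) {
      p <- parents[i]
      while (!is.na(p)) {
        ip <- idx[[as.character(p)]]
        if (bound[ip]) break
        bound[ip] <- TRUE
        p <- parents[ip]
      }
    }
    list(tr = tr, bound = bound)
  })

  ells <- sort(unique(unlist(lapply(labelled, function(l)
    vapply(l$tr, `[[`, integer(1), "ell")))))
  summary <- list()
  phi_amp <- list()
  phi_non <- list()
  omitted <- integer(0)
  for (ell in ells) {
    spectra_a <- list()
    spectra_n <- list()
    for (l in labelled) {
      at <- vapply(l$tr, function(e) e$ell == ell, logical(1))
      spectra_a <- c(spectra_a, lapply(l$tr[at & l$bound], `[[`, "lam"))
      spectra_n <- c(spectra_n, lapply(l$tr[at & !l$bound], `[[`, "lam"))
    }
    if (length(spectra_a) == 0 || length(spectra_n) == 0) {
      omitted <- c(omitted, ell)
      next
    }
    pa <- ensemble_density(spectra_a, grid = grid)
    pn <- ensemble_density(spectra_n, grid = grid)
    key <- as.character(ell)
    phi_amp[[key]] <- pa
    phi_non[[key]] <- pn
    summary[[key]] <- tibble(ell = ell, n_amp = length(spectra_a),
                             n_non = length(spectra_n),
                             distance = trapz(grid, abs(pa$values - pn$values)))
  }
  if (length(omitted))
    inform(sprintf("spectral_dynamics: omitted steps with an empty set: %s",
                   paste(omitted, collapse = ", ")))
  structure(list(summary = dplyr::bind_rows(summary), phi_amp = phi_amp,
                 phi_non = phi_non, omitted = omitted),
            class = "spectral_dynamics")
}

#' @export
tidy.spectral_dynamics <- function(x, ...) x$summary

#' @export
autoplot.spectral_dynamics <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$ell, y = .data$distance)) +
    geom_line() + geom_point() +
    labs(x = "edge removals", y = "spectral distance d(G, G')")
}
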