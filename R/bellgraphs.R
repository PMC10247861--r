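#' @title Bell-like graph families
#'
#' @description Bell-like graphs join two identical dense blocks by one or two
#' bridges (paths of `b` edges). Blocks: complete graphs \eqn{K_a} (barbell
#' `B(a,b)`), cycles \eqn{C_a} (dumbbell `D(a,b)`), Moebius ladders (cycle
#' plus rungs between opposite vertices, `M(a,b)`) and antiprisms (circulant
#' with offsets 1 and 2, `A(a,b)`). A one-bridge graph has
#' \eqn{N = 2a + b - 1} vertices (the bridge contributes `b - 1` interior
#' vertices); the two-bridge variants attach two vertex-disjoint bridges at
#' adjacent bridgeheads on each side, giving \eqn{N = 2a + 2(b - 1)}.
#' One-bridge members with `b > 3` (barbell) are transient amplifiers of
#' death-Birth updating in the weak-selection sense
#' (\eqn{N_{\mathrm{eff}}/N > 1}); two-bridge members are not.
#' @name bellgraphs
NULL

bell_families <- c("barbell", "dumbbell", "moebius", "antiprism")

# edge list of one block on vertices offset+1 .. offset+a;
# duplicate unordered pairs are collapsed (a = 4 Moebius/antiprism
# degenerate to K4)
bell_block_edges <- function(family, a, offset = 0) {
  if (family == "antiprism") {
    ring <- cbind(seq_len(a), (seq_len(a) %% a) + 1)
    chords <- cbind(seq_len(a), ((seq_len(a) + 1) %% a) + 1)
    e <- unique(t(apply(rbind(ring, chords), 1, sort)))
    return(e[e[, 1] != e[, 2], , drop = FALSE] + offset)
  }
  if (family == "moebius") {
    ring <- cbind(seq_len(a), (seq_len(a) %% a) + 1)
    rungs <- cbind(seq_len(a / 2), seq_len(a / 2) + a / 2)
    e <- unique(t(apply(rbind(ring, rungs), 1, sort)))
    return(e[e[, 1] != e[, 2], , drop = FALSE] + offset)
  }
  if (family == "dumbbell") {
    return(cbind(seq_len(a), (seq_len(a) %% a) + 1) + offset)
  }
  t(utils::combn(a, 2)) + offset
}

#' Construct a bell-like graph
#'
#' @param family One of `"barbell"`, `"dumbbell"`, `"moebius"`,
#'   `"antiprism"`.
#' @param a Vertices per block (`>= 3`; Moebius/antiprism need even
#'   `a >= 4`; `a = 4` degenerates to \eqn{K_4} blocks for both).
#' @param b Edges per bridge (`>= 1`; `b = 1` is a direct edge).
#' @param bridges 1 (default) or 2. Two-bridge variants use adjacent block
#'   vertices 1 and 2 as bridgeheads on each side.
#' @return A connected simple igraph object.
#' @examples
#' igraph::vcount(make_bell("barbell", 8, 3)) # 18
#' @export
make_bell <- function(family = bell_families, a, b, bridges = 1) {
  family <- match.arg(family)
  if (a < 3) abort("`a` must be at least 3")
  if (family %in% c("moebius", "antiprism") && (a < 4 || a %% 2 != 0))
    abort("Moebius/antiprism blocks need even a >= 4")
  if (b < 1) abort("`b` must be at least 1")
  if (!bridges %in% c(1, 2)) abort("`bridges` must be 1 or 2")

  edges <- rbind(bell_block_edges(family, a, 0),
                 bell_block_edges(family, a, a))
  nxt <- 2 * a
  add_bridge <- function(from, to) {
    if (b == 1) return(rbind(c(from, to)))
    interior <- nxt + seq_len(b - 1)
    nxt <<- nxt + b - 1
    chain <- c(from, interior, to)
    cbind(chain[-length(chain)], chain[-1])
  }
  if (bridges == 1) {
    edges <- rbind(edges, add_bridge(1, a + 1))
  } else {
    edges <- rbind(edges, add_bridge(1, a + 1), add_bridge(2, a + 2))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  stopifnot(igraph::vcount(g) ==
              if (bridges == 1) 2 * a + b - 1 else 2 * a + 2 * (b - 1))
  g
}

#' Amplification scan over a bell-graph family
#'
#' Computes \eqn{N_{\mathrm{eff}}} and the ratio \eqn{N_{\mathrm{eff}}/N}
#' for every `(a, b)` combination.
#'
#' @inheritParams make_bell
#' @param a_values,b_values Integer vectors of block sizes and bridge lengths.
#' @return A tibble of class `bell_scan` with columns `family`, `bridges`,
#'   `a`, `b`, `n`, `n_eff`, `ratio`.
#' @export
scan_family <- function(family = bell_families, bridges = 1,
                        a_values, b_values) {
  family <- match.arg(family)
  grid <- expand.grid(a = a_values, b = b_values)
  rows <- purrr::pmap(grid, function(a, b) {
    g <- make_bell(family, a, b, bridges)
    n <- igraph::vcount(g)
    n_eff <- effective_population_size(g)$n_eff
    tibble(family = family, bridges = bridges, a = a, b = b, n = n,
           n_eff = n_eff, ratio = n_eff / n)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$a, .data$b)
  class(out) <- c("bell_scan", class(out))
  out
}

#' Smallest amplifying members of a bell-graph family
#'
#' Searches the `(a, b)` box in ascending graph order `N` and stops at the
#' first `N` where some member has \eqn{N_{\mathrm{eff}}/N > 1}, so only
#' small graphs are ever evaluated.
#'
#' @inheritParams make_bell
#' @param a_max,b_max Search box (defaults `a <= 12`, `b <= 40`, large enough
#'   to contain the known minima of all four families).
#' @param tol Amplification margin on `n_eff - n`.
#' @return A tibble with one row per `(a, b)` attaining the minimal
#'   amplifying `N`, sorted by `(n, a, b)`; empty (with a warning) if the box
#'   holds no amplifier.
#' @export
smallest_amplifier <- function(family = bell_families, bridges = 1,
                               a_max = 12, b_max = 40, tol = 1e-9) {
  family <- match.arg(family)
  a_min <- if (family %in% c("moebius", "antiprism")) 4 else 3
  a_vals <- seq(a_min, a_max)
  if (family %in% c("moebius", "antiprism")) a_vals <- a_vals[a_vals %% 2 == 0]
  order_of <- function(a, b) if (bridges == 1) 2 * a + b - 1 else 2 * a + 2 * (b - 1)
  combos <- expand.grid(a = a_vals, b = seq_len(b_max))
  combos$n <- order_of(combos$a, combos$b)
  combos <- combos[order(combos$n, combos$a, combos$b), ]
  hits <- list()
  for (n in unique(combos$n)) {
    sub <- combos[combos$n == n, ]
    for (i in seq_len(nrow(sub))) {
      g <- make_bell(family, sub$a[i], sub$b[i], bridges)
      n_eff <- effective_population_size(g)$n_eff
      if (n_eff - n > tol)
        hits[[length(hits) + 1]] <- tibble(a = sub$a[i], b = sub$b[i], n = n,
                                           n_eff = n_eff, ratio = n_eff / n)
    }
    if (length(hits) > 0) break
  }
  if (length(hits) == 0) {
    warn(sprintf("no amplifying %s graph in the box a <= %d, b <= %d",
                 family, a_max, b_max))
    return(tibble(a = integer(0), b = integer(0), n = integer(0),
                  n_eff = numeric(0), ratio = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(hits), .data$n, .data$a, .data$b)
}

#' @export
autoplot.bell_scan <- function(object, ...) {
  ggplot(object, aes(x = .data$b, y = .data$ratio,
                     colour = factor(.data$a))) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "bridge length b", y = expression(N[eff] / N), colour = "a")
}
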