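# Independent oracles and fixture builders used across the suite.

path_graph <- function(n) igraph::make_graph(rbind(1:(n - 1), 2:n),
                                             directed = FALSE)

random_connected_graph <- function(n, p = 0.5) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) > 0 && igraph::is_connected(g)) return(g)
  }
}

# Monte-Carlo oracle for the pairwise coalescence time: at each step one of
# the two walkers (probability 1/2) moves to a uniformly random neighbor.
# Vectorized over replicates; returns mean and standard error.
simulate_meeting_time <- function(g, i, j, reps) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  nbrs <- lapply(seq_len(nrow(A)), function(v) which(A[v, ] > 0))
  pos1 <- rep.int(i, reps)
  pos2 <- rep.int(j, reps)
  met_at <- rep.int(NA_real_, reps)
  active <- which(pos1 != pos2)
  t <- 0
  while (length(active) > 0) {
    t <- t + 1
    move_first <- stats::runif(length(active)) < 0.5
    movers1 <- active[move_first]
    movers2 <- active[!move_first]
    cur1 <- pos1[movers1]
    cur2 <- pos2[movers2]
    for (v in unique(c(cur1, cur2))) {
      nb <- nbrs[[v]]
      sel1 <- movers1[cur1 == v]
      if (length(sel1)) # index into nb: sample(nb, ...) misfires on scalar nb
        pos1[sel1] <- nb[sample.int(length(nb), length(sel1), replace = TRUE)]
      sel2 <- movers2[cur2 == v]
      if (length(sel2))
        pos2[sel2] <- nb[sample.int(length(nb), length(sel2), replace = TRUE)]
    }
    done <- active[pos1[active] == pos2[active]]
    met_at[done] <- t
    active <- active[pos1[active] != pos2[active]]
  }
  list(mean = mean(met_at), se = stats::sd(met_at) / sqrt(reps))
}

# Independent lumped-chain oracle for the complete graph: death-Birth on K_N
# reduces to a birth-death chain on the mutant count; solved here as a plain
# tridiagonal linear system (not the ratio formula the package uses).
lumped_chain_fixation <- function(n, r) {
  m <- 1:(n - 1)
  p_up <- ((n - m) / n) * (r * m) / (r * m + (n - 1 - m))
  p_down <- (m / n) * (n - m) / (r * (m - 1) + (n - m))
  M <- diag(p_up + p_down)
  for (k in seq_len(n - 2)) {
    M[k, k + 1] <- -p_up[k]
    M[k + 1, k] <- -p_down[k + 1]
  }
  b <- c(rep(0, n - 2), p_up[n - 1])
  solve(M, b)[1]
}

adjacency_of <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  dimnames(A) <- NULL
  A
}

# graph6 line a graph serializes to
write_read_key <- function(g) {
  p <- tempfile(fileext = ".g6")
  on.exit(unlink(p))
  write_graph6(g, p)
  readLines(p)
}
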