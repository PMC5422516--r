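# Independent brute-force oracles.

# Column-by-column scan for fixed substitutions, written as plainly as
# possible (nested loops, explicit conditions) to stay independent of the
# package's vectorised implementation.
oracle_fixed_sites <- function(aln, taxa) {
  pa <- intersect(aln$samples, samples_of_role(taxa, "parentA"))
  pb <- intersect(aln$samples, samples_of_role(taxa, "parentB"))
  hits <- list()
  for (j in seq_len(aln$length)) {
    a_states <- character(0); b_states <- character(0)
    for (s in pa) a_states <- c(a_states, substr(aln$seqs[[s]], j, j))
    for (s in pb) b_states <- c(b_states, substr(aln$seqs[[s]], j, j))
    ok <- function(v) length(unique(v)) == 1L &&
      unique(v) %in% c("A", "C", "G", "T")
    if (ok(a_states) && ok(b_states) &&
        unique(a_states) != unique(b_states))
      hits[[length(hits) + 1L]] <- data.frame(
        position = j, base_a = unique(a_states), base_b = unique(b_states),
        stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(position = integer(), base_a = character(),
                  base_b = character())
}

samples_of_role <- function(taxa, role)
  taxa$assignments$sample_id[taxa$assignments$role == role]

# --- median-joining oracle (igraph-based) ----------------------------

oracle_mst_cost <- function(states) {
  n <- length(states)
  if (n <= 1L) return(0)
  d <- matrix(0, n, n)
  sp <- strsplit(states, "")
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(sp[[i]] != sp[[j]])
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# quasi-medians of a triple by explicit per-column enumeration (same
# expansion cap as the implementation: larger triples are skipped)
oracle_quasi_medians <- function(a, b, c, max_expand = 2187) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  sc <- strsplit(c, "")[[1]]
  cand <- list("")
  for (j in seq_along(sa)) {
    col <- c(sa[j], sb[j], sc[j])
    states <- if (any(duplicated(col))) names(which.max(table(col)))
    else unique(col)
    cand <- unlist(lapply(cand, function(p) paste0(p, states)))
    if (length(cand) > max_expand) return(character(0))
  }
  unique(cand)
}

# MSN adjacency via the minimax characterisation computed from an igraph
# MST: the minimax connection cost of (u, v) is the maximum edge weight
# on their (unique) MST path; an MSN edge has d(u, v) no larger than it.
oracle_msn_adj <- function(states, epsilon = 0) {
  n <- length(states)
  sp <- strsplit(states, "")
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) d[i, j] <- sum(sp[[i]] != sp[[j]])
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  t <- igraph::mst(g)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ep <- igraph::shortest_paths(t, i, j, output = "epath")$epath[[1]]
    minimax <- max(igraph::E(t)$weight[as.integer(ep)])
    adj[i, j] <- adj[j, i] <- d[i, j] <= minimax + epsilon
  }
  adj
}

# Greedy median-joining over MSN-connected triples: same algorithm
# contract as the package (lexicographic tie-breaks, pruning of medians
# that do not reduce spanning cost) but independent mechanics throughout.
oracle_mj_nodes <- function(observed, epsilon = 0) {
  nodes <- observed
  medians <- character(0)
  repeat {
    all_states <- c(nodes, medians)
    if (length(all_states) < 3L) break
    cost0 <- oracle_mst_cost(all_states)
    adj <- oracle_msn_adj(all_states, epsilon)
    cand <- character(0)
    for (v in seq_along(all_states)) {
      nb <- which(adj[v, ])
      if (length(nb) < 2) next
      for (x in seq_len(length(nb) - 1)) for (y in (x + 1):length(nb))
        cand <- c(cand, oracle_quasi_medians(all_states[v],
                                             all_states[nb[x]],
                                             all_states[nb[y]]))
    }
    cand <- setdiff(unique(cand), all_states)
    if (!length(cand)) break
    costs <- vapply(cand, function(x) oracle_mst_cost(c(all_states, x)), 0)
    if (min(costs) >= cost0) break
    medians <- c(medians, sort(cand[costs == min(costs)])[1])
  }
  repeat {
    all_states <- c(nodes, medians)
    cost0 <- oracle_mst_cost(all_states)
    drop <- NULL
    for (mv in sort(medians))
      if (oracle_mst_cost(setdiff(all_states, mv)) <= cost0) { drop <- mv; break }
    if (is.null(drop)) break
    medians <- setdiff(medians, drop)
  }
  sort(c(nodes, medians))
}

# random distinct haplotype states for network property tests
random_states <- function(n_hap, n_char, n_states = 3L) {
  alpha <- c("A", "C", "G", "T")[seq_len(n_states)]
  n_hap <- min(n_hap, n_states^n_char)  # distinct strings must exist
  repeat {
    s <- replicate(n_hap, paste(sample(alpha, n_char, TRUE), collapse = ""))
    if (!any(duplicated(s))) return(s)
  }
}
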