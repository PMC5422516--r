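#' Recode aligned haplotypes for network construction
#'
#' Builds the character matrix the median-joining procedure works on:
#' each registered multi-column indel event is collapsed to a single
#' binary presence/absence character (an indel of two or more nucleotides
#' is one mutational event), remaining gap columns keep the gap as a fifth
#' character state, and constant columns are dropped.
#'
#' @param haplotypes named character vector of distinct aligned haplotype
#'   sequences (names are haplotype labels).
#' @param indel_registry optional data.frame with columns `start`, `end`
#'   (1-based inclusive) listing indel event ranges; ranges must not
#'   overlap, and within a range every haplotype must be either fully
#'   gapped or fully ungapped.
#' @return a `network_matrix`: character matrix (haplotypes x characters)
#'   with attributes `columns` (source column of each substitution
#'   character, `NA` for indel characters) and `events` (the registry).
#' @export
recode_matrix <- function(haplotypes, indel_registry = NULL) {
  if (length(haplotypes) < 1L) stop("at least one haplotype required")
  if (is.null(names(haplotypes)))
    names(haplotypes) <- paste0("H", seq_along(haplotypes))
  m <- do.call(rbind, strsplit(toupper(haplotypes), ""))
  rownames(m) <- names(haplotypes)
  drop_cols <- integer()
  event_chars <- NULL
  if (!is.null(indel_registry) && nrow(indel_registry)) {
    reg <- indel_registry[order(indel_registry$start), , drop = FALSE]
    if (any(reg$end < reg$start)) stop("indel event with end < start")
    if (nrow(reg) > 1L && any(reg$start[-1L] <= reg$end[-nrow(reg)]))
      stop("overlapping indel events in registry")
    event_chars <- vapply(seq_len(nrow(reg)), function(i) {
      blk <- m[, reg$start[i]:reg$end[i], drop = FALSE]
      state <- apply(blk, 1L, function(r) {
        if (all(r == "-")) "0"
        else if (all(r != "-")) "1"
        else stop(sprintf("haplotype partially gapped inside indel event %d-%d",
                          reg$start[i], reg$end[i]))
      })
      state
    }, character(nrow(m)))
    if (is.null(dim(event_chars)))
      event_chars <- matrix(event_chars, nrow = nrow(m))
    drop_cols <- unlist(lapply(seq_len(nrow(reg)),
                               function(i) reg$start[i]:reg$end[i]))
  }
  sub <- if (length(drop_cols)) m[, -drop_cols, drop = FALSE] else m
  src <- setdiff(seq_len(ncol(m)), drop_cols)
  variable <- apply(sub, 2L, function(col) length(unique(col)) > 1L)
  sub <- sub[, variable, drop = FALSE]
  src <- src[variable]
  if (!is.null(event_chars)) {
    ev_var <- apply(event_chars, 2L, function(col) length(unique(col)) > 1L)
    event_chars <- event_chars[, ev_var, drop = FALSE]
    out <- cbind(sub, event_chars)
    src <- c(src, rep(NA_integer_, ncol(event_chars)))
  } else out <- sub
  colnames(out) <- NULL
  structure(out, columns = src, events = indel_registry,
            class = c("network_matrix", class(out)))
}

# Pairwise Hamming distance matrix between rows of a state matrix.
row_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n < 2L || ncol(m) == 0L) return(d)
  for (j in seq_len(ncol(m)))
    d <- d + outer(m[, j], m[, j], "!=")
  d
}

# Hamming distances from every row of `cand` to every row of `m`.
cross_dist <- function(cand, m) {
  d <- matrix(0L, nrow(cand), nrow(m))
  for (j in seq_len(ncol(m)))
    d <- d + outer(cand[, j], m[, j], "!=")
  d
}

# Pairwise Hamming distance matrix between state strings.
state_dist <- function(states) {
  if (length(states) < 2L)
    return(matrix(0L, length(states), length(states)))
  row_dist(do.call(rbind, strsplit(states, "")))
}

# Total MST weight given a precomputed distance matrix (Prim).
mst_cost_d <- function(d) {
  n <- nrow(d)
  if (n <= 1L) return(0L)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  key <- d[1L, ]
  total <- 0L
  for (step in seq_len(n - 1L)) {
    key[in_tree] <- Inf
    v <- which.min(key)
    total <- total + key[v]
    in_tree[v] <- TRUE
    key <- pmin(key, d[v, ])
  }
  as.integer(total)
}

mst_cost <- function(states) mst_cost_d(state_dist(states))

# Quasi-median set of a state-matrix triple: per column the majority
# state; where all three states differ every one is a candidate
# (cartesian expansion, capped — triples beyond the cap are skipped).
quasi_medians_m <- function(trip, max_expand = 2187L) {
  opts <- lapply(seq_len(ncol(trip)), function(j) {
    s <- trip[, j]
    if (any(duplicated(s))) names(which.max(table(s))) else unique(s)
  })
  if (prod(lengths(opts)) > max_expand) return(NULL)
  as.matrix(expand.grid(opts, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE))
}

#' Build a median-joining haplotype network
#'
#' Starting from the observed haplotypes, the procedure repeatedly
#' (1) computes pairwise Hamming distances over the recoded characters and
#' the minimum spanning network they induce, (2) enumerates the
#' quasi-median (consensus) vectors of every network-connected triplet —
#' the per-position majority state, expanded over all three states where
#' the triple is fully distinct (expansion capped at 3^7 per triple;
#' larger triples are skipped), (3) adds the median vector that most
#' reduces the total spanning cost of the node set, and repeats to a
#' fixed point; median
#' vectors whose removal leaves the spanning cost unchanged are then
#' pruned.  The reported edges form the minimum spanning network over the
#' final node set: a link is kept when its length is within `epsilon` of
#' the minimax connection cost between its endpoints, so at `epsilon = 0`
#' the network is the union of all minimum spanning trees.
#'
#' All tie-breaking is deterministic: candidate medians of equal gain are
#' resolved to the lexicographically smallest state vector, and pruning
#' processes median nodes in lexicographic order.
#'
#' @param mat a [recode_matrix()] result (or plain character matrix of
#'   single-character states, rows = haplotypes).
#' @param epsilon non-negative integer relaxation of the connection cost
#'   (default 0, the common published default).
#' @return a `haplotype_network`: list with `nodes` (data.frame `id`,
#'   `states`, `type` = observed/median) and `edges` (data.frame `from`,
#'   `to`, `weight`).
#' @export
build_mj_network <- function(mat, epsilon = 0L) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  labels <- rownames(mat)
  if (is.null(labels)) labels <- paste0("H", seq_len(nrow(mat)))
  obs <- apply(mat, 1L, paste, collapse = "")
  if (ncol(mat) == 0L) obs <- rep("", nrow(mat))
  if (anyDuplicated(obs))
    stop("haplotypes must be distinct; collapse duplicates before building")
  n_obs <- nrow(mat)
  cur <- mat                      # observed rows first, then medians

  # --- median generation to a fixed point -----------------------------
  repeat {
    n <- nrow(cur)
    if (n < 3L || ncol(mat) == 0L) break
    d <- row_dist(cur)
    cost0 <- mst_cost_d(d)
    # triples where one vertex is MSN-adjacent to the two others
    adj <- msn_adjacency(d, epsilon)
    trips <- connected_triples(adj)
    if (!nrow(trips)) break
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(trips)), function(i)
      quasi_medians_m(cur[as.integer(trips[i, ]), , drop = FALSE]))))
    if (is.null(cand) || !nrow(cand)) break
    cand_str <- apply(cand, 1L, paste, collapse = "")
    keep <- !(cand_str %in% apply(cur, 1L, paste, collapse = ""))
    cand <- cand[keep, , drop = FALSE]
    cand_str <- cand_str[keep]
    if (!nrow(cand)) break
    dc <- cross_dist(cand, cur)
    gains <- vapply(seq_len(nrow(cand)), function(i)
      mst_cost_d(rbind(cbind(d, dc[i, ]), c(dc[i, ], 0L))), 0L)
    best <- min(gains)
    if (best >= cost0) break
    pick <- which(gains == best)[order(cand_str[gains == best])[1L]]
    cur <- rbind(cur, cand[pick, , drop = FALSE])
  }

  # --- prune medians that no longer pay for themselves ----------------
  repeat {
    n <- nrow(cur)
    if (n <= n_obs) break
    d <- row_dist(cur)
    cost0 <- mst_cost_d(d)
    med_idx <- (n_obs + 1L):n
    med_str <- apply(cur[med_idx, , drop = FALSE], 1L, paste, collapse = "")
    removed <- FALSE
    for (i in med_idx[order(med_str)]) {
      if (mst_cost_d(d[-i, -i, drop = FALSE]) <= cost0) {
        cur <- cur[-i, , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  all_states <- apply(cur, 1L, paste, collapse = "")
  if (ncol(mat) == 0L) all_states <- rep("", nrow(cur))
  medians <- all_states[-seq_len(n_obs)]
  ids <- c(labels, if (length(medians)) paste0("mv", seq_along(medians)))
  nodes_df <- data.frame(
    id = ids, states = all_states,
    type = c(rep("observed", n_obs), rep("median", length(medians))),
    stringsAsFactors = FALSE)
  rownames(nodes_df) <- NULL
  edges_df <- msn_edges(all_states, ids, epsilon)
  structure(list(nodes = nodes_df, edges = edges_df, epsilon = epsilon),
            class = "haplotype_network")
}

# MSN adjacency matrix from a distance matrix: edge (u, v) kept when
# d(u, v) <= minimax-connection-cost(u, v) + epsilon.
msn_adjacency <- function(d, epsilon = 0L) {
  n <- nrow(d)
  comp <- seq_len(n)
  t_join <- matrix(Inf, n, n)
  for (w in sort(unique(d[upper.tri(d)]))) {
    before <- comp
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (d[i, j] <= w && comp[i] != comp[j])
        comp[comp == comp[j]] <- comp[i]
    newly <- outer(before, before, "!=") & outer(comp, comp, "==")
    t_join[newly & !is.finite(t_join)] <- w
  }
  adj <- d <= t_join + epsilon
  diag(adj) <- FALSE
  adj
}

# Triples {u, v, w} where some vertex is adjacent to both others.
connected_triples <- function(adj) {
  n <- nrow(adj)
  out <- list()
  for (v in seq_len(n)) {
    nb <- which(adj[v, ])
    if (length(nb) >= 2L) {
      pr <- utils::combn(nb, 2L)
      for (k in seq_len(ncol(pr)))
        out[[length(out) + 1L]] <- sort(c(v, pr[1L, k], pr[2L, k]))
    }
  }
  if (!length(out)) return(matrix(integer(), 0L, 3L))
  unique(do.call(rbind, out))
}

# Minimum spanning network edges: pair (u, v) kept when d(u, v) <=
# minimax-connection-cost(u, v) + epsilon.
msn_edges <- function(states, ids, epsilon = 0L) {
  n <- length(states)
  empty <- data.frame(from = character(), to = character(),
                      weight = integer(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  d <- state_dist(states)
  adj <- msn_adjacency(d, epsilon)
  keep <- which(upper.tri(d) & adj, arr.ind = TRUE)
  out <- data.frame(from = ids[keep[, 1L]], to = ids[keep[, 2L]],
                    weight = d[keep], stringsAsFactors = FALSE)
  out <- out[order(out$weight, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d observed + %d median nodes, %d edges (epsilon = %d)\n",
              sum(x$nodes$type == "observed"), sum(x$nodes$type == "median"),
              nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Build the network for one locus straight from an inventory
#'
#' Collects the distinct haplotypes across all taxa at a locus, recodes
#' them (with the supplied indel events), builds the median-joining
#' network, and annotates observed nodes with carrier counts and taxon
#' composition.
#'
#' @param inv a [build_inventory()] result.
#' @param locus_id locus to analyse (use the inventory's `cp_locus` for the
#'   combined chloroplast system).
#' @param indel_registry optional indel events for [recode_matrix()].
#' @param epsilon see [build_mj_network()].
#' @return a `haplotype_network` whose `nodes` carry `count` and `taxa`
#'   columns.
#' @export
network_from_inventory <- function(inv, locus_id, indel_registry = NULL,
                                   epsilon = 0L) {
  d <- inv$inventory[inv$inventory$locus_id == locus_id, ]
  if (!nrow(d)) stop(sprintf("no haplotypes for locus %s", locus_id))
  agg <- stats::aggregate(count ~ sequence, data = d, FUN = sum)
  agg <- agg[order(-agg$count, agg$sequence), ]
  haps <- stats::setNames(agg$sequence, paste0("H", seq_len(nrow(agg))))
  taxa_of <- vapply(haps, function(s)
    paste(sort(unique(d$taxon[d$sequence == s])), collapse = "+"), "")
  mat <- recode_matrix(haps, indel_registry)
  net <- build_mj_network(mat, epsilon)
  net$nodes$count <- ifelse(net$nodes$type == "observed",
                            agg$count[match(net$nodes$id, names(haps))], 0L)
  net$nodes$taxa <- ifelse(net$nodes$type == "observed",
                           taxa_of[match(net$nodes$id, names(haps))], "")
  net
}

#' Export a haplotype network
#'
#' @param net a `haplotype_network`.
#' @param path output file.
#' @param format `"tsv"` (edge list: node1, node2, steps) or `"dot"`
#'   (Graphviz, node labels annotated with counts and taxa when present).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "dot")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(
      data.frame(node1 = net$edges$from, node2 = net$edges$to,
                 steps = net$edges$weight),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lab <- net$nodes$id
    if (!is.null(net$nodes$count)) {
      taxa <- if (is.null(net$nodes$taxa)) rep("", nrow(net$nodes)) else net$nodes$taxa
      extra <- ifelse(net$nodes$type == "observed",
                      sprintf("\\n(n=%d%s)", net$nodes$count,
                              ifelse(nzchar(taxa), paste0("; ", taxa), "")),
                      "")
      lab <- paste0(lab, extra)
    }
    lines <- c("graph haplotypes {",
               sprintf("  \"%s\" [label=\"%s\", shape=%s];", net$nodes$id, lab,
                       ifelse(net$nodes$type == "median", "point", "circle")),
               sprintf("  \"%s\" -- \"%s\" [label=\"%d\"];",
                       net$edges$from, net$edges$to, net$edges$weight),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
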