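## Stage 3: resolve per-gene haplotype-pair ambiguity globally with a
## switch-penalized minimum-cost path over the gene-adjacency graph.
##
## The graph is layered: one layer per gene in the global order, one node
## per (gene, candidate pair), plus pseudo source and sink nodes.  An edge
## connects every state of a gene to every state of the next gene; its
## weight is the rate-derived edge weight of the mean combined mapping rate
## of the two incident states plus a constant penalty per switched
## haplotype.  Genes with no reads carry a single wildcard state ("*") that
## is switch-free against any neighbour.

#' Edge weight from a combined mapping rate
#'
#' w(M) = 1 / (-log(1 - M)), with M clamped into `[eps, 1-eps]` so the
#' weight stays finite at M = 0 and M = 1.  Strictly decreasing in M: the
#' better a pair captures a gene's reads, the cheaper it is to route the
#' path through it.
#'
#' @param M combined mapping rate(s) in `[0,1]`.
#' @param eps clamping constant (default 1e-9).
#' @return non-negative numeric weight(s).
#' @export
edge_weight <- function(M, eps = 1e-9) {
  if (any(!is.na(M) & (M < 0 | M > 1)))
    stopf("combined mapping rate outside [0,1]")
  ## clamp the complement so the transform stays finite at M = 0 and M = 1
  om <- pmin(pmax(1 - M, eps), 1 - eps)
  1 / (-log(om))
}

#' Number of haplotype switches between two pairs
#'
#' Pairs are unordered multisets; the switch count is 2 minus the size of
#' their maximum multiset intersection, i.e. 0 for identical pairs, 1 when
#' one haplotype is shared, 2 when none is.
#'
#' @param p1,p2 character vectors of length 2 (haplotype pairs; a homozygous
#'   pair repeats its haplotype).
#' @return integer in \{0, 1, 2\}.
#' @export
switch_count <- function(p1, p2) {
  stopifnot(length(p1) == 2L, length(p2) == 2L)
  common <- 0L
  pool <- p2
  for (h in p1) {
    j <- match(h, pool)
    if (!is.na(j)) { common <- common + 1L; pool <- pool[-j] }
  }
  2L - common
}

WILDCARD <- "*"

#' Build the gene graph
#'
#' @param order global gene order (character vector); genes without
#'   candidates get a wildcard state.
#' @param candidates candidate-pair table from
#'   [candidate_haplotype_pairs()].
#' @param penalty additive cost per switched haplotype (default 0.0028).
#' @param eps clamp for [edge_weight()].
#' @return an object of class `gene_graph`.
#' @export
build_gene_graph <- function(order, candidates, penalty = 0.0028,
                             eps = 1e-9) {
  if (length(order) == 0L) stopf("empty gene list")
  cand <- data.table::as.data.table(candidates)
  states <- lapply(order, function(g) {
    cg <- cand[gene_id == g]
    if (nrow(cg) == 0L) {
      data.table::data.table(label = WILDCARD, h1 = NA_character_,
                             h2 = NA_character_, M = NA_real_,
                             wildcard = TRUE)
    } else {
      s <- cg[, .(label = pair, h1, h2, M, wildcard = FALSE)]
      ## deterministic state order: homozygous first, then sorted labels
      s[order(ifelse(h1 == h2, 0L, 1L), h1, h2)]
    }
  })
  names(states) <- order
  structure(list(genes = order, states = states, penalty = penalty,
                 eps = eps), class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  ns <- vapply(x$states, nrow, 0L)
  cat(sprintf("gene graph: %d genes, %d states, penalty %g\n",
              length(x$genes), sum(ns), x$penalty))
  invisible(x)
}

## weight of the edge between state rows a and b (single rows)
state_edge_weight <- function(a, b, penalty, eps) {
  Ms <- c(a$M, b$M)
  w <- if (all(is.na(Ms))) 0 else edge_weight(mean(Ms, na.rm = TRUE), eps)
  sw <- if (isTRUE(a$wildcard) || isTRUE(b$wildcard)) 0L
        else switch_count(c(a$h1, a$h2), c(b$h1, b$h2))
  w + penalty * sw
}

## matrix of edge weights between two state tables
layer_weights <- function(sa, sb, penalty, eps) {
  W <- matrix(0, nrow(sa), nrow(sb))
  for (i in seq_len(nrow(sa)))
    for (j in seq_len(nrow(sb)))
      W[i, j] <- state_edge_weight(sa[i], sb[j], penalty, eps)
  W
}

terminal_weight <- function(s, eps) {
  ifelse(is.na(s$M), 0, edge_weight(ifelse(is.na(s$M), 0.5, s$M), eps))
}

#' Edge list of a gene graph
#'
#' Tabular dump of all edges (including the pseudo source and sink) with
#' their weights, for debugging and for export to other graph tools.
#'
#' @param graph a `gene_graph`.
#' @return data.table with `from_gene`, `from_state`, `to_gene`,
#'   `to_state`, `weight`.
#' @export
graph_edges <- function(graph) {
  g <- graph$genes
  out <- list()
  s1 <- graph$states[[1]]
  out[[1]] <- data.table::data.table(
    from_gene = ".source", from_state = ".source", to_gene = g[1],
    to_state = s1$label, weight = terminal_weight(s1, graph$eps))
  k <- 2L
  if (length(g) > 1L) for (i in seq_len(length(g) - 1L)) {
    sa <- graph$states[[i]]; sb <- graph$states[[i + 1L]]
    W <- layer_weights(sa, sb, graph$penalty, graph$eps)
    out[[k]] <- data.table::data.table(
      from_gene = g[i], from_state = rep(sa$label, times = nrow(sb)),
      to_gene = g[i + 1L], to_state = rep(sb$label, each = nrow(sa)),
      weight = as.vector(W))
    k <- k + 1L
  }
  sn <- graph$states[[length(g)]]
  out[[k]] <- data.table::data.table(
    from_gene = g[length(g)], from_state = sn$label, to_gene = ".sink",
    to_state = ".sink", weight = terminal_weight(sn, graph$eps))
  data.table::rbindlist(out)
}

#' Convert a gene graph to an igraph object
#'
#' Vertices are named `gene|state` (plus `.source` and `.sink`); edge
#' weights are in the `weight` attribute, so igraph's shortest-path
#' machinery can be applied directly.
#'
#' @param graph a `gene_graph`.
#' @return an `igraph` directed graph.
#' @export
as_igraph <- function(graph) {
  e <- graph_edges(graph)
  from <- ifelse(e$from_gene == ".source", ".source",
                 paste(e$from_gene, e$from_state, sep = "|"))
  to <- ifelse(e$to_gene == ".sink", ".sink",
               paste(e$to_gene, e$to_state, sep = "|"))
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = e$weight))
}

#' Minimum-cost haplotype path
#'
#' Computes the minimum-total-weight source-to-sink state sequence through
#' the layered gene graph (the graph is a DAG, solved by exact dynamic
#' programming; edge weights are non-negative, so the result coincides with
#' Dijkstra's).  Ties are broken deterministically: homozygous states are
#' preferred, then the lexicographically smallest sorted pair label,
#' applied left to right along the gene order.
#'
#' @param graph a `gene_graph`.
#' @param tol cost tolerance for tie detection.
#' @return data.table of haplotype calls: `gene_id`, `h1`, `h2`, `pair`,
#'   `M`, `zygosity`, `wildcard`; total path cost in attribute `cost`.
#' @export
best_haplotype_path <- function(graph, tol = 1e-9) {
  g <- graph$genes
  n <- length(g)
  S <- graph$states
  ## backward cost-to-sink
  back <- vector("list", n)
  sn <- S[[n]]
  back[[n]] <- terminal_weight(sn, graph$eps)
  if (n > 1L) for (i in seq(n - 1L, 1L)) {
    W <- layer_weights(S[[i]], S[[i + 1L]], graph$penalty, graph$eps)
    back[[i]] <- apply(W + rep(back[[i + 1L]], each = nrow(W)), 1L, min)
  }
  ## forward reconstruction with deterministic tie-break (states are stored
  ## in preference order, so the first index among ties wins)
  pick <- integer(n)
  src_cost <- terminal_weight(S[[1]], graph$eps) + back[[1]]
  total <- min(src_cost)
  pick[1] <- which(src_cost <= total + tol)[1]
  if (n > 1L) for (i in seq_len(n - 1L)) {
    sa <- S[[i]][pick[i]]
    W <- vapply(seq_len(nrow(S[[i + 1L]])), function(j)
      state_edge_weight(sa, S[[i + 1L]][j], graph$penalty, graph$eps), 0)
    tot <- W + back[[i + 1L]]
    pick[i + 1L] <- which(tot <= min(tot) + tol)[1]
  }
  calls <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    s <- S[[i]][pick[i]]
    data.table::data.table(
      gene_id = g[i], h1 = s$h1, h2 = s$h2, pair = s$label, M = s$M,
      zygosity = if (s$wildcard) NA_character_
                 else if (s$h1 == s$h2) "hom" else "het",
      wildcard = s$wildcard)
  }))
  data.table::setattr(calls, "cost", total)
  calls[]
}

#' Exhaustive minimum-cost path (test oracle)
#'
#' Enumerates every state sequence and returns the global minimum with the
#' same tie-break as [best_haplotype_path()].  Refuses instances with more
#' than `max_states` combinations.
#'
#' @param graph a `gene_graph`.
#' @param max_states enumeration guard (default 1e6).
#' @return as [best_haplotype_path()].
#' @export
brute_force_path <- function(graph, max_states = 1e6) {
  n <- length(graph$genes)
  S <- graph$states
  sizes <- vapply(S, nrow, 0L)
  if (prod(sizes) > max_states)
    stopf("instance too large for brute force (%g sequences)", prod(sizes))
  grid <- do.call(data.table::CJ, c(rev(lapply(sizes, seq_len)),
                                    list(sorted = FALSE)))
  grid <- grid[, rev(seq_len(n)), with = FALSE]  # column i = state of gene i
  best_cost <- Inf; best_idx <- NULL
  for (r in seq_len(nrow(grid))) {
    idx <- unlist(grid[r], use.names = FALSE)
    cost <- terminal_weight(S[[1]][idx[1]], graph$eps) +
      terminal_weight(S[[n]][idx[n]], graph$eps)
    if (n > 1L) for (i in seq_len(n - 1L)) {
      cost <- cost + state_edge_weight(S[[i]][idx[i]], S[[i + 1L]][idx[i + 1L]],
                                       graph$penalty, graph$eps)
    }
    better <- cost < best_cost - 1e-9
    tie <- abs(cost - best_cost) <= 1e-9
    if (better || (tie && lex_less(idx, best_idx))) {
      best_cost <- cost; best_idx <- idx
    }
  }
  calls <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    s <- S[[i]][best_idx[i]]
    data.table::data.table(
      gene_id = graph$genes[i], h1 = s$h1, h2 = s$h2, pair = s$label,
      M = s$M,
      zygosity = if (s$wildcard) NA_character_
                 else if (s$h1 == s$h2) "hom" else "het",
      wildcard = s$wildcard)
  }))
  data.table::setattr(calls, "cost", best_cost)
  calls[]
}

## TRUE if index sequence a precedes b in the state-preference order
lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  d <- which(a != b)
  length(d) > 0L && a[d[1]] < b[d[1]]
}
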