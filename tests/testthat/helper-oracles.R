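# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's internals (and igraph): adjacency is
# tested pair-by-pair against the raw edge list, components come from a
# hand-written BFS, and the statistics are computed from first principles.

edge_keys <- function(edges) {
  if (!nrow(edges)) return(character())
  paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]),
        sep = "\r")
}

pair_key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\r")

# Enumerates every node pair of both networks.
oracle_topo_scores <- function(net1, net2, aln) {
  v1 <- network_nodes(net1)
  e1 <- edge_keys(network_edges(net1))
  e2 <- edge_keys(network_edges(net2))
  map <- alignment_map(aln)

  conserved <- character()
  if (length(v1) > 1L) {
    for (i in seq_along(v1)[-1L]) for (j in seq_len(i - 1L)) {
      u <- v1[i]; v <- v1[j]
      if (!(pair_key(u, v) %in% e1)) next
      if (u %in% names(map) && v %in% names(map) &&
          pair_key(map[[u]], map[[v]]) %in% e2) {
        conserved <- c(conserved, pair_key(u, v))
      }
    }
  }
  img <- unname(map)
  induced <- 0L
  if (length(img) > 1L) {
    for (i in seq_along(img)[-1L]) for (j in seq_len(i - 1L)) {
      if (pair_key(img[i], img[j]) %in% e2) induced <- induced + 1L
    }
  }
  n_cons <- length(conserved)

  # largest component of (aligned nodes, conserved edges) via BFS
  lcc_nodes <- 0L
  if (n_cons > 0L) {
    ends <- do.call(rbind, strsplit(conserved, "\r", fixed = TRUE))
    verts <- unique(c(ends))
    seen <- character()
    for (start in verts) {
      if (start %in% seen) next
      queue <- start; comp <- character()
      while (length(queue)) {
        x <- queue[1L]; queue <- queue[-1L]
        if (x %in% comp) next
        comp <- c(comp, x)
        nb <- c(ends[ends[, 1L] == x, 2L], ends[ends[, 2L] == x, 1L])
        queue <- c(queue, setdiff(nb, comp))
      }
      seen <- c(seen, comp)
      lcc_nodes <- max(lcc_nodes, length(comp))
    }
  }

  m1 <- length(e1)
  c(nc = length(map) / length(v1),
    ec = if (m1 == 0L) NA_real_ else n_cons / m1,
    ics = if (induced == 0L) NA_real_ else n_cons / induced,
    s3 = if (m1 + induced - n_cons == 0L) NA_real_ else n_cons / (m1 + induced - n_cons),
    lcc = lcc_nodes / length(v1))
}

# Double loop over mapped pairs; annotated counts restricted to network nodes.
oracle_bio_score <- function(aln, ann1, ann2, net1, net2) {
  a1 <- intersect(names(ann1$annotations), network_nodes(net1))
  a2 <- intersect(names(ann2$annotations), network_nodes(net2))
  shared <- 0L
  for (i in seq_len(alignment_size(aln))) {
    u <- aln$pairs$source[i]; v <- aln$pairs$target[i]
    if (!(u %in% a1) || !(v %in% a2)) next
    hit <- FALSE
    for (t1 in ann1$annotations[[u]]) for (t2 in ann2$annotations[[v]]) {
      if (t1 == t2) hit <- TRUE
    }
    if (hit) shared <- shared + 1L
  }
  denom <- min(length(a1), length(a2))
  if (denom == 0L) NA_real_ else shared / denom
}

# Reference BH step-up written out longhand.
reference_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1L):1L) if (m > 1L) adj[i] <- min(adj[i], adj[i + 1L])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exhaustive hypergeometric upper tail: enumerate all n-subsets of 1..N with
# carriers 1..K, count subsets holding at least k carriers.
enumerate_hyper_tail <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Random instances -------------------------------------------------------

random_network <- function(n, p, name, prefix) {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- t(utils::combn(nodes, 2L))
  pick <- stats::runif(nrow(pairs)) < p
  ppi_network(nodes, pairs[pick, , drop = FALSE], name = name)
}

random_injection <- function(net1, net2, size = NULL) {
  v1 <- network_nodes(net1); v2 <- network_nodes(net2)
  if (is.null(size)) size <- sample.int(length(v1), 1L)
  ppi_alignment(cbind(sample(v1, size), sample(v2, size)),
                source_net = net1$name, target_net = net2$name)
}
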