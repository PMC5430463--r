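#' Specification for a synthetic network-alignment study
#'
#' Bundles the parameters of the synthetic generator: a pair of PPI-like
#' networks of unequal size with a planted correspondence, optionally
#' corrupted alignments, and annotation tables with tunable functional
#' coherence. Synthetic pairs are test and benchmarking fixtures; they do not
#' model PPI evolution.
#'
#' @param n1,n2 node counts of the smaller and larger network (`n1 <= n2`).
#' @param model `"duplication"` (default): the larger network extends a copy
#'   of the smaller one by preferential attachment plus edge rewiring, so the
#'   pair shares genuine conserved structure; `"erdos-renyi"`: two
#'   independent G(n, p) graphs, a null model with no planted signal.
#' @param p_edge edge probability of the smaller network (and of the larger
#'   one under `"erdos-renyi"`).
#' @param attach_edges edges added per extra node under `"duplication"`.
#' @param rewire fraction of the larger network's edges re-wired to random
#'   non-adjacent pairs under `"duplication"`.
#' @param shuffle_fraction default corruption level for [corrupt_alignment()].
#' @param n_terms,coherence annotation-table parameters for
#'   [make_annotations()]: vocabulary size and the probability that planted
#'   partners share a term.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n1 = 60L, n2 = 90L,
                           model = c("duplication", "erdos-renyi"),
                           p_edge = 0.08, attach_edges = 2L, rewire = 0.1,
                           shuffle_fraction = 0, n_terms = 50L,
                           coherence = 0.8, seed = 1L) {
  model <- match.arg(model)
  if (n1 > n2) stop("n1 must not exceed n2")
  if (n1 < 2L) stop("n1 must be at least 2")
  stopifnot(p_edge > 0, p_edge <= 1,
            rewire >= 0, rewire <= 1,
            shuffle_fraction >= 0, shuffle_fraction <= 1,
            coherence >= 0, coherence <= 1)
  if (n_terms < 1L) stop("n_terms must be at least 1")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), model = model,
                 p_edge = p_edge, attach_edges = as.integer(attach_edges),
                 rewire = rewire, shuffle_fraction = shuffle_fraction,
                 n_terms = as.integer(n_terms), coherence = coherence,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Run code under a given seed, restoring the caller's RNG state afterwards.
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic network pair with a planted alignment
#'
#' Builds the smaller network G1 as an Erdos-Renyi graph, then the larger
#' network G2 either by the duplication model (copy G1 under fresh labels,
#' attach `n2 - n1` extra nodes preferentially by degree, rewire a fraction
#' of edges) or as an independent Erdos-Renyi graph. The planted alignment is
#' the identity-like correspondence mapping every G1 node to its copy.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `net1`, `net2` ([ppi_network()]s) and `planted`
#'   (a [ppi_alignment()] of size `n1`).
#' @export
make_network_pair <- function(spec) {
  with_rng_seed(spec$seed, {
    src <- sprintf("s%04d", seq_len(spec$n1))
    tgt <- sprintf("t%04d", seq_len(spec$n2))
    g1 <- igraph::sample_gnp(spec$n1, spec$p_edge)
    if (igraph::ecount(g1) == 0L) {
      stop("edge density produced no edges; increase p_edge or n1")
    }
    e1 <- igraph::as_edgelist(g1, names = FALSE)
    net1 <- ppi_network(src, cbind(src[e1[, 1L]], src[e1[, 2L]]), name = "G1")

    if (spec$model == "erdos-renyi") {
      g2 <- igraph::sample_gnp(spec$n2, spec$p_edge)
      if (igraph::ecount(g2) == 0L) stop("edge density produced no edges in G2")
      e2 <- igraph::as_edgelist(g2, names = FALSE)
      net2 <- ppi_network(tgt, cbind(tgt[e2[, 1L]], tgt[e2[, 2L]]), name = "G2")
    } else {
      edges <- e1  # integer indices into tgt
      deg <- function(e, n) tabulate(c(e), nbins = n)
      for (v in (spec$n1 + 1L):spec$n2) {
        w <- deg(edges, v - 1L) + 1
        nb <- sample.int(v - 1L, size = min(spec$attach_edges, v - 1L),
                         prob = w)
        edges <- rbind(edges, cbind(nb, v))
      }
      # rewire: move one endpoint of a random subset of edges
      n_rw <- round(spec$rewire * nrow(edges))
      if (n_rw > 0L) {
        has_edge <- new.env(hash = TRUE)
        ekey <- function(a, b) paste(min(a, b), max(a, b))
        for (i in seq_len(nrow(edges))) {
          assign(ekey(edges[i, 1L], edges[i, 2L]), TRUE, has_edge)
        }
        for (i in sample.int(nrow(edges), n_rw)) {
          keep <- edges[i, sample.int(2L, 1L)]
          for (try in 1:20) {
            new <- sample.int(spec$n2, 1L)
            if (new != keep && !exists(ekey(keep, new), has_edge)) {
              rm(list = ekey(edges[i, 1L], edges[i, 2L]), envir = has_edge)
              assign(ekey(keep, new), TRUE, has_edge)
              edges[i, ] <- c(keep, new)
              break
            }
          }
        }
      }
      net2 <- ppi_network(tgt, cbind(tgt[edges[, 1L]], tgt[edges[, 2L]]),
                          name = "G2")
    }
    planted <- ppi_alignment(cbind(src, tgt[seq_len(spec$n1)]),
                             source_net = "G1", target_net = "G2",
                             aligner = "planted", alpha = NA_real_)
    list(net1 = net1, net2 = net2, planted = planted)
  })
}

#' Corrupt an alignment by shuffling a fraction of its mappings
#'
#' Re-targets a given fraction of the mapping pairs: the selected source
#' nodes are assigned, without replacement, uniformly chosen targets from the
#' pool of larger-network nodes not used by the untouched pairs. Injectivity
#' is preserved. At fraction 0 the alignment is returned unchanged; at
#' fraction 1 the result behaves like a random injection.
#'
#' @param aln a [ppi_alignment()] (typically the planted alignment).
#' @param net2 the larger [ppi_network()] supplying the target pool.
#' @param shuffle_fraction fraction in `[0, 1]` of pairs to re-target.
#' @param seed integer seed.
#' @return a [ppi_alignment()] of the same size, tagged
#'   `aligner = "shuffled"` with `alpha = shuffle_fraction`.
#' @export
corrupt_alignment <- function(aln, net2, shuffle_fraction, seed = 1L) {
  if (shuffle_fraction < 0 || shuffle_fraction > 1) {
    stop("shuffle_fraction must be in [0, 1]")
  }
  k <- round(shuffle_fraction * alignment_size(aln))
  if (k == 0L) return(aln)
  with_rng_seed(seed, {
    pairs <- aln$pairs
    pick <- sample.int(nrow(pairs), k)
    pool <- setdiff(network_nodes(net2), pairs$target[-pick])
    if (length(pool) < k) {
      stop("not enough distinct targets in the larger network to re-target ",
           k, " pairs")
    }
    pairs$target[pick] <- sample(pool, k)
    ppi_alignment(pairs, source_net = aln$source_net,
                  target_net = aln$target_net,
                  aligner = "shuffled", alpha = shuffle_fraction)
  })
}

#' Generate annotation tables with tunable functional coherence
#'
#' Every protein of both networks receives one term drawn uniformly from a
#' vocabulary of `n_terms` (so all proteins are annotated and chance overlap
#' is about `1/n_terms`); additionally, each planted pair shares one common
#' term with probability `coherence`. At coherence 1 the planted alignment
#' scores 1 on the annotation-overlap measure; at coherence 0 it scores at
#' the chance baseline.
#'
#' @param net1,net2 the smaller and larger [ppi_network()]s.
#' @param planted the planted [ppi_alignment()].
#' @param n_terms vocabulary size (>= 1).
#' @param coherence probability in `[0, 1]` that planted partners share a
#'   term.
#' @param seed integer seed.
#' @return list of two [annotation_set()]s (`ann1`, `ann2`) in namespace
#'   `"KEGG"`.
#' @export
make_annotations <- function(net1, net2, planted, n_terms = 50L,
                             coherence = 0.8, seed = 1L) {
  if (n_terms < 1L) stop("n_terms must be at least 1")
  if (coherence < 0 || coherence > 1) stop("coherence must be in [0, 1]")
  with_rng_seed(seed, {
    terms <- sprintf("T%03d", seq_len(n_terms))
    a1 <- stats::setNames(as.list(sample(terms, n_nodes(net1), replace = TRUE)),
                          network_nodes(net1))
    a2 <- stats::setNames(as.list(sample(terms, n_nodes(net2), replace = TRUE)),
                          network_nodes(net2))
    if (alignment_size(planted)) {
      share <- stats::runif(alignment_size(planted)) < coherence
      shared_terms <- sample(terms, alignment_size(planted), replace = TRUE)
      for (i in which(share)) {
        u <- planted$pairs$source[i]
        v <- planted$pairs$target[i]
        a1[[u]] <- c(a1[[u]], shared_terms[i])
        a2[[v]] <- c(a2[[v]], shared_terms[i])
      }
    }
    list(ann1 = annotation_set(a1, namespace = "KEGG"),
         ann2 = annotation_set(a2, namespace = "KEGG"))
  })
}

#' Write a full synthetic study to disk
#'
#' Generates a network pair, the planted alignment, a corrupted alignment at
#' the spec's `shuffle_fraction`, and annotation tables, and writes them in
#' the package's file formats (edge-list TSV, two-column alignment TSV,
#' annotation TSV).
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named character vector of written paths.
#' @export
write_synthetic_study <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- make_network_pair(spec)
  ann <- make_annotations(sim$net1, sim$net2, sim$planted,
                          n_terms = spec$n_terms, coherence = spec$coherence,
                          seed = spec$seed + 1L)
  shuffled <- corrupt_alignment(sim$planted, sim$net2, spec$shuffle_fraction,
                                seed = spec$seed + 2L)
  paths <- c(net1 = file.path(dir, "net1.gw"), net2 = file.path(dir, "net2.gw"),
             planted = file.path(dir, "planted.tsv"),
             shuffled = file.path(dir, "shuffled.tsv"),
             ann1 = file.path(dir, "ann1.tsv"), ann2 = file.path(dir, "ann2.tsv"))
  # LEDA format so that isolated nodes survive the round trip
  write_network(sim$net1, paths[["net1"]], format = "gw")
  write_network(sim$net2, paths[["net2"]], format = "gw")
  write_alignment(sim$planted, paths[["planted"]])
  write_alignment(shuffled, paths[["shuffled"]])
  write_annotations(ann$ann1, paths[["ann1"]])
  write_annotations(ann$ann2, paths[["ann2"]])
  invisible(paths)
}
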