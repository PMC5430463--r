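#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n proteins without
#' replacement from a universe of N in which K carry the term, the
#' probability of seeing at least k carriers. Evaluated through
#' [stats::phyper()], which works in log space and is stable for large N.
#'
#' @param k observed carriers in the draw.
#' @param K carriers in the universe.
#' @param n draw size.
#' @param N universe size.
#' @return probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || n > N || K > N || k > min(n, K)) {
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K), n <= N, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR control: sort ascending, multiply p(i) by m/i, enforce
#' monotonicity from the largest down, cap at 1, return in input order
#' (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, elementwise >= `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Term enrichment of soft clusters
#'
#' For every eligible cluster (at least two annotated members) and every term
#' carried by at least one member, tests over-representation against a
#' background universe by the upper-tail hypergeometric probability (sampling
#' without replacement), then applies Benjamini-Hochberg correction. Only
#' annotated members count: unannotated proteins carry no information under
#' sampling from the annotated universe, and terms absent from a cluster are
#' not tested. The companion summary is the fraction of eligible clusters
#' with at least one term significant after correction.
#'
#' @param clusters a `soft_clustering` from [soft_clusters()].
#' @param ann an [annotation_set()] for the cluster members' species.
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @param universe background protein set; defaults to all annotated proteins
#'   of `ann`. Pass the source network's node set to restrict the background
#'   to one interactome. Unannotated universe proteins are ignored.
#' @param bh_scope `"cluster"` (default): BH within each cluster's term
#'   family, matching the per-cluster "at least one enriched term" question;
#'   `"global"`: one BH family over all (cluster, term) tests.
#' @return list with `results`, a data frame with one row per (cluster, term)
#'   — columns `cluster`, `term`, `k`, `n`, `K`, `N`, `p_raw`, `p_adj` — and
#'   `significant_fraction`, the share of eligible clusters with any
#'   `p_adj <= alpha` (`NA` with a warning if no cluster is eligible).
#' @export
cluster_enrichment <- function(clusters, ann, alpha = 0.05, universe = NULL,
                               bh_scope = c("cluster", "global")) {
  bh_scope <- match.arg(bh_scope)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(universe)) universe <- names(ann$annotations)
  universe <- intersect(universe, names(ann$annotations))
  N <- length(universe)
  term_members <- split(
    rep(universe, lengths(ann$annotations[universe])),
    unlist(ann$annotations[universe], use.names = FALSE))
  term_K <- lengths(term_members)

  rows <- list()
  eligible <- character()
  for (cl in names(clusters)) {
    members <- intersect(clusters[[cl]], universe)
    n <- length(members)
    if (n < 2L) next
    eligible <- c(eligible, cl)
    terms <- sort(unique(unlist(ann$annotations[members], use.names = FALSE)))
    k <- vapply(terms, function(t) length(intersect(term_members[[t]], members)),
                integer(1L))
    p <- vapply(seq_along(terms), function(i) {
      hypergeom_upper_tail(k[i], term_K[[terms[i]]], n, N)
    }, numeric(1L))
    rows[[cl]] <- data.frame(cluster = cl, term = terms, k = k, n = n,
                             K = unname(term_K[terms]), N = N, p_raw = p,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(eligible)) {
    warning("no cluster has two or more annotated members; fraction undefined")
    return(list(results = data.frame(), significant_fraction = NA_real_))
  }
  if (bh_scope == "cluster") {
    for (cl in names(rows)) rows[[cl]]$p_adj <- bh_adjust(rows[[cl]]$p_raw)
    results <- do.call(rbind, rows)
  } else {
    results <- do.call(rbind, rows)
    results$p_adj <- bh_adjust(results$p_raw)
  }
  row.names(results) <- NULL
  hit <- tapply(results$p_adj <= alpha, results$cluster, any)
  list(results = results,
       significant_fraction = mean(hit[eligible]))
}
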