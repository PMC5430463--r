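#' Score tables
#'
#' A score table holds one row per scored alignment: identification columns
#' `aligner`, `alpha`, `pair`, and one numeric column per quality metric
#' (conventionally `nc`, `ec`, `ics`, `s3`, `lcc`, `kp`, `go_bp`, `go_mf`,
#' `go_cc`; missing scores are `NA`). `(aligner, alpha, pair)` identifies a
#' row.
#'
#' @param x data frame to validate.
#' @return the validated data frame, invisibly classed `score_table`.
#' @export
score_table <- function(x) {
  need <- c("aligner", "alpha", "pair")
  if (!all(need %in% names(x))) {
    stop("score table needs columns: ", paste(need, collapse = ", "))
  }
  metrics <- setdiff(names(x), need)
  if (!length(metrics)) stop("score table has no metric columns")
  for (m in metrics) {
    v <- x[[m]]
    if (!is.numeric(v) || any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("metric column '", m, "' must be numeric in [0, 1]")
    }
  }
  key <- interaction(x$aligner, x$alpha, x$pair, drop = TRUE)
  if (anyDuplicated(key)) stop("(aligner, alpha, pair) must identify a row")
  class(x) <- unique(c("score_table", class(x)))
  x
}

score_metrics <- function(table) {
  setdiff(names(table), c("aligner", "alpha", "pair"))
}

#' Best average score of an aligner over its parameter sweep
#'
#' For a given aligner and metric, averages the metric over network pairs at
#' each value of the balancing parameter alpha (missing values excluded) and
#' returns the alpha achieving the highest average together with that
#' average. Ties go to the smallest alpha. This is the per-cell reduction
#' behind aligner comparisons: only the best parameterization of each aligner
#' is reported.
#'
#' @param table a [score_table()].
#' @param aligner,metric row and column selectors.
#' @return list with `alpha` and `mean`.
#' @export
best_mean_score <- function(table, aligner, metric) {
  rows <- table[table$aligner == aligner & !is.na(table[[metric]]), ]
  if (!nrow(rows)) stop("no non-missing '", metric, "' value for aligner '", aligner, "'")
  means <- tapply(rows[[metric]], rows$alpha, mean)
  alphas <- as.numeric(names(means))
  ord <- order(-means, alphas)
  list(alpha = alphas[ord[1L]], mean = unname(means[ord[1L]]))
}

#' Matrix of best average scores, aligners by metrics
#'
#' @param table a [score_table()].
#' @param metrics metric columns to include; defaults to all present.
#' @return numeric matrix, aligners in rows, metrics in columns; `NA` where
#'   an aligner has no non-missing value for a metric (with a warning).
#' @export
best_score_matrix <- function(table, metrics = score_metrics(table)) {
  aligners <- unique(table$aligner)
  out <- matrix(NA_real_, length(aligners), length(metrics),
                dimnames = list(aligners, metrics))
  for (a in aligners) for (m in metrics) {
    out[a, m] <- tryCatch(best_mean_score(table, a, m)$mean,
                          error = function(e) NA_real_)
  }
  if (anyNA(out)) warning("some aligner/metric cells have no data and are NA")
  out
}

#' Topology/biology trade-off score
#'
#' Geometric mean of the S3 and KP scores of an alignment, balancing
#' topological against biological coherence. `NA` propagates.
#'
#' @param s3,kp fractions in `[0, 1]` (vectorized).
#' @return `sqrt(s3 * kp)`.
#' @export
tradeoff_score <- function(s3, kp) {
  bad <- !is.na(s3) & !is.na(kp) & (s3 < 0 | s3 > 1 | kp < 0 | kp > 1)
  if (any(bad)) stop("s3 and kp must be in [0, 1]")
  sqrt(s3 * kp)
}

#' Competition ranking (higher value is better)
#'
#' Tied values share the minimal rank and the next distinct value's rank is
#' 1 + the number of strictly better values (the "1, 1, 1, 4" pattern). `NA`
#' values receive `NA` ranks and do not affect the others.
#'
#' @param x numeric vector of scores.
#' @return integer vector of ranks.
#' @export
competition_rank <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  out[ok] <- vapply(x[ok], function(v) 1L + sum(x[ok] > v), integer(1L))
  out
}

#' Aggregate per-metric ranks into a rank table
#'
#' Given a matrix of per-metric ranks (aligners in rows), computes each
#' aligner's average rank over all metrics (`avg_all`) and over the S3 and KP
#' columns only (`avg_s3_kp`), and sorts the table. The default ordering is
#' by `avg_s3_kp` with `avg_all` breaking ties, the ordering used when both
#' averages are reported side by side; set `sort_by = "avg_all"` to order by
#' the overall average instead.
#'
#' @param ranks numeric matrix, aligners x metrics, containing ranks.
#' @param s3_kp the two column names averaged into `avg_s3_kp`; set to `NULL`
#'   to skip that column.
#' @param sort_by `"avg_s3_kp"` (default) or `"avg_all"`.
#' @return data frame classed `rank_table`: aligner, the per-metric ranks,
#'   `avg_s3_kp` (if computed) and `avg_all`.
#' @export
aggregate_ranks <- function(ranks, s3_kp = c("s3", "kp"),
                            sort_by = c("avg_s3_kp", "avg_all")) {
  sort_by <- match.arg(sort_by)
  avg_all <- rowMeans(ranks, na.rm = TRUE)
  out <- data.frame(aligner = rownames(ranks), ranks, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(s3_kp)) {
    if (!all(s3_kp %in% colnames(ranks))) stop("columns not found: ",
                                               paste(s3_kp, collapse = ", "))
    out$avg_s3_kp <- rowMeans(ranks[, s3_kp, drop = FALSE], na.rm = TRUE)
  }
  out$avg_all <- avg_all
  ord <- if (sort_by == "avg_s3_kp" && !is.null(s3_kp)) {
    order(out$avg_s3_kp, out$avg_all)
  } else order(out$avg_all)
  out <- out[ord, , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- unique(c("rank_table", class(out)))
  out
}

#' Rank aligners from their best scores
#'
#' Applies descending-score competition ranking per metric to a best-score
#' matrix (see [best_score_matrix()]), then aggregates via
#' [aggregate_ranks()]. An aligner missing a metric is excluded from that
#' metric's ranking (its rank is `NA`) and flagged with a warning.
#'
#' @param best numeric matrix of best mean scores, aligners x metrics.
#' @inheritParams aggregate_ranks
#' @return a `rank_table` data frame.
#' @export
rank_aligners <- function(best, s3_kp = intersect(c("s3", "kp"), colnames(best)),
                          sort_by = c("avg_s3_kp", "avg_all")) {
  if (nrow(best) < 2L) stop("need at least two aligners to rank")
  if (anyNA(best)) {
    warning("aligner(s) with missing metrics excluded from those rankings")
  }
  ranks <- apply(best, 2L, competition_rank)
  dimnames(ranks) <- dimnames(best)
  if (!length(s3_kp)) s3_kp <- NULL
  aggregate_ranks(ranks, s3_kp = s3_kp, sort_by = sort_by)
}

#' Pearson correlation matrix of alignment scores
#'
#' Correlates every pair of metric columns of a score table over alignments,
#' using pairwise-complete observations so a single missing score does not
#' discard a whole alignment. Metrics with zero variance yield `NA` entries
#' and a warning.
#'
#' @param table a [score_table()] (or any data frame with metric columns and
#'   the `aligner`/`alpha`/`pair` identifiers).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
score_correlation <- function(table) {
  m <- as.matrix(table[, score_metrics(table), drop = FALSE])
  if (nrow(m) < 3L) stop("need at least three scored alignments")
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0)) {
    warning("zero-variance metric(s): ",
            paste(colnames(m)[!is.na(sds) & sds == 0], collapse = ", "))
  }
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cc) <- ifelse(colSums(!is.na(m)) > 0L, 1, NA_real_)
  cc
}
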