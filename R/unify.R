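#' Unify several one-to-one alignments into a many-to-many mapping
#'
#' The union of the mappings of several global alignments of the same network
#' pair. The result is no longer one-to-one: a source node may map to several
#' targets and vice versa. Each (source, target) pair records which input
#' alignments support it.
#'
#' @param alignments list of one or more [ppi_alignment()]s on the same
#'   (canonically oriented) network pair.
#' @param labels optional labels for the inputs; defaults to
#'   [alignment_label()] values, deduplicated.
#' @return an object of class `unified_mapping`: list with a `pairs` data
#'   frame (`source`, `target`, `support_count`), a `support` list of
#'   contributing labels per pair (same order as `pairs`), and the network
#'   labels.
#' @export
unify_alignments <- function(alignments, labels = NULL) {
  if (!length(alignments)) stop("need at least one alignment")
  if (is.null(labels)) {
    labels <- make.unique(vapply(alignments, alignment_label, character(1L)))
  }
  for (a in alignments[-1L]) check_same_pair(alignments[[1L]], a)
  src <- unlist(lapply(alignments, function(a) a$pairs$source))
  tgt <- unlist(lapply(alignments, function(a) a$pairs$target))
  lab <- rep(labels, vapply(alignments, alignment_size, integer(1L)))
  key <- paste(src, tgt, sep = "\r")
  first <- !duplicated(key)
  support <- split(lab, factor(key, levels = key[first]))
  pairs <- data.frame(source = src[first], target = tgt[first],
                      support_count = lengths(support),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(pairs = pairs, support = unname(support),
                 source_net = alignments[[1L]]$source_net,
                 target_net = alignments[[1L]]$target_net),
            class = "unified_mapping")
}

#' @export
print.unified_mapping <- function(x, ...) {
  cat(sprintf("<unified_mapping> %s -> %s: %d pairs (%d sources, %d targets)\n",
              x$source_net, x$target_net, nrow(x$pairs),
              length(unique(x$pairs$source)), length(unique(x$pairs$target))))
  invisible(x)
}

#' Coverage-versus-k curve of a sequence of alignments
#'
#' Entry k of the curve is the fraction of the chosen side's network covered
#' by the union of the first k alignments' node sets on that side; entry 0 is
#' 0 (no alignment). The caller fixes the order, typically best aligner first
#' according to a chosen score.
#'
#' @param alignments ordered list of [ppi_alignment()]s.
#' @param net the [ppi_network()] of the chosen side (the larger network for
#'   `side = "target"`).
#' @param side `"target"` (default) or `"source"`.
#' @return numeric vector of length `length(alignments) + 1`, non-decreasing,
#'   in `[0, 1]`.
#' @export
coverage_curve <- function(alignments, net, side = c("target", "source")) {
  side <- match.arg(side)
  total <- n_nodes(net)
  covered <- character()
  curve <- numeric(length(alignments) + 1L)
  for (k in seq_along(alignments)) {
    covered <- union(covered, alignments[[k]]$pairs[[side]])
    curve[k + 1L] <- length(covered) / total
  }
  curve
}

#' Soft clustering induced by a unified mapping
#'
#' Groups the smaller network's proteins that are mapped to the same larger
#' network protein. Clusters are keyed by the target protein and may overlap:
#' a source node mapped to k distinct targets belongs to k clusters.
#'
#' @param u a `unified_mapping` from [unify_alignments()].
#' @return an object of class `soft_clustering`: a named list, target
#'   protein -> character vector of source proteins, with the network labels
#'   as attributes.
#' @export
soft_clusters <- function(u) {
  if (!nrow(u$pairs)) stop("empty unified mapping")
  cl <- split(u$pairs$source, u$pairs$target)
  cl <- lapply(cl, unique)
  structure(cl, class = "soft_clustering",
            source_net = u$source_net, target_net = u$target_net)
}

#' @export
print.soft_clustering <- function(x, ...) {
  cat(sprintf("<soft_clustering> %d clusters, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Flatten a soft clustering back to (source, target) pairs
#'
#' Inverse of [soft_clusters()]: re-emits every (member, cluster key) pair.
#'
#' @param clusters a `soft_clustering`.
#' @return data frame with columns `source`, `target`.
#' @export
flatten_clusters <- function(clusters) {
  data.frame(source = unlist(clusters, use.names = FALSE),
             target = rep(names(clusters), lengths(clusters)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotation-transfer consistency of a soft clustering
#'
#' For each cluster whose target protein is annotated, the cluster is
#' consistent if the union of its members' annotations shares at least one
#' term with the target protein's annotations. The returned value is the
#' fraction of such clusters that are consistent — how often annotations
#' could validly be transferred through the mapping.
#'
#' @param clusters a `soft_clustering` (source-species members keyed by
#'   target-species proteins).
#' @param ann_src,ann_tgt [annotation_set()]s for the source and target
#'   species; namespaces must match.
#' @return fraction in `[0, 1]`, `NA` with a warning if no cluster target is
#'   annotated.
#' @export
transfer_consistency <- function(clusters, ann_src, ann_tgt) {
  if (!identical(ann_src$namespace, ann_tgt$namespace)) {
    stop("annotation namespaces differ")
  }
  targets <- names(clusters)
  annotated <- targets %in% names(ann_tgt$annotations)
  if (!any(annotated)) {
    return(undefined_score("transfer consistency", "no annotated cluster target"))
  }
  consistent <- vapply(which(annotated), function(i) {
    src_terms <- unique(unlist(ann_src$annotations[clusters[[i]]],
                               use.names = FALSE))
    length(intersect(src_terms, ann_tgt$annotations[[targets[i]]])) > 0L
  }, logical(1L))
  mean(consistent)
}

#' Read/write a unified mapping
#'
#' Four-column TSV: source, target, support count, comma-joined contributing
#' aligner labels.
#'
#' @param u a `unified_mapping`.
#' @param path file path.
#' @param source_net,target_net network labels to attach on reading.
#' @return `read_unified()` a `unified_mapping`; `write_unified()` the path,
#'   invisibly.
#' @export
write_unified <- function(u, path) {
  writeLines(paste(u$pairs$source, u$pairs$target, u$pairs$support_count,
                   vapply(u$support, paste, character(1L), collapse = ","),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_unified
#' @export
read_unified <- function(path, source_net = NA_character_,
                         target_net = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty unified mapping file: ", path)
  toks <- strsplit(lines, "\t")
  if (any(lengths(toks) < 4L)) stop("parse error in ", path, ": expected four columns")
  support <- lapply(toks, function(x) strsplit(x[4L], ",")[[1L]])
  pairs <- data.frame(source = vapply(toks, `[`, "", 1L),
                      target = vapply(toks, `[`, "", 2L),
                      support_count = lengths(support),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, support = support,
                 source_net = source_net, target_net = target_net),
            class = "unified_mapping")
}
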