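#' Annotation-overlap score of an alignment (KP / GO-BP / GO-MF / GO-CC)
#'
#' Two aligned proteins are functionally similar if they share at least one
#' annotation term (a common KEGG pathway, or a common GO term within one
#' aspect). The score is the number of aligned pairs whose two proteins are
#' both annotated and share a term, divided by the smaller of the two
#' per-network annotated-protein counts. Pairs with an unannotated protein
#' contribute 0 to the numerator but are not removed from the denominator,
#' which counts annotated proteins, not annotated pairs. Annotations of
#' proteins absent from a network are ignored.
#'
#' @param aln a [ppi_alignment()] from `net1` into `net2`.
#' @param ann1,ann2 [annotation_set()]s for the source and target species;
#'   must share a namespace.
#' @param net1,net2 the smaller and larger [ppi_network()]s, used to restrict
#'   the annotated-protein counts to network nodes.
#' @return an object of class `bio_score`: list with `namespace`, `value`
#'   (fraction, `NA` if no protein of either network is annotated),
#'   `shared_pairs` and `denominator`.
#' @export
annotation_overlap_score <- function(aln, ann1, ann2, net1, net2) {
  if (!identical(ann1$namespace, ann2$namespace)) {
    stop("annotation namespaces differ: ", ann1$namespace, " vs ", ann2$namespace)
  }
  a1 <- annotated_in(ann1, net1)
  a2 <- annotated_in(ann2, net2)
  denom <- min(length(a1), length(a2))
  shared <- 0L
  if (alignment_size(aln)) {
    src <- aln$pairs$source
    tgt <- aln$pairs$target
    ok <- src %in% a1 & tgt %in% a2
    if (any(ok)) {
      shared <- sum(mapply(function(u, v) {
        length(intersect(ann1$annotations[[u]], ann2$annotations[[v]])) > 0L
      }, src[ok], tgt[ok]))
    }
  }
  value <- if (denom == 0L) {
    undefined_score(paste0(ann1$namespace, " score"), "no annotated protein in one network")
  } else shared / denom
  structure(list(namespace = ann1$namespace, value = value,
                 shared_pairs = shared, denominator = denom),
            class = "bio_score")
}

#' @export
print.bio_score <- function(x, ...) {
  cat(sprintf("<bio_score> %s: %s (%d / %d)\n", x$namespace,
              format(x$value, digits = 4L), x$shared_pairs, x$denominator))
  invisible(x)
}

#' All nine quality scores of one alignment
#'
#' Convenience wrapper producing one row of a score table: the five
#' topological scores plus one annotation-overlap score per supplied
#' namespace.
#'
#' @inheritParams topo_scores
#' @param annotations named list of namespaces; each element is a list of two
#'   [annotation_set()]s, `list(ann1, ann2)` for source and target species.
#' @return named numeric vector: `nc`, `ec`, `ics`, `s3`, `lcc`, then one
#'   entry per annotation namespace (lower-cased, `-` replaced by `_`).
#' @export
score_alignment <- function(net1, net2, aln, annotations = list()) {
  out <- topo_scores(net1, net2, aln)
  for (ns in names(annotations)) {
    pair <- annotations[[ns]]
    bs <- annotation_overlap_score(aln, pair[[1L]], pair[[2L]], net1, net2)
    out[[tolower(gsub("-", "_", ns))]] <- bs$value
  }
  out
}
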