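#' Node mapping agreement of two alignments
#'
#' On the larger network, let S_i be the proteins used as targets by
#' alignment i and S_j those used by alignment j. The node mapping agreement
#' is `|S_i intersect S_j| / min(|S_i|, |S_j|)`: how similarly the two
#' alignments use the larger network, normalized by the smaller image.
#'
#' @param aln_i,aln_j two [ppi_alignment()]s targeting the same larger
#'   network.
#' @return fraction in `[0, 1]`, `NA` with a warning if either alignment is
#'   empty.
#' @export
node_mapping_agreement <- function(aln_i, aln_j) {
  check_same_pair(aln_i, aln_j)
  si <- aln_i$pairs$target
  sj <- aln_j$pairs$target
  if (!length(si) || !length(sj)) {
    return(undefined_score("node mapping agreement", "empty alignment"))
  }
  length(intersect(si, sj)) / min(length(si), length(sj))
}

#' Exact mapping agreement of two alignments
#'
#' The fraction of identical protein mappings: source nodes mapped by both
#' alignments to the same target, normalized by the size of the smaller
#' alignment. Always bounded above by the node mapping agreement, since an
#' identical mapping implies a shared image node.
#'
#' @inheritParams node_mapping_agreement
#' @return fraction in `[0, 1]`, `NA` with a warning if either alignment is
#'   empty.
#' @export
exact_mapping_agreement <- function(aln_i, aln_j) {
  check_same_pair(aln_i, aln_j)
  if (!alignment_size(aln_i) || !alignment_size(aln_j)) {
    return(undefined_score("exact mapping agreement", "empty alignment"))
  }
  mi <- alignment_map(aln_i)
  mj <- alignment_map(aln_j)
  both <- intersect(names(mi), names(mj))
  same <- sum(mi[both] == mj[both])
  same / min(length(mi), length(mj))
}

check_same_pair <- function(aln_i, aln_j) {
  same <- (is.na(aln_i$source_net) || is.na(aln_j$source_net) ||
           identical(aln_i$source_net, aln_j$source_net)) &&
          (is.na(aln_i$target_net) || is.na(aln_j$target_net) ||
           identical(aln_i$target_net, aln_j$target_net))
  if (!same) stop("alignments do not share a network pair: ",
                  aln_i$source_net, "->", aln_i$target_net, " vs ",
                  aln_j$source_net, "->", aln_j$target_net)
  invisible(TRUE)
}

#' Pairwise agreement matrices for a set of alignments
#'
#' Computes both the node mapping agreement and the exact mapping agreement
#' for every pair of alignments of the same network pair, as the basis for
#' concurrent-usage analyses.
#'
#' @param alignments list of at least two [ppi_alignment()]s on the same
#'   network pair.
#' @param labels optional character vector of row/column labels; defaults to
#'   [alignment_label()] of each alignment (deduplicated).
#' @return an object of class `agreement_matrix`: list with symmetric
#'   matrices `node_agreement` and `exact_agreement` (unit diagonal for
#'   non-empty alignments) and their mean off-diagonal values
#'   `mean_node_agreement`, `mean_exact_agreement`.
#' @export
agreement_matrix <- function(alignments, labels = NULL) {
  k <- length(alignments)
  if (k < 2L) stop("need at least two alignments")
  if (is.null(labels)) {
    labels <- make.unique(vapply(alignments, alignment_label, character(1L)))
  }
  node <- exact <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    node[i, i] <- exact[i, i] <- if (alignment_size(alignments[[i]])) 1 else NA_real_
    for (j in seq_len(k)) {
      if (j <= i) next
      node[i, j] <- node[j, i] <-
        suppressWarnings(node_mapping_agreement(alignments[[i]], alignments[[j]]))
      exact[i, j] <- exact[j, i] <-
        suppressWarnings(exact_mapping_agreement(alignments[[i]], alignments[[j]]))
    }
  }
  off <- upper.tri(node)
  structure(list(labels = labels,
                 node_agreement = node, exact_agreement = exact,
                 mean_node_agreement = mean(node[off], na.rm = TRUE),
                 mean_exact_agreement = mean(exact[off], na.rm = TRUE)),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat(sprintf("<agreement_matrix> %d alignments; mean node agreement %.4f, mean exact agreement %.4f\n",
              length(x$labels), x$mean_node_agreement, x$mean_exact_agreement))
  invisible(x)
}
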