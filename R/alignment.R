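#' Construct a one-to-one network alignment
#'
#' A global alignment is an injective partial mapping from the nodes of the
#' smaller network to the nodes of the larger one, tagged with the aligner
#' that produced it and (optionally) its topology/sequence balancing
#' parameter alpha.
#'
#' @param pairs two-column character matrix or data frame: source node,
#'   target node. May have zero rows.
#' @param source_net,target_net labels of the source (smaller) and target
#'   (larger) networks.
#' @param aligner aligner label, or `NA`.
#' @param alpha balancing parameter in `[0, 1]`, or `NA`.
#' @return an object of class `ppi_alignment` with a `pairs` data frame
#'   (columns `source`, `target`).
#' @export
ppi_alignment <- function(pairs, source_net = NA_character_,
                          target_net = NA_character_,
                          aligner = NA_character_, alpha = NA_real_) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) pairs <- matrix(character(), ncol = 2L)
  if (ncol(pairs) != 2L) stop("alignment pairs must have two columns")
  storage.mode(pairs) <- "character"
  pairs[] <- trimws(pairs)
  dup_s <- pairs[duplicated(pairs[, 1L]), 1L]
  if (length(dup_s)) {
    stop("alignment is not one-to-one: source node \"", dup_s[1L],
         "\" is mapped more than once")
  }
  dup_t <- pairs[duplicated(pairs[, 2L]), 2L]
  if (length(dup_t)) {
    stop("alignment is not one-to-one: target node \"", dup_t[1L],
         "\" is used more than once")
  }
  if (!is.na(alpha) && (alpha < 0 || alpha > 1)) stop("alpha must be in [0, 1]")
  structure(
    list(pairs = data.frame(source = unname(pairs[, 1L]),
                            target = unname(pairs[, 2L]),
                            stringsAsFactors = FALSE),
         source_net = source_net, target_net = target_net,
         aligner = aligner, alpha = alpha),
    class = "ppi_alignment")
}

#' @export
print.ppi_alignment <- function(x, ...) {
  cat(sprintf("<ppi_alignment> %s -> %s: %d pairs (aligner %s, alpha %s)\n",
              x$source_net, x$target_net, alignment_size(x),
              x$aligner, format(x$alpha)))
  invisible(x)
}

#' Alignment accessors
#'
#' @param aln a [ppi_alignment()].
#' @return `alignment_size()` the number of mapped pairs;
#'   `alignment_map()` a named character vector target-by-source;
#'   `alignment_label()` a display label built from aligner and alpha.
#' @export
alignment_size <- function(aln) nrow(aln$pairs)

#' @rdname alignment_size
#' @export
alignment_map <- function(aln) {
  stats::setNames(aln$pairs$target, aln$pairs$source)
}

#' @rdname alignment_size
#' @export
alignment_label <- function(aln) {
  lab <- if (is.na(aln$aligner)) "alignment" else aln$aligner
  if (!is.na(aln$alpha)) lab <- sprintf("%s@%.2g", lab, aln$alpha)
  lab
}

#' Read a one-to-one alignment from a two-column TSV file
#'
#' Each line gives a source (smaller-network) node and its target
#' (larger-network) node, separated by whitespace. Rows referencing nodes
#' absent from the given networks raise an error, as do violations of
#' injectivity.
#'
#' @param path file path.
#' @param source,target the source and target [ppi_network()] objects used to
#'   validate node references.
#' @inheritParams ppi_alignment
#' @return a [ppi_alignment()].
#' @export
read_alignment <- function(path, source, target,
                           aligner = NA_character_, alpha = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  pairs <- matrix(character(), ncol = 2L)
  if (length(keep)) {
    toks <- strsplit(trimws(lines[keep]), "\\s+")
    bad <- which(lengths(toks) < 2L)
    if (length(bad)) {
      stop(sprintf("parse error in %s at line %d: expected two columns",
                   path, keep[bad[1L]]))
    }
    pairs <- t(vapply(toks, function(x) x[1:2], character(2L)))
  }
  unknown_s <- setdiff(pairs[, 1L], network_nodes(source))
  if (length(unknown_s)) {
    stop("alignment references node(s) absent from source network: ",
         paste(utils::head(unknown_s, 5L), collapse = ", "))
  }
  unknown_t <- setdiff(pairs[, 2L], network_nodes(target))
  if (length(unknown_t)) {
    stop("alignment references node(s) absent from target network: ",
         paste(utils::head(unknown_t, 5L), collapse = ", "))
  }
  ppi_alignment(pairs, source_net = source$name, target_net = target$name,
                aligner = aligner, alpha = alpha)
}

#' Write an alignment as a two-column TSV file
#'
#' @param aln a [ppi_alignment()].
#' @param path file path.
#' @export
write_alignment <- function(aln, path) {
  writeLines(paste(aln$pairs$source, aln$pairs$target, sep = "\t"), path)
  invisible(path)
}

#' Re-orient an alignment to the canonical smaller-to-larger direction
#'
#' If an alignment was produced with source/target roles swapped relative to
#' the canonical ordering of the pair (see [order_network_pair()]), its pairs
#' are flipped; injectivity makes the inversion lossless.
#'
#' @param aln a [ppi_alignment()].
#' @param smaller,larger the canonically ordered [ppi_network()] pair.
#' @return a [ppi_alignment()] mapping `smaller` into `larger`.
#' @export
orient_alignment <- function(aln, smaller, larger) {
  if (identical(aln$source_net, smaller$name)) return(aln)
  if (identical(aln$source_net, larger$name) &&
      identical(aln$target_net, smaller$name)) {
    return(ppi_alignment(aln$pairs[, c("target", "source")],
                         source_net = smaller$name, target_net = larger$name,
                         aligner = aln$aligner, alpha = aln$alpha))
  }
  stop("alignment does not connect the given network pair")
}
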