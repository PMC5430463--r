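#' Construct a protein annotation set
#'
#' Maps proteins to non-empty sets of opaque term identifiers within one
#' namespace (KEGG pathways or one Gene Ontology aspect). Terms are matched
#' by exact identifier equality; no ontology-graph propagation is performed.
#'
#' @param annotations named list: protein identifier -> character vector of
#'   terms (each non-empty).
#' @param namespace label, e.g. `"KEGG"`, `"GO-BP"`, `"GO-MF"`, `"GO-CC"`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(annotations, namespace = "KEGG") {
  if (is.null(names(annotations)) && length(annotations)) {
    stop("annotations must be a named list (protein -> terms)")
  }
  annotations <- lapply(annotations, function(t) unique(trimws(as.character(t))))
  if (any(lengths(annotations) == 0L) ||
      any(vapply(annotations, function(t) any(!nzchar(t)), logical(1L)))) {
    stop("every annotated protein must carry at least one non-empty term")
  }
  names(annotations) <- trimws(names(annotations))
  structure(list(namespace = namespace, annotations = annotations),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d proteins, %d distinct terms\n",
              x$namespace, length(x$annotations),
              length(unique(unlist(x$annotations, use.names = FALSE)))))
  invisible(x)
}

#' Proteins of an annotation set that are nodes of a network
#'
#' @param ann an [annotation_set()].
#' @param net a [ppi_network()].
#' @return character vector of annotated proteins present in the network.
#' @export
annotated_in <- function(ann, net) {
  intersect(names(ann$annotations), network_nodes(net))
}

#' Read protein annotations
#'
#' Two formats: `"tsv"` with one (protein, term) pair per line, and `"gmt"`
#' (gene-set format: term, description, then member proteins, tab-separated).
#' Duplicate (protein, term) rows collapse silently.
#'
#' @param path file path.
#' @param namespace annotation namespace label.
#' @param format `"tsv"` (default) or `"gmt"`.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, namespace = "KEGG",
                             format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  prot <- character(); term <- character()
  if (format == "tsv") {
    for (i in keep) {
      toks <- strsplit(lines[i], "\t|\\s{2,}| ")[[1L]]
      toks <- trimws(toks)
      toks <- toks[nzchar(toks)]
      if (length(toks) < 2L) {
        stop(sprintf("parse error in %s at line %d: expected protein and term",
                     path, i))
      }
      prot <- c(prot, toks[1L]); term <- c(term, toks[2L])
    }
  } else {
    for (i in keep) {
      toks <- trimws(strsplit(lines[i], "\t")[[1L]])
      if (length(toks) < 3L || !nzchar(toks[1L])) {
        stop(sprintf("parse error in %s at line %d: GMT needs term, description, members",
                     path, i))
      }
      members <- toks[-(1:2)]
      if (any(!nzchar(members))) {
        stop(sprintf("parse error in %s at line %d: empty member field", path, i))
      }
      prot <- c(prot, members); term <- c(term, rep(toks[1L], length(members)))
    }
  }
  if (!length(prot)) stop("no annotations in ", path)
  annotation_set(split(term, prot), namespace = namespace)
}

#' Write an annotation set as (protein, term) TSV
#'
#' @param ann an [annotation_set()].
#' @param path file path.
#' @export
write_annotations <- function(ann, path) {
  prot <- rep(names(ann$annotations), lengths(ann$annotations))
  term <- unlist(ann$annotations, use.names = FALSE)
  writeLines(paste(prot, term, sep = "\t"), path)
  invisible(path)
}
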