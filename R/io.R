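#' Read and write allele graphs
#'
#' Two plain-text interchange formats are supported. JSON:
#' `{"labels": [...], "edges": [["u","v"], ...], "undirected_edges": [...]}`,
#' where `edges` are arrows and `undirected_edges` expand to arrow pairs.
#' TSV: two label columns (`from`, `to`), with an optional third column that
#' marks a row as bidirectional when equal to `"both"`. Vertices are ordered
#' lexicographically on read.
#'
#' @param path file path.
#' @param format `"json"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @return `read_allele_graph()` returns an [allele_graph()];
#'   `write_allele_graph()` invisibly returns `path`.
#' @examples
#' tf <- tempfile(fileext = ".json")
#' write_allele_graph(graph_path(3), tf)
#' read_allele_graph(tf)$adjacency
#' @export
read_allele_graph <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    labels <- as.character(obj$labels)
    edges <- edge_matrix(obj$edges)
    undirected <- edge_matrix(obj$undirected_edges)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", comment.char = "#",
                            fill = TRUE)
    both <- ncol(df) >= 3 & df[[min(3, ncol(df))]] == "both"
    if (ncol(df) < 3) both <- rep(FALSE, nrow(df))
    edges <- as.matrix(df[!both, 1:2, drop = FALSE])
    undirected <- as.matrix(df[both, 1:2, drop = FALSE])
    labels <- sort(unique(c(df[[1]], df[[2]])))
  }
  build_from_edges(labels, edges, undirected)
}

edge_matrix <- function(x) {
  if (is.null(x) || length(x) == 0) return(matrix(character(), 0, 2))
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.character))
  x <- as.matrix(x)
  if (ncol(x) != 2) {
    abort("edge lists must have two columns.", class = "accperc_invalid_graph")
  }
  x
}

build_from_edges <- function(labels, edges, undirected) {
  n <- length(labels)
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  place <- function(e, sym) {
    if (nrow(e) == 0) return(invisible())
    iu <- match(e[, 1], labels)
    iv <- match(e[, 2], labels)
    if (anyNA(iu) || anyNA(iv)) {
      abort("edge endpoint not present in `labels`.",
            class = "accperc_invalid_graph")
    }
    for (k in seq_along(iu)) {
      adj[iu[k], iv[k]] <<- 1L
      if (sym) adj[iv[k], iu[k]] <<- 1L
    }
  }
  place(edges, sym = FALSE)
  place(undirected, sym = TRUE)
  allele_graph(adj, labels = labels)
}

#' @rdname read_allele_graph
#' @param graph an [allele_graph()] to serialize.
#' @export
write_allele_graph <- function(graph, path,
                               format = c("auto", "json", "tsv")) {
  assert_graph(graph)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  idx <- which(graph$adjacency == 1L, arr.ind = TRUE)
  from <- graph$labels[idx[, 1]]
  to <- graph$labels[idx[, 2]]
  # report mutual arrow pairs once, as undirected edges
  key <- paste(from, to)
  rkey <- paste(to, from)
  mutual <- key %in% rkey
  und_sel <- mutual & from < to
  dir_sel <- !mutual
  if (format == "json") {
    obj <- list(
      labels = graph$labels,
      edges = unname(Map(c, from[dir_sel], to[dir_sel])),
      undirected_edges = unname(Map(c, from[und_sel], to[und_sel]))
    )
    jsonlite::write_json(obj, path, auto_unbox = FALSE)
  } else {
    df <- rbind(
      data.frame(from = from[dir_sel], to = to[dir_sel], mode = ""),
      data.frame(from = from[und_sel], to = to[und_sel], mode = "both")
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read and write divergence matrices as CSV
#'
#' The CSV carries allele labels in the header row and first column and the
#' divergence weight `p[v, w]` in each cell.
#'
#' @param path file path.
#' @param graph an [allele_graph()] the matrix must match.
#' @return `read_divergence_csv()` returns a numeric matrix in the graph's
#'   vertex order.
#' @export
read_divergence_csv <- function(path, graph) {
  assert_graph(graph)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  align_allele_matrix(m, graph, "p")
}

#' @rdname read_divergence_csv
#' @param p divergence matrix to write.
#' @export
write_divergence_csv <- function(p, path) {
  utils::write.csv(as.data.frame(p), path, row.names = TRUE)
  invisible(path)
}
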