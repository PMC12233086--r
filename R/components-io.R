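# Component payload loaders: tables (csv/txt/parquet/xlsx), graphs
# (edge lists, adjacency matrices, GraphML/GML/GEXF/CYJS, embedded
# HTML), interactive plot JSON, and raw text blocks.

DELIM_CANDIDATES <- c(",", "\t", ";")

# majority vote over the first 10 lines: each line votes for the
# candidate delimiter it contains most of; the most-voted wins
probe_delimiter <- function(lines) {
  lines <- utils::head(lines[nzchar(lines)], 10L)
  if (!length(lines)) return(",")
  votes <- vapply(lines, function(ln) {
    counts <- vapply(DELIM_CANDIDATES, function(d)
      lengths(regmatches(ln, gregexpr(d, ln, fixed = TRUE))), integer(1))
    if (all(counts == 0L)) NA_character_ else DELIM_CANDIDATES[which.max(counts)]
  }, character(1))
  votes <- votes[!is.na(votes)]
  if (!length(votes)) return(",")
  tab <- table(votes)
  names(tab)[which.max(tab)]
}

# plain data.frame, numeric columns as double, everything non-numeric as
# character: the same logical table then compares identical() across
# csv/txt/parquet/xlsx loaders
normalize_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.factor(col)) col <- as.character(col)
    if (is.numeric(col) || is.logical(col)) col <- as.numeric(col)
    else col <- as.character(col)
    df[[j]] <- col
  }
  rownames(df) <- NULL
  df
}

#' Load a table component
#'
#' Reads a table from CSV, TXT, Parquet or XLSX into a plain data.frame.
#' For delimited text the first row is the header and the delimiter, when
#' not given, is probed by majority vote over the first 10 lines (comma,
#' tab, semicolon). XLSX files are read from their first sheet only
#' (a warning is raised if the workbook has more).
#'
#' @param path file path.
#' @param file_format one of `csv`, `txt`, `parquet`, `xlsx`; inferred
#'   from the extension when `NULL`.
#' @param delimiter single-character field separator (csv/txt only); a
#'   configured delimiter always wins over the probe.
#' @return A data.frame (numeric columns as double, others as character).
#' @export
load_table <- function(path, file_format = NULL, delimiter = NULL) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  file_format <- check_enum(
    file_format %||% tolower(tools::file_ext(path)), TABLE_FORMATS,
    "file_format")
  if (file_format %in% c("csv", "txt")) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !any(nzchar(lines)))
      stop("empty table file: ", path, call. = FALSE)
    sep <- delimiter %||% probe_delimiter(lines)
    nf <- utils::count.fields(path, sep = sep, quote = "\"",
                              blank.lines.skip = TRUE)
    nf <- nf[!is.na(nf)]
    if (length(unique(nf)) > 1L) {
      bad <- which(nf != nf[1])[1]
      stop("ragged table in ", path, ": line ", bad + 0L,
           " has ", nf[bad], " fields, expected ", nf[1], call. = FALSE)
    }
    df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            comment.char = "")
  } else if (file_format == "parquet") {
    df <- as.data.frame(arrow::read_parquet(path))
  } else { # xlsx
    sheets <- readxl::excel_sheets(path)
    if (length(sheets) > 1L)
      warning("workbook has ", length(sheets),
              " sheets; reading only the first ('", sheets[1], "')",
              call. = FALSE)
    df <- as.data.frame(readxl::read_excel(path, sheet = 1L))
  }
  if (!nrow(df) && !ncol(df)) stop("empty table file: ", path, call. = FALSE)
  normalize_table(df)
}

## ---- graphs ---------------------------------------------------------------

#' Construct a graph value
#'
#' Lightweight container used by all network loaders: a character node
#' vector, an edge table with `from`/`to` (plus optional `weight` and
#' extra attribute columns), and a directedness flag. Edge endpoints
#' must be members of `nodes`; undirected graphs hold each edge once.
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame with at least `from` and `to` columns.
#' @param directed logical.
#' @return An object of class `rf_graph`.
#' @export
rf_graph <- function(nodes, edges, directed = FALSE) {
  nodes <- as.character(nodes)
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  stray <- setdiff(c(edges$from, edges$to), nodes)
  if (length(stray))
    stop("edge endpoints not in node set: ", paste(stray, collapse = ", "),
         call. = FALSE)
  if (!directed && nrow(edges)) {
    # normalize: store undirected edges with sorted endpoints, once
    lo <- pmin(edges$from, edges$to)
    hi <- pmax(edges$from, edges$to)
    edges$from <- lo
    edges$to <- hi
    edges <- edges[!duplicated(paste(lo, hi, sep = "\r")), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
            class = "rf_graph")
}

#' @export
print.rf_graph <- function(x, ...) {
  cat("<rf_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      if (x$directed) " directed" else " undirected", " edges\n", sep = "")
  invisible(x)
}

edge_list_to_graph <- function(df, path) {
  if (ncol(df) < 2L)
    stop("edge list in ", path, " needs at least 2 columns (source, target)",
         call. = FALSE)
  edges <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
                      stringsAsFactors = FALSE)
  if (ncol(df) >= 3L && is.numeric(df[[3]])) {
    edges$weight <- as.numeric(df[[3]])
    rest <- df[-(1:3)]
  } else {
    rest <- df[-(1:2)]
  }
  # extra columns ride along as edge attributes
  for (nm in names(rest)) edges[[nm]] <- rest[[nm]]
  rf_graph(sort(unique(c(edges$from, edges$to))), edges, directed = FALSE)
}

adjacency_to_graph <- function(path, delimiter) {
  lines <- readLines(path, warn = FALSE)
  sep <- delimiter %||% probe_delimiter(lines)
  m <- tryCatch(
    as.matrix(utils::read.table(path, sep = sep, header = TRUE,
                                row.names = 1, check.names = FALSE,
                                comment.char = "")),
    error = function(e) stop("cannot read adjacency matrix in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(m) != ncol(m))
    stop("adjacency matrix in ", path, " is not square (",
         nrow(m), "x", ncol(m), ")", call. = FALSE)
  if (!is.numeric(m))
    stop("adjacency matrix in ", path, " has non-numeric cells", call. = FALSE)
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  diag(m) <- 0  # self-loops ignored
  symmetric <- isTRUE(all.equal(m, t(m), check.attributes = FALSE))
  if (symmetric) {
    idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  } else {
    idx <- which(m != 0, arr.ind = TRUE)
  }
  edges <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                      weight = m[idx], stringsAsFactors = FALSE)
  rf_graph(labels, edges, directed = !symmetric)
}

igraph_to_graph <- function(g) {
  nodes <- if ("name" %in% igraph::vertex_attr_names(g))
    as.character(igraph::V(g)$name) else as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                      stringsAsFactors = FALSE)
  if ("weight" %in% igraph::edge_attr_names(g))
    edges$weight <- as.numeric(igraph::E(g)$weight)
  rf_graph(nodes, edges, directed = igraph::is_directed(g))
}

gexf_to_graph <- function(path) {
  doc <- xml2::read_xml(path)
  ns_strip <- xml2::xml_ns_strip(doc)
  gnode <- xml2::xml_find_first(doc, ".//graph")
  directed <- identical(xml2::xml_attr(gnode, "defaultedgetype"), "directed")
  nodes <- xml2::xml_find_all(doc, ".//node")
  ids <- xml2::xml_attr(nodes, "id")
  enodes <- xml2::xml_find_all(doc, ".//edge")
  edges <- data.frame(from = xml2::xml_attr(enodes, "source"),
                      to = xml2::xml_attr(enodes, "target"),
                      stringsAsFactors = FALSE)
  w <- xml2::xml_attr(enodes, "weight")
  if (length(w) && any(!is.na(w))) edges$weight <- as.numeric(w)
  rf_graph(ids, edges, directed = directed)
}

cyjs_to_graph <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  els <- doc$elements %||% doc
  get_data <- function(x, key) as.character(x$data[[key]])
  ids <- vapply(els$nodes %||% list(), get_data, character(1), key = "id")
  en <- els$edges %||% list()
  edges <- data.frame(from = vapply(en, get_data, character(1), key = "source"),
                      to = vapply(en, get_data, character(1), key = "target"),
                      stringsAsFactors = FALSE)
  w <- lapply(en, function(e) e$data$weight)
  if (length(w) && any(!vapply(w, is.null, logical(1))))
    edges$weight <- vapply(w, function(x) if (is.null(x)) NA_real_
                           else as.numeric(x), numeric(1))
  rf_graph(ids, edges, directed = FALSE)
}

#' Load a network component
#'
#' Reads a graph from an edge list or adjacency matrix (CSV/TXT), or
#' from GraphML, GML, GEXF or CYJS (Cytoscape JSON). HTML network views
#' (`html_embed`) are passed through unparsed for embedding. Adjacency
#' matrices must be square and labeled; the diagonal is ignored,
#' symmetric matrices yield an undirected graph (each pair emitted
#' once), asymmetric ones a directed graph. An edge list's third
#' numeric column is taken as the edge weight; further columns become
#' edge attributes.
#'
#' @param path file path.
#' @param net_format one of `edge_list`, `adjacency`, `graphml`, `gml`,
#'   `gexf`, `cyjs`, `html_embed`; inferred from the extension/name when
#'   `NULL`.
#' @param delimiter optional single-character separator for
#'   edge-list/adjacency text files.
#' @return An [rf_graph()], or for `html_embed` a list of class
#'   `rf_graph_html` with the raw `$html` text.
#' @export
load_graph <- function(path, net_format = NULL, delimiter = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  if (is.null(net_format)) {
    cls <- classify_file(path)
    net_format <- if (cls$kind == "network") cls$subtype
      else stop("cannot infer network format for ", path, call. = FALSE)
  }
  net_format <- check_enum(net_format, NET_FORMATS, "net_format")
  switch(net_format,
    edge_list = {
      df <- load_table(path, file_format = tolower(tools::file_ext(path)),
                       delimiter = delimiter)
      edge_list_to_graph(df, path)
    },
    adjacency = adjacency_to_graph(path, delimiter),
    graphml = igraph_to_graph(igraph::read_graph(path, format = "graphml")),
    gml = igraph_to_graph(igraph::read_graph(path, format = "gml")),
    gexf = gexf_to_graph(path),
    cyjs = cyjs_to_graph(path),
    html_embed = structure(list(html = load_text_component(path, "html")),
                           class = "rf_graph_html"))
}

#' Write a graph as an edge-list CSV
#'
#' Inverse of the edge-list loader (modulo node isolation: isolated
#' nodes are not representable in an edge list).
#'
#' @param graph an [rf_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "rf_graph"))
  utils::write.csv(graph$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- plots & text ----------------------------------------------------------

#' Detect the dialect of an interactive plot JSON payload
#'
#' A top-level `$schema` string containing "vega" marks a Vega/Vega-Lite
#' spec (`vega_family`); top-level `data` plus `layout` keys mark a
#' Plotly-style figure object (`figure_object`); anything else is
#' `unknown` and is rendered as a pretty-printed code block with a
#' warning rather than aborting the report.
#'
#' @param json_payload parsed JSON value (nested list).
#' @return One of `"vega_family"`, `"figure_object"`, `"unknown"`.
#' @export
detect_plot_dialect <- function(json_payload) {
  if (!is.list(json_payload)) return("unknown")
  schema <- json_payload[["$schema"]]
  if (is.character(schema) && length(schema) == 1L &&
      grepl("vega", schema, ignore.case = TRUE))
    return("vega_family")
  if (all(c("data", "layout") %in% names(json_payload)))
    return("figure_object")
  "unknown"
}

#' Load a Markdown or HTML component as text
#'
#' Returns the file content unmodified (trusted local inputs; no
#' sanitization). Non-UTF-8 bytes are replacement-decoded with a
#' warning; an empty file yields an empty payload with a warning.
#'
#' @param path file path.
#' @param kind `"markdown"` or `"html"` (informational only).
#' @return A single string.
#' @export
load_text_component <- function(path, kind = c("markdown", "html")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("cannot read ", kind, " file: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  if (!all(validUTF8(txt))) {
    warning(kind, " file ", path,
            " is not valid UTF-8; invalid bytes replaced", call. = FALSE)
    txt <- iconv(txt, from = "UTF-8", to = "UTF-8", sub = "�")
  }
  if (!nzchar(txt))
    warning("empty ", kind, " file: ", path, call. = FALSE)
  Encoding(txt) <- "UTF-8"
  txt
}
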