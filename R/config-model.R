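# Report data model: report -> sections -> subsections -> components,
# plus YAML (de)serialization and validation.

#' Component kinds understood by the report model
#'
#' Seven renderable unit types: static/interactive plots, tables
#' (dataframes), networks, Markdown text, raw HTML, and the two
#' web-app-only panels (API call, chatbot).
#' @export
COMPONENT_KINDS <- c("plot", "dataframe", "network", "markdown", "html",
                     "apicall", "chatbot")

#' Supported report output formats
#'
#' `webapp` is a multi-page Streamlit-style source bundle; the rest are
#' compiled from a single Quarto Markdown document. The static set
#' (`pdf`, `docx`, `odt`, `pptx`) cannot host interactive widgets.
#' @export
REPORT_TYPES <- c("webapp", "html", "pdf", "docx", "odt", "revealjs",
                  "pptx", "notebook")

#' @rdname REPORT_TYPES
#' @export
STATIC_REPORT_TYPES <- c("pdf", "docx", "odt", "pptx")

PLOT_FORMATS   <- c("interactive_json", "static_image")
JSON_DIALECTS  <- c("figure_object", "vega_family", "unknown")
TABLE_FORMATS  <- c("csv", "txt", "parquet", "xlsx")
NET_FORMATS    <- c("edge_list", "adjacency", "graphml", "gml", "gexf",
                    "cyjs", "html_embed")
API_METHODS    <- c("GET", "POST", "PUT")
CHATBOT_MODES  <- c("standard", "streaming")

# canonical attribute keys per kind, in serialization order
kind_attr_keys <- list(
  plot      = c("plot_format", "json_dialect"),
  dataframe = c("file_format", "delimiter"),
  network   = c("net_format", "delimiter"),
  markdown  = character(0),
  html      = character(0),
  apicall   = c("api_url", "method", "request_body", "headers"),
  chatbot   = c("api_url", "model", "mode", "headers")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

chr1 <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
  x
}

check_enum <- function(x, allowed, what) {
  if (is.null(x)) return(NULL)
  x <- chr1(x, what)
  if (!x %in% allowed)
    stop(what, " must be one of: ", paste(allowed, collapse = ", "),
         " (got '", x, "')", call. = FALSE)
  x
}

#' Normalize a report type name
#'
#' Case-insensitive; accepts the aliases `streamlit` (-> `webapp`) and
#' `jupyter` (-> `notebook`).
#'
#' @param x report type name.
#' @return One of [REPORT_TYPES].
#' @export
report_type <- function(x) {
  x <- tolower(chr1(x, "report type"))
  x <- switch(x, streamlit = "webapp", jupyter = "notebook", x)
  if (!x %in% REPORT_TYPES)
    stop("unknown report type '", x, "'; legal values: ",
         paste(REPORT_TYPES, collapse = ", "), call. = FALSE)
  x
}

#' Create a report component
#'
#' One renderable unit of a report. All kinds except `apicall` and
#' `chatbot` point at a file on disk; the kind-specific attributes are
#' passed through `...` (e.g. `delimiter` for a csv table, `api_url` and
#' `method` for an API-call panel).
#'
#' @param title component title (non-empty).
#' @param kind one of [COMPONENT_KINDS].
#' @param file_path path to the payload file, interpreted relative to
#'   the config/scan root; `NULL` for `apicall`/`chatbot`.
#' @param caption optional caption text.
#' @param ... kind-specific attributes (see Details).
#' @param extras named list of unknown config keys carried through
#'   serialization.
#'
#' @details Attribute keys by kind: plot — `plot_format`
#'   (`interactive_json`/`static_image`), `json_dialect`
#'   (`figure_object`/`vega_family`/`unknown`); dataframe —
#'   `file_format` (`csv`/`txt`/`parquet`/`xlsx`), `delimiter`;
#'   network — `net_format` (`edge_list`/`adjacency`/`graphml`/`gml`/
#'   `gexf`/`cyjs`/`html_embed`), `delimiter`; apicall — `api_url`,
#'   `method`, `request_body`, `headers`; chatbot — `api_url`, `model`,
#'   `mode`, `headers`.
#' @return An object of class `report_component`.
#' @export
report_component <- function(title, kind, file_path = NULL, caption = NULL,
                             ..., extras = list()) {
  title <- chr1(title, "component title")
  if (!nzchar(title)) stop("component title must be non-empty", call. = FALSE)
  kind <- check_enum(kind, COMPONENT_KINDS, "component kind")
  dots <- list(...)
  keys <- kind_attr_keys[[kind]]
  bad <- setdiff(names(dots), keys)
  if (length(bad))
    stop("attributes not valid for kind '", kind, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  attrs <- stats::setNames(vector("list", length(keys)), keys)
  for (k in intersect(names(dots), keys)) attrs[[k]] <- dots[[k]]

  if (kind %in% c("apicall", "chatbot")) {
    if (!is.null(file_path))
      stop(kind, " components take no file_path", call. = FALSE)
    attrs$api_url <- chr1(attrs$api_url, "api_url")
    if (is.null(attrs$api_url))
      stop(kind, " components require api_url", call. = FALSE)
  } else {
    file_path <- chr1(file_path, "file_path")
    if (is.null(file_path))
      stop("components of kind '", kind, "' require file_path", call. = FALSE)
  }

  if (kind == "plot") {
    if (is.null(attrs$plot_format)) {
      ext <- tolower(tools::file_ext(file_path))
      attrs$plot_format <- if (ext == "json") "interactive_json" else "static_image"
    }
    attrs$plot_format <- check_enum(attrs$plot_format, PLOT_FORMATS, "plot_format")
    if (identical(attrs$plot_format, "static_image")) {
      attrs$json_dialect <- NULL
    } else {
      attrs$json_dialect <- check_enum(attrs$json_dialect %||% "unknown",
                                       JSON_DIALECTS, "json_dialect")
    }
  }
  if (kind == "dataframe") {
    if (is.null(attrs$file_format))
      attrs$file_format <- tolower(tools::file_ext(file_path))
    attrs$file_format <- check_enum(attrs$file_format, TABLE_FORMATS, "file_format")
    if (!attrs$file_format %in% c("csv", "txt")) attrs$delimiter <- NULL
  }
  if (kind == "network")
    attrs$net_format <- check_enum(attrs$net_format, NET_FORMATS, "net_format")
  if (!is.null(attrs$delimiter)) {
    attrs$delimiter <- chr1(attrs$delimiter, "delimiter")
    if (nchar(attrs$delimiter) != 1L)
      stop("delimiter must be a single character", call. = FALSE)
  }
  if (kind == "apicall")
    attrs$method <- check_enum(attrs$method %||% "GET", API_METHODS, "method")
  if (kind == "chatbot") {
    attrs$model <- chr1(attrs$model, "model") %||% "default"
    attrs$mode  <- check_enum(attrs$mode %||% "standard", CHATBOT_MODES, "mode")
  }
  if (!is.null(attrs$headers)) {
    if (!is.list(attrs$headers) || is.null(names(attrs$headers)))
      stop("headers must be a named list", call. = FALSE)
    attrs$headers <- lapply(attrs$headers, as.character)
  }

  # canonical shape: every legal key present (NULL when unset), fixed order
  attrs <- stats::setNames(lapply(keys, function(k) attrs[[k]]), keys)
  structure(
    list(title = title, caption = chr1(caption, "caption"), kind = kind,
         file_path = file_path, attrs = attrs,
         extras = if (length(extras)) extras else list()),
    class = "report_component")
}

#' Create a report subsection
#'
#' @param title subsection title (non-empty).
#' @param description optional description.
#' @param components ordered list of [report_component()] objects.
#' @return An object of class `report_subsection`.
#' @export
report_subsection <- function(title, description = NULL, components = list()) {
  title <- chr1(title, "subsection title")
  if (!nzchar(title)) stop("subsection title must be non-empty", call. = FALSE)
  stopifnot(all(vapply(components, inherits, logical(1), "report_component")))
  structure(
    list(title = title, description = chr1(description, "description"),
         components = unname(components)),
    class = "report_subsection")
}

#' Create a report section
#'
#' Sections hold subsections and may additionally hold components
#' directly (without a subsection level).
#'
#' @param title section title (non-empty).
#' @param description optional description.
#' @param subsections ordered list of [report_subsection()] objects.
#' @param components ordered list of direct [report_component()]s.
#' @return An object of class `report_section`.
#' @export
report_section <- function(title, description = NULL, subsections = list(),
                           components = list()) {
  title <- chr1(title, "section title")
  if (!nzchar(title)) stop("section title must be non-empty", call. = FALSE)
  stopifnot(all(vapply(subsections, inherits, logical(1), "report_subsection")),
            all(vapply(components, inherits, logical(1), "report_component")))
  structure(
    list(title = title, description = chr1(description, "description"),
         subsections = unname(subsections), components = unname(components)),
    class = "report_section")
}

#' Create a report specification
#'
#' The full report model: metadata plus the ordered section hierarchy.
#'
#' @param title report title (non-empty).
#' @param description optional description shown under the title.
#' @param graphical_abstract,logo optional image paths.
#' @param sections ordered list of [report_section()] objects.
#' @return An object of class `report_spec`.
#' @export
report_spec <- function(title, description = NULL, graphical_abstract = NULL,
                        logo = NULL, sections = list()) {
  title <- chr1(title, "report title")
  if (is.null(title) || !nzchar(title))
    stop("report title must be non-empty", call. = FALSE)
  stopifnot(all(vapply(sections, inherits, logical(1), "report_section")))
  structure(
    list(title = title, description = chr1(description, "description"),
         graphical_abstract = chr1(graphical_abstract, "graphical_abstract"),
         logo = chr1(logo, "logo"), sections = unname(sections)),
    class = "report_spec")
}

#' Structural equality of report specs
#'
#' Compares two specs field by field, including order of sections,
#' subsections and components; bookkeeping attributes (`base_dir`,
#' scan logs) are ignored.
#'
#' @param a,b `report_spec` objects.
#' @return `TRUE` or `FALSE`.
#' @export
spec_equal <- function(a, b) {
  strip <- function(x) { attributes(x) <- attributes(x)["names"]; x }
  identical(strip(unclass(a)), strip(unclass(b)))
}

#' @export
print.report_spec <- function(x, ...) {
  n_sub <- sum(vapply(x$sections, function(s) length(s$subsections), integer(1)))
  n_cmp <- n_components(x)
  cat("<report_spec> ", x$title, "\n",
      "  sections: ", length(x$sections),
      "  subsections: ", n_sub, "  components: ", n_cmp, "\n", sep = "")
  for (s in x$sections) {
    cat("  - ", s$title,
        if (length(s$components)) paste0(" [", length(s$components), " direct]"),
        "\n", sep = "")
    for (ss in s$subsections)
      cat("      * ", ss$title, " (", length(ss$components), ")\n", sep = "")
  }
  invisible(x)
}

# all components of a spec, flattened in render order
spec_components <- function(spec) {
  out <- list()
  for (s in spec$sections) {
    out <- c(out, s$components)
    for (ss in s$subsections) out <- c(out, ss$components)
  }
  out
}

n_components <- function(spec) length(spec_components(spec))

## ---- serialization -------------------------------------------------------

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

component_to_list <- function(cp) {
  out <- c(list(title = cp$title, component_type = cp$kind,
                file_path = cp$file_path, caption = cp$caption),
           drop_null(cp$attrs), cp$extras)
  drop_null(out)
}

subsection_to_list <- function(ss) {
  drop_null(list(title = ss$title, description = ss$description,
                 components = lapply(ss$components, component_to_list)))
}

section_to_list <- function(s) {
  out <- list(title = s$title, description = s$description)
  if (length(s$components))
    out$components <- lapply(s$components, component_to_list)
  if (length(s$subsections))
    out$subsections <- lapply(s$subsections, subsection_to_list)
  drop_null(out)
}

#' Serialize a report spec to YAML
#'
#' Deterministic output: report metadata first, then sections in order;
#' unset optional fields are omitted entirely. Two serializations of the
#' same spec are byte-identical, and
#' `parse_config(serialize_config(spec))` reproduces an equal spec.
#'
#' @param spec a [report_spec()].
#' @return A single string of YAML text.
#' @export
serialize_config <- function(spec) {
  stopifnot(inherits(spec, "report_spec"))
  x <- list(
    report = drop_null(list(
      title = spec$title, description = spec$description,
      graphical_abstract = spec$graphical_abstract, logo = spec$logo)),
    sections = lapply(spec$sections, section_to_list))
  yaml::as.yaml(x, indent = 2, line.sep = "\n")
}

#' Write a report spec to a YAML config file
#'
#' @param spec a [report_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(spec, path) {
  con <- try(file(path, open = "wb"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write config file '", path, "'", call. = FALSE)
  on.exit(close(con))
  writeBin(charToRaw(serialize_config(spec)), con)
  invisible(path)
}

## ---- parsing -------------------------------------------------------------

KNOWN_COMPONENT_KEYS <- c("title", "component_type", "file_path", "caption",
                          unique(unlist(kind_attr_keys)))

parse_component_node <- function(node, where, warn) {
  if (!is.list(node))
    stop("schema error at ", where, ": component must be a mapping",
         call. = FALSE)
  kind <- node$component_type
  if (is.null(kind)) {
    # infer from the file extension when unstated
    if (!is.null(node$file_path)) {
      cls <- classify_file(node$file_path)
      if (cls$kind != "unclassified") kind <- cls$kind
    }
    if (is.null(kind))
      stop("schema error at ", where,
           ".component_type: cannot resolve component kind", call. = FALSE)
  }
  kind <- check_enum(kind, COMPONENT_KINDS, paste0(where, ".component_type"))
  title <- node$title
  if (is.null(title) && !is.null(node$file_path))
    title <- parse_name(strip_ext(basename(node$file_path)))$title
  if (is.null(title))
    stop("schema error at ", where, ".title: component title missing",
         call. = FALSE)
  unknown <- setdiff(names(node), KNOWN_COMPONENT_KEYS)
  if (length(unknown))
    warn(paste0("unknown key(s) at ", where, ": ",
                paste(unknown, collapse = ", "), " (preserved as extras)"))
  attrs <- node[intersect(names(node), kind_attr_keys[[kind]])]
  do.call(report_component,
          c(list(title = as.character(title), kind = kind,
                 file_path = if (!is.null(node$file_path))
                   as.character(node$file_path),
                 caption = if (!is.null(node$caption))
                   as.character(node$caption),
                 extras = node[unknown]),
            attrs))
}

parse_subsection_node <- function(node, where, warn) {
  if (is.null(node$title))
    stop("schema error at ", where, ".title: subsection title missing",
         call. = FALSE)
  unknown <- setdiff(names(node), c("title", "description", "components"))
  if (length(unknown))
    warn(paste0("unknown key(s) at ", where, ": ",
                paste(unknown, collapse = ", "), " (ignored)"))
  comps <- node$components %||% list()
  report_subsection(
    title = as.character(node$title),
    description = if (!is.null(node$description)) as.character(node$description),
    components = lapply(seq_along(comps), function(j)
      parse_component_node(comps[[j]],
                           sprintf("%s.components[%d]", where, j - 1L), warn)))
}

parse_section_node <- function(node, where, warn) {
  if (is.null(node$title))
    stop("schema error at ", where, ".title: section title missing",
         call. = FALSE)
  unknown <- setdiff(names(node),
                     c("title", "description", "components", "subsections"))
  if (length(unknown))
    warn(paste0("unknown key(s) at ", where, ": ",
                paste(unknown, collapse = ", "), " (ignored)"))
  subs <- node$subsections %||% list()
  comps <- node$components %||% list()
  report_section(
    title = as.character(node$title),
    description = if (!is.null(node$description)) as.character(node$description),
    subsections = lapply(seq_along(subs), function(j)
      parse_subsection_node(subs[[j]],
                            sprintf("%s.subsections[%d]", where, j - 1L), warn)),
    components = lapply(seq_along(comps), function(j)
      parse_component_node(comps[[j]],
                           sprintf("%s.components[%d]", where, j - 1L), warn)))
}

#' Parse a YAML report configuration
#'
#' Reads the YAML report schema (a `report` metadata block plus a
#' `sections` list) into a [report_spec()], filling defaults for unset
#' optional fields. Unknown component keys are preserved in an extras
#' map and reported with a warning; unset optionals may be given as
#' `null` or omitted (equivalent).
#'
#' @param yaml_text YAML text (single string or character vector of lines).
#' @param base_dir directory against which relative `file_path`s are
#'   resolved later (stored as an attribute, not part of the spec value).
#' @return A [report_spec()].
#' @export
parse_config <- function(yaml_text, base_dir = ".") {
  txt <- paste(yaml_text, collapse = "\n")
  doc <- tryCatch(yaml::yaml.load(txt),
                  error = function(e)
                    stop("malformed YAML: ", conditionMessage(e), call. = FALSE))
  if (!is.list(doc)) stop("schema error at <root>: mapping expected", call. = FALSE)
  warnings <- character(0)
  warn <- function(msg) {
    warnings <<- c(warnings, msg)
    warning(msg, call. = FALSE)
  }
  rep <- doc$report
  if (is.null(rep) || is.null(rep$title))
    stop("schema error at report.title: report title missing", call. = FALSE)
  secs <- doc$sections %||% list()
  spec <- report_spec(
    title = as.character(rep$title),
    description = if (!is.null(rep$description)) as.character(rep$description),
    graphical_abstract = if (!is.null(rep$graphical_abstract))
      as.character(rep$graphical_abstract),
    logo = if (!is.null(rep$logo)) as.character(rep$logo),
    sections = lapply(seq_along(secs), function(i)
      parse_section_node(secs[[i]], sprintf("sections[%d]", i - 1L), warn)))
  attr(spec, "base_dir") <- base_dir
  attr(spec, "parse_warnings") <- warnings
  spec
}

#' Read a report configuration file
#'
#' Convenience wrapper around [parse_config()]; relative component paths
#' are interpreted relative to the config file's directory.
#'
#' @param path path to a YAML config file.
#' @return A [report_spec()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  parse_config(readChar(path, file.info(path)$size, useBytes = TRUE),
               base_dir = dirname(path))
}

## ---- validation ----------------------------------------------------------

issue_df <- function(severity = character(0), path = character(0),
                     message = character(0)) {
  data.frame(severity = severity, path = path, message = message,
             stringsAsFactors = FALSE)
}

resolve_path <- function(p, base_dir) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
}

#' Validate a report spec for a given output format
#'
#' Returns all problems found as data, not exceptions: `error` issues
#' block rendering (missing component files), `warning` issues do not
#' (web-app-only components under a non-webapp format, which renderers
#' skip; sections or subsections with no content, which render as
#' placeholders).
#'
#' @param spec a [report_spec()].
#' @param type target report type (see [REPORT_TYPES]); any alias
#'   accepted by [report_type()].
#' @param base_dir base directory for relative paths; defaults to the
#'   one recorded when the spec was parsed or scanned.
#' @return A data.frame with columns `severity`, `path`, `message`;
#'   zero rows iff the spec is renderable with no caveats.
#' @export
validate_spec <- function(spec, type, base_dir = NULL) {
  stopifnot(inherits(spec, "report_spec"))
  type <- report_type(type)
  base_dir <- base_dir %||% attr(spec, "base_dir") %||% "."
  iss <- issue_df()
  add <- function(severity, path, message)
    iss <<- rbind(iss, issue_df(severity, path, message))
  for (i in seq_along(spec$sections)) {
    s <- spec$sections[[i]]
    spath <- sprintf("sections[%d]", i - 1L)
    if (!length(s$subsections) && !length(s$components))
      add("warning", spath,
          sprintf("section '%s' has no subsections or components", s$title))
    check_component <- function(cp, cpath) {
      if (cp$kind %in% c("apicall", "chatbot")) {
        if (type != "webapp")
          add("warning", cpath,
              sprintf("%s component '%s' is supported only in webapp reports; it will be skipped for %s",
                      cp$kind, cp$title, type))
      } else {
        fp <- resolve_path(cp$file_path, base_dir)
        if (!file.exists(fp))
          add("error", paste0(cpath, ".file_path"),
              sprintf("component file not found: %s", fp))
      }
    }
    for (j in seq_along(s$components))
      check_component(s$components[[j]],
                      sprintf("%s.components[%d]", spath, j - 1L))
    for (k in seq_along(s$subsections)) {
      ss <- s$subsections[[k]]
      sspath <- sprintf("%s.subsections[%d]", spath, k - 1L)
      if (!length(ss$components))
        add("warning", sspath,
            sprintf("subsection '%s' has no components", ss$title))
      for (j in seq_along(ss$components))
        check_component(ss$components[[j]],
                        sprintf("%s.components[%d]", sspath, j - 1L))
    }
  }
  iss
}
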