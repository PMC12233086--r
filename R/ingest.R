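# Directory ingestion: infer a report_spec from a results directory.
# Folder levels map to sections/subsections, files to typed components,
# names to titles and explicit ordering.

#' Default basename tokens marking a CSV/TXT/HTML file as a network
#' @export
NETWORK_HINT_TOKENS <- c("edge_list", "edgelist", "adjacency", "network",
                         "graph")

strip_ext <- function(x) sub("\\.[^.]*$", "", x)

#' Parse a folder or file name into a title and an explicit order
#'
#' A trailing `_<integer>` token is stripped and used as the item's
#' order; a leading `<integer>_` prefix is accepted too (the suffix wins
#' if both are present). Remaining underscores/hyphens become spaces and
#' each word is capitalized. The title is never empty: degenerate names
#' fall back to the raw input.
#'
#' @param raw a folder name, or a file name without its extension.
#' @return A list with `raw`, `order` (integer or `NULL`), `title`.
#' @export
#' @examples
#' parse_name("exploratory_data_analysis_1")
#' parse_name("network-analysis")
parse_name <- function(raw) {
  raw <- chr1(raw, "name")
  stem <- raw
  ord <- NULL
  m <- regmatches(stem, regexec("^(.*)_([0-9]+)$", stem))[[1]]
  if (length(m) == 3L && nzchar(m[2])) {
    ord <- as.integer(m[3])
    stem <- m[2]
  } else {
    m <- regmatches(stem, regexec("^([0-9]+)_(.*)$", stem))[[1]]
    if (length(m) == 3L && nzchar(m[3])) {
      ord <- as.integer(m[2])
      stem <- m[3]
    }
  }
  words <- strsplit(gsub("[_-]+", " ", stem), " ", fixed = TRUE)[[1]]
  words <- words[nzchar(words)]
  title <- paste(vapply(words, function(w) {
    substr(w, 1, 1) <- toupper(substr(w, 1, 1))
    w
  }, character(1)), collapse = " ")
  if (!nzchar(title)) {
    title <- raw
    ord <- NULL
  }
  list(raw = raw, order = ord, title = title)
}

#' Sort key for parsed names
#'
#' Items with an explicit order sort first, ascending numerically
#' (so `_2` precedes `_10`); items without one follow, ordered
#' case-insensitively by title. Equal orders tie-break alphabetically,
#' making the result independent of filesystem enumeration order.
#'
#' @param parse a [parse_name()] result.
#' @return A list usable as a compound sort key.
#' @export
order_key <- function(parse) {
  list(unordered = is.null(parse$order),
       order = if (is.null(parse$order)) Inf else as.numeric(parse$order),
       alpha = tolower(parse$title))
}

# order() permutation for a list of parse_name() results
name_order <- function(parses) {
  keys <- lapply(parses, order_key)
  order(vapply(keys, `[[`, logical(1), "unordered"),
        vapply(keys, `[[`, numeric(1), "order"),
        vapply(keys, `[[`, character(1), "alpha"))
}

#' Sort raw names by the report ordering rules
#'
#' @param raws character vector of names (extensions already stripped).
#' @return `raws`, reordered.
#' @export
sort_names <- function(raws) {
  raws[name_order(lapply(raws, parse_name))]
}

has_hint_token <- function(name, tokens) {
  any(vapply(tokens, function(tk) grepl(tk, name, ignore.case = TRUE),
             logical(1)))
}

#' Classify a file into a component kind
#'
#' Component types are inferred from file extensions and names:
#' image files are static plots, JSON files interactive plots,
#' csv/txt/parquet/xlsx are tables, md is Markdown, graphml/gml/gexf/
#' cyjs are networks, and html is an HTML block — except that a
#' csv/txt/html basename containing a network hint token (see
#' `hint_tokens`) is classified as a network (edge list, adjacency
#' matrix, or embedded HTML view). Unknown extensions are not errors:
#' they return kind `unclassified` with `confident = FALSE` and are
#' skipped by the scanner with a warning.
#'
#' @param path file path (need not exist; only the name is inspected).
#' @param hint_tokens tokens marking tabular/HTML files as networks.
#' @return A list with `kind`, `subtype`, `confident`.
#' @export
#' @examples
#' classify_file("heatmap.png")
#' classify_file("taxa_edge_list.csv")
classify_file <- function(path, hint_tokens = NETWORK_HINT_TOKENS) {
  base <- basename(path)
  ext <- tolower(tools::file_ext(base))
  stem <- strip_ext(base)
  res <- function(kind, subtype, confident = TRUE)
    list(kind = kind, subtype = subtype, confident = confident)
  if (ext %in% c("png", "svg", "jpg", "jpeg"))
    return(res("plot", "static_image"))
  if (ext == "json") return(res("plot", "interactive_json"))
  if (ext %in% c("csv", "txt")) {
    if (has_hint_token(stem, hint_tokens)) {
      sub <- if (grepl("adjacency", stem, ignore.case = TRUE))
        "adjacency" else "edge_list"
      return(res("network", sub))
    }
    return(res("dataframe", ext))
  }
  if (ext %in% c("parquet", "xlsx")) return(res("dataframe", ext))
  if (ext == "md") return(res("markdown", "md"))
  if (ext %in% c("graphml", "gml", "gexf", "cyjs"))
    return(res("network", ext))
  if (ext == "html") {
    if (has_hint_token(stem, hint_tokens))
      return(res("network", "html_embed"))
    return(res("html", "html"))
  }
  res("unclassified", ext, confident = FALSE)
}

## ---- scanning ------------------------------------------------------------

# immediate child directories / files, hidden entries separated out
list_children <- function(dir) {
  entries <- list.files(dir, all.files = TRUE, no.. = TRUE, full.names = TRUE)
  hidden <- grepl("^\\.", basename(entries))
  list(dirs = entries[!hidden & dir.exists(entries)],
       files = entries[!hidden & !dir.exists(entries)],
       hidden = entries[hidden])
}

# build one component from a classified file; rel is the path stored in
# the spec (relative to the scan root)
file_to_component <- function(path, rel, cls) {
  pn <- parse_name(strip_ext(basename(path)))
  args <- list(title = pn$title, kind = cls$kind, file_path = rel)
  if (cls$kind == "plot") {
    args$plot_format <- cls$subtype
    if (cls$subtype == "interactive_json") {
      payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                          error = function(e) NULL)
      args$json_dialect <- if (is.null(payload)) "unknown"
                           else detect_plot_dialect(payload)
    }
  } else if (cls$kind == "dataframe") {
    args$file_format <- cls$subtype
  } else if (cls$kind == "network") {
    args$net_format <- cls$subtype
  }
  do.call(report_component, args)
}

#' Infer a report spec from a results directory
#'
#' First-level folders become sections and second-level folders become
#' subsections; classified files inside them become components. Files
#' directly inside a section folder become that section's direct
#' components; files at the scan root are ignored with a warning.
#' Content nested deeper than two folder levels is flattened into its
#' depth-2 subsection. Hidden (dot-prefixed) entries, zero-byte files
#' and unclassifiable files are skipped with warnings. Sections,
#' subsections and components are ordered by their numerical name
#' suffixes (then alphabetically), so the result is independent of
#' filesystem enumeration order.
#'
#' @param root directory to scan.
#' @param report_title report title; defaults to the root folder name,
#'   prettified by [parse_name()].
#' @param hint_tokens see [classify_file()].
#' @return A [report_spec()]; the scan log (skip warnings) is attached
#'   as attribute `scan_log`, the normalized root as `base_dir`.
#' @export
scan_directory <- function(root, report_title = NULL,
                           hint_tokens = NETWORK_HINT_TOKENS) {
  if (!dir.exists(root))
    stop("input directory not found or unreadable: ", root, call. = FALSE)
  root_norm <- normalizePath(root)
  log <- character(0)
  note <- function(msg) log <<- c(log, msg)
  seen_dirs <- new.env(parent = emptyenv())
  assign(root_norm, TRUE, envir = seen_dirs)

  visit_dir <- function(dir) {
    # symlink-cycle guard: each resolved directory is entered once
    real <- normalizePath(dir)
    if (!identical(dir, real) || grepl("/\\.\\./", dir)) {
      if (exists(real, envir = seen_dirs)) {
        note(paste0("skipping already-visited directory (symlink cycle?): ", dir))
        return(FALSE)
      }
    }
    assign(real, TRUE, envir = seen_dirs)
    TRUE
  }

  usable_files <- function(files) {
    keep <- character(0)
    for (f in files) {
      sz <- file.size(f)
      if (is.na(sz)) {
        note(paste0("skipping unreadable entry: ", f))
      } else if (sz == 0) {
        note(paste0("skipping zero-byte file: ", f))
      } else keep <- c(keep, f)
    }
    keep
  }

  rel_to_root <- function(path) {
    p <- normalizePath(path)
    sub("^/", "", substring(p, nchar(root_norm) + 1L))
  }

  components_from_files <- function(files) {
    comps <- list()
    parses <- list()
    for (f in files) {
      cls <- classify_file(f, hint_tokens)
      if (!cls$confident) {
        note(paste0("skipping unclassifiable file: ", f))
        next
      }
      comps[[length(comps) + 1L]] <- file_to_component(f, rel_to_root(f), cls)
      parses[[length(parses) + 1L]] <- parse_name(strip_ext(basename(f)))
    }
    if (length(comps)) comps[name_order(parses)] else comps
  }

  # all files under a subsection dir, flattened (depth >2 attaches here)
  collect_subsection_files <- function(dir) {
    ch <- list_children(dir)
    for (h in ch$hidden) note(paste0("skipping hidden entry: ", h))
    files <- usable_files(ch$files)
    for (d in ch$dirs) {
      if (!visit_dir(d)) next
      note(paste0("flattening deeply nested folder into its subsection: ", d))
      files <- c(files, collect_subsection_files(d))
    }
    files
  }

  top <- list_children(root)
  for (h in top$hidden) note(paste0("skipping hidden entry: ", h))
  for (f in top$files)
    note(paste0("ignoring file at report root (sections are folders): ", f))

  sections <- list()
  sec_parses <- list()
  for (sdir in top$dirs) {
    if (!visit_dir(sdir)) next
    ch <- list_children(sdir)
    for (h in ch$hidden) note(paste0("skipping hidden entry: ", h))
    direct <- components_from_files(usable_files(ch$files))
    subsections <- list()
    sub_parses <- list()
    for (ssdir in ch$dirs) {
      if (!visit_dir(ssdir)) next
      pn <- parse_name(basename(ssdir))
      subsections[[length(subsections) + 1L]] <- report_subsection(
        title = pn$title,
        components = components_from_files(collect_subsection_files(ssdir)))
      sub_parses[[length(sub_parses) + 1L]] <- pn
    }
    if (length(subsections)) subsections <- subsections[name_order(sub_parses)]
    pn <- parse_name(basename(sdir))
    sections[[length(sections) + 1L]] <- report_section(
      title = pn$title, subsections = subsections, components = direct)
    sec_parses[[length(sec_parses) + 1L]] <- pn
  }
  if (length(sections)) sections <- sections[name_order(sec_parses)]

  total <- sum(vapply(sections, function(s)
    length(s$components) +
      sum(vapply(s$subsections, function(ss) length(ss$components),
                 integer(1))), integer(1)))
  if (total == 0L)
    stop("nothing to report: no classifiable files under ", root,
         call. = FALSE)

  title <- report_title %||% parse_name(basename(root_norm))$title
  spec <- report_spec(title = title, sections = sections)
  attr(spec, "base_dir") <- root_norm
  attr(spec, "scan_log") <- log
  spec
}

#' Generate a YAML config file from a results directory
#'
#' Runs [scan_directory()] and writes the serialized spec to `out`.
#' The generated file is meant to be edited afterwards (descriptions,
#' captions, reordering) and fed back through [read_config()]. Running
#' twice on an unchanged tree produces byte-identical files.
#'
#' @inheritParams scan_directory
#' @param out output YAML path.
#' @return The scanned [report_spec()], invisibly.
#' @export
directory_to_config <- function(root, out, report_title = NULL,
                                hint_tokens = NETWORK_HINT_TOKENS) {
  spec <- scan_directory(root, report_title = report_title,
                         hint_tokens = hint_tokens)
  write_config(spec, out)
  invisible(spec)
}
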