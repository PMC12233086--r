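# Report compilation: a validated report_spec becomes either a
# multi-page Streamlit-style web-app source bundle or a single Quarto
# Markdown document per output format, with interactive plots and
# networks converted to static images where the format requires it.

slugify <- function(x) {
  s <- gsub("[^a-z0-9]+", "_", tolower(x))
  s <- gsub("^_+|_+$", "", s)
  if (!nzchar(s)) "item" else s
}

qmd_format_of <- list(html = "html", pdf = "pdf", docx = "docx", odt = "odt",
                      revealjs = "revealjs", pptx = "pptx",
                      notebook = "ipynb")

report_bundle <- function(report_type, root, files, render_command,
                          warnings = character(0)) {
  structure(list(report_type = report_type, root = root, files = files,
                 render_command = render_command, warnings = warnings),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", x$report_type, " in ", x$root, "\n", sep = "")
  print(table(x$files$role))
  cat("render with: ", x$render_command, "\n", sep = "")
  if (length(x$warnings))
    cat(length(x$warnings), "warning(s); see $warnings\n")
  invisible(x)
}

stop_on_errors <- function(spec, type, base_dir) {
  iss <- validate_spec(spec, type, base_dir = base_dir)
  errs <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("config has ", nrow(errs), " blocking error(s):\n",
         paste0("  - ", errs$path, ": ", errs$message, collapse = "\n"),
         call. = FALSE)
  iss
}

write_text_file <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  invisible(path)
}

## ---- static export --------------------------------------------------------

placeholder_png <- function(file, msg, width, height) {
  ragg::agg_png(file, width = width, height = height, background = "white")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::box(col = "grey70")
  graphics::text(0.5, 0.5, msg, cex = 1.2, col = "grey30")
  invisible(file)
}

num_or_seq <- function(x, n) {
  v <- suppressWarnings(as.numeric(unlist(x)))
  if (length(v) && !anyNA(v)) v else seq_len(n)
}

# minimal renderer for Plotly-style figure objects: scatter/line/bar
# traces with x/y arrays
render_figure_object <- function(payload, file, width, height) {
  traces <- payload$data
  if (!length(traces)) return(placeholder_png(file, "empty figure", width, height))
  title <- payload$layout$title
  if (is.list(title)) title <- title$text
  types <- vapply(traces, function(tr) tr$type %||% "scatter", character(1))
  ragg::agg_png(file, width = width, height = height, background = "white")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4.5, 4.5, if (is.null(title)) 1 else 3, 1))
  if (all(types == "bar")) {
    tr <- traces[[1]]
    y <- suppressWarnings(as.numeric(unlist(tr$y)))
    graphics::barplot(y, names.arg = as.character(unlist(tr$x)),
                      col = "#4878A8", border = NA,
                      main = title %||% "", las = 2)
  } else {
    xs <- lapply(traces, function(tr) num_or_seq(tr$x, length(unlist(tr$y))))
    ys <- lapply(traces, function(tr) suppressWarnings(as.numeric(unlist(tr$y))))
    graphics::plot(range(unlist(xs), finite = TRUE),
                   range(unlist(ys), finite = TRUE),
                   type = "n", xlab = "x", ylab = "y", main = title %||% "")
    for (i in seq_along(traces)) {
      mode <- traces[[i]]$mode %||%
        if (types[i] == "scatter") "markers" else "lines"
      if (grepl("lines", mode))
        graphics::lines(xs[[i]], ys[[i]], col = i + 1L, lwd = 2)
      if (grepl("markers", mode) || !grepl("lines", mode))
        graphics::points(xs[[i]], ys[[i]], col = i + 1L, pch = 19)
    }
  }
  invisible(file)
}

# minimal renderer for Vega-Lite specs: inline data values with a
# point/line/bar mark and x/y field encodings
render_vega_spec <- function(payload, file, width, height) {
  values <- payload$data$values
  enc <- payload$encoding
  mark <- payload$mark
  if (is.list(mark)) mark <- mark$type
  if (!length(values) || is.null(enc$x$field) || is.null(enc$y$field))
    return(placeholder_png(file, "vega spec (not renderable offline)",
                           width, height))
  xf <- enc$x$field
  yf <- enc$y$field
  xs <- lapply(values, `[[`, xf)
  ys <- suppressWarnings(as.numeric(vapply(values, function(v)
    as.character(v[[yf]] %||% NA), character(1))))
  title <- payload$title
  if (is.list(title)) title <- title$text
  ragg::agg_png(file, width = width, height = height, background = "white")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4.5, 4.5, if (is.null(title)) 1 else 3, 1))
  if (identical(mark, "bar")) {
    graphics::barplot(ys, names.arg = as.character(unlist(xs)),
                      col = "#4878A8", border = NA, main = title %||% "",
                      las = 2)
  } else {
    xn <- suppressWarnings(as.numeric(as.character(unlist(xs))))
    if (anyNA(xn)) xn <- seq_along(ys)
    graphics::plot(xn, ys, type = if (identical(mark, "line")) "l" else "p",
                   pch = 19, col = "#4878A8", lwd = 2,
                   xlab = xf, ylab = yf, main = title %||% "")
  }
  invisible(file)
}

render_network_png <- function(graph, file, width, height, layout_seed) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to"), drop = FALSE],
    directed = graph$directed,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
  set.seed(layout_seed)
  lay <- igraph::layout_with_fr(g)
  ragg::agg_png(file, width = width, height = height, background = "white")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  igraph::plot.igraph(g, layout = lay, vertex.color = "#4878A8",
                      vertex.label.color = "black", vertex.size = 18,
                      vertex.label.cex = 0.9, edge.color = "grey50")
  invisible(file)
}

#' Convert an interactive plot or network component to a static image
#'
#' Interactive chart JSON (Plotly-style figure objects and Vega-Lite
#' specs) and network files are rendered to a PNG so that static report
#' formats (PDF, DOCX, ODT, PPTX) can embed them. Static-image plot
#' components are returned unchanged (identity). Network drawings use a
#' fixed layout seed, so repeated runs are byte-stable. Unrenderable
#' payloads produce an explicit placeholder image, never a silent blank.
#'
#' @param component a plot or network [report_component()].
#' @param outdir directory for the exported image.
#' @param base_dir base for resolving the component's `file_path`.
#' @param name output file name (without extension); defaults to the
#'   slugified component title.
#' @param width,height image size in pixels.
#' @param layout_seed seed for the network layout.
#' @return A list of class `staticized_asset` with the `component` and
#'   the `image_path` of the exported (or passed-through) image.
#' @export
staticize <- function(component, outdir, base_dir = ".", name = NULL,
                      width = 1000, height = 600, layout_seed = 42L) {
  stopifnot(inherits(component, "report_component"))
  if (!component$kind %in% c("plot", "network"))
    stop("staticize applies to plot and network components, not ",
         component$kind, call. = FALSE)
  if (component$kind == "plot" &&
      identical(component$attrs$plot_format, "static_image")) {
    return(structure(list(component = component,
                          image_path = resolve_path(component$file_path,
                                                    base_dir)),
                     class = "staticized_asset"))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  src <- resolve_path(component$file_path, base_dir)
  file <- file.path(outdir, paste0(name %||% slugify(component$title), ".png"))
  if (component$kind == "plot") {
    payload <- tryCatch(jsonlite::fromJSON(src, simplifyVector = FALSE),
                        error = function(e) NULL)
    dialect <- if (is.null(payload)) "unknown" else detect_plot_dialect(payload)
    switch(dialect,
      figure_object = render_figure_object(payload, file, width, height),
      vega_family = render_vega_spec(payload, file, width, height),
      placeholder_png(file, paste0("unrenderable plot spec: ",
                                   basename(src)), width, height))
  } else {
    g <- load_graph(src, net_format = component$attrs$net_format,
                    delimiter = component$attrs$delimiter)
    if (inherits(g, "rf_graph_html")) {
      placeholder_png(file, paste0("embedded HTML network view: ",
                                   basename(src)), width, height)
    } else {
      render_network_png(g, file, width, height, layout_seed)
    }
  }
  structure(list(component = component, image_path = file),
            class = "staticized_asset")
}

## ---- qmd document ---------------------------------------------------------

md_escape_cell <- function(x) gsub("\\|", "\\\\|", as.character(x))

md_table <- function(df, max_rows = 200L) {
  note <- NULL
  if (nrow(df) > max_rows) {
    note <- sprintf("*(showing first %d of %d rows)*", max_rows, nrow(df))
    df <- utils::head(df, max_rows)
  }
  header <- paste0("| ", paste(md_escape_cell(names(df)), collapse = " | "),
                   " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r)
    paste0("| ", paste(md_escape_cell(r), collapse = " | "), " |"))
  c(header, rule, rows, note)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# interactive table widget for HTML output (DataTables over a plain
# HTML table; sorting/filtering/pagination come from the library)
html_table_widget <- function(df, id) {
  head_cells <- paste0("<th>", html_escape(names(df)), "</th>", collapse = "")
  body <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", html_escape(r), "</td>", collapse = ""),
           "</tr>"))
  c("```{=html}",
    "<link rel=\"stylesheet\" href=\"https://cdn.datatables.net/1.13.8/css/jquery.dataTables.min.css\">",
    "<script src=\"https://code.jquery.com/jquery-3.7.1.min.js\"></script>",
    "<script src=\"https://cdn.datatables.net/1.13.8/js/jquery.dataTables.min.js\"></script>",
    sprintf("<table id=\"%s\" class=\"display compact\">", id),
    paste0("<thead><tr>", head_cells, "</tr></thead>"),
    "<tbody>", body, "</tbody></table>",
    sprintf("<script>$(function(){ $(\"#%s\").DataTable(); });</script>", id),
    "```")
}

embed_interactive_plot <- function(payload_text, dialect, id) {
  if (dialect == "figure_object") {
    c("```{=html}",
      sprintf("<div id=\"%s\" style=\"width:100%%;min-height:420px;\"></div>", id),
      "<script src=\"https://cdn.plot.ly/plotly-2.32.0.min.js\"></script>",
      "<script>",
      sprintf("var spec_%s = %s;", id, payload_text),
      sprintf("Plotly.newPlot(\"%s\", spec_%s.data, spec_%s.layout || {});",
              id, id, id),
      "</script>",
      "```")
  } else if (dialect == "vega_family") {
    c("```{=html}",
      sprintf("<div id=\"%s\"></div>", id),
      "<script src=\"https://cdn.jsdelivr.net/npm/vega@5\"></script>",
      "<script src=\"https://cdn.jsdelivr.net/npm/vega-lite@5\"></script>",
      "<script src=\"https://cdn.jsdelivr.net/npm/vega-embed@6\"></script>",
      sprintf("<script>vegaEmbed(\"#%s\", %s);</script>", id, payload_text),
      "```")
  } else {
    c("```json", payload_text, "```")
  }
}

component_marker <- function(cp)
  paste0("<!-- component: ", cp$file_path %||% slugify(cp$title), " -->")

#' Compile a report spec into a Quarto Markdown document bundle
#'
#' Emits one `report.qmd` with format-specific front matter: sections as
#' level-1 headings, subsections as level-2 headings (each subsection
#' starts a new slide in presentation formats), and every component
#' embedded in order. For static formats (PDF, DOCX, ODT, PPTX) and
#' notebook output, interactive plots and networks are first converted
#' to PNG via [staticize()]; HTML output embeds them as live widgets and
#' renders tables interactively. API-call and chatbot components are
#' web-app-only and are skipped with a warning. Empty sections and
#' subsections render a visible placeholder. Regenerating from the same
#' spec yields an identical file tree.
#'
#' @param spec a [report_spec()] with no validation errors.
#' @param type any non-webapp member of [REPORT_TYPES].
#' @param outdir output directory (created if needed).
#' @param base_dir base for relative component paths; defaults to the
#'   spec's recorded one.
#' @return A `report_bundle` (document source + static image assets).
#' @export
generate_document <- function(spec, type, outdir, base_dir = NULL) {
  type <- report_type(type)
  if (type == "webapp")
    stop("use generate_webapp() for webapp reports", call. = FALSE)
  base_dir <- base_dir %||% attr(spec, "base_dir") %||% "."
  stop_on_errors(spec, type, base_dir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  staticize_all <- type %in% c(STATIC_REPORT_TYPES, "notebook")
  interactive_html <- type %in% c("html", "revealjs")
  warnings <- character(0)
  assets <- character(0)
  comp_idx <- 0L

  render_component <- function(cp) {
    comp_idx <<- comp_idx + 1L
    id <- sprintf("rf_c%03d", comp_idx)
    head <- c(component_marker(cp), "", paste0("### ", cp$title), "")
    tail <- if (!is.null(cp$caption)) c("", paste0("*", cp$caption, "*"), "")
            else ""
    src <- if (!is.null(cp$file_path)) resolve_path(cp$file_path, base_dir)
    body <- switch(cp$kind,
      plot = {
        if (identical(cp$attrs$plot_format, "static_image")) {
          sprintf("![%s](%s)", cp$caption %||% cp$title, src)
        } else if (staticize_all) {
          asset <- staticize(cp, file.path(outdir, "static"),
                             base_dir = base_dir, name = id)
          assets <<- c(assets, asset$image_path)
          sprintf("![%s](static/%s)", cp$caption %||% cp$title,
                  basename(asset$image_path))
        } else if (interactive_html) {
          payload_text <- paste(readLines(src, warn = FALSE), collapse = "\n")
          payload <- tryCatch(jsonlite::fromJSON(src, simplifyVector = FALSE),
                              error = function(e) NULL)
          dialect <- if (is.null(payload)) "unknown"
                     else detect_plot_dialect(payload)
          if (dialect == "unknown")
            warnings <<- c(warnings, paste0("unknown plot JSON dialect in ",
                                            cp$file_path,
                                            "; shown as a code block"))
          embed_interactive_plot(payload_text, dialect, id)
        }
      },
      network = {
        if (interactive_html &&
            identical(cp$attrs$net_format, "html_embed")) {
          c("```{=html}", load_text_component(src, "html"), "```")
        } else {
          asset <- staticize(cp, file.path(outdir, "static"),
                             base_dir = base_dir, name = id)
          assets <<- c(assets, asset$image_path)
          sprintf("![%s](static/%s)", cp$caption %||% cp$title,
                  basename(asset$image_path))
        }
      },
      dataframe = {
        df <- load_table(src, file_format = cp$attrs$file_format,
                         delimiter = cp$attrs$delimiter)
        if (type == "html") html_table_widget(df, id) else md_table(df)
      },
      markdown = strsplit(load_text_component(src, "markdown"), "\n")[[1]],
      html = {
        if (interactive_html) {
          c("```{=html}", load_text_component(src, "html"), "```")
        } else {
          # raw HTML is honored only in HTML-based outputs; static
          # formats reference the file instead
          sprintf("[%s](%s)", cp$title, src)
        }
      },
      apicall = ,
      chatbot = {
        warnings <<- c(warnings,
                       sprintf("%s component '%s' is webapp-only; skipped in %s output",
                               cp$kind, cp$title, type))
        comp_idx <<- comp_idx - 1L
        return(NULL)
      })
    c(head, body, tail)
  }

  lines <- c("---",
             paste0("title: \"", gsub("\"", "\\\\\"", spec$title), "\""),
             paste0("format: ", qmd_format_of[[type]]),
             "---", "")
  if (!is.null(spec$description)) lines <- c(lines, spec$description, "")
  if (!is.null(spec$graphical_abstract))
    lines <- c(lines, sprintf("![](%s)",
                              resolve_path(spec$graphical_abstract, base_dir)),
               "")
  for (s in spec$sections) {
    lines <- c(lines, paste0("# ", s$title), "")
    if (!is.null(s$description)) lines <- c(lines, s$description, "")
    if (!length(s$subsections) && !length(s$components))
      lines <- c(lines, "*(this section has no components yet)*", "")
    for (cp in s$components) {
      out <- render_component(cp)
      if (!is.null(out)) lines <- c(lines, out, "")
    }
    for (ss in s$subsections) {
      lines <- c(lines, paste0("## ", ss$title), "")
      if (!is.null(ss$description)) lines <- c(lines, ss$description, "")
      if (!length(ss$components))
        lines <- c(lines, "*(this subsection has no components yet)*", "")
      for (cp in ss$components) {
        out <- render_component(cp)
        if (!is.null(out)) lines <- c(lines, out, "")
      }
    }
  }
  doc <- file.path(outdir, "report.qmd")
  write_text_file(lines, doc)
  files <- data.frame(
    path = c("report.qmd",
             if (length(assets)) file.path("static", basename(assets))),
    role = c("document_source", rep("static_image", length(assets))),
    stringsAsFactors = FALSE)
  report_bundle(type, outdir, files,
                render_command = paste("quarto render",
                                       file.path(outdir, "report.qmd")),
                warnings = warnings)
}

## ---- webapp ---------------------------------------------------------------

py_str <- function(x) {
  # python string literal (escaped double-quoted)
  paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)), "\"")
}

py_dict <- function(named) {
  if (is.null(named) || !length(named)) return("{}")
  paste0("{", paste(vapply(names(named), function(k)
    paste0(py_str(k), ": ", py_str(as.character(named[[k]]))),
    character(1)), collapse = ", "), "}")
}

webapp_component_code <- function(cp, idx, base_dir) {
  src <- if (!is.null(cp$file_path)) resolve_path(cp$file_path, base_dir)
  key <- sprintf("c%03d", idx)
  head <- c(paste0("# component: ", cp$file_path %||% slugify(cp$title)),
            paste0("st.subheader(", py_str(cp$title), ")"))
  if (!is.null(cp$caption))
    head <- c(head, paste0("st.caption(", py_str(cp$caption), ")"))
  body <- switch(cp$kind,
    plot = {
      if (identical(cp$attrs$plot_format, "static_image")) {
        paste0("st.image(", py_str(src), ", use_container_width=True)")
      } else if (identical(cp$attrs$json_dialect, "vega_family")) {
        c(paste0("with open(", py_str(src), ", encoding=\"utf-8\") as fh:"),
          "    spec = json.load(fh)",
          "st.vega_lite_chart(spec, use_container_width=True)")
      } else {
        c(paste0("with open(", py_str(src), ", encoding=\"utf-8\") as fh:"),
          "    fig = pio.from_json(fh.read())",
          "st.plotly_chart(fig, use_container_width=True)")
      }
    },
    dataframe = {
      fmt <- cp$attrs$file_format
      reader <- switch(fmt,
        parquet = paste0("df = pd.read_parquet(", py_str(src), ")"),
        xlsx = paste0("df = pd.read_excel(", py_str(src), ")"),
        if (!is.null(cp$attrs$delimiter))
          paste0("df = pd.read_csv(", py_str(src), ", sep=",
                 py_str(cp$attrs$delimiter), ")")
        else
          paste0("df = pd.read_csv(", py_str(src),
                 ", sep=None, engine=\"python\")"))
      c(reader,
        "st.dataframe(df, use_container_width=True, hide_index=True)")
    },
    network = {
      fmt <- cp$attrs$net_format
      loader <- switch(fmt,
        graphml = paste0("G = nx.read_graphml(", py_str(src), ")"),
        gml = paste0("G = nx.read_gml(", py_str(src), ")"),
        gexf = paste0("G = nx.read_gexf(", py_str(src), ")"),
        cyjs = c(paste0("with open(", py_str(src),
                        ", encoding=\"utf-8\") as fh:"),
                 "    G = nx.cytoscape_graph(json.load(fh))"),
        adjacency = c(paste0("adj = pd.read_csv(", py_str(src),
                             ", index_col=0, sep=None, engine=\"python\")"),
                      "G = nx.from_pandas_adjacency(adj)"),
        edge_list = c(paste0("el = pd.read_csv(", py_str(src),
                             ", sep=None, engine=\"python\")"),
                      "G = nx.from_pandas_edgelist(el, source=el.columns[0], target=el.columns[1])"),
        html_embed = NULL)
      if (identical(fmt, "html_embed")) {
        c(paste0("with open(", py_str(src), ", encoding=\"utf-8\") as fh:"),
          "    st.components.v1.html(fh.read(), height=520, scrolling=True)")
      } else {
        c(loader,
          "net = Network(height=\"500px\", width=\"100%\", notebook=False, cdn_resources=\"remote\")",
          "net.from_nx(G)",
          "st.components.v1.html(net.generate_html(), height=520)")
      }
    },
    markdown = c(paste0("with open(", py_str(src),
                        ", encoding=\"utf-8\") as fh:"),
                 "    st.markdown(fh.read())"),
    html = c(paste0("with open(", py_str(src), ", encoding=\"utf-8\") as fh:"),
             "    st.components.v1.html(fh.read(), height=420, scrolling=True)"),
    apicall = {
      a <- cp$attrs
      body_arg <- if (!is.null(a$request_body))
        paste0(", json=json.loads(", py_str(a$request_body), ")") else ""
      c(paste0("if st.button(\"Send request\", key=", py_str(key), "):"),
        paste0("    resp = requests.request(", py_str(a$method), ", ",
               py_str(a$api_url), ", headers=", py_dict(a$headers),
               body_arg, ", timeout=30)"),
        "    try:",
        "        st.json(resp.json())",
        "    except ValueError:",
        "        st.text(resp.text)")
    },
    chatbot = {
      a <- cp$attrs
      c(paste0("prompt = st.chat_input(\"Message the assistant\", key=",
               py_str(key), ")"),
        "if prompt:",
        "    st.chat_message(\"user\").write(prompt)",
        paste0("    payload = {\"model\": ", py_str(a$model),
               ", \"messages\": [{\"role\": \"user\", \"content\": prompt}]",
               if (identical(a$mode, "streaming")) ", \"stream\": True",
               "}"),
        if (identical(a$mode, "streaming")) c(
          paste0("    with requests.post(", py_str(a$api_url),
                 ", json=payload, headers=", py_dict(a$headers),
                 ", stream=True, timeout=120) as resp:"),
          "        chunks = [line.decode(\"utf-8\", \"replace\") for line in resp.iter_lines() if line]",
          "    st.chat_message(\"assistant\").write(\"\".join(chunks))")
        else c(
          paste0("    resp = requests.post(", py_str(a$api_url),
                 ", json=payload, headers=", py_dict(a$headers),
                 ", timeout=120)"),
          "    st.chat_message(\"assistant\").write(resp.json().get(\"content\", resp.text))"))
    })
  c(head, body, "")
}

page_imports <- function(components) {
  kinds <- vapply(components, `[[`, character(1), "kind")
  dialects <- unlist(lapply(components, function(cp) cp$attrs$json_dialect))
  net_fmts <- unlist(lapply(components, function(cp) cp$attrs$net_format))
  plot_fmts <- unlist(lapply(components, function(cp) cp$attrs$plot_format))
  imports <- "import streamlit as st"
  needs_json <- ("plot" %in% kinds && "interactive_json" %in% plot_fmts) ||
    any(net_fmts %in% "cyjs") ||
    any(vapply(components, function(cp)
      cp$kind == "apicall" && !is.null(cp$attrs$request_body), logical(1)))
  if (needs_json) imports <- c("import json", "", imports)
  if (any(kinds == "dataframe") || any(net_fmts %in% c("edge_list", "adjacency")))
    imports <- c(imports, "import pandas as pd")
  if ("interactive_json" %in% plot_fmts &&
      !all(dialects %in% "vega_family"))
    imports <- c(imports, "import plotly.io as pio")
  if (any(kinds %in% c("apicall", "chatbot")))
    imports <- c(imports, "import requests")
  if (any(kinds == "network") && !all(net_fmts %in% "html_embed"))
    imports <- c(imports, "import networkx as nx",
                 "from pyvis.network import Network")
  imports
}

webapp_page <- function(title, description, components, base_dir, idx_offset) {
  lines <- c(page_imports(components), "",
             paste0("st.header(", py_str(title), ")"))
  if (!is.null(description))
    lines <- c(lines, paste0("st.markdown(", py_str(description), ")"))
  lines <- c(lines, "")
  if (!length(components))
    lines <- c(lines,
               "st.info(\"This page has no components yet.\")", "")
  for (i in seq_along(components))
    lines <- c(lines, webapp_component_code(components[[i]], idx_offset + i,
                                            base_dir))
  lines
}

#' Compile a report spec into a multi-page web-app source bundle
#'
#' Emits a Streamlit-style application: one entry script (`app.py`) with
#' the navigation across all pages, one subdirectory per section, and
#' one Python page script per subsection (plus one per section that has
#' direct components). Pages render interactive charts from their JSON
#' specs, tables as sortable/filterable widgets, networks as interactive
#' views, Markdown/HTML blocks, and API-call and chatbot panels. All
#' emitted scripts are syntactically valid Python.
#'
#' @param spec a [report_spec()] with no validation errors.
#' @param outdir output directory (created if needed).
#' @param base_dir base for relative component paths; defaults to the
#'   spec's recorded one.
#' @return A `report_bundle` (entry + page files).
#' @export
generate_webapp <- function(spec, outdir, base_dir = NULL) {
  base_dir <- base_dir %||% attr(spec, "base_dir") %||% "."
  stop_on_errors(spec, "webapp", base_dir)
  base_dir <- normalizePath(base_dir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pages <- character(0)   # relative page paths
  nav_entries <- list()   # section title -> page entries
  comp_idx <- 0L

  for (i in seq_along(spec$sections)) {
    s <- spec$sections[[i]]
    sdir <- sprintf("%02d_%s", i, slugify(s$title))
    dir.create(file.path(outdir, sdir), showWarnings = FALSE)
    entries <- character(0)
    if (length(s$components)) {
      rel <- file.path(sdir, "00_overview.py")
      write_text_file(
        webapp_page(paste0(s$title, " — Overview"), s$description,
                    s$components, base_dir, comp_idx),
        file.path(outdir, rel))
      comp_idx <- comp_idx + length(s$components)
      pages <- c(pages, rel)
      entries <- c(entries, sprintf(
        "st.Page(%s, title=%s, url_path=%s)",
        py_str(rel), py_str("Overview"), py_str(sprintf("s%02d-overview", i))))
    }
    for (j in seq_along(s$subsections)) {
      ss <- s$subsections[[j]]
      rel <- file.path(sdir, sprintf("%02d_%s.py", j, slugify(ss$title)))
      write_text_file(
        webapp_page(ss$title, ss$description, ss$components, base_dir,
                    comp_idx),
        file.path(outdir, rel))
      comp_idx <- comp_idx + length(ss$components)
      pages <- c(pages, rel)
      entries <- c(entries, sprintf(
        "st.Page(%s, title=%s, url_path=%s)",
        py_str(rel), py_str(ss$title),
        py_str(sprintf("s%02d-%02d-%s", i, j, slugify(ss$title)))))
    }
    nav_entries[[s$title]] <- entries
  }

  entry <- c("import streamlit as st", "",
             paste0("st.set_page_config(page_title=", py_str(spec$title),
                    ", layout=\"wide\")"))
  if (!is.null(spec$logo))
    entry <- c(entry, paste0("st.logo(",
                             py_str(resolve_path(spec$logo, base_dir)), ")"))
  entry <- c(entry, "", "pages = {")
  for (sec_title in names(nav_entries)) {
    entry <- c(entry, paste0("    ", py_str(sec_title), ": ["))
    for (e in nav_entries[[sec_title]])
      entry <- c(entry, paste0("        ", e, ","))
    entry <- c(entry, "    ],")
  }
  entry <- c(entry, "}", "",
             paste0("st.sidebar.title(", py_str(spec$title), ")"))
  if (!is.null(spec$description))
    entry <- c(entry, paste0("st.sidebar.markdown(",
                             py_str(spec$description), ")"))
  entry <- c(entry, "", "nav = st.navigation(pages)", "nav.run()")
  write_text_file(entry, file.path(outdir, "app.py"))

  files <- data.frame(path = c("app.py", pages),
                      role = c("entry", rep("page", length(pages))),
                      stringsAsFactors = FALSE)
  report_bundle("webapp", outdir, files,
                render_command = paste("streamlit run",
                                       file.path(outdir, "app.py")))
}

## ---- external rendering ---------------------------------------------------

#' Render a bundle with its external renderer
#'
#' Optional integration step: document bundles are compiled with the
#' Quarto CLI; web-app bundles get a smoke check (the entry script must
#' byte-compile with the local Python). All other functionality works
#' without any external renderer installed.
#'
#' @param bundle a `report_bundle`.
#' @return Character vector of produced artifact paths (for documents)
#'   or the verified entry script path (webapp), invisibly.
#' @export
render_external <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (bundle$report_type == "webapp") {
    py <- Sys.which("python")
    if (!nzchar(py))
      stop("python not found on PATH; install Python (and streamlit) to run the web app",
           call. = FALSE)
    entry <- file.path(bundle$root,
                       bundle$files$path[bundle$files$role == "entry"])
    res <- system2(py, c("-m", "py_compile", shQuote(entry)),
                   stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(res, "status")) && attr(res, "status") != 0)
      stop("web-app entry script failed to compile:\n",
           paste(res, collapse = "\n"), call. = FALSE)
    return(invisible(entry))
  }
  quarto <- Sys.which("quarto")
  if (!nzchar(quarto))
    stop("quarto not found on PATH; install the Quarto CLI to render ",
         bundle$report_type, " reports", call. = FALSE)
  doc <- file.path(bundle$root,
                   bundle$files$path[bundle$files$role == "document_source"])
  before <- list.files(bundle$root, recursive = TRUE)
  res <- system2(quarto, c("render", shQuote(doc)), stdout = TRUE,
                 stderr = TRUE)
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0)
    stop("quarto render failed:\n", paste(res, collapse = "\n"),
         call. = FALSE)
  after <- list.files(bundle$root, recursive = TRUE)
  invisible(file.path(bundle$root, setdiff(after, before)))
}
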