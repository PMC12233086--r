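# helper: a small spec with the two web-app-only panel kinds appended
spec_with_panels <- function(base_manifest) {
  spec <- scan_directory(base_manifest$root)
  panels <- report_section("Live Data", subsections = list(
    report_subsection("Annotations", components = list(
      report_component("Taxon Annotation", "apicall",
                       api_url = "https://api.example.org/annotate",
                       method = "POST", request_body = "{\"taxon\": \"otu1\"}",
                       headers = list(`X-Token` = "abc")),
      report_component("Assistant", "chatbot",
                       api_url = "https://llm.example.org/chat",
                       model = "demo-model", mode = "streaming")))))
  out <- report_spec(spec$title, sections = c(spec$sections, list(panels)))
  attr(out, "base_dir") <- attr(spec, "base_dir")
  out
}

test_that("webapp bundles obey the structure law and parse as Python", {
  m <- get_basic_fixture()
  spec <- scan_directory(m$root)
  out <- file.path(tempdir(), "wa_basic")
  unlink(out, recursive = TRUE)
  bundle <- generate_webapp(spec, out)
  expect_identical(bundle$files$role,
                   c("entry", rep("page", nrow(bundle$files) - 1L)))
  # one subdirectory per section
  expect_identical(length(list.dirs(out, recursive = FALSE)),
                   m$expected$n_sections)
  # one page per subsection plus one per section with direct components
  n_direct_sections <- sum(vapply(spec$sections,
                                  function(s) length(s$components) > 0,
                                  logical(1)))
  expect_identical(sum(bundle$files$role == "page"),
                   m$expected$n_subsections + n_direct_sections)
  for (f in bundle$files$path)
    expect_python_parses(file.path(out, f))
  # every component appears on exactly one page
  markers <- unlist(lapply(
    bundle$files$path[bundle$files$role == "page"],
    function(f) py_component_markers(readLines(file.path(out, f)))))
  expect_identical(sort(markers), sort(m$file_list$relpath))
})

test_that("API-call and chatbot components render as webapp panels", {
  m <- get_basic_fixture()
  spec <- spec_with_panels(m)
  out <- file.path(tempdir(), "wa_panels")
  unlink(out, recursive = TRUE)
  bundle <- generate_webapp(spec, out)
  pages <- bundle$files$path[bundle$files$role == "page"]
  txt <- lapply(pages, function(f) readLines(file.path(out, f)))
  has_api <- vapply(txt, function(x)
    any(grepl("requests.request(\"POST\", \"https://api.example.org/annotate\"",
              x, fixed = TRUE)), logical(1))
  expect_identical(sum(has_api), 1L)  # exactly one page carries the call
  panel_page <- txt[[which(has_api)]]
  expect_true(any(grepl("json.loads(\"{\\\"taxon\\\": \\\"otu1\\\"}\")",
                        panel_page, fixed = TRUE)))
  expect_true(any(grepl("st.chat_input", panel_page, fixed = TRUE)))
  expect_true(any(grepl("stream=True", panel_page, fixed = TRUE)))
  for (f in bundle$files$path) expect_python_parses(file.path(out, f))
})

test_that("document bundles obey the heading and conservation laws", {
  m <- get_basic_fixture()
  spec <- scan_directory(m$root)
  for (type in c("html", "pptx")) {
    out <- file.path(tempdir(), paste0("doc_", type))
    unlink(out, recursive = TRUE)
    bundle <- generate_document(spec, type, out)
    expect_identical(sum(bundle$files$role == "document_source"), 1L)
    qmd <- readLines(file.path(out, "report.qmd"))
    expect_identical(sum(grepl("^# ", qmd)), m$expected$n_sections)
    expect_identical(sum(grepl("^## ", qmd)), m$expected$n_subsections)
    markers <- component_markers(qmd)
    expect_identical(sort(markers), sort(m$file_list$relpath))
  }
})

test_that("static formats embed no interactive payloads and regenerate identically", {
  m <- get_basic_fixture()
  spec <- scan_directory(m$root)
  n_interactive <- sum(m$file_list$subtype == "interactive_json") +
    sum(m$file_list$kind == "network")
  out <- file.path(tempdir(), "doc_pdf_pure")
  unlink(out, recursive = TRUE)
  bundle <- generate_document(spec, "pdf", out)
  qmd <- readLines(file.path(out, "report.qmd"))
  expect_false(any(grepl("\\$schema|Plotly\\.newPlot|vegaEmbed|\\.json\\)", qmd)))
  expect_identical(sum(bundle$files$role == "static_image"), n_interactive)
  for (p in bundle$files$path[bundle$files$role == "static_image"])
    expect_gt(file.size(file.path(out, p)), 0)
  out2 <- file.path(tempdir(), "doc_pdf_pure2")
  unlink(out2, recursive = TRUE)
  generate_document(spec, "pdf", out2)
  expect_true(trees_identical(out, out2))
})

test_that("interactive HTML output embeds live chart specs and table widgets", {
  m <- get_basic_fixture()
  spec <- scan_directory(m$root)
  out <- file.path(tempdir(), "doc_html_live")
  unlink(out, recursive = TRUE)
  generate_document(spec, "html", out)
  qmd <- readLines(file.path(out, "report.qmd"))
  expect_true(any(grepl("Plotly.newPlot", qmd, fixed = TRUE)))
  expect_true(any(grepl("vegaEmbed", qmd, fixed = TRUE)))
  expect_true(any(grepl("DataTable()", qmd, fixed = TRUE)))
  # raw HTML components are embedded, not linked
  expect_true(any(grepl("Methods overview", qmd, fixed = TRUE)))
})

test_that("web-app-only components are skipped with warnings in documents", {
  m <- get_basic_fixture()
  spec <- spec_with_panels(m)
  out <- file.path(tempdir(), "doc_docx_panels")
  unlink(out, recursive = TRUE)
  bundle <- generate_document(spec, "docx", out)
  expect_length(bundle$warnings, 2L)
  expect_true(all(grepl("webapp-only", bundle$warnings)))
  qmd <- readLines(file.path(out, "report.qmd"))
  expect_false(any(grepl("Taxon Annotation|chat", qmd)))
  expect_identical(sort(component_markers(qmd)), sort(m$file_list$relpath))
})

test_that("empty sections render visible placeholders, not nothing", {
  spec <- report_spec("T", sections = list(report_section("Hollow")))
  out <- file.path(tempdir(), "doc_hollow")
  unlink(out, recursive = TRUE)
  generate_document(spec, "html", out, base_dir = tempdir())
  qmd <- readLines(file.path(out, "report.qmd"))
  expect_true(any(grepl("^# Hollow", qmd)))
  expect_true(any(grepl("no components yet", qmd)))
  wa <- file.path(tempdir(), "wa_hollow")
  unlink(wa, recursive = TRUE)
  bundle <- generate_webapp(spec, wa, base_dir = tempdir())
  expect_identical(length(list.dirs(wa, recursive = FALSE)), 1L)
})

test_that("rendering refuses specs with blocking validation errors", {
  spec <- report_spec("T", sections = list(report_section("S",
    components = list(report_component("Gone", "markdown",
                                       file_path = "missing.md")))))
  expect_error(generate_document(spec, "html", tempfile(),
                                 base_dir = tempdir()),
               "blocking error")
  expect_error(generate_webapp(spec, tempfile(), base_dir = tempdir()),
               "blocking error")
})

test_that("staticize passes static images through and exports the rest as PNG", {
  m <- get_basic_fixture()
  spec <- scan_directory(m$root)
  comps <- reportforge:::spec_components(spec)
  `%||%` <- function(a, b) if (is.null(a)) b else a
  kinds <- vapply(comps, `[[`, character(1), "kind")
  fmts <- vapply(comps, function(cp) cp$attrs$plot_format %||% "",
                 character(1))
  static_plot <- comps[[which(kinds == "plot" & fmts == "static_image")[1]]]
  out <- file.path(tempdir(), "staticized")
  a1 <- staticize(static_plot, out, base_dir = m$root)
  expect_identical(normalizePath(a1$image_path),
                   normalizePath(file.path(m$root, static_plot$file_path)))
  vega <- comps[[which(vapply(comps, function(cp)
    identical(cp$attrs$json_dialect, "vega_family"), logical(1)))[1]]]
  a2 <- staticize(vega, out, base_dir = m$root)
  expect_true(file.exists(a2$image_path))
  expect_gt(file.size(a2$image_path), 0)
  expect_identical(unname(png_dims(a2$image_path)), c(1000L, 600L))
  # network drawing is byte-stable under the fixed layout seed
  net <- comps[[which(kinds == "network")[1]]]
  b1 <- staticize(net, file.path(tempdir(), "net1"), base_dir = m$root)
  b2 <- staticize(net, file.path(tempdir(), "net2"), base_dir = m$root)
  expect_identical(read_bytes(b1$image_path), read_bytes(b2$image_path))
  # unknown payloads give an explicit placeholder, never a blank failure
  uf <- tempfile(fileext = ".json")
  writeLines("{\"foo\": 1}", uf)
  odd <- report_component("Odd", "plot", file_path = basename(uf),
                          plot_format = "interactive_json")
  a3 <- staticize(odd, file.path(tempdir(), "odd"), base_dir = dirname(uf))
  expect_true(file.exists(a3$image_path))
  expect_gt(file.size(a3$image_path), 0)
})

test_that("external rendering reports its tooling honestly", {
  m <- get_basic_fixture()
  spec <- scan_directory(m$root)
  wa <- file.path(tempdir(), "wa_ext")
  unlink(wa, recursive = TRUE)
  bundle <- generate_webapp(spec, wa)
  # python is available in the test image: the entry script must compile
  expect_no_error(render_external(bundle))
  doc <- generate_document(spec, "html", file.path(tempdir(), "doc_ext"))
  if (nzchar(Sys.which("quarto"))) {
    arts <- render_external(doc)
    expect_true(any(grepl("\\.html$", arts)))
  } else {
    expect_error(render_external(doc), "quarto")
  }
})
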