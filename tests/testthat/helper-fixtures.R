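# Shared test utilities: memoized fixtures, byte helpers, a python
# syntax checker for emitted web-app pages, and a random-spec generator
# for round-trip property tests.

.fixture_cache <- new.env(parent = emptyenv())

get_basic_fixture <- function(seed = 7L) {
  key <- paste0("basic_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_basic_fixture(
      file.path(tempdir(), paste0("fx_basic_", seed)), seed)
  .fixture_cache[[key]]
}

get_emp_fixture <- function(seed = 7L) {
  key <- paste0("emp_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_emp_style_fixture(
      file.path(tempdir(), paste0("fx_emp_", seed)), seed)
  .fixture_cache[[key]]
}

read_bytes <- function(path) readBin(path, "raw", n = file.size(path))

trees_identical <- function(a, b) {
  fa <- sort(list.files(a, recursive = TRUE, all.files = TRUE, no.. = TRUE))
  fb <- sort(list.files(b, recursive = TRUE, all.files = TRUE, no.. = TRUE))
  if (!identical(fa, fb)) return(FALSE)
  all(vapply(fa, function(f)
    identical(read_bytes(file.path(a, f)), read_bytes(file.path(b, f))),
    logical(1)))
}

expect_python_parses <- function(path) {
  out <- suppressWarnings(system2(
    "python", c("-c", shQuote("import ast, sys; ast.parse(open(sys.argv[1]).read())"),
                shQuote(path)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect(is.null(status) || status == 0,
         sprintf("emitted script %s is not valid Python:\n%s",
                 path, paste(out, collapse = "\n")))
}

# PNG pixel dimensions straight from the IHDR chunk
png_dims <- function(path) {
  bytes <- readBin(path, "raw", n = 24)
  dim <- readBin(bytes[17:24], "integer", n = 2, size = 4, endian = "big")
  c(width = dim[1], height = dim[2])
}

component_markers <- function(lines)
  sub("^<!-- component: (.*) -->$", "\\1",
      grep("^<!-- component: ", lines, value = TRUE))

py_component_markers <- function(lines)
  sub("^# component: ", "", grep("^# component: ", lines, value = TRUE))

# random small specs for serialization round-trip properties;
# file paths need not exist (parse/serialize never touch disk)
rand_title <- function() {
  pool <- c("Alpha", "Beta", "Gamma", "Delta", "Omega", "Taxa", "Counts",
            "Network", "Summary", "Overview", "Diversity", "Samples")
  paste(sample(pool, sample(1:3, 1)), collapse = " ")
}

rand_component <- function(i) {
  kind <- sample(COMPONENT_KINDS, 1)
  cap <- if (stats::runif(1) < 0.3) "a caption"
  switch(kind,
    plot = report_component(rand_title(), "plot",
      file_path = sprintf("files/p%d.%s", i, sample(c("png", "json"), 1)),
      caption = cap),
    dataframe = {
      fmt <- sample(TABLE_FORMATS <- c("csv", "txt", "parquet", "xlsx"), 1)
      report_component(rand_title(), "dataframe",
        file_path = sprintf("files/t%d.%s", i, fmt), caption = cap,
        delimiter = if (fmt %in% c("csv", "txt") && stats::runif(1) < 0.5) ";")
    },
    network = report_component(rand_title(), "network",
      file_path = sprintf("files/n%d.graphml", i), net_format = "graphml",
      caption = cap),
    markdown = report_component(rand_title(), "markdown",
      file_path = sprintf("files/m%d.md", i), caption = cap),
    html = report_component(rand_title(), "html",
      file_path = sprintf("files/h%d.html", i), caption = cap),
    apicall = report_component(rand_title(), "apicall",
      api_url = "https://api.example.org/v1",
      method = sample(c("GET", "POST", "PUT"), 1),
      request_body = if (stats::runif(1) < 0.5) "{\"query\": 1}",
      headers = if (stats::runif(1) < 0.5) list(Authorization = "Bearer x")),
    chatbot = report_component(rand_title(), "chatbot",
      api_url = "https://llm.example.org/chat", model = "model-1",
      mode = sample(c("standard", "streaming"), 1)))
}

rand_spec <- function() {
  k <- 0L
  mk_comp <- function() {
    k <<- k + 1L
    rand_component(k)
  }
  sections <- lapply(seq_len(sample(1:3, 1)), function(i) {
    subs <- lapply(seq_len(sample(0:2, 1)), function(j)
      report_subsection(rand_title(),
        description = if (stats::runif(1) < 0.4) "sub description",
        components = lapply(seq_len(sample(1:3, 1)),
                            function(x) mk_comp())))
    report_section(rand_title(),
      description = if (stats::runif(1) < 0.4) "section description",
      subsections = subs,
      components = lapply(seq_len(sample(0:2, 1)), function(x) mk_comp()))
  })
  report_spec(rand_title(),
              description = if (stats::runif(1) < 0.5) "report description",
              logo = if (stats::runif(1) < 0.3) "assets/logo.png",
              sections = sections)
}

# two-sheet OOXML workbook, for the first-sheet-only contract
write_two_sheet_xlsx <- function(df, path) {
  tmp <- tempfile("xlsx2_")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE))
  decl <- "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>"
  w <- function(lines, f) writeLines(lines, file.path(tmp, f))
  w(c(decl,
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/content-types\">",
    "<Default Extension=\"rels\" ContentType=\"application/vnd.openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Override PartName=\"/xl/workbook.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml\"/>",
    "<Override PartName=\"/xl/worksheets/sheet1.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml\"/>",
    "<Override PartName=\"/xl/worksheets/sheet2.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml\"/>",
    "</Types>"), "[Content_Types].xml")
  w(c(decl,
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument\" Target=\"xl/workbook.xml\"/>",
    "</Relationships>"), "_rels/.rels")
  w(c(decl,
    "<workbook xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\" xmlns:r=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships\">",
    "<sheets><sheet name=\"first\" sheetId=\"1\" r:id=\"rId1\"/><sheet name=\"second\" sheetId=\"2\" r:id=\"rId2\"/></sheets>",
    "</workbook>"), "xl/workbook.xml")
  w(c(decl,
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet\" Target=\"worksheets/sheet1.xml\"/>",
    "<Relationship Id=\"rId2\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet\" Target=\"worksheets/sheet2.xml\"/>",
    "</Relationships>"), "xl/_rels/workbook.xml.rels")
  sheet_xml <- function(d) {
    cell <- function(ref, v) {
      if (is.numeric(v)) sprintf("<c r=\"%s\"><v>%s</v></c>", ref, v)
      else sprintf("<c r=\"%s\" t=\"inlineStr\"><is><t>%s</t></is></c>", ref, v)
    }
    rows <- sprintf("<row r=\"1\">%s</row>", paste(vapply(seq_along(d),
      function(j) cell(paste0(LETTERS[j], "1"), names(d)[j]), character(1)),
      collapse = ""))
    for (i in seq_len(nrow(d)))
      rows <- c(rows, sprintf("<row r=\"%d\">%s</row>", i + 1L,
        paste(vapply(seq_along(d), function(j)
          cell(paste0(LETTERS[j], i + 1L), d[[j]][i]), character(1)),
          collapse = "")))
    c(decl,
      "<worksheet xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\">",
      "<sheetData>", rows, "</sheetData>", "</worksheet>")
  }
  w(sheet_xml(df), "xl/worksheets/sheet1.xml")
  w(sheet_xml(data.frame(other = c("x", "y"))), "xl/worksheets/sheet2.xml")
  members <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
               "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml",
               "xl/worksheets/sheet2.xml")
  zip::zip(file.path(normalizePath(dirname(path)), basename(path)),
           members, mode = "mirror", include_directories = FALSE, root = tmp)
  invisible(path)
}

# labeled adjacency matrix -> CSV (header row with leading empty cell)
write_adjacency_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", col.names = NA, quote = FALSE)
  invisible(path)
}
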