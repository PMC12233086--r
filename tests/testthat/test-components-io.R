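test_that("delimited tables load with explicit or probed delimiters", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4"), f)
  tb <- load_table(f)
  expect_identical(names(tb), c("a", "b"))
  expect_identical(dim(tb), c(2L, 2L))
  expect_identical(tb$a, c(1, 3))
  # same content tab-separated, delimiter unset: probe picks tab
  ft <- tempfile(fileext = ".txt")
  writeLines(c("a\tb", "1\t2", "3\t4"), ft)
  expect_identical(load_table(ft), tb)
  # configured delimiter wins
  fs <- tempfile(fileext = ".csv")
  writeLines(c("a;b", "1;2", "3;4"), fs)
  expect_identical(load_table(fs, delimiter = ";"), tb)
})

test_that("the same logical table loads equal across all four formats", {
  df <- data.frame(id = c("s1", "s2", "s3"), value = c(1.5, 2, 3.25),
                   n = c(10, 20, 30), stringsAsFactors = FALSE)
  fc <- tempfile(fileext = ".csv")
  utils::write.table(df, fc, sep = ",", row.names = FALSE, quote = FALSE)
  ft <- tempfile(fileext = ".txt")
  utils::write.table(df, ft, sep = "\t", row.names = FALSE, quote = FALSE)
  fp <- tempfile(fileext = ".parquet")
  arrow::write_parquet(df, fp)
  fx <- tempfile(fileext = ".xlsx")
  reportforge:::write_minimal_xlsx(df, fx)
  tabs <- list(load_table(fc), load_table(ft), load_table(fp), load_table(fx))
  for (i in 2:4)
    expect_identical(tabs[[i]], tabs[[1]], info = paste("format", i))
})

test_that("ragged and empty delimited files are load errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4,5"), f)
  expect_error(load_table(f), "ragged.*line 3")
  e <- tempfile(fileext = ".csv")
  file.create(e)
  expect_error(load_table(e), "empty")
})

test_that("xlsx reads the first sheet only, warning when others exist", {
  df <- data.frame(x = c("a", "b"), y = c(1, 2), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".xlsx")
  write_two_sheet_xlsx(df, f)
  expect_warning(tb <- load_table(f), "first")
  expect_identical(names(tb), c("x", "y"))
  expect_identical(nrow(tb), 2L)
})

test_that("edge lists load with weights and round-trip isomorphically", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("source,target", "A,B", "B,C"), f)
  g <- load_graph(f, "edge_list")
  expect_identical(sort(g$nodes), c("A", "B", "C"))
  expect_identical(nrow(g$edges), 2L)
  expect_false(g$directed)
  # third numeric column becomes weight; extras ride along
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("source,target,weight,evidence", "A,B,0.5,lit", "B,C,0.9,pred"),
             f2)
  g2 <- load_graph(f2, "edge_list")
  expect_identical(g2$edges$weight, c(0.5, 0.9))
  expect_identical(g2$edges$evidence, c("lit", "pred"))
  out <- tempfile(fileext = ".csv")
  write_edge_list(g2, out)
  g3 <- load_graph(out, "edge_list")
  expect_identical(sort(g3$nodes), sort(g2$nodes))
  key <- function(g) sort(paste(g$edges$from, g$edges$to))
  expect_identical(key(g3), key(g2))
  expect_error(load_graph({
    f3 <- tempfile(fileext = ".csv")
    writeLines(c("only_one", "A", "B"), f3)
    f3
  }, "edge_list"), "2 columns")
})

test_that("adjacency matrices map nonzero cells to edges", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- m["b", "a"] <- 1
  m["b", "c"] <- m["c", "b"] <- 2
  f <- tempfile(fileext = ".csv")
  write_adjacency_csv(m, f)
  g <- load_graph(f, "adjacency")
  expect_identical(length(g$nodes), 3L)
  expect_identical(nrow(g$edges), 2L)   # each symmetric pair once
  expect_false(g$directed)
  # asymmetric matrix -> directed graph; diagonal ignored
  m2 <- m
  m2["a", "c"] <- 5
  diag(m2) <- 9
  f2 <- tempfile(fileext = ".csv")
  write_adjacency_csv(m2, f2)
  g2 <- load_graph(f2, "adjacency")
  expect_true(g2$directed)
  expect_identical(nrow(g2$edges), 5L)  # 2 symmetric pairs (4) + 1 extra
  # non-square is a format error
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("x,a,b,c", "r1,0,1,0", "r2,1,0,1"), f3)
  expect_error(load_graph(f3, "adjacency"), "not square")
})

test_that("graph exchange formats load with the counts the fixture wrote", {
  m <- get_basic_fixture()
  gm <- file.path(m$root,
                  "networks_and_text_3/correlation_networks_1/cooccurrence_network.graphml")
  g <- load_graph(gm, "graphml")
  expect_identical(length(g$nodes), m$graphs$graphml$nodes)
  expect_identical(nrow(g$edges), m$graphs$graphml$edges)
  # independent structural check: count raw XML node/edge elements
  doc <- xml2::read_xml(gm)
  xml2::xml_ns_strip(doc)
  expect_identical(length(xml2::xml_find_all(doc, ".//node")),
                   m$graphs$graphml$nodes)
  expect_identical(length(xml2::xml_find_all(doc, ".//edge")),
                   m$graphs$graphml$edges)
})

test_that("GML, GEXF and CYJS parse to the same small graph", {
  ig <- igraph::make_graph(~ A - B, B - C, C - A, A - D)
  fgml <- tempfile(fileext = ".gml")
  igraph::write_graph(ig, fgml, format = "gml")
  g <- load_graph(fgml, "gml")
  expect_identical(length(g$nodes), 4L)
  expect_identical(nrow(g$edges), 4L)

  fgexf <- tempfile(fileext = ".gexf")
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://gexf.net/1.3\" version=\"1.3\">",
    "<graph defaultedgetype=\"undirected\">",
    "<nodes><node id=\"A\" label=\"A\"/><node id=\"B\" label=\"B\"/>",
    "<node id=\"C\" label=\"C\"/><node id=\"D\" label=\"D\"/></nodes>",
    "<edges><edge id=\"0\" source=\"A\" target=\"B\"/>",
    "<edge id=\"1\" source=\"B\" target=\"C\"/>",
    "<edge id=\"2\" source=\"C\" target=\"A\"/>",
    "<edge id=\"3\" source=\"A\" target=\"D\"/></edges>",
    "</graph></gexf>"), fgexf)
  gx <- load_graph(fgexf, "gexf")
  expect_identical(sort(gx$nodes), c("A", "B", "C", "D"))
  expect_identical(nrow(gx$edges), 4L)
  expect_false(gx$directed)

  fcyjs <- tempfile(fileext = ".cyjs")
  writeLines(jsonlite::toJSON(list(elements = list(
    nodes = lapply(c("A", "B", "C", "D"), function(id)
      list(data = list(id = id))),
    edges = list(list(data = list(source = "A", target = "B")),
                 list(data = list(source = "B", target = "C")),
                 list(data = list(source = "C", target = "A")),
                 list(data = list(source = "A", target = "D"))))),
    auto_unbox = TRUE), fcyjs)
  gc <- load_graph(fcyjs, "cyjs")
  expect_identical(sort(gc$nodes), sort(gx$nodes))
  key <- function(g) sort(paste(pmin(g$edges$from, g$edges$to),
                                pmax(g$edges$from, g$edges$to)))
  expect_identical(key(gc), key(gx))
})

test_that("plot JSON dialects are detected by their structural keys", {
  expect_identical(detect_plot_dialect(list(
    `$schema` = "https://vega.github.io/schema/vega-lite/v5.json",
    mark = "bar")), "vega_family")
  expect_identical(detect_plot_dialect(list(
    data = list(), layout = list())), "figure_object")
  expect_identical(detect_plot_dialect(list(foo = 1)), "unknown")
  expect_identical(detect_plot_dialect("not json-like"), "unknown")
})

test_that("text components pass through byte-identically, with decode warnings", {
  f <- tempfile(fileext = ".md")
  txt <- "### Heading\n\nEquation: $\\alpha + \\beta$\n"
  writeBin(charToRaw(txt), f)
  expect_identical(load_text_component(f, "markdown"), txt)
  e <- tempfile(fileext = ".md")
  file.create(e)
  expect_warning(out <- load_text_component(e, "markdown"), "empty")
  expect_identical(out, "")
  b <- tempfile(fileext = ".html")
  writeBin(as.raw(c(0x3c, 0x70, 0x3e, 0xff, 0xfe, 0x3c, 0x2f, 0x70, 0x3e)), b)
  expect_warning(out2 <- load_text_component(b, "html"), "UTF-8")
  expect_true(validUTF8(out2))
})
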