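test_that("names parse into titles and numeric order tokens", {
  p <- parse_name("exploratory_data_analysis_1")
  expect_identical(p$title, "Exploratory Data Analysis")
  expect_identical(p$order, 1L)
  p <- parse_name("network-analysis")
  expect_identical(p$title, "Network Analysis")
  expect_null(p$order)
  expect_identical(parse_name("phylum_barplot_10")$order, 10L)
  # prefix numbering is accepted; suffix wins when both are present
  expect_identical(parse_name("02_quality_control")$order, 2L)
  expect_identical(parse_name("02_quality_control")$title, "Quality Control")
  expect_identical(parse_name("2_results_5")$order, 5L)
  # degenerate names fall back to the raw string
  expect_identical(parse_name("___")$title, "___")
})

test_that("ordering is numeric-first, then case-insensitive alphabetical", {
  expect_identical(sort_names(c("b_2", "a_10", "c")), c("b_2", "a_10", "c"))
  expect_identical(sort_names(c("beta", "Alpha")), c("Alpha", "beta"))
  # equal order values tie-break alphabetically (enumeration-order free)
  expect_identical(sort_names(c("z_1", "a_1")), c("a_1", "z_1"))
  k <- order_key(parse_name("x_3"))
  expect_false(k$unordered)
  expect_identical(k$order, 3)
})

test_that("classification follows extensions with name-based network hints", {
  expect_identical(classify_file("heatmap.png")$kind, "plot")
  expect_identical(classify_file("heatmap.png")$subtype, "static_image")
  expect_identical(classify_file("a/b/cooccurrence.graphml")$subtype, "graphml")
  expect_identical(classify_file("taxa_edge_list.csv")$kind, "network")
  expect_identical(classify_file("taxa_edge_list.csv")$subtype, "edge_list")
  expect_identical(classify_file("abundance.parquet")$subtype, "parquet")
  cls <- classify_file("mystery.xyz")
  expect_identical(cls$kind, "unclassified")
  expect_false(cls$confident)
  # hint tokens are configurable
  expect_identical(classify_file("links.csv", hint_tokens = "links")$kind,
                   "network")
  expect_identical(classify_file("taxa_edge_list.csv",
                                 hint_tokens = "nothinghere")$kind,
                   "dataframe")
})

test_that("scan matches the fixture manifests exactly (structure oracle)", {
  for (seed in c(7L, 123L)) {
    m <- make_basic_fixture(file.path(tempdir(), paste0("scan_", seed)), seed)
    spec <- scan_directory(m$root)
    expect_true(spec_equal(spec, m$expected_spec),
                info = paste("seed", seed))
  }
  emp <- get_emp_fixture()
  spec <- scan_directory(emp$root)
  expect_true(spec_equal(spec, emp$expected_spec))
  expect_identical(vapply(spec$sections, `[[`, character(1), "title"),
                   c("Exploratory Data Analysis", "Metagenomics",
                     "Network Analysis"))
})

test_that("scan completeness: every file is a component or a logged skip", {
  m <- get_basic_fixture()
  root <- file.path(tempdir(), "scan_complete")
  unlink(root, recursive = TRUE)
  fs_copy <- file.copy(m$root, tempdir(), recursive = TRUE)
  root <- file.path(tempdir(), basename(m$root))
  # add skippable noise
  writeLines("x", file.path(root, "stray_root_file.txt"))
  writeLines("x", file.path(root, "exploratory_plots_1", "mystery.xyz"))
  file.create(file.path(root, "exploratory_plots_1", "static_plots_1",
                        "empty.png"))
  dir.create(file.path(root, ".hidden_dir"))
  spec <- scan_directory(root)
  log <- attr(spec, "scan_log")
  n_files <- length(list.files(root, recursive = TRUE))
  # hidden *directories* are logged too but are not files
  skips <- sum(grepl("skipping|ignoring", log) & !grepl("hidden_dir", log))
  expect_identical(reportforge:::n_components(spec) + skips, n_files)
  expect_true(any(grepl("hidden_dir", log)))
  expect_true(any(grepl("stray_root_file", log)))
  expect_true(any(grepl("mystery.xyz", log)))
  expect_true(any(grepl("empty.png", log)))
  unlink(root, recursive = TRUE)
})

test_that("content deeper than two levels is flattened into its subsection", {
  root <- file.path(tempdir(), "deep_tree")
  unlink(root, recursive = TRUE)
  deep <- file.path(root, "sec_1", "sub_1", "nested", "deeper")
  dir.create(deep, recursive = TRUE)
  writeLines("### hi", file.path(root, "sec_1", "sub_1", "top.md"))
  writeLines("### deep", file.path(deep, "buried.md"))
  spec <- scan_directory(root)
  ss <- spec$sections[[1]]$subsections[[1]]
  expect_identical(vapply(ss$components, `[[`, character(1), "title"),
                   c("Buried", "Top"))
  expect_true(any(grepl("flatten", attr(spec, "scan_log"))))
})

test_that("unscannable inputs raise clear errors", {
  expect_error(scan_directory(file.path(tempdir(), "does_not_exist")),
               "not found")
  root <- file.path(tempdir(), "junk_only")
  dir.create(file.path(root, "sec"), recursive = TRUE, showWarnings = FALSE)
  writeLines("x", file.path(root, "sec", "data.xyz"))
  expect_error(scan_directory(root), "nothing to report")
})

test_that("scan is deterministic and idempotent through the config format", {
  m <- get_basic_fixture()
  s1 <- scan_directory(m$root)
  s2 <- scan_directory(m$root)
  expect_true(spec_equal(s1, s2))
  cfg1 <- tempfile(fileext = ".yaml")
  cfg2 <- tempfile(fileext = ".yaml")
  directory_to_config(m$root, cfg1)
  directory_to_config(m$root, cfg2)
  expect_identical(read_bytes(cfg1), read_bytes(cfg2))
  expect_true(spec_equal(read_config(cfg1), s1))
})

test_that("a hand-edited generated config feeds back into rendering", {
  m <- get_basic_fixture()
  cfg <- tempfile(fileext = ".yaml")
  directory_to_config(m$root, cfg)
  txt <- readLines(cfg)
  txt <- sub("^  title: Basic Report$",
             "  title: Basic Report\n  description: Edited by hand", txt)
  writeLines(txt, cfg)
  spec <- read_config(cfg)
  expect_identical(spec$description, "Edited by hand")
  out <- tempfile()
  bundle <- generate_document(spec, "html", out, base_dir = m$root)
  qmd <- readLines(file.path(out, "report.qmd"))
  expect_true(any(grepl("Edited by hand", qmd)))
})
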