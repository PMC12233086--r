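test_that("fixture manifests match what exists on disk", {
  for (m in list(get_basic_fixture(), get_emp_fixture())) {
    on_disk <- sort(list.files(m$root, recursive = TRUE))
    expect_identical(sort(m$file_list$relpath), on_disk)
    expect_identical(m$expected$n_components, nrow(m$file_list))
    expect_identical(sum(m$expected$by_kind), m$expected$n_components)
  }
})

test_that("fixture generation is byte-deterministic in the seed", {
  a <- make_basic_fixture(file.path(tempdir(), "det_a"), 7L)
  b <- make_basic_fixture(file.path(tempdir(), "det_b"), 7L)
  expect_true(trees_identical(a$root, b$root))
  # a different seed changes content but not structure
  c3 <- make_basic_fixture(file.path(tempdir(), "det_c"), 99L)
  expect_identical(sort(c3$file_list$relpath), sort(a$file_list$relpath))
  expect_false(trees_identical(a$root, c3$root))
  ea <- make_emp_style_fixture(file.path(tempdir(), "det_ea"), 7L)
  eb <- make_emp_style_fixture(file.path(tempdir(), "det_eb"), 7L)
  expect_true(trees_identical(ea$root, eb$root))
})

test_that("fixture charts carry the dialects the components declare", {
  m <- get_basic_fixture()
  for (i in seq_len(nrow(m$file_list))) {
    row <- m$file_list[i, ]
    if (row$subtype != "interactive_json") next
    payload <- jsonlite::fromJSON(file.path(m$root, row$relpath),
                                  simplifyVector = FALSE)
    expect_true(detect_plot_dialect(payload) %in%
                  c("figure_object", "vega_family"),
                info = row$relpath)
  }
})

test_that("fixture graphs have the node and edge counts the manifest records", {
  m <- get_emp_fixture()
  g <- load_graph(file.path(
    m$root, "network_analysis_3/cooccurrence_networks_1/taxa_cooccurrence_1.graphml"))
  expect_identical(length(g$nodes), m$graphs$graphml$nodes)
  expect_identical(nrow(g$edges), m$graphs$graphml$edges)
})

test_that("fixtures do not disturb the caller's RNG stream", {
  set.seed(1)
  before <- stats::runif(1)
  set.seed(1)
  invisible(make_basic_fixture(file.path(tempdir(), "rng_check"), 7L))
  after <- stats::runif(1)
  expect_identical(before, after)
})
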