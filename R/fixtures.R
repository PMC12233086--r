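# Deterministic synthetic example directories emulating typical
# bioinformatics results trees, with ground-truth manifests used as the
# test oracle for ingestion and rendering. All content is generated
# from the seed; no timestamps are embedded, so a fixture regenerated
# with the same seed is byte-identical.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

## ---- low-level writers ----------------------------------------------------

write_csv_file <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     eol = "\n")
}

col_letter <- function(j) {
  # 1 -> A, 27 -> AA
  out <- ""
  while (j > 0) {
    out <- paste0(LETTERS[(j - 1) %% 26 + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Minimal single-sheet OOXML spreadsheet writer (inline strings, no
# styles). Member file mtimes are pinned so the zip container is
# byte-stable across runs.
write_minimal_xlsx <- function(df, path) {
  tmp <- tempfile("xlsx_")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE))
  decl <- "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>"
  write_text_file(c(decl,
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/content-types\">",
    "<Default Extension=\"rels\" ContentType=\"application/vnd.openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Override PartName=\"/xl/workbook.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml\"/>",
    "<Override PartName=\"/xl/worksheets/sheet1.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml\"/>",
    "</Types>"), file.path(tmp, "[Content_Types].xml"))
  write_text_file(c(decl,
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument\" Target=\"xl/workbook.xml\"/>",
    "</Relationships>"), file.path(tmp, "_rels", ".rels"))
  write_text_file(c(decl,
    "<workbook xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\" xmlns:r=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships\">",
    "<sheets><sheet name=\"Sheet1\" sheetId=\"1\" r:id=\"rId1\"/></sheets>",
    "</workbook>"), file.path(tmp, "xl", "workbook.xml"))
  write_text_file(c(decl,
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet\" Target=\"worksheets/sheet1.xml\"/>",
    "</Relationships>"), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  cell <- function(ref, value) {
    if (is.numeric(value) && !is.na(value))
      sprintf("<c r=\"%s\"><v>%s</v></c>", ref, format(value, digits = 15))
    else
      sprintf("<c r=\"%s\" t=\"inlineStr\"><is><t>%s</t></is></c>", ref,
              xml_escape(as.character(value)))
  }
  rows <- sprintf("<row r=\"1\">%s</row>", paste(vapply(seq_along(df),
    function(j) cell(paste0(col_letter(j), "1"), names(df)[j]),
    character(1)), collapse = ""))
  for (i in seq_len(nrow(df))) {
    rows <- c(rows, sprintf("<row r=\"%d\">%s</row>", i + 1L,
      paste(vapply(seq_along(df), function(j)
        cell(paste0(col_letter(j), i + 1L), df[[j]][i]), character(1)),
        collapse = "")))
  }
  write_text_file(c(decl,
    "<worksheet xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\">",
    "<sheetData>", rows, "</sheetData>", "</worksheet>"),
    file.path(tmp, "xl", "worksheets", "sheet1.xml"))
  members <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
               "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml")
  Sys.setFileTime(file.path(tmp, members),
                  as.POSIXct("2020-01-01 00:00:00", tz = "UTC"))
  if (file.exists(path)) unlink(path)
  target <- file.path(normalizePath(dirname(path)), basename(path))
  zip::zip(target, members, mode = "mirror",
           include_directories = FALSE, root = tmp)
  invisible(path)
}

write_plotly_json <- function(path, x, y, title, mode = "lines+markers") {
  payload <- list(
    data = list(list(type = "scatter", mode = mode, x = x, y = y,
                     name = "series 1")),
    layout = list(title = list(text = title)))
  write_text_file(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 6,
                                   pretty = TRUE), path)
}

write_vega_bar_json <- function(path, categories, values, title) {
  payload <- list(
    `$schema` = "https://vega.github.io/schema/vega-lite/v5.json",
    title = title,
    data = list(values = lapply(seq_along(categories), function(i)
      list(category = categories[i], count = values[i]))),
    mark = "bar",
    encoding = list(x = list(field = "category", type = "nominal"),
                    y = list(field = "count", type = "quantitative")))
  write_text_file(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 6,
                                   pretty = TRUE), path)
}

write_scatter_png <- function(path, n, main) {
  x <- round(stats::rnorm(n), 3)
  y <- round(x * 0.8 + stats::rnorm(n, sd = 0.5), 3)
  ragg::agg_png(path, width = 640, height = 420, background = "white")
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(x, y, pch = 19, col = "#4878A8", main = main)
  grDevices::dev.off()
  invisible(path)
}

write_hist_png <- function(path, n, main) {
  x <- round(stats::rgamma(n, shape = 2), 3)
  ragg::agg_png(path, width = 640, height = 420, background = "white")
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::hist(x, col = "#4878A8", border = "white", main = main,
                 xlab = "value")
  grDevices::dev.off()
  invisible(path)
}

write_heatmap_png <- function(path, n, main) {
  m <- matrix(round(stats::runif(n * n), 3), n, n)
  ragg::agg_png(path, width = 640, height = 420, background = "white")
  graphics::par(mar = c(2, 2, 3, 1))
  graphics::image(m, main = main, col = grDevices::hcl.colors(12, "YlGnBu"))
  grDevices::dev.off()
  invisible(path)
}

# seeded sparse undirected graph with fixed node/edge counts
random_fixture_graph <- function(n_nodes, n_edges, prefix = "taxon") {
  pairs <- utils::combn(n_nodes, 2)
  sel <- sort(sample(ncol(pairs), n_edges))
  igraph::graph_from_data_frame(
    data.frame(from = paste0(prefix, pairs[1, sel]),
               to = paste0(prefix, pairs[2, sel]),
               weight = round(stats::runif(n_edges, 0.2, 1), 3)),
    directed = FALSE,
    vertices = data.frame(name = paste0(prefix, seq_len(n_nodes))))
}

fixture_manifest <- function(root, seed, file_list, expected_spec, graphs) {
  kinds <- table(factor(file_list$kind, levels = COMPONENT_KINDS))
  structure(list(
    root = root, seed = seed,
    expected = list(
      n_sections = length(expected_spec$sections),
      n_subsections = sum(vapply(expected_spec$sections,
                                 function(s) length(s$subsections),
                                 integer(1))),
      n_components = nrow(file_list),
      by_kind = kinds[kinds > 0]),
    file_list = file_list,
    graphs = graphs,
    expected_spec = expected_spec),
    class = "fixture_manifest")
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat("<fixture_manifest> seed ", x$seed, " at ", x$root, "\n",
      "  sections: ", x$expected$n_sections,
      "  subsections: ", x$expected$n_subsections,
      "  components: ", x$expected$n_components, "\n", sep = "")
  print(x$expected$by_kind)
  invisible(x)
}

fl_row <- function(relpath, kind, subtype)
  data.frame(relpath = relpath, kind = kind, subtype = subtype,
             stringsAsFactors = FALSE)

## ---- basic fixture --------------------------------------------------------

#' Generate the basic example results directory
#'
#' Creates a deterministic two-level tree (`basic_report/` under
#' `outdir`) with 3 section folders, 5 subsection folders and 13 files
#' covering every classifiable component subtype: static images,
#' interactive chart JSON in both dialects (figure object and
#' Vega-Lite), tables as CSV/TXT/Parquet/XLSX, an edge-list CSV, a
#' GraphML network, Markdown and HTML — with numerical name suffixes
#' exercising the ordering rules (including a 2-before-10 case) and one
#' component placed directly under a section. All content derives from
#' `seed`; a rerun with the same seed is byte-identical.
#'
#' @param outdir writable directory; the fixture root is created inside.
#' @param seed integer seed.
#' @return A `fixture_manifest`: the ground truth (expected counts,
#'   per-file kinds, expected [report_spec()]) for this tree.
#' @export
make_basic_fixture <- function(outdir, seed = 7L) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory under ", outdir, call. = FALSE)
  root <- file.path(outdir, "basic_report")
  unlink(root, recursive = TRUE)
  d1a <- file.path(root, "exploratory_plots_1", "static_plots_1")
  d1b <- file.path(root, "exploratory_plots_1", "interactive_plots_2")
  d2a <- file.path(root, "data_tables_2", "summary_tables_1")
  d3a <- file.path(root, "networks_and_text_3", "correlation_networks_1")
  d3b <- file.path(root, "networks_and_text_3", "project_notes_2")
  for (d in c(d1a, d1b, d2a, d3a, d3b))
    dir.create(d, recursive = TRUE)

  graphs <- with_seed(seed, {
    write_scatter_png(file.path(d1a, "scatter_plot_1.png"), 15,
                      "Scatter Plot")
    write_hist_png(file.path(d1a, "abundance_histogram_2.png"), 20,
                   "Abundance Histogram")
    write_heatmap_png(file.path(root, "exploratory_plots_1",
                                "overview_heatmap.png"), 5,
                      "Overview Heatmap")
    write_plotly_json(file.path(d1b, "line_chart_2.json"),
                      x = 1:12, y = round(cumsum(stats::rnorm(12)), 3),
                      title = "Line Chart")
    write_vega_bar_json(file.path(d1b, "bar_chart_10.json"),
                        categories = paste0("grp", 1:5),
                        values = sample(5:40, 5), title = "Bar Chart")

    abundance <- data.frame(taxon = paste0("taxon", 1:8),
                            sample_a = round(stats::runif(8, 0, 100), 2),
                            sample_b = round(stats::runif(8, 0, 100), 2))
    write_csv_file(abundance, file.path(d2a, "abundance_table_1.csv"))
    meta <- data.frame(sample_id = paste0("S", 1:6),
                       group = rep(c("control", "treated"), 3),
                       reads = sample(1e4:5e4, 6))
    write_csv_file(meta, file.path(d2a, "sample_metadata_2.txt"), sep = "\t")
    counts <- data.frame(taxon = paste0("taxon", 1:10),
                         count = sample(0:500, 10),
                         prevalence = round(stats::runif(10), 3))
    arrow::write_parquet(counts, file.path(d2a, "taxa_counts_3.parquet"))
    alpha <- data.frame(sample_id = paste0("S", 1:6),
                        shannon = round(stats::runif(6, 1, 4), 3),
                        observed = sample(20:120, 6))
    write_minimal_xlsx(alpha, file.path(d2a, "alpha_diversity_4.xlsx"))

    g <- random_fixture_graph(7, 8)
    igraph::write_graph(g, file.path(d3a, "cooccurrence_network.graphml"),
                        format = "graphml")
    el <- data.frame(source = paste0("otu", c(1, 1, 2, 3, 4)),
                     target = paste0("otu", c(2, 3, 4, 5, 6)),
                     weight = round(stats::runif(5, 0.1, 0.9), 3))
    write_csv_file(el, file.path(d3a, "taxa_edge_list.csv"))
    list(graphml = list(nodes = 7L, edges = 8L),
         edge_list = list(nodes = 6L, edges = 5L))
  })

  write_text_file(c(
    "### Analysis summary", "",
    "This report aggregates example outputs from a small synthetic",
    "analysis: plots, tables and a co-occurrence network.", "",
    "Mean relative abundance is defined as",
    "$\\bar{a}_i = \\frac{1}{n}\\sum_{j=1}^{n} a_{ij}$."),
    file.path(d3b, "summary_1.md"))
  write_text_file(c(
    "<div>", "<h3>Methods overview</h3>",
    "<p>Synthetic components were generated from a fixed seed;",
    "no external data were used.</p>",
    "<table><tr><th>step</th><th>tool</th></tr>",
    "<tr><td>tables</td><td>generator</td></tr>",
    "<tr><td>networks</td><td>generator</td></tr></table>",
    "</div>"), file.path(d3b, "methods_overview_2.html"))

  cmp <- function(title, kind, fp, ...)
    report_component(title = title, kind = kind, file_path = fp, ...)
  expected_spec <- report_spec(
    title = "Basic Report",
    sections = list(
      report_section("Exploratory Plots",
        components = list(
          cmp("Overview Heatmap", "plot",
              "exploratory_plots_1/overview_heatmap.png",
              plot_format = "static_image")),
        subsections = list(
          report_subsection("Static Plots", components = list(
            cmp("Scatter Plot", "plot",
                "exploratory_plots_1/static_plots_1/scatter_plot_1.png",
                plot_format = "static_image"),
            cmp("Abundance Histogram", "plot",
                "exploratory_plots_1/static_plots_1/abundance_histogram_2.png",
                plot_format = "static_image"))),
          report_subsection("Interactive Plots", components = list(
            cmp("Line Chart", "plot",
                "exploratory_plots_1/interactive_plots_2/line_chart_2.json",
                plot_format = "interactive_json",
                json_dialect = "figure_object"),
            cmp("Bar Chart", "plot",
                "exploratory_plots_1/interactive_plots_2/bar_chart_10.json",
                plot_format = "interactive_json",
                json_dialect = "vega_family"))))),
      report_section("Data Tables",
        subsections = list(
          report_subsection("Summary Tables", components = list(
            cmp("Abundance Table", "dataframe",
                "data_tables_2/summary_tables_1/abundance_table_1.csv",
                file_format = "csv"),
            cmp("Sample Metadata", "dataframe",
                "data_tables_2/summary_tables_1/sample_metadata_2.txt",
                file_format = "txt"),
            cmp("Taxa Counts", "dataframe",
                "data_tables_2/summary_tables_1/taxa_counts_3.parquet",
                file_format = "parquet"),
            cmp("Alpha Diversity", "dataframe",
                "data_tables_2/summary_tables_1/alpha_diversity_4.xlsx",
                file_format = "xlsx"))))),
      report_section("Networks And Text",
        subsections = list(
          report_subsection("Correlation Networks", components = list(
            cmp("Cooccurrence Network", "network",
                "networks_and_text_3/correlation_networks_1/cooccurrence_network.graphml",
                net_format = "graphml"),
            cmp("Taxa Edge List", "network",
                "networks_and_text_3/correlation_networks_1/taxa_edge_list.csv",
                net_format = "edge_list"))),
          report_subsection("Project Notes", components = list(
            cmp("Summary", "markdown",
                "networks_and_text_3/project_notes_2/summary_1.md"),
            cmp("Methods Overview", "html",
                "networks_and_text_3/project_notes_2/methods_overview_2.html")))))))

  file_list <- rbind(
    fl_row("exploratory_plots_1/overview_heatmap.png", "plot", "static_image"),
    fl_row("exploratory_plots_1/static_plots_1/scatter_plot_1.png",
           "plot", "static_image"),
    fl_row("exploratory_plots_1/static_plots_1/abundance_histogram_2.png",
           "plot", "static_image"),
    fl_row("exploratory_plots_1/interactive_plots_2/line_chart_2.json",
           "plot", "interactive_json"),
    fl_row("exploratory_plots_1/interactive_plots_2/bar_chart_10.json",
           "plot", "interactive_json"),
    fl_row("data_tables_2/summary_tables_1/abundance_table_1.csv",
           "dataframe", "csv"),
    fl_row("data_tables_2/summary_tables_1/sample_metadata_2.txt",
           "dataframe", "txt"),
    fl_row("data_tables_2/summary_tables_1/taxa_counts_3.parquet",
           "dataframe", "parquet"),
    fl_row("data_tables_2/summary_tables_1/alpha_diversity_4.xlsx",
           "dataframe", "xlsx"),
    fl_row("networks_and_text_3/correlation_networks_1/cooccurrence_network.graphml",
           "network", "graphml"),
    fl_row("networks_and_text_3/correlation_networks_1/taxa_edge_list.csv",
           "network", "edge_list"),
    fl_row("networks_and_text_3/project_notes_2/summary_1.md",
           "markdown", "md"),
    fl_row("networks_and_text_3/project_notes_2/methods_overview_2.html",
           "html", "html"))
  fixture_manifest(root, seed, file_list, expected_spec, graphs)
}

## ---- EMP-style fixture ----------------------------------------------------

#' Generate an Earth-Microbiome-style example directory
#'
#' A synthetic stand-in for a global microbiome survey results tree
#' (no real data are downloaded): three sections — exploratory data
#' analysis, metagenomics, and network analysis — each holding
#' components plausible for that analysis stage (an ordination-style
#' scatter, alpha-diversity outputs, a phylum-level bar chart and
#' abundance table, a taxon co-occurrence network with its centrality
#' table). Deterministic in `seed`, like [make_basic_fixture()].
#'
#' @inheritParams make_basic_fixture
#' @return A `fixture_manifest`.
#' @export
make_emp_style_fixture <- function(outdir, seed = 7L) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory under ", outdir, call. = FALSE)
  root <- file.path(outdir, "microbiome_survey_report")
  unlink(root, recursive = TRUE)
  d1a <- file.path(root, "exploratory_data_analysis_1", "sample_overview_1")
  d1b <- file.path(root, "exploratory_data_analysis_1", "alpha_diversity_2")
  d2  <- file.path(root, "metagenomics_2")
  d2a <- file.path(d2, "taxonomic_composition_1")
  d3a <- file.path(root, "network_analysis_3", "cooccurrence_networks_1")
  for (d in c(d1a, d1b, d2a, d3a)) dir.create(d, recursive = TRUE)

  graphs <- with_seed(seed, {
    # ordination-style scatter: two axes, seeded sample coordinates
    write_plotly_json(file.path(d1a, "ordination_scatter_1.json"),
                      x = round(stats::rnorm(20), 3),
                      y = round(stats::rnorm(20), 3),
                      title = "Principal coordinates (PCoA)",
                      mode = "markers")
    meta <- data.frame(sample_id = paste0("EMP", 1:12),
                       biome = rep(c("soil", "water", "sediment"), 4),
                       ph = round(stats::runif(12, 4, 9), 2))
    write_csv_file(meta, file.path(d1a, "sample_metadata_2.csv"))
    write_hist_png(file.path(d1b, "shannon_diversity_boxplot_1.png"), 24,
                   "Shannon Diversity")
    alpha <- data.frame(sample_id = paste0("EMP", 1:12),
                        shannon = round(stats::runif(12, 2, 6), 3),
                        faith_pd = round(stats::runif(12, 5, 30), 2))
    write_csv_file(alpha, file.path(d1b, "alpha_diversity_table_2.csv"))
    write_vega_bar_json(file.path(d2a, "phylum_barplot_1.json"),
                        categories = c("Proteobacteria", "Firmicutes",
                                       "Bacteroidetes", "Actinobacteria",
                                       "Acidobacteria"),
                        values = sample(10:60, 5),
                        title = "Phylum-level composition")
    phylum <- data.frame(phylum = c("Proteobacteria", "Firmicutes",
                                    "Bacteroidetes", "Actinobacteria",
                                    "Acidobacteria", "Other"),
                         mean_abundance = round(stats::runif(6, 1, 40), 3))
    arrow::write_parquet(phylum, file.path(d2a, "phylum_abundance_2.parquet"))
    g <- random_fixture_graph(9, 11, prefix = "otu")
    igraph::write_graph(g, file.path(d3a, "taxa_cooccurrence_1.graphml"),
                        format = "graphml")
    centr <- data.frame(otu = paste0("otu", 1:9),
                        degree = sample(1:6, 9, replace = TRUE),
                        betweenness = round(stats::runif(9, 0, 12), 3))
    write_csv_file(centr, file.path(d3a, "centrality_metrics_2.csv"))
    list(graphml = list(nodes = 9L, edges = 11L))
  })

  write_text_file(c(
    "### Metagenomics overview", "",
    "Taxonomic profiles were summarized at the phylum level;",
    "relative abundances are means across samples."),
    file.path(d2, "metagenomics_summary.md"))
  write_text_file(c(
    "### Community structure", "",
    "The co-occurrence network links taxa whose abundances covary",
    "across samples; hub taxa are listed in the centrality table."),
    file.path(d3a, "community_description_3.md"))

  cmp <- function(title, kind, fp, ...)
    report_component(title = title, kind = kind, file_path = fp, ...)
  expected_spec <- report_spec(
    title = "Microbiome Survey Report",
    sections = list(
      report_section("Exploratory Data Analysis",
        subsections = list(
          report_subsection("Sample Overview", components = list(
            cmp("Ordination Scatter", "plot",
                "exploratory_data_analysis_1/sample_overview_1/ordination_scatter_1.json",
                plot_format = "interactive_json",
                json_dialect = "figure_object"),
            cmp("Sample Metadata", "dataframe",
                "exploratory_data_analysis_1/sample_overview_1/sample_metadata_2.csv",
                file_format = "csv"))),
          report_subsection("Alpha Diversity", components = list(
            cmp("Shannon Diversity Boxplot", "plot",
                "exploratory_data_analysis_1/alpha_diversity_2/shannon_diversity_boxplot_1.png",
                plot_format = "static_image"),
            cmp("Alpha Diversity Table", "dataframe",
                "exploratory_data_analysis_1/alpha_diversity_2/alpha_diversity_table_2.csv",
                file_format = "csv"))))),
      report_section("Metagenomics",
        components = list(
          cmp("Metagenomics Summary", "markdown",
              "metagenomics_2/metagenomics_summary.md")),
        subsections = list(
          report_subsection("Taxonomic Composition", components = list(
            cmp("Phylum Barplot", "plot",
                "metagenomics_2/taxonomic_composition_1/phylum_barplot_1.json",
                plot_format = "interactive_json",
                json_dialect = "vega_family"),
            cmp("Phylum Abundance", "dataframe",
                "metagenomics_2/taxonomic_composition_1/phylum_abundance_2.parquet",
                file_format = "parquet"))))),
      report_section("Network Analysis",
        subsections = list(
          report_subsection("Cooccurrence Networks", components = list(
            cmp("Taxa Cooccurrence", "network",
                "network_analysis_3/cooccurrence_networks_1/taxa_cooccurrence_1.graphml",
                net_format = "graphml"),
            cmp("Centrality Metrics", "dataframe",
                "network_analysis_3/cooccurrence_networks_1/centrality_metrics_2.csv",
                file_format = "csv"),
            cmp("Community Description", "markdown",
                "network_analysis_3/cooccurrence_networks_1/community_description_3.md")))))))

  file_list <- rbind(
    fl_row("exploratory_data_analysis_1/sample_overview_1/ordination_scatter_1.json",
           "plot", "interactive_json"),
    fl_row("exploratory_data_analysis_1/sample_overview_1/sample_metadata_2.csv",
           "dataframe", "csv"),
    fl_row("exploratory_data_analysis_1/alpha_diversity_2/shannon_diversity_boxplot_1.png",
           "plot", "static_image"),
    fl_row("exploratory_data_analysis_1/alpha_diversity_2/alpha_diversity_table_2.csv",
           "dataframe", "csv"),
    fl_row("metagenomics_2/metagenomics_summary.md", "markdown", "md"),
    fl_row("metagenomics_2/taxonomic_composition_1/phylum_barplot_1.json",
           "plot", "interactive_json"),
    fl_row("metagenomics_2/taxonomic_composition_1/phylum_abundance_2.parquet",
           "dataframe", "parquet"),
    fl_row("network_analysis_3/cooccurrence_networks_1/taxa_cooccurrence_1.graphml",
           "network", "graphml"),
    fl_row("network_analysis_3/cooccurrence_networks_1/centrality_metrics_2.csv",
           "dataframe", "csv"),
    fl_row("network_analysis_3/cooccurrence_networks_1/community_description_3.md",
           "markdown", "md"))
  fixture_manifest(root, seed, file_list, expected_spec, graphs)
}
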