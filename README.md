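# reportforge

Automated multi-format scientific reports from a directory of analysis
outputs.

Bioinformatics projects accumulate heterogeneous result files — plots,
tables, networks, Markdown notes, HTML fragments — scattered across a
results tree. Turning those into a shareable, structured report usually
means hand-writing a document or a web app. `reportforge` removes that
step: it infers a hierarchical report structure from the directory
itself (first-level folders become sections, second-level folders
subsections, files typed components), writes that structure to an
editable YAML configuration, and compiles it into any of eight report
formats — a multi-page Streamlit-style web application, or Quarto
Markdown sources targeting HTML, PDF, DOCX, ODT, PPTX, Reveal.js and
Jupyter notebooks. Interactive chart specs (Plotly-style figure
objects, Vega-Lite) and networks are embedded live in interactive
formats and converted to static PNGs for static ones.

The core model is the report specification

```
report (title, description, logo, graphical abstract)
 └─ sections*            (title, description)
     ├─ components*      (directly under a section)
     └─ subsections*     (title, description)
         └─ components*  (plot | dataframe | network | markdown |
                          html | apicall | chatbot)
```

with component types inferred from file extensions and names
(`*.json` → interactive plot, `*_edge_list.csv` → network, …) and
explicit ordering taken from numerical suffixes in folder/file names
(`methods_2` sorts before `results_10`, numerically).

## Worked example

```r
library(reportforge)

# deterministic synthetic results tree (3 sections, 5 subsections,
# 13 typed components)
m <- make_basic_fixture(tempdir(), seed = 7)
spec <- scan_directory(m$root)
spec
#> <report_spec> Basic Report
#>   sections: 3  subsections: 5  components: 13
#>   - Exploratory Plots [1 direct]
#>       * Static Plots (2)
#>       * Interactive Plots (2)
#>   - Data Tables
#>       * Summary Tables (4)
#>   - Networks And Text
#>       * Correlation Networks (2)
#>       * Project Notes (2)

# persist the editable YAML configuration
write_config(spec, "report_config.yaml")

# compile: a PDF-ready document bundle ...
generate_document(spec, "pdf", "report_pdf")
#> <report_bundle> pdf in report_pdf
#> document_source    static_image
#>               1               4
#> render with: quarto render report_pdf/report.qmd
```

The four `static_image` assets are the two interactive charts and two
networks of the fixture, exported to PNG so the PDF contains no
interactive payloads. The same spec drives the web application:

```r
generate_webapp(spec, "report_app")   # app.py + one page per subsection
```

Or from a shell, via the bundled CLI:

```sh
Rscript inst/scripts/report_cli.R --directory results/ --report_type html
```

which scans `results/`, saves the auto-generated config next to the
bundle, and prints a summary (`3 section(s), 5 subsection(s),
13 component(s); 0 warning(s)`). Exit codes: 0 success, 1
validation/render error, 2 usage error.

An annotated configuration covering every component kind ships in
`inst/extdata/example_config.yaml`.

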