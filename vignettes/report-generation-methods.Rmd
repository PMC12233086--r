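---
title: "From results directory to multi-format report: the reportforge method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From results directory to multi-format report: the reportforge method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The report model

`reportforge` treats a report as a three-level hierarchy: a report
holds ordered sections, sections hold ordered subsections (and may hold
components directly), and subsections hold ordered components. A
component is one renderable unit of one of seven kinds: `plot`
(static image or interactive chart JSON), `dataframe` (a table),
`network`, `markdown`, `html`, and the two web-app-only panels
`apicall` and `chatbot`. Every kind except the two panels points at a
file on disk; the panels are defined entirely by configuration
(endpoint URL, HTTP method, request body, model name, standard or
streaming mode).

The same model has two sources and eight sinks. Sources: a YAML
configuration file, or a results directory from which the model is
inferred. Sinks: a multi-page Streamlit-style web-application source
bundle, or a single Quarto Markdown document whose front matter selects
HTML, PDF, DOCX, ODT, PPTX, Reveal.js or Jupyter-notebook output.
Because every sink consumes the same validated `report_spec`, one
configuration drives all formats.

### Assumptions

* Inputs are trusted local analysis outputs. Markdown and HTML
  components are passed through verbatim, with no sanitization; this is
  documented behavior, not an oversight, and the reason the tool should
  not be pointed at untrusted trees.
* The directory convention is two levels deep: first-level folders are
  sections, second-level folders subsections. Deeper nesting is
  flattened into the depth-2 ancestor with a warning, because the
  report model has no third level and silently dropping files would
  violate the completeness invariant (every classifiable file appears
  exactly once, or is logged as skipped).
* Files directly at the scan root belong to no section and are ignored
  with a warning; hidden (dot-prefixed) entries and zero-byte files are
  skipped with warnings.

## Directory inference

Titles come from names: underscores and hyphens become spaces and each
word is capitalized, so `exploratory_data_analysis_1` titles
"Exploratory Data Analysis". A trailing `_<integer>` token is the
item's explicit order (a leading `<integer>_` prefix is accepted too;
the suffix wins if both occur). Ordering is numeric-first — `_2`
precedes `_10` — then case-insensitive alphabetical for unordered
items. Equal order values also tie-break alphabetically rather than by
filesystem position: the scan result must be a pure function of the
tree's *content*, not of enumeration order, or the determinism and
idempotence guarantees (scan → serialize → parse → same spec; two scans
→ byte-identical configs) would not hold.

Component types are inferred from extensions, with one name-based
rule: a `csv`/`txt`/`html` file whose basename contains a network hint
token (`edge_list`, `edgelist`, `adjacency`, `network`, `graph`;
case-insensitive, configurable via the `hint_tokens` argument and the
`--network-hint-tokens` CLI flag) is classified as a network rather
than a table or HTML block, with `adjacency` in the name selecting the
adjacency-matrix reader. The token list is a convention, not a
standard; making it configurable is the escape hatch for trees that
use other naming habits. Unknown extensions are never errors — the file
is skipped with a warning, because a report generator that aborts on
one stray file is useless on real results directories.

## The YAML configuration

The schema uses lowercase snake_case keys (`report:` metadata, then
`sections:` → `subsections:` → `components:`). The component kind is
always written explicitly (`component_type`), even when inferable from
the path, so hand-written configs are unambiguous. Unset optional
fields are omitted on write, and `null` and omitted are equivalent on
read. Unknown component keys are preserved in an extras map and
re-emitted on serialization, so user annotations survive a round-trip;
they are also reported as warnings so typos in known keys do not pass
silently. Relative `file_path`s are resolved against the config file's
directory (or the scan root); resolution state travels as an attribute
outside the spec value, so structural equality and round-trips are
unaffected.

Serialization is deterministic (fixed key order, byte-identical
repeats) because generated configs are meant to be committed to version
control and diffed after hand-editing.

Validation is data, not exceptions: a data.frame of issues with
`severity`, a config path like `sections[1].components[0].file_path`,
and a message. Missing component files are errors and block rendering;
web-app-only panels under a non-webapp format, and sections or
subsections with no content, are warnings — the renderers skip the
former with a logged warning and give the latter a visible placeholder,
so the report always mirrors the configuration.

## Component payloads

* **Tables** load from CSV, TXT, Parquet (via `arrow`) and XLSX (via
  `readxl`, first sheet only, warning if more). For delimited text the
  delimiter, when unconfigured, is probed by majority vote over the
  first 10 lines among comma, tab and semicolon; a configured delimiter
  always wins. Ragged files are errors naming the first offending line.
  Loaded tables are normalized to plain data.frames with double numeric
  columns and character everything-else, so the same logical table
  compares identical across all four physical formats.
* **Networks** load from edge lists (third numeric column = weight,
  further columns = edge attributes), labeled adjacency matrices
  (diagonal ignored; symmetric → undirected with each pair emitted
  once; asymmetric → directed), GraphML/GML (via `igraph`), GEXF and
  CYJS (small standards-based parsers over `xml2`/`jsonlite`, since no
  installed R package reads these two), or pass through as embedded
  HTML. Undirected graphs are normalized to sorted endpoint pairs with
  duplicates removed.
* **Interactive plots** are JSON; the dialect is detected
  structurally — a top-level `$schema` mentioning "vega" marks a
  Vega/Vega-Lite spec, top-level `data` plus `layout` keys mark a
  Plotly-style figure object — and anything else renders as a
  pretty-printed code block with a warning rather than failing the
  report.

## Rendering

**Documents.** Sections map to level-1 headings and subsections to
level-2 headings (the heading depth is a package convention; in
presentation formats each subsection thereby starts a new slide). Every
component is preceded by an HTML comment marker carrying its source
path, which makes component conservation — each component referenced
exactly once, minus skipped panels — mechanically checkable and is
invisible in all outputs. HTML output embeds interactive charts live
(CDN-loaded Plotly/vega-embed with the spec inlined) and renders tables
as sortable/filterable DataTables widgets; static formats receive
Markdown pipe tables (capped at 200 display rows) and PNG exports of
every interactive chart and network, so their document source contains
no interactive payload at all. Raw HTML components are honored only in
HTML-based outputs; static formats reference the file as a link, since
raw HTML is meaningless to a DOCX/PDF toolchain but the component must
still be accounted for.

**Notebook output** also uses staticized images: raw HTML/JS in
notebook markdown cells does not render in offline viewers, so the
conservative choice is the one that always displays.

**Static export** has no R backend for Plotly/Vega JSON in this stack,
so the package carries its own small rasterizer over base graphics
(`ragg` device, default 1000×600 px — proportioned for A4 pages and
slides, configurable): scatter, line and bar marks from both dialects,
which covers what the component model emits; anything else produces an
explicit labeled placeholder image, never a silent blank. Network
drawings use `igraph` with a Fruchterman–Reingold layout under a fixed
seed (default 42), making exported images byte-stable across runs —
regenerating a bundle from the same spec yields an identical file tree,
which the test suite asserts byte-for-byte.

**Web application.** The bundle is an entry script (`app.py` with the
navigation tree, title, description and logo) plus one subdirectory per
section and one Python page script per subsection (plus an overview
page for sections with direct components). Pages render charts from
their JSON specs, tables as interactive dataframe widgets, networks as
browser-rendered views, Markdown/HTML blocks, and the API-call and
chatbot panels (standard and streaming modes). The package emits the
Python sources but never executes them; the test suite checks every
emitted script with a Python AST parse, and `render_external()` offers
a byte-compile smoke check. Quarto and Streamlit themselves are an
optional integration layer: every guarantee above is asserted on the
generated sources, keeping the test surface hermetic.

## The fixture generators

Because the pipeline's job is structural, the synthetic fixtures are
first-class, tested code, and their manifests are hand-written literal
oracles — the expected spec is constructed constructor-by-constructor,
never by running the scanner on its own output. `make_basic_fixture()`
emulates a small mixed results tree: 3 sections, 5 subsections, 13
components covering every classifiable subtype (both chart dialects,
all four table formats, GraphML and edge-list networks, Markdown,
HTML), a direct-under-section component, and name suffixes exercising
the numeric ordering rules including the 2-before-10 case.
`make_emp_style_fixture()` emulates a global microbiome survey results
tree — exploratory data analysis, metagenomics and network analysis
sections with ordination scatter, alpha-diversity, phylum-composition
and co-occurrence-network components — standing in for that kind of
real-world study without downloading any data. Charts carry at most ~20
points so static export runs in milliseconds; all content derives from
the seed and no timestamps are embedded (the one container format that
stores them, XLSX, is written with pinned member times), so equal seeds
give byte-identical trees.

What the fixtures deliberately do **not** emulate: large tables,
malformed or adversarial files, non-UTF-8 text at scale, deeply nested
trees, or the statistical content of real studies. Passing tests
therefore demonstrate structural correctness of inference, serialization
and rendering — not robustness to arbitrary real-world input, beyond
the specific degenerate cases (ragged tables, empty files, unknown
extensions, broken JSON) that have their own tests. The XLSX writer in
the fixture module is minimal by design (one sheet, inline strings);
reading arbitrary workbooks is delegated to `readxl`.

## Numerical and degenerate-input choices

* Delimiter probe: majority vote over ≤10 lines; ties resolve to the
  first candidate in (comma, tab, semicolon) order.
* Adjacency symmetry uses `all.equal` tolerance, not exact equality,
  so matrices written through decimal text round-trips still count as
  symmetric; the diagonal is ignored.
* Empty tables and text files: empty delimited/spreadsheet files are
  errors (a table with no header is unrenderable); empty Markdown/HTML
  yields an empty payload with a warning (an empty note is renderable).
* Degenerate names (`___`, pure punctuation) fall back to the raw
  string rather than an empty title.
* Symlinked directories are followed, but each resolved directory is
  entered at most once, so link cycles terminate.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen as
the smallest sizes that still exercise every code path: the two fixture
trees (13 and 10 components), 100 randomly generated small specs for
the round-trip property, 50 random adjacency matrices (3–8 nodes) for
the edge-count oracle, and full generation of all eight formats from
both fixtures. The complete suite runs in well under a minute.

## Known limitations

* Interactive network views exist only in the web application; all
  document formats (including HTML) receive a static drawing of the
  graph.
* The built-in chart rasterizer covers scatter/line/bar marks with
  inline data; faceted or layered Vega specs and exotic Plotly trace
  types fall back to a placeholder in static formats (they still render
  live in HTML and webapp outputs).
* One config version, no migration; no theming beyond logo and
  graphical abstract; no multi-sheet spreadsheet support; no archive
  extraction or content sniffing beyond the delimiter probe.
* The chatbot panel emits a minimal request/response client for an
  LLM-style endpoint; it does not implement any provider's full
  protocol.
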