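Package: reportforge
Title: Automated Multi-Format Scientific Reports from Analysis Output Directories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structured scientific reports from a directory of
    heterogeneous analysis outputs or from a YAML configuration file.
    First-level folders become report sections and second-level folders
    become subsections; files are classified into typed components
    (static and interactive plots, tables, networks, Markdown, HTML,
    API-call and chatbot panels) from their extensions and names.
    The inferred structure is serialized to an editable YAML
    configuration and compiled into a multi-page web-application source
    bundle or into Quarto Markdown documents targeting HTML, PDF, DOCX,
    ODT, PPTX, Reveal.js and Jupyter notebook outputs, converting
    interactive plots and networks into static images where the output
    format requires it. Includes deterministic synthetic fixture
    generators so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    yaml,
    jsonlite,
    igraph,
    xml2,
    arrow,
    readxl,
    zip,
    ragg,
    utils,
    stats,
    tools,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
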