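# Annotated report configuration covering every component kind.
# Paths are resolved relative to this file's directory; unset optional
# keys may be omitted entirely (writing them as null is equivalent).
report:
  title: Example Multi-Omics Report          # required
  description: What this report aggregates.  # optional
  graphical_abstract: assets/abstract.png    # optional image
  logo: assets/logo.png                      # optional image
sections:
- title: Exploratory Analysis
  description: Optional section description.
  # components may sit directly under a section, without a subsection
  components:
  - title: Study Overview
    component_type: markdown
    file_path: overview.md
  subsections:
  - title: Quality Control
    components:
    - title: Read Quality            # static plot: png/svg/jpg/jpeg
      component_type: plot
      file_path: plots/read_quality.png
      caption: Per-sample read quality.
    - title: Ordination              # interactive plot: JSON
      component_type: plot
      file_path: plots/pcoa.json
      plot_format: interactive_json
      json_dialect: figure_object    # or vega_family; detected if omitted
- title: Results
  subsections:
  - title: Tables
    components:
    - title: Abundance               # dataframe: csv/txt/parquet/xlsx
      component_type: dataframe
      file_path: tables/abundance.csv
      delimiter: ','                 # optional for csv/txt; probed if unset
  - title: Networks
    components:
    - title: Co-occurrence           # network: edge_list/adjacency/
      component_type: network        #   graphml/gml/gexf/cyjs/html_embed
      file_path: networks/cooccurrence.graphml
      net_format: graphml
  - title: Extras
    components:
    - title: External Dashboard      # raw HTML block
      component_type: html
      file_path: extras/dashboard.html
    - title: Annotation Lookup       # web-app only
      component_type: apicall
      api_url: https://api.example.org/annotate
      method: POST
      request_body: '{"id": "otu1"}'
      headers:
        X-Token: replace-me
    - title: Assistant               # web-app only
      component_type: chatbot
      api_url: https://llm.example.org/chat
      model: demo-model
      mode: streaming                # or standard
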