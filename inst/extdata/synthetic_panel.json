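{
  "version": "1.0",
  "note": "Default synthetic colon-style panel and cell-type roster. Versioned fixture: tests load this file rather than regenerating it. CHGA is a low-signal/low-background channel; CD15 and CD16 carry high background; exposure_scale varies per channel to emulate staining-strength and exposure-time differences; CD69/CD127 are phenotypic continuum markers with band-valued expression.",
  "markers": [
    {"name": "CHGA",        "kind": "lineage",    "signal_mean": 8,  "signal_sd": 1.5,  "background_mean": 0.4, "background_sd": 0.25, "exposure_scale": 0.5},
    {"name": "Cytokeratin", "kind": "lineage",    "signal_mean": 50, "signal_sd": 15, "background_mean": 3.0, "background_sd": 1.5,  "exposure_scale": 4.0},
    {"name": "MUC2",        "kind": "lineage",    "signal_mean": 40, "signal_sd": 12, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.5},
    {"name": "Ki67",        "kind": "lineage",    "signal_mean": 35, "signal_sd": 10, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.2},
    {"name": "CD3",         "kind": "lineage",    "signal_mean": 40, "signal_sd": 12, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 2.0},
    {"name": "CD4",         "kind": "lineage",    "signal_mean": 35, "signal_sd": 10, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.8},
    {"name": "CD8",         "kind": "lineage",    "signal_mean": 35, "signal_sd": 10, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.6},
    {"name": "CD20",        "kind": "lineage",    "signal_mean": 40, "signal_sd": 12, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.4},
    {"name": "CD45",        "kind": "lineage",    "signal_mean": 45, "signal_sd": 13, "background_mean": 2.5, "background_sd": 1.2,  "exposure_scale": 2.5},
    {"name": "CD68",        "kind": "lineage",    "signal_mean": 35, "signal_sd": 10, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.3},
    {"name": "CD11c",       "kind": "lineage",    "signal_mean": 30, "signal_sd": 9,  "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.1},
    {"name": "HLA-DR",      "kind": "lineage",    "signal_mean": 40, "signal_sd": 12, "background_mean": 3.0, "background_sd": 1.5,  "exposure_scale": 2.0},
    {"name": "CD15",        "kind": "lineage",    "signal_mean": 40, "signal_sd": 12, "background_mean": 12.0, "background_sd": 5.0, "exposure_scale": 1.2},
    {"name": "CD16",        "kind": "lineage",    "signal_mean": 40, "signal_sd": 12, "background_mean": 11.0, "background_sd": 4.5, "exposure_scale": 1.3},
    {"name": "CD138",       "kind": "lineage",    "signal_mean": 40, "signal_sd": 12, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.5},
    {"name": "CD31",        "kind": "lineage",    "signal_mean": 40, "signal_sd": 12, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 2.2},
    {"name": "CD34",        "kind": "lineage",    "signal_mean": 38, "signal_sd": 11, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 2.0},
    {"name": "Podoplanin",  "kind": "lineage",    "signal_mean": 35, "signal_sd": 10, "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.2},
    {"name": "aSMA",        "kind": "lineage",    "signal_mean": 55, "signal_sd": 16, "background_mean": 3.0, "background_sd": 1.5,  "exposure_scale": 3.5},
    {"name": "Vimentin",    "kind": "lineage",    "signal_mean": 40, "signal_sd": 12, "background_mean": 3.0, "background_sd": 1.5,  "exposure_scale": 2.8},
    {"name": "CD69",        "kind": "phenotypic", "signal_mean": 30, "signal_sd": 9,  "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.0},
    {"name": "CD127",       "kind": "phenotypic", "signal_mean": 30, "signal_sd": 9,  "background_mean": 2.0, "background_sd": 1.0,  "exposure_scale": 1.0}
  ],
  "cell_types": [
    {"name": "Enterocyte",                 "abundance": 0.120, "compartment": "epithelium",
     "expression": {"Cytokeratin": 1.0}},
    {"name": "Goblet cell",                "abundance": 0.080, "compartment": "epithelium",
     "expression": {"Cytokeratin": 0.9, "MUC2": 1.0}},
    {"name": "Transit amplifying cell",    "abundance": 0.070, "compartment": "epithelium",
     "expression": {"Cytokeratin": 0.9, "Ki67": 1.0}},
    {"name": "Neuroendocrine cell",        "abundance": 0.003, "compartment": "epithelium",
     "expression": {"Cytokeratin": 0.9, "CHGA": 1.0}},
    {"name": "CD4 T cell CD69+",           "abundance": 0.050, "compartment": "stroma",
     "expression": {"CD45": 1.0, "CD3": 1.0, "CD4": 1.0, "CD69": [0.5, 1.0], "CD127": [0.0, 0.25]}},
    {"name": "CD4 T cell CD127+",          "abundance": 0.050, "compartment": "stroma",
     "expression": {"CD45": 1.0, "CD3": 1.0, "CD4": 1.0, "CD127": [0.5, 1.0], "CD69": [0.0, 0.25]}},
    {"name": "CD8 T cell",                 "abundance": 0.060, "compartment": "stroma",
     "expression": {"CD45": 1.0, "CD3": 1.0, "CD8": 1.0, "CD69": [0.0, 0.4]}},
    {"name": "B cell",                     "abundance": 0.050, "compartment": "stroma",
     "expression": {"CD45": 1.0, "CD20": 1.0, "HLA-DR": 0.7}},
    {"name": "Plasma cell",                "abundance": 0.060, "compartment": "stroma",
     "expression": {"CD45": 0.5, "CD138": 1.0}},
    {"name": "Macrophage",                 "abundance": 0.050, "compartment": "stroma",
     "expression": {"CD45": 1.0, "CD68": 1.0, "HLA-DR": 0.8, "CD16": 0.4}},
    {"name": "Dendritic cell",             "abundance": 0.020, "compartment": "stroma",
     "expression": {"CD45": 1.0, "CD11c": 1.0, "HLA-DR": 1.0}},
    {"name": "Neutrophil",                 "abundance": 0.003, "compartment": "stroma",
     "expression": {"CD45": 1.0, "CD15": 1.0, "CD16": 1.0}},
    {"name": "Fibroblast",                 "abundance": 0.120, "compartment": "stroma",
     "expression": {"Vimentin": 1.0}},
    {"name": "Endothelial cell",           "abundance": 0.060, "compartment": "vasculature",
     "expression": {"CD31": 1.0, "CD34": 1.0, "Vimentin": 0.5}},
    {"name": "Lymphatic endothelial cell", "abundance": 0.020, "compartment": "stroma",
     "expression": {"Podoplanin": 1.0, "CD31": 0.5, "Vimentin": 0.4}},
    {"name": "Smooth muscle",              "abundance": 0.184, "compartment": "muscle",
     "expression": {"aSMA": 1.0, "Vimentin": 0.4}}
  ]
}
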