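{
  "note": "Best-effort reconstruction of the four-granularity human-colon cell-type ontology (35 granular types including 'Noise', merging to 20, 14 and 7 classes). The published membership map lives in supplementary material not shipped here; this fixture reproduces the published level counts and the type names mentioned in the main text (neuroendocrine cells, neutrophils, enterocytes, CD69+/CD127+ CD4 T subsets, plasma cells, interstitial cells of Cajal, smooth muscle muscularis externa/mucosae, noise). Assignments of the remaining types to coarse classes are the maintainers' reconstruction; known ambiguities: pericytes are grouped with endothelium under 'Vascular' and adipocytes under 'Stroma'.",
  "levels": [
    ["Enterocyte", "Goblet cell", "Transit amplifying cell", "Stem cell",
     "Neuroendocrine cell", "Tuft cell", "Paneth cell", "M cell",
     "CD4+ T cell", "CD4+ T cell CD69+", "CD4+ T cell CD127+", "Regulatory T cell",
     "CD8+ T cell", "CD8+ T cell CD69+", "B cell", "Plasma cell",
     "Macrophage", "Dendritic cell", "Neutrophil", "Mast cell", "NK cell",
     "Fibroblast", "Myofibroblast", "Reticular stromal cell", "Stromal other", "Adipocyte",
     "Endothelial cell", "Pericyte", "Lymphatic endothelial cell",
     "Smooth muscle muscularis externa", "Smooth muscle muscularis mucosae",
     "Interstitial cells of Cajal", "Nerve", "Glial cell", "Noise"],
    ["Enterocyte", "Goblet cell", "TA/Stem", "Neuroendocrine cell", "Secretory epithelial",
     "CD4+ T cell", "CD8+ T cell", "B cell", "Plasma cell", "Macrophage/DC",
     "Neutrophil", "Mast cell", "NK cell", "Stroma", "Endothelial",
     "Lymphatic endothelial", "Smooth muscle", "ICC", "Neuronal", "Noise"],
    ["Epithelial absorptive", "Epithelial secretory", "T cell", "B cell", "Plasma cell",
     "Myeloid", "NK cell", "Stroma", "Endothelial", "Lymphatic", "Smooth muscle",
     "ICC", "Neuronal", "Noise"],
    ["Epithelial", "Immune", "Stromal", "Vascular", "Muscle", "Neuronal", "Noise"]
  ],
  "parents": {
    "1to2": {
      "Enterocyte": "Enterocyte",
      "Goblet cell": "Goblet cell",
      "Transit amplifying cell": "TA/Stem",
      "Stem cell": "TA/Stem",
      "Neuroendocrine cell": "Neuroendocrine cell",
      "Tuft cell": "Secretory epithelial",
      "Paneth cell": "Secretory epithelial",
      "M cell": "Secretory epithelial",
      "CD4+ T cell": "CD4+ T cell",
      "CD4+ T cell CD69+": "CD4+ T cell",
      "CD4+ T cell CD127+": "CD4+ T cell",
      "Regulatory T cell": "CD4+ T cell",
      "CD8+ T cell": "CD8+ T cell",
      "CD8+ T cell CD69+": "CD8+ T cell",
      "B cell": "B cell",
      "Plasma cell": "Plasma cell",
      "Macrophage": "Macrophage/DC",
      "Dendritic cell": "Macrophage/DC",
      "Neutrophil": "Neutrophil",
      "Mast cell": "Mast cell",
      "NK cell": "NK cell",
      "Fibroblast": "Stroma",
      "Myofibroblast": "Stroma",
      "Reticular stromal cell": "Stroma",
      "Stromal other": "Stroma",
      "Adipocyte": "Stroma",
      "Endothelial cell": "Endothelial",
      "Pericyte": "Endothelial",
      "Lymphatic endothelial cell": "Lymphatic endothelial",
      "Smooth muscle muscularis externa": "Smooth muscle",
      "Smooth muscle muscularis mucosae": "Smooth muscle",
      "Interstitial cells of Cajal": "ICC",
      "Nerve": "Neuronal",
      "Glial cell": "Neuronal",
      "Noise": "Noise"
    },
    "2to3": {
      "Enterocyte": "Epithelial absorptive",
      "TA/Stem": "Epithelial absorptive",
      "Goblet cell": "Epithelial secretory",
      "Neuroendocrine cell": "Epithelial secretory",
      "Secretory epithelial": "Epithelial secretory",
      "CD4+ T cell": "T cell",
      "CD8+ T cell": "T cell",
      "B cell": "B cell",
      "Plasma cell": "Plasma cell",
      "Macrophage/DC": "Myeloid",
      "Neutrophil": "Myeloid",
      "Mast cell": "Myeloid",
      "NK cell": "NK cell",
      "Stroma": "Stroma",
      "Endothelial": "Endothelial",
      "Lymphatic endothelial": "Lymphatic",
      "Smooth muscle": "Smooth muscle",
      "ICC": "ICC",
      "Neuronal": "Neuronal",
      "Noise": "Noise"
    },
    "3to4": {
      "Epithelial absorptive": "Epithelial",
      "Epithelial secretory": "Epithelial",
      "T cell": "Immune",
      "B cell": "Immune",
      "Plasma cell": "Immune",
      "Myeloid": "Immune",
      "NK cell": "Immune",
      "Stroma": "Stromal",
      "Endothelial": "Vascular",
      "Lymphatic": "Vascular",
      "Smooth muscle": "Muscle",
      "ICC": "Muscle",
      "Neuronal": "Neuronal",
      "Noise": "Noise"
    }
  }
}
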