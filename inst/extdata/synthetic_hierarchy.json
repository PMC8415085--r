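{
  "note": "Hierarchy for the synthetic panel: 17 level-1 labels (16 generated types plus Noise) merging to 13, 8 and 6.",
  "levels": [
    ["Enterocyte", "Goblet cell", "Transit amplifying cell", "Neuroendocrine cell",
     "CD4 T cell CD69+", "CD4 T cell CD127+", "CD8 T cell", "B cell", "Plasma cell",
     "Macrophage", "Dendritic cell", "Neutrophil", "Fibroblast",
     "Endothelial cell", "Lymphatic endothelial cell", "Smooth muscle", "Noise"],
    ["Enterocyte", "Goblet cell", "Transit amplifying cell", "Neuroendocrine cell",
     "CD4 T cell", "CD8 T cell", "B cell", "Plasma cell", "Myeloid",
     "Fibroblast", "Endothelial", "Smooth muscle", "Noise"],
    ["Epithelial", "T cell", "B lineage", "Myeloid", "Stroma", "Vascular", "Muscle", "Noise"],
    ["Epithelial", "Immune", "Stromal", "Vascular", "Muscle", "Noise"]
  ],
  "parents": {
    "1to2": {
      "Enterocyte": "Enterocyte",
      "Goblet cell": "Goblet cell",
      "Transit amplifying cell": "Transit amplifying cell",
      "Neuroendocrine cell": "Neuroendocrine cell",
      "CD4 T cell CD69+": "CD4 T cell",
      "CD4 T cell CD127+": "CD4 T cell",
      "CD8 T cell": "CD8 T cell",
      "B cell": "B cell",
      "Plasma cell": "Plasma cell",
      "Macrophage": "Myeloid",
      "Dendritic cell": "Myeloid",
      "Neutrophil": "Myeloid",
      "Fibroblast": "Fibroblast",
      "Endothelial cell": "Endothelial",
      "Lymphatic endothelial cell": "Endothelial",
      "Smooth muscle": "Smooth muscle",
      "Noise": "Noise"
    },
    "2to3": {
      "Enterocyte": "Epithelial",
      "Goblet cell": "Epithelial",
      "Transit amplifying cell": "Epithelial",
      "Neuroendocrine cell": "Epithelial",
      "CD4 T cell": "T cell",
      "CD8 T cell": "T cell",
      "B cell": "B lineage",
      "Plasma cell": "B lineage",
      "Myeloid": "Myeloid",
      "Fibroblast": "Stroma",
      "Endothelial": "Vascular",
      "Smooth muscle": "Muscle",
      "Noise": "Noise"
    },
    "3to4": {
      "Epithelial": "Epithelial",
      "T cell": "Immune",
      "B lineage": "Immune",
      "Myeloid": "Immune",
      "Stroma": "Stromal",
      "Vascular": "Vascular",
      "Muscle": "Muscle",
      "Noise": "Noise"
    }
  }
}
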