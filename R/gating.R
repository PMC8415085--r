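# Programmatic hierarchical 2D gating: a tree of rectangle/polygon gates in
# treated-intensity space. At each node the first sibling gate (in document
# order) containing the cell's (marker_x, marker_y) values claims it;
# unclaimed cells fall to the "rest" branch. Every cell receives exactly one
# leaf label. This emulates sequential manual gating and deliberately
# inherits its failure modes (e.g. spillover-driven misassignment upstream).

#' Define a 2D gate
#'
#' @param name gate name.
#' @param marker_x,marker_y marker names spanning the gate plane.
#' @param region either `c(x_min, x_max, y_min, y_max)` (use `-Inf`/`Inf`
#'   for open sides; bounds are inclusive) or a two-column vertex matrix of
#'   a simple polygon (membership by the even-odd rule).
#' @param then the branch for cells inside the gate: a leaf label string or
#'   a [gating_level()].
#' @return a `gate` node.
#' @export
gate <- function(name, marker_x, marker_y, region, then) {
  if (is.matrix(region)) {
    stop_if_not(ncol(region) == 2 && nrow(region) >= 3,
                "polygon region needs a vertex matrix with >= 3 rows")
  } else {
    stop_if_not(length(region) == 4 && region[1] <= region[2] &&
                  region[3] <= region[4],
                "rectangle region must be ordered c(x_min, x_max, y_min, y_max)")
  }
  structure(list(name = name, marker_x = marker_x, marker_y = marker_y,
                 region = region, then = then),
            class = "gate")
}

#' A level of sibling gates with a rest branch
#'
#' @param gates ordered list of [gate()] nodes (first match wins).
#' @param rest branch for cells matching no sibling: label string or nested
#'   `gating_level`.
#' @return a `gating_level`.
#' @export
gating_level <- function(gates, rest) {
  structure(list(gates = gates, rest = rest), class = "gating_level")
}

#' A full gating tree
#'
#' @param root a [gating_level()].
#' @param treatment name of the treatment whose intensity space the gate
#'   coordinates live in.
#' @return a `gating_tree`.
#' @export
gating_tree <- function(root, treatment = "arcsinh") {
  structure(list(root = root, treatment = treatment), class = "gating_tree")
}

# Even-odd rule point-in-polygon, vectorized over points.
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

gate_contains <- function(g, vx, vy) {
  if (is.matrix(g$region)) {
    points_in_polygon(vx, vy, g$region)
  } else {
    vx >= g$region[1] & vx <= g$region[2] &
      vy >= g$region[3] & vy <= g$region[4]
  }
}

descend_level <- function(level, m, rows, out) {
  remaining <- rows
  for (g in level$gates) {
    if (length(remaining) == 0) break
    inside <- gate_contains(g, m[remaining, g$marker_x], m[remaining, g$marker_y])
    claimed <- remaining[inside]
    remaining <- remaining[!inside]
    if (length(claimed) == 0) next
    if (is.character(g$then)) {
      out[claimed] <- g$then
    } else {
      out <- descend_level(g$then, m, claimed, out)
    }
  }
  if (length(remaining) > 0) {
    if (is.character(level$rest)) {
      out[remaining] <- level$rest
    } else {
      out <- descend_level(level$rest, m, remaining, out)
    }
  }
  out
}

#' Gate every cell of a table
#'
#' Applies the treatment named in the tree, then descends each cell through
#' the gate hierarchy. Cells with any NA marker value are labelled
#' "ungated" with a warning.
#'
#' @param table a `cell_table`.
#' @param tree a [gating_tree()].
#' @param cfg a [normalization_config()].
#' @return an `annotation_set` with provenance "gated".
#' @export
apply_gating_tree <- function(table, tree, cfg = normalization_config()) {
  m <- apply_treatment(intensity_matrix(table), tree$treatment, cfg)
  m <- unclass(m)
  bad <- which(rowSums(is.na(m)) > 0)
  out <- rep(NA_character_, nrow(m))
  rows <- setdiff(seq_len(nrow(m)), bad)
  out <- descend_level(tree$root, m, rows, out)
  if (length(bad) > 0) {
    warning(length(bad), " cell(s) with NA marker values labelled 'ungated'")
    out[bad] <- "ungated"
  }
  annotation_set(out, provenance = list(kind = "gated",
                                        treatment = tree$treatment))
}

#' Default gating tree for the synthetic panel
#'
#' A hierarchical scheme analogous to manual colon gating: epithelium by
#' cytokeratin first (subtyped by CHGA/MUC2/Ki67), then smooth muscle by
#' aSMA, vasculature by CD31/podoplanin, immune lineages under CD45, plasma
#' cells by CD138, and a fibroblast rest branch. Gates live in arcsinh
#' space; each marker's threshold is the midpoint between its expected
#' background and expected positive level, derived from the panel — so the
#' tree is calibrated on noise-free expectations, not fitted to data.
#'
#' @param panel list of [marker_spec()] (default panel).
#' @param cfg a [normalization_config()] (for the arcsinh cofactor).
#' @return a `gating_tree` in "arcsinh" space.
#' @export
default_gating_tree <- function(panel = default_panel(),
                                cfg = normalization_config()) {
  specs <- stats::setNames(panel, vapply(panel, `[[`, "", "name"))
  thr <- function(mk) {
    s <- specs[[mk]]
    neg <- asinh(s$exposure_scale * s$background_mean / cfg$arcsinh_cofactor)
    pos <- asinh(s$exposure_scale * (s$signal_mean + s$background_mean) /
                   cfg$arcsinh_cofactor)
    (neg + pos) / 2
  }
  pos_rect <- function(mx, my = NULL, thr_y = NULL) {
    if (is.null(my)) c(thr(mx), Inf, -Inf, Inf) else c(thr(mx), Inf, thr(my), Inf)
  }
  epi <- gating_level(list(
    gate("NE", "CHGA", "Cytokeratin", c(thr("CHGA"), Inf, -Inf, Inf),
         "Neuroendocrine cell"),
    gate("Goblet", "MUC2", "Cytokeratin", c(thr("MUC2"), Inf, -Inf, Inf),
         "Goblet cell"),
    gate("TA", "Ki67", "Cytokeratin", c(thr("Ki67"), Inf, -Inf, Inf),
         "Transit amplifying cell")
  ), rest = "Enterocyte")
  cd4 <- gating_level(list(
    gate("CD69+", "CD69", "CD127", c(thr("CD69"), Inf, -Inf, Inf),
         "CD4 T cell CD69+")
  ), rest = "CD4 T cell CD127+")
  immune <- gating_level(list(
    gate("CD4 T", "CD3", "CD4", c(thr("CD3"), Inf, thr("CD4"), Inf), cd4),
    gate("CD8 T", "CD3", "CD8", c(thr("CD3"), Inf, thr("CD8"), Inf),
         "CD8 T cell"),
    gate("B", "CD20", "CD45", c(thr("CD20"), Inf, -Inf, Inf), "B cell"),
    gate("Neutrophil", "CD15", "CD16", c(thr("CD15"), Inf, thr("CD16"), Inf),
         "Neutrophil"),
    gate("Macrophage", "CD68", "CD45", c(thr("CD68"), Inf, -Inf, Inf),
         "Macrophage"),
    gate("DC", "CD11c", "HLA-DR", c(thr("CD11c"), Inf, thr("HLA-DR"), Inf),
         "Dendritic cell"),
    gate("Plasma", "CD138", "CD45", c(thr("CD138"), Inf, -Inf, Inf),
         "Plasma cell")
  ), rest = "Macrophage")
  vasc <- gating_level(list(
    gate("Lymphatic", "Podoplanin", "CD31", c(thr("Podoplanin"), Inf, -Inf, Inf),
         "Lymphatic endothelial cell")
  ), rest = "Endothelial cell")
  root <- gating_level(list(
    gate("Epithelium", "Cytokeratin", "aSMA",
         c(thr("Cytokeratin"), Inf, -Inf, thr("aSMA")), epi),
    gate("Muscle", "aSMA", "CD45", c(thr("aSMA"), Inf, -Inf, Inf),
         "Smooth muscle"),
    gate("Vasculature", "CD31", "CD34", c(thr("CD31"), Inf, -Inf, Inf), vasc),
    gate("Lymphatic2", "Podoplanin", "CD31",
         c(thr("Podoplanin"), Inf, -Inf, Inf), "Lymphatic endothelial cell"),
    gate("Immune", "CD45", "Cytokeratin", c(thr("CD45"), Inf, -Inf, Inf),
         immune),
    gate("Plasma2", "CD138", "CD45", c(thr("CD138"), Inf, -Inf, Inf),
         "Plasma cell")
  ), rest = "Fibroblast")
  gating_tree(root, "arcsinh")
}

#' Spillover-driven gating misassignment rate
#'
#' Fraction of truth-endothelial cells that hierarchical gating assigns to
#' an epithelial leaf — the hallmark failure mode when a cytokeratin-like
#' stain bleeds into adjacent endothelium through imperfect segmentation.
#'
#' @param dataset a `synthetic_dataset` with truth labels.
#' @param tree a [gating_tree()] (default panel tree).
#' @param endothelial_type truth label of the affected population.
#' @return fraction in `[0, 1]`.
#' @export
spillover_misassignment_rate <- function(dataset,
                                         tree = default_gating_tree(),
                                         endothelial_type = "Endothelial cell") {
  is_endo <- dataset$truth == endothelial_type
  stop_if_not(any(is_endo), "no truth-endothelial cells in dataset")
  ann <- apply_gating_tree(dataset$cell_table, tree)
  l4 <- merge_to_level(ann$labels, dataset$hierarchy, 4)
  mean(l4[is_endo] == "Epithelial")
}
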