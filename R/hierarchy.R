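# Four-level cell-type hierarchy: level 1 is the most granular vocabulary,
# level 4 the coarsest. "Noise" exists at every level and maps to itself.

#' Construct a cell-type hierarchy
#'
#' @param levels list of 4 character vectors (label sets, granular to coarse).
#' @param parents list with named character maps `1to2`, `2to3`, `3to4`.
#' @return a `cell_type_hierarchy`.
#' @export
cell_type_hierarchy <- function(levels, parents) {
  h <- structure(list(levels = lapply(levels, as.character), parents = parents),
                 class = "cell_type_hierarchy")
  v <- validate_hierarchy(h)
  if (length(v) > 0) {
    stop("invalid hierarchy:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  h
}

#' Validate a hierarchy
#'
#' Checks that every level-1 label has a complete chain to level 4, that the
#' parent maps are total onto the declared level sets, that level sizes
#' strictly decrease, and that "Noise" is present everywhere and maps to
#' itself.
#'
#' @param h a `cell_type_hierarchy` (or a bare list with the same fields).
#' @return character vector of violations (empty when valid).
#' @export
validate_hierarchy <- function(h) {
  out <- character()
  if (length(h$levels) != 4) return("hierarchy must have exactly 4 levels")
  sizes <- lengths(h$levels)
  if (any(diff(sizes) >= 0)) {
    out <- c(out, sprintf("level sizes must strictly decrease (got %s)",
                          paste(sizes, collapse = " > ")))
  }
  maps <- c("1to2", "2to3", "3to4")
  for (i in 1:3) {
    m <- h$parents[[maps[i]]]
    from <- h$levels[[i]]
    to <- h$levels[[i + 1]]
    orphan <- setdiff(from, names(m))
    for (lb in orphan) {
      out <- c(out, sprintf("orphan: level-%d label '%s' has no parent", i, lb))
    }
    bad <- setdiff(unname(unlist(m[intersect(names(m), from)])), to)
    for (lb in bad) {
      out <- c(out, sprintf("parent '%s' of map %s not in level %d", lb, maps[i], i + 1))
    }
  }
  for (i in 1:4) {
    if (!"Noise" %in% h$levels[[i]]) {
      out <- c(out, sprintf("'Noise' missing from level %d", i))
    }
  }
  for (i in 1:3) {
    if (!identical(unname(h$parents[[maps[i]]]["Noise"]), "Noise")) {
      out <- c(out, sprintf("'Noise' must map to itself in %s", maps[i]))
    }
  }
  out
}

#' Map level-1 labels to a coarser level
#'
#' @param labels character vector of level-1 labels.
#' @param h a `cell_type_hierarchy`.
#' @param level target granularity 1 (identity) to 4 (coarsest).
#' @return character vector of labels at the requested level.
#' @export
merge_to_level <- function(labels, h, level) {
  stop_if_not(level %in% 1:4, "level must be 1..4")
  unknown <- setdiff(unique(labels), h$levels[[1]])
  if (length(unknown) > 0) {
    stop("label(s) not in hierarchy level 1: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (level == 1) return(labels)
  out <- labels
  maps <- c("1to2", "2to3", "3to4")
  for (i in seq_len(level - 1)) {
    out <- unname(h$parents[[maps[i]]][out])
  }
  out
}

#' Distinct label counts at each level
#' @param h a `cell_type_hierarchy`.
#' @return integer vector of length 4.
#' @export
hierarchy_level_counts <- function(h) {
  counts <- integer(4)
  l <- h$levels[[1]]
  for (lv in 1:4) {
    counts[lv] <- length(unique(merge_to_level(l, h, lv)))
  }
  counts
}

read_hierarchy_file <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  parents <- lapply(raw$parents, function(m) {
    v <- unlist(m)
    stats::setNames(as.character(v), names(v))
  })
  cell_type_hierarchy(raw$levels, parents)
}

#' Read a hierarchy from JSON
#' @param path JSON file with `levels` and `parents` fields.
#' @return a `cell_type_hierarchy`.
#' @export
read_hierarchy <- function(path) read_hierarchy_file(path)

#' Write a hierarchy to JSON
#' @param h a `cell_type_hierarchy`.
#' @param path output file.
#' @export
write_hierarchy <- function(h, path) {
  jsonlite::write_json(list(levels = h$levels,
                            parents = lapply(h$parents, as.list)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Hierarchy of the synthetic panel
#'
#' 17 level-1 labels (16 types plus "Noise") merging to 13, 8 and 6 labels.
#'
#' @return a `cell_type_hierarchy`.
#' @export
synthetic_hierarchy <- function() {
  read_hierarchy_file(fixture_path("synthetic_hierarchy.json"))
}

#' Reconstructed colon cell-type hierarchy
#'
#' A best-effort reconstruction of the four-granularity colon ontology used
#' for the level-count checks: 35 granular types (including "Noise") merging
#' to 20, 14 and 7. See the fixture file header for its provenance notes.
#'
#' @return a `cell_type_hierarchy`.
#' @export
colon_hierarchy <- function() {
  read_hierarchy_file(fixture_path("colon_hierarchy.json"))
}
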