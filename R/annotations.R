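# Polygon annotations in the two common WSI dialects: ASAP XML (the
# `PartOfGroup` attribute carries the class) and GeoJSON (QuPath-style
# `properties.classification.name`).

#' Construct an annotation set
#'
#' @param regions List of regions; each a list with `polygon` (two-column
#'   vertex matrix, level-0 pixel coordinates, treated as closed) and
#'   `class_label` (one of [wsi_classes()]), optionally `name`.
#' @param source_dialect `"asap_xml"`, `"geojson"` or `"memory"`.
#' @param mpp Optional microns-per-pixel of the annotated slide's level 0;
#'   used by patch extraction to map footprints across magnifications.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(regions = list(), source_dialect = "memory",
                           mpp = NA_real_) {
  for (r in regions) {
    if (!r$class_label %in% WSI_CLASSES)
      stop("unknown class label: ", r$class_label)
    if (nrow(r$polygon) < 3) stop("polygon needs >= 3 vertices")
  }
  structure(list(regions = regions, source_dialect = source_dialect,
                 mpp = mpp),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d region(s) [%s]\n", length(x$regions),
              x$source_dialect))
  if (length(x$regions)) {
    tab <- table(vapply(x$regions, `[[`, "", "class_label"))
    for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$regions)

annotation_classes <- function(ann)
  vapply(ann$regions, `[[`, "", "class_label")

#' Write annotations to disk
#'
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @param dialect `"asap_xml"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, dialect = c("asap_xml", "geojson")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ann, "annotation_set"))
  if (dialect == "asap_xml") {
    doc <- xml2::xml_new_root("ASAP_Annotations")
    anns <- xml2::xml_add_child(doc, "Annotations")
    for (i in seq_along(ann$regions)) {
      r <- ann$regions[[i]]
      a <- xml2::xml_add_child(anns, "Annotation",
                               Name = r$name %||% sprintf("region_%d", i),
                               Type = "Polygon", PartOfGroup = r$class_label,
                               Color = "#F4FA58")
      coords <- xml2::xml_add_child(a, "Coordinates")
      for (v in seq_len(nrow(r$polygon))) {
        xml2::xml_add_child(coords, "Coordinate", Order = as.character(v - 1),
                            X = format(r$polygon[v, 1], digits = 10),
                            Y = format(r$polygon[v, 2], digits = 10))
      }
    }
    groups <- xml2::xml_add_child(doc, "AnnotationGroups")
    for (cl in unique(annotation_classes(ann)))
      xml2::xml_add_child(groups, "Group", Name = cl, PartOfGroup = "None",
                          Color = "#64FE2E")
    xml2::write_xml(doc, path)
  } else {
    feats <- lapply(seq_along(ann$regions), function(i) {
      r <- ann$regions[[i]]
      ring <- rbind(r$polygon, r$polygon[1, , drop = FALSE])  # closed ring
      list(type = "Feature",
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                             function(v) c(ring[v, 1], ring[v, 2])))),
           properties = list(name = r$name %||% sprintf("region_%d", i),
                             classification = list(name = r$class_label)))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read annotations from disk
#'
#' Unknown class names abort unless `class_map` (a named character vector,
#' file label -> vocabulary label) resolves them.
#'
#' @param path Annotation file.
#' @param dialect `"asap_xml"` or `"geojson"`.
#' @param class_map Optional named character vector mapping foreign class
#'   names onto [wsi_classes()].
#' @param mpp Optional level-0 mpp to attach.
#' @return An `annotation_set`; vertex order is preserved.
#' @export
read_annotations <- function(path, dialect = c("asap_xml", "geojson"),
                             class_map = NULL, mpp = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  map_class <- function(cl) {
    if (cl %in% WSI_CLASSES) return(cl)
    if (!is.null(class_map) && cl %in% names(class_map)) {
      mapped <- unname(class_map[[cl]])
      if (mapped %in% WSI_CLASSES) return(mapped)
    }
    stop("unknown class '", cl, "' and no mapping provided")
  }
  regions <- list()
  if (dialect == "asap_xml") {
    doc <- xml2::read_xml(path)
    for (a in xml2::xml_find_all(doc, ".//Annotation")) {
      cl <- map_class(xml2::xml_attr(a, "PartOfGroup"))
      cs <- xml2::xml_find_all(a, ".//Coordinate")
      ord <- order(as.numeric(xml2::xml_attr(cs, "Order")))
      poly <- cbind(x = as.numeric(xml2::xml_attr(cs, "X"))[ord],
                    y = as.numeric(xml2::xml_attr(cs, "Y"))[ord])
      regions[[length(regions) + 1]] <-
        list(polygon = poly, class_label = cl,
             name = xml2::xml_attr(a, "Name"))
    }
  } else {
    js <- jsonlite::read_json(path)
    for (f in js$features) {
      ring <- f$geometry$coordinates[[1]]
      poly <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
      colnames(poly) <- c("x", "y")
      # drop the GeoJSON closing vertex (duplicate of the first)
      if (nrow(poly) > 3 && all(poly[1, ] == poly[nrow(poly), ]))
        poly <- poly[-nrow(poly), , drop = FALSE]
      cl <- map_class(f$properties$classification$name)
      regions[[length(regions) + 1]] <-
        list(polygon = poly, class_label = cl,
             name = f$properties$name %||% "region")
    }
  }
  annotation_set(regions, source_dialect = dialect, mpp = mpp)
}
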