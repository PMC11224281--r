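#' Read a labeled image dataset from a class-per-directory tree
#'
#' Reads images laid out as `<root>/<class>/<image>` into the labeled-image
#' tibble used throughout the package. PNG images (read with the \pkg{png}
#' package) are converted to grayscale luminance
#' (0.299 R + 0.587 G + 0.114 B); `.csv` files are read as plain pixel
#' matrices (the format written by the command-line `synth` tool). Pixel
#' values are clamped to \[0, 1\].
#'
#' @param root Directory whose sub-directories name the classes.
#' @param classes Optional class subset/order; default all sub-directories,
#'   sorted.
#' @return Tibble with columns `image`, `label` (factor over `classes`) and
#'   `provenance = "original"`.
#' @export
read_image_dataset <- function(root, classes = NULL) {
  stopifnot(dir.exists(root))
  if (is.null(classes)) {
    classes <- sort(basename(list.dirs(root, recursive = FALSE)))
  }
  if (length(classes) == 0) stop("no class sub-directories under '", root, "'")
  rows <- lapply(classes, function(cls) {
    files <- sort(list.files(file.path(root, cls),
                             pattern = "\\.(png|csv)$", ignore.case = TRUE,
                             full.names = TRUE))
    tibble::tibble(
      image = lapply(files, .read_one_image),
      label = rep(cls, length(files))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no .png or .csv images found under '", root, "'")
  out$label <- factor(out$label, levels = classes)
  out$provenance <- "original"
  out
}

.read_one_image <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    img <- as.matrix(utils::read.csv(path))
    dimnames(img) <- NULL
  } else {
    px <- png::readPNG(path)
    img <- if (length(dim(px)) == 3) {
      0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      px
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Read Pascal-VOC XML annotations
#'
#' Parses the bounding-box ground truth attached to a smear image. Boxes use
#' the Pascal-VOC convention: integer pixel coordinates, 1-based and
#' inclusive, with `xmin < xmax` and `ymin < ymax`.
#'
#' @param path Path to a Pascal-VOC XML file.
#' @return Tibble with one row per annotated object: `label`, `xmin`,
#'   `ymin`, `xmax`, `ymax` (integers). Zero rows if the file annotates no
#'   objects.
#' @export
read_voc_annotations <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop("failed to parse VOC XML '", path, "': ", conditionMessage(e))
    }
  )
  objs <- xml2::xml_find_all(doc, ".//object")
  get_num <- function(node, field) {
    v <- xml2::xml_text(xml2::xml_find_first(node, paste0(".//", field)))
    out <- suppressWarnings(as.integer(round(as.numeric(v))))
    if (is.na(out)) {
      stop("VOC file '", path, "': object is missing a numeric <", field, ">")
    }
    out
  }
  rows <- lapply(objs, function(o) {
    box <- tibble::tibble(
      label = xml2::xml_text(xml2::xml_find_first(o, ".//name")),
      xmin = get_num(o, "xmin"), ymin = get_num(o, "ymin"),
      xmax = get_num(o, "xmax"), ymax = get_num(o, "ymax")
    )
    if (box$xmin >= box$xmax || box$ymin >= box$ymax) {
      stop("VOC file '", path, "': invalid box [", box$xmin, ",", box$ymin,
           ",", box$xmax, ",", box$ymax, "] (min must be below max)")
    }
    box
  })
  if (length(rows) == 0) {
    return(tibble::tibble(label = character(), xmin = integer(),
                          ymin = integer(), xmax = integer(),
                          ymax = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Write Pascal-VOC XML annotations
#'
#' Inverse of [read_voc_annotations()]: writes a minimal Pascal-VOC
#' annotation file that re-parses to the same object table.
#'
#' @param objects Tibble/data frame with columns `label`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (1-based inclusive pixel coordinates).
#' @param path Output file path.
#' @param filename Image file name recorded in the annotation.
#' @param width,height,depth Image size recorded in the annotation.
#' @return `path`, invisibly.
#' @export
write_voc_annotations <- function(objects, path, filename = "image.jpg",
                                  width = 0, height = 0, depth = 3) {
  stopifnot(is.data.frame(objects),
            all(c("label", "xmin", "ymin", "xmax", "ymax") %in% names(objects)))
  root <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(root, "filename", filename)
  size <- xml2::xml_add_child(root, "size")
  xml2::xml_add_child(size, "width", as.character(width))
  xml2::xml_add_child(size, "height", as.character(height))
  xml2::xml_add_child(size, "depth", as.character(depth))
  for (i in seq_len(nrow(objects))) {
    if (objects$xmin[i] >= objects$xmax[i] ||
        objects$ymin[i] >= objects$ymax[i]) {
      stop("invalid box in row ", i, ": min must be below max")
    }
    o <- xml2::xml_add_child(root, "object")
    xml2::xml_add_child(o, "name", as.character(objects$label[i]))
    b <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(b, "xmin", as.character(as.integer(objects$xmin[i])))
    xml2::xml_add_child(b, "ymin", as.character(as.integer(objects$ymin[i])))
    xml2::xml_add_child(b, "xmax", as.character(as.integer(objects$xmax[i])))
    xml2::xml_add_child(b, "ymax", as.character(as.integer(objects$ymax[i])))
  }
  xml2::write_xml(root, path)
  invisible(path)
}
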