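# On-disk artifact plumbing: roLabelImg-dialect rotated-box XML, the CSV
# manifest tying images/masks/annotations to shark IDs and series labels,
# and the photographic cleaning pass (duplicates, low resolution, blur).

#' Construct a rotated patch box
#'
#' Coordinates are 0-based pixel centers (x rightward, y downward); `angle`
#' is in radians, clockwise positive, normalized into `[0, 2*pi)`; the box
#' x-axis (the `w` extent) points toward the shark's head.
#'
#' @param patch_type One of `"head"`, `"pec"`, `"FDF"`, `"FDB"`.
#' @param cx,cy Box center, pixels.
#' @param w,h Extents along/perpendicular to the box x-axis (> 0).
#' @param angle Rotation of the box x-axis from the image x-axis, radians.
#' @return A `RotatedBox` list.
#' @export
rotated_box <- function(patch_type, cx, cy, w, h, angle) {
  if (!patch_type %in% PATCH_TYPES)
    stopf("unrecognized patch label '%s' (expected one of %s)", patch_type,
          paste(PATCH_TYPES, collapse = ", "))
  if (w <= 0 || h <= 0) stopf("box extents must be positive")
  angle <- ((angle %% (2 * pi)) + 2 * pi) %% (2 * pi)
  structure(list(patch_type = patch_type, cx = cx, cy = cy, w = w, h = h,
                 angle = angle, head_side = "along_box_x"),
            class = "RotatedBox")
}

#' Read rotated-box annotations from a roLabelImg-dialect XML file
#'
#' @param xml_path Path to an annotation XML with
#'   `annotation/object/robndbox{cx,cy,w,h,angle}` nodes.
#' @return Named list of `RotatedBox`, one per recognized patch label.
#' @export
read_rolabelimg <- function(xml_path) {
  doc <- xml2::read_xml(xml_path)
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- list()
  for (ob in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(ob, "./name"))
    if (!nm %in% PATCH_TYPES)
      stopf("unrecognized patch label '%s' in %s", nm, xml_path)
    if (nm %in% names(boxes))
      stopf("duplicate patch label '%s' in %s", nm, xml_path)
    rb <- xml2::xml_find_first(ob, "./robndbox")
    if (is.na(xml2::xml_name(rb)))
      stopf("object '%s' in %s has no robndbox node", nm, xml_path)
    fld <- function(f) {
      node <- xml2::xml_find_first(rb, paste0("./", f))
      if (is.na(xml2::xml_name(node)))
        stopf("robndbox of '%s' in %s is missing field '%s'", nm, xml_path, f)
      as.numeric(xml2::xml_text(node))
    }
    boxes[[nm]] <- rotated_box(nm, fld("cx"), fld("cy"), fld("w"), fld("h"),
                               fld("angle"))
  }
  boxes
}

#' Write rotated-box annotations as roLabelImg-dialect XML
#'
#' @param boxes Named or unnamed list of exactly four `RotatedBox`, one per
#'   patch type.
#' @param image_path Path of the annotated image (recorded in the XML).
#' @param xml_path Output XML path.
#' @export
write_rolabelimg <- function(boxes, image_path, xml_path) {
  types <- vapply(boxes, function(b) b$patch_type, character(1))
  missing <- setdiff(PATCH_TYPES, types)
  if (length(missing))
    stopf("missing patch type(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(types))
    stopf("duplicate patch type(s): %s",
          paste(unique(types[duplicated(types)]), collapse = ", "))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", basename(image_path))
  xml2::xml_add_child(doc, "path", image_path)
  for (b in boxes) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", b$patch_type)
    xml2::xml_add_child(ob, "type", "robndbox")
    rb <- xml2::xml_add_child(ob, "robndbox")
    for (f in c("cx", "cy", "w", "h", "angle"))
      xml2::xml_add_child(rb, f, sprintf("%.12f", b[[f]]))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

MANIFEST_HEADER <- c("image_path", "mask_path", "annotation_path",
                     "shark_id", "life_stage", "series", "time_marker")

validate_manifest <- function(df, path = "<manifest>") {
  if (!identical(names(df), MANIFEST_HEADER))
    stopf("%s: header must be exactly '%s'", path,
          paste(MANIFEST_HEADER, collapse = ","))
  for (i in seq_len(nrow(df))) {
    s <- df$series[i]; tm <- df$time_marker[i]
    if (!s %in% c("baseline", "time"))
      stopf("%s row %d: series '%s' invalid", path, i, s)
    if (s == "time" && !grepl("^T[0-9]+$", tm))
      stopf("%s row %d: time series requires marker T<n>, got '%s'",
            path, i, tm)
    if (s == "baseline" && nzchar(tm))
      stopf("%s row %d: baseline rows must have empty time_marker, got '%s'",
            path, i, tm)
  }
  invisible(df)
}

#' Read and validate a dataset manifest CSV
#'
#' @param csv_path Manifest path.
#' @return Data frame with the canonical manifest columns; rows are
#'   validated (series/time-marker invariants) with row-indexed errors.
#' @export
read_manifest <- function(csv_path) {
  df <- utils::read.csv(csv_path, colClasses = "character")
  df$time_marker[is.na(df$time_marker)] <- ""
  validate_manifest(df, csv_path)
}

#' Write a dataset manifest CSV
#'
#' @param rows Data frame with the canonical manifest columns.
#' @param csv_path Output path.
#' @export
write_manifest <- function(rows, csv_path) {
  validate_manifest(rows)
  utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Variance-of-Laplacian sharpness of an image
#'
#' @param img `H x W x 3` array in `[0, 1]` (or an `H x W` matrix).
#' @return Non-negative scalar; 0 for a uniform image, larger = sharper.
#' @export
laplacian_sharpness <- function(img) {
  g <- if (length(dim(img)) == 3L)
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3] else img
  H <- nrow(g); W <- ncol(g)
  if (H < 3 || W < 3) return(0)
  core <- g[2:(H - 1), 2:(W - 1)]
  lap <- g[1:(H - 2), 2:(W - 1)] + g[3:H, 2:(W - 1)] +
         g[2:(H - 1), 1:(W - 2)] + g[2:(H - 1), 3:W] - 4 * core
  stats::var(as.vector(lap))
}

#' Clean a photographic dataset
#'
#' Applies the curation rules used before training: drop byte-identical
#' duplicates (first occurrence kept), images whose shorter side is below
#' `min_side`, images whose variance-of-Laplacian sharpness falls below
#' `blur_threshold`, unreadable files, and rows carrying an upstream
#' `exclude` flag (manual curation, e.g. non-dorsal orientation).
#'
#' @param rows Manifest data frame (optionally with a logical/`"1"`-coded
#'   `exclude` column).
#' @param min_side Minimum acceptable shorter image side, pixels.
#' @param blur_threshold Minimum acceptable sharpness (variance of
#'   Laplacian).
#' @return List with `kept` (manifest rows) and `rejected` (data frame of
#'   `image_path`, `reason`).
#' @export
clean_dataset <- function(rows, min_side = 380, blur_threshold = 1e-5) {
  exclude <- if ("exclude" %in% names(rows))
    rows$exclude %in% c(TRUE, "TRUE", "1", "yes") else rep(FALSE, nrow(rows))
  keep <- rep(TRUE, nrow(rows))
  reasons <- character(0); rej_paths <- character(0)
  seen_hash <- character(0)
  reject <- function(i, why) {
    keep[i] <<- FALSE
    rej_paths <<- c(rej_paths, rows$image_path[i])
    reasons <<- c(reasons, why)
  }
  for (i in seq_len(nrow(rows))) {
    if (exclude[i]) { reject(i, "excluded"); next }
    p <- rows$image_path[i]
    img <- tryCatch(read_image(p), error = function(e) NULL)
    if (is.null(img)) { reject(i, "unreadable"); next }
    h <- unname(tools::md5sum(p))
    if (h %in% seen_hash) { reject(i, "duplicate"); next }
    seen_hash <- c(seen_hash, h)
    if (min(dim(img)[1:2]) < min_side) { reject(i, "low_resolution"); next }
    if (laplacian_sharpness(img) < blur_threshold) { reject(i, "blurry"); next }
  }
  list(kept = rows[keep, setdiff(names(rows), "exclude"), drop = FALSE],
       rejected = data.frame(image_path = rej_paths, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Numeric index of a time marker (`"T10"` -> 10)
#' @param marker Marker string.
#' @return Integer index; errors on malformed markers.
#' @export
time_marker_index <- function(marker) {
  if (!all(grepl("^T[0-9]+$", marker)))
    stopf("malformed time marker(s): %s",
          paste(marker[!grepl("^T[0-9]+$", marker)], collapse = ", "))
  as.integer(sub("^T", "", marker))
}
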