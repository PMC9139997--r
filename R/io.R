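# Input/output: JSON shape specifications (lossless round trip of the part
# tree and growth realizations), SVG/PNG stimulus rendering, and CSV
# trial/response tables. All outputs are deterministic given seed and
# config (no timestamps inside data files).

SHAPE_SCHEMA_VERSION <- "1.0"

#' Serialize a shape to a JSON document
#'
#' Writes the body parameters and the full part tree (attachment, side,
#' angular deviations, segment lengths, width parameters) so that
#' [load_shape()] regenerates the silhouette exactly.
#'
#' @param shp A `shape`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
serialize_shape <- function(shp, path = NULL) {
  stopifnot(inherits(shp, "shape"))
  doc <- list(
    schema_version = SHAPE_SCHEMA_VERSION,
    body = list(width = shp$body$width,
                width_profile = shp$body$width_profile),
    parts = lapply(shp$parts, function(p) {
      list(id = p$id, parent = p$parent, order = p$order,
           attach_t = p$attach_t, side = p$side,
           dev0_deg = p$dev0_deg, turns_deg = as.numeric(p$turns_deg),
           seg_lengths = as.numeric(p$seg_lengths),
           base_width = p$base_width,
           pair_id = p$pair_id, size_scale = p$size_scale,
           params = unclass(p$params))
    }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Load a shape from a JSON document
#'
#' Regenerates the shape from a [serialize_shape()] document; the silhouette
#' matches the original to floating-point accuracy. Unknown extra fields are
#' accepted with a warning; a schema-version mismatch is an error.
#'
#' @param json A JSON string or the path of a JSON file.
#' @param compose Compose the silhouette after loading?
#' @return A `shape`.
#' @export
load_shape <- function(json, compose = TRUE) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(doc$schema_version) ||
      !identical(doc$schema_version, SHAPE_SCHEMA_VERSION))
    stop("shape schema version mismatch: found `",
         if (is.null(doc$schema_version)) "<none>" else doc$schema_version,
         "`, expected `", SHAPE_SCHEMA_VERSION, "`", call. = FALSE)
  extra <- setdiff(names(doc), c("schema_version", "body", "parts"))
  if (length(extra))
    warning("ignoring unknown fields: ", paste(extra, collapse = ", "),
            call. = FALSE)
  body <- main_body(width = doc$body$width,
                    width_profile = unlist(doc$body$width_profile))
  shp <- shape(body, compose = FALSE)
  for (p in doc$parts) {
    params <- do.call(growth_params, c(
      p$params[c("angle_range_deg", "n_joints", "taper", "rel_width",
                 "rel_length", "angle_min_deg")],
      list(seg_length_range = unlist(p$params$seg_length_range),
           width_profile = unlist(p$params$width_profile))))
    shp$parts[[p$id]] <- new_limb(
      id = p$id, parent = p$parent, order = p$order, attach_t = p$attach_t,
      side = p$side, dev0_deg = p$dev0_deg,
      turns_deg = as.numeric(unlist(p$turns_deg)),
      seg_lengths = as.numeric(unlist(p$seg_lengths)),
      params = params, base_width = p$base_width,
      pair_id = if (is.null(p$pair_id)) NA_character_ else p$pair_id,
      size_scale = if (is.null(p$size_scale)) NA_real_ else p$size_scale)
  }
  if (compose) compose_shape(shp) else shp
}

#' Rendering configuration
#'
#' @param canvas Canvas size in pixels (square, >= 64).
#' @param margin Margin fraction on each side, in `[0, 0.4)`.
#' @param fill Fill color of the silhouette (SVG color string).
#' @param background Background color.
#' @param skeleton_overlay Draw the skeletal paths and joints on top?
#' @return Object of class `render_config`.
#' @export
render_config <- function(canvas = 512L, margin = 0.08, fill = "#1a1a1a",
                          background = "#ffffff", skeleton_overlay = FALSE) {
  canvas <- as.integer(canvas)
  if (canvas < 64L) stop("`canvas` must be >= 64 px", call. = FALSE)
  if (margin < 0 || margin >= 0.4) stop("`margin` must lie in [0, 0.4)", call. = FALSE)
  structure(list(canvas = canvas, margin = margin, fill = fill,
                 background = background,
                 skeleton_overlay = isTRUE(skeleton_overlay)),
            class = "render_config")
}

# Map canvas-unit coordinates into pixel space (y flipped for SVG).
canvas_transform <- function(shp, config) {
  sil <- silhouette(shp)
  bb <- apply(sil, 2, range)
  span <- max(bb[2, ] - bb[1, ])
  usable <- config$canvas * (1 - 2 * config$margin)
  sc <- usable / span
  cx <- mean(bb[, 1]); cy <- mean(bb[, 2])
  list(fx = function(x) (x - cx) * sc + config$canvas / 2,
       fy = function(y) config$canvas / 2 - (y - cy) * sc)
}

#' Write a shape silhouette to an SVG file
#'
#' The silhouette is a single filled path (no stroke), centered with the
#' configured margin; the optional overlay draws the skeletal paths and
#' joints of every part.
#'
#' @param shp A composed `shape`.
#' @param path Output file path.
#' @param config A [render_config()].
#' @return The output path, invisibly.
#' @export
shape_to_svg <- function(shp, path, config = render_config()) {
  tr <- canvas_transform(shp, config)
  sil <- silhouette(shp)
  d <- paste0("M ", paste(sprintf("%.3f %.3f", tr$fx(sil[, 1]), tr$fy(sil[, 2])),
                          collapse = " L "), " Z")
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            config$canvas, config$canvas, config$canvas, config$canvas),
    sprintf('<rect width="%d" height="%d" fill="%s"/>',
            config$canvas, config$canvas, config$background),
    sprintf('<path d="%s" fill="%s" stroke="none"/>', d, config$fill))
  if (config$skeleton_overlay) {
    for (id in names(shp$geom$paths)) {
      pth <- shp$geom$paths[[id]]
      pts <- paste(sprintf("%.3f,%.3f", tr$fx(pth[, 1]), tr$fy(pth[, 2])),
                   collapse = " ")
      lines <- c(lines, sprintf(
        '<polyline points="%s" fill="none" stroke="#2060c0" stroke-width="1.5"/>', pts))
      j <- shp$geom$joints[[id]]
      lines <- c(lines, sprintf(
        '<circle cx="%.3f" cy="%.3f" r="2.5" fill="#c02020"/>',
        tr$fx(j[, 1]), tr$fy(j[, 2])))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Rasterize a shape silhouette to a PNG file
#'
#' Renders by point-in-polygon sampling at pixel centers (deterministic, no
#' graphics device required).
#'
#' @inheritParams shape_to_svg
#' @return The output path invisibly, with attribute `"foreground"` giving
#'   the foreground pixel fraction.
#' @export
shape_to_png <- function(shp, path, config = render_config()) {
  tr <- canvas_transform(shp, config)
  n <- config$canvas
  px <- seq(0.5, n - 0.5, by = 1)
  grid <- cbind(rep(px, each = n), rep(px, times = n))  # (x, y) pixel centers
  sil <- silhouette(shp)
  poly_px <- cbind(tr$fx(sil[, 1]), tr$fy(sil[, 2]))
  inside <- points_in_poly(grid, poly_px)
  img <- matrix(1, nrow = n, ncol = n)  # white background
  img[cbind(grid[inside, 2] + 0.5, grid[inside, 1] + 0.5)] <- 0.1
  png::writePNG(img, path)
  out <- invisible(path)
  attr(out, "foreground") <- mean(inside)
  out
}

#' Write a trial or response table to CSV
#'
#' UTF-8, comma-separated, header row, `.` decimal; stable column order.
#'
#' @param table Data frame (e.g. from [trial_table()] or the simulators).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trials <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a response table from CSV
#'
#' Checks that 2-AFC choices are `"left"`/`"right"` and slider ratings lie
#' in `[0, 1]`; offending rows are reported by index in the error message.
#'
#' @param path CSV file path.
#' @return Data frame of class `response_table`.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- character(0)
  if ("choice" %in% names(df)) {
    bad <- which(!df$choice %in% c("left", "right"))
    if (length(bad))
      problems <- c(problems, paste0("invalid choice in row(s) ",
                                     paste(bad, collapse = ", ")))
  }
  if ("rating" %in% names(df)) {
    bad <- which(!is.finite(df$rating) | df$rating < 0 | df$rating > 1)
    if (length(bad))
      problems <- c(problems, paste0("rating outside [0, 1] in row(s) ",
                                     paste(bad, collapse = ", ")))
  }
  if (!any(c("choice", "rating", "chose_b") %in% names(df)))
    problems <- c(problems, "no `choice`, `chose_b` or `rating` column found")
  if (length(problems))
    stop("invalid response table: ", paste(problems, collapse = "; "),
         call. = FALSE)
  class(df) <- c("response_table", class(df))
  df
}
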