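# File formats. Images travel as portable anymaps (PGM/PPM, both ASCII and
# binary variants) — self-describing, dependency-free and good enough for
# fixtures and pipeline artifacts. Annotations travel as either the
# package's detection CSV dialect or YOLO-txt normalized boxes.

#' Write an image as a PGM/PPM file
#'
#' Grayscale matrices become PGM, RGB arrays become PPM; `ascii = TRUE`
#' writes the plain-text variants (P2/P3), otherwise binary (P5/P6).
#'
#' @param img A [frame()], RGB array or grayscale matrix, values `[0, 255]`.
#' @param path Output file path.
#' @param ascii Write the plain-text variant? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  px <- as_pixels(img)
  rgb <- !is.matrix(px)
  vals <- if (rgb) {
    aperm(px, c(3, 2, 1))   # interleave channels, row-major
  } else {
    t(px)
  }
  vals <- as.integer(round_half_up(clamp255(as.numeric(vals))))
  h <- if (rgb) dim(px)[1] else nrow(px)
  w <- if (rgb) dim(px)[2] else ncol(px)
  magic <- if (ascii) (if (rgb) "P3" else "P2") else (if (rgb) "P6" else "P5")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(magic, paste(w, h), "255"), con, sep = "\n")
  if (ascii) {
    writeLines(paste(vals, collapse = "\n"), con)
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Read a PGM/PPM file
#'
#' Supports P2/P3 (ASCII) and P5/P6 (binary) with 8-bit depth.
#'
#' @param path File path.
#' @return A grayscale matrix (PGM) or RGB array (PPM).
#' @export
read_pnm <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") {
        if (nzchar(tok)) return(tok)
        stop(sprintf("truncated PNM header in '%s'", path))
      }
      if (ch == "#") {           # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop(sprintf("'%s' is not an 8-bit PGM/PPM image (magic %s)", path, magic))
  }
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval > 255) {
    stop(sprintf("unsupported PNM header in '%s'", path))
  }
  rgb <- magic %in% c("P3", "P6")
  nvals <- w * h * if (rgb) 3L else 1L
  vals <- if (magic %in% c("P2", "P3")) {
    as.integer(scan(con, what = integer(), n = nvals, quiet = TRUE))
  } else {
    as.integer(readBin(con, "raw", n = nvals))
  }
  if (length(vals) < nvals) stop(sprintf("truncated pixel data in '%s'", path))
  if (rgb) {
    aperm(array(as.numeric(vals), dim = c(3L, w, h)), c(3, 2, 1))
  } else {
    t(matrix(as.numeric(vals), w, h))
  }
}

#' Read frames from a directory of images
#'
#' Loads every `.pgm`/`.ppm` file in lexicographic order and assigns frame
#' indices 0, 1, 2, ... Grayscale images are promoted to RGB. Decoding
#' video containers is out of scope in this dependency-free build: extract
#' frames to images first (e.g. `ffmpeg -i video.mp4 frames/f_%04d.ppm`).
#'
#' @param path Directory containing images.
#' @param source_id Source label; defaults to the directory name.
#' @return A list of [frame()] objects.
#' @export
read_frames <- function(path, source_id = basename(normalizePath(path))) {
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      stop(sprintf(paste0("'%s' is a file, not a directory; video decoding ",
                          "is not supported — extract frames to PGM/PPM ",
                          "images first"), path))
    }
    stop(sprintf("path '%s' does not exist", path))
  }
  files <- sort(list.files(path, pattern = "\\.(pgm|ppm)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("directory '%s' contains no PGM/PPM images", path))
  }
  lapply(seq_along(files), function(i) {
    px <- read_pnm(files[i])
    if (is.matrix(px)) {
      px <- array(rep(px, 3L), dim = c(dim(px), 3L))
    }
    frame(px, source_id, i - 1L)
  })
}

#' Write detection results as CSV
#'
#' Dialect: header `source_id,frame_index,x_min,y_min,x_max,y_max,score,method`;
#' a row with empty geometry cells encodes "no detection".
#'
#' @param detections A list of `detection_result` objects.
#' @param frames The corresponding list of [frame()]s (for identity columns).
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_detections_csv <- function(detections, frames, path) {
  stopifnot(length(detections) == length(frames))
  rows <- lapply(seq_along(detections), function(i) {
    d <- detections[[i]]; f <- frames[[i]]
    if (is.null(d$bbox)) {
      data.frame(source_id = f$source_id, frame_index = f$index,
                 x_min = NA_integer_, y_min = NA_integer_,
                 x_max = NA_integer_, y_max = NA_integer_,
                 score = NA_real_, method = d$method,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(source_id = f$source_id, frame_index = f$index,
                 x_min = d$bbox[["x_min"]], y_min = d$bbox[["y_min"]],
                 x_max = d$bbox[["x_max"]], y_max = d$bbox[["y_max"]],
                 score = if (is.null(attr(d$circle, "score"))) NA_real_
                         else attr(d$circle, "score"),
                 method = d$method, stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}

#' Read bounding-box annotations
#'
#' Two dialects: `csv` rows are `image_id,x_min,y_min,x_max,y_max`
#' (half-open pixel coordinates, with or without a header); `yolo` rows are
#' `class cx cy w h` with all but class normalized to `[0, 1]`, converted
#' via `x_min = round((cx - w/2) * img_w)` etc. (one object per line; the
#' image id is the file's base name).
#'
#' @param path Annotation file.
#' @param dialect `"csv"` or `"yolo"`.
#' @param img_w,img_h Image dimensions, required for the YOLO dialect.
#' @return A named list of [bbox()] keyed by image id.
#' @export
read_annotations <- function(path, dialect = c("csv", "yolo"),
                             img_w = NULL, img_h = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("annotation file '%s' not found", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "csv") {
    first <- strsplit(lines[1], ",")[[1]]
    if (suppressWarnings(anyNA(as.numeric(first[-1])))) lines <- lines[-1]
    out <- list()
    for (ln in seq_along(lines)) {
      parts <- trimws(strsplit(lines[ln], ",")[[1]])
      parts <- gsub('^"|"$', "", parts)
      if (length(parts) != 5L) {
        stop(sprintf("%s:%d: expected 'id,x_min,y_min,x_max,y_max'", path, ln))
      }
      coords <- suppressWarnings(as.numeric(parts[2:5]))
      if (anyNA(coords)) {
        stop(sprintf("%s:%d: non-numeric coordinates", path, ln))
      }
      out[[parts[1]]] <- bbox(coords[1], coords[2], coords[3], coords[4])
    }
    out
  } else {
    if (is.null(img_w) || is.null(img_h)) {
      stop("YOLO dialect requires img_w and img_h")
    }
    out <- list()
    for (ln in seq_along(lines)) {
      parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(parts) != 5L) {
        stop(sprintf("%s:%d: expected 'class cx cy w h'", path, ln))
      }
      v <- suppressWarnings(as.numeric(parts))
      if (anyNA(v)) stop(sprintf("%s:%d: non-numeric values", path, ln))
      if (any(v[2:5] < 0) || any(v[2:5] > 1)) {
        stop(sprintf("%s:%d: normalized values outside [0, 1]", path, ln))
      }
      id <- sub("\\.[^.]*$", "", basename(path))
      if (length(lines) > 1L) id <- sprintf("%s#%d", id, ln - 1L)
      out[[id]] <- bbox(round((v[2] - v[4] / 2) * img_w),
                        round((v[3] - v[5] / 2) * img_h),
                        round((v[2] + v[4] / 2) * img_w),
                        round((v[3] + v[5] / 2) * img_h))
    }
    out
  }
}

#' Write a bounding box in YOLO-txt normalized form
#'
#' One line per box: `class cx cy w h`, all but class normalized by the
#' image dimensions.
#'
#' @param boxes A list of [bbox()].
#' @param path Output file.
#' @param img_w,img_h Image dimensions.
#' @param class_id Object class index (default 0).
#' @return `path`, invisibly.
#' @export
write_yolo <- function(boxes, path, img_w, img_h, class_id = 0L) {
  lines <- vapply(boxes, function(b) {
    sprintf("%d %.6f %.6f %.6f %.6f", class_id,
            (b[["x_min"]] + b[["x_max"]]) / 2 / img_w,
            (b[["y_min"]] + b[["y_max"]]) / 2 / img_h,
            (b[["x_max"]] - b[["x_min"]]) / img_w,
            (b[["y_max"]] - b[["y_min"]]) / img_h)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write homographies as CSV
#'
#' One row per image: `image_id` plus the nine row-major matrix entries.
#'
#' @param homographies List of [homography()] (or `NULL` for skipped
#'   frames, written as NA).
#' @param ids Character vector of image ids.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_homographies_csv <- function(homographies, ids, path) {
  stopifnot(length(homographies) == length(ids))
  rows <- lapply(seq_along(ids), function(i) {
    h <- homographies[[i]]
    v <- if (is.null(h)) rep(NA_real_, 9) else as.numeric(t(unclass(h)))
    df <- data.frame(image_id = ids[i], stringsAsFactors = FALSE)
    for (j in 1:9) df[[paste0("h", (j - 1) %/% 3 + 1, (j - 1) %% 3 + 1)]] <- v[j]
    df
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}

#' Pipeline configuration
#'
#' Flat key-value configuration with validated fields covering detection,
#' cropping, mosaicing, normalization and seeding. Unknown keys are
#' rejected.
#'
#' @param ... Overrides for the defaults (see [cht_params()] and
#'   [mosaic_params()] for the geometry/registration fields; plus
#'   `canvas_side`, `normalize`, `normalize_round`, `seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_radius_frac = 0.10, max_radius_frac = 0.45,
    accumulator_threshold = 0.25, min_center_distance_frac = 0.10,
    blur_kernel = 9L, radius_step = 1L, working_width = 480L,
    canvas_side = 400L,
    ratio = 0.8, ransac_tol = 3, min_inliers = 10L, max_iter = 2000L,
    max_keypoints = 1500L,
    normalize = TRUE, normalize_round = TRUE, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  # constructors validate their slice of the configuration
  cfg_cht <- cht_params(cfg$min_radius_frac, cfg$max_radius_frac,
                        cfg$accumulator_threshold,
                        cfg$min_center_distance_frac, cfg$blur_kernel,
                        cfg$radius_step, cfg$working_width)
  cfg_mos <- mosaic_params(cfg$ratio, cfg$ransac_tol, cfg$min_inliers,
                           cfg$max_iter, cfg$max_keypoints)
  structure(c(cfg, list(cht = cfg_cht, mosaic = cfg_mos)),
            class = "pipeline_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key: value` (a flat YAML-like dialect); `#` starts a
#' comment. Values are coerced to numeric or logical where possible.
#'
#' @param path Configuration file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num
                 else if (tolower(val) %in% c("true", "false"))
                   as.logical(toupper(val))
                 else val
  }
  do.call(pipeline_config, kv)
}
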