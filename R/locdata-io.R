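#' Construct a localization table
#'
#' A localization table holds fitted single-molecule positions from an
#' SMLM/STORM acquisition: 2D coordinates in nm, the acquisition frame
#' index, the per-molecule localization precision estimate in nm, and a
#' channel label (e.g. `"561"`, `"647"`). It is a plain `data.frame` with
#' class `"localization_table"` and a `meta` attribute carrying the source
#' identifier.
#'
#' @param x_nm,y_nm numeric molecule coordinates in nm; must be finite.
#' @param frame non-negative integer acquisition-frame index (recycled).
#' @param uncertainty_nm per-molecule localization precision in nm, >= 0.
#' @param channel channel label, non-empty character (recycled).
#' @param source free-text source identifier stored in `meta`.
#'
#' @return A `localization_table`: a data.frame with columns
#'   `x_nm`, `y_nm`, `frame`, `uncertainty_nm`, `channel`.
#' @export
localization_table <- function(x_nm = numeric(), y_nm = numeric(),
                               frame = 0L, uncertainty_nm = 0,
                               channel = "0", source = "in-memory") {
  n <- length(x_nm)
  stopifnot(length(y_nm) == n)
  df <- data.frame(
    x_nm = as.numeric(x_nm),
    y_nm = as.numeric(y_nm),
    frame = as.integer(rep_len(frame, n)),
    uncertainty_nm = as.numeric(rep_len(uncertainty_nm, n)),
    channel = as.character(rep_len(channel, n)),
    stringsAsFactors = FALSE
  )
  validate_localization_table(df)
  attr(df, "meta") <- list(source = source)
  class(df) <- c("localization_table", "data.frame")
  df
}

validate_localization_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (!all(is.finite(df$x_nm)) || !all(is.finite(df$y_nm)))
    stop("localization coordinates must be finite", call. = FALSE)
  if (any(!is.finite(df$uncertainty_nm) | df$uncertainty_nm < 0))
    stop("uncertainty_nm must be finite and >= 0", call. = FALSE)
  if (any(is.na(df$channel) | !nzchar(df$channel)))
    stop("channel labels must be non-empty", call. = FALSE)
  if (any(is.na(df$frame) | df$frame < 0L))
    stop("frame indices must be non-negative integers", call. = FALSE)
  invisible(df)
}

#' Default column mapping for localization CSV files
#'
#' Maps the logical fields (`x`, `y`, `frame`, `uncertainty`, `channel`)
#' to header names in a delimited file. The default dialect is the
#' package's own export format: comma-separated with header
#' `x_nm,y_nm,frame,uncertainty_nm,channel`. Other SMLM export dialects
#' (e.g. ThunderSTORM-style headers) can be read by overriding entries.
#'
#' @param x,y,frame,uncertainty,channel header names; `frame` may be `NA`
#'   if the file has no frame column (frames then default to 0).
#' @return Named list of column names.
#' @export
loc_dialect <- function(x = "x_nm", y = "y_nm", frame = "frame",
                        uncertainty = "uncertainty_nm", channel = "channel") {
  list(x = x, y = y, frame = frame, uncertainty = uncertainty,
       channel = channel)
}

#' Read a localization table from a delimited text file
#'
#' Rows whose coordinate or uncertainty fields fail numeric parsing are an
#' error naming the offending row numbers; with `permissive = TRUE` they
#' are dropped with a warning instead. This avoids silent data loss from
#' malformed exports.
#'
#' @param path path to a comma-separated file with a header row.
#' @param dialect column mapping from [loc_dialect()].
#' @param permissive if `TRUE`, downgrade unparseable rows to warn+skip.
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, dialect = loc_dialect(),
                               permissive = FALSE) {
  if (!file.exists(path))
    stop("localization file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  required <- c("x", "y", "uncertainty", "channel")
  for (f in required) {
    if (!dialect[[f]] %in% names(raw))
      stop("mapped column '", dialect[[f]], "' (field ", f,
           ") missing from ", path, call. = FALSE)
  }
  has_frame <- !is.na(dialect$frame) && dialect$frame %in% names(raw)

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  x <- num(dialect$x); y <- num(dialect$y); u <- num(dialect$uncertainty)
  frame <- if (has_frame) suppressWarnings(as.integer(raw[[dialect$frame]]))
           else rep(0L, nrow(raw))
  bad <- which(is.na(x) | is.na(y) | is.na(u) | is.na(frame))
  if (length(bad)) {
    msg <- paste0("unparseable numeric value(s) in row(s) ",
                  paste(bad, collapse = ", "), " of ", path)
    if (!permissive) stop(msg, call. = FALSE)
    warning(msg, "; rows dropped", call. = FALSE)
    keep <- setdiff(seq_len(nrow(raw)), bad)
    x <- x[keep]; y <- y[keep]; u <- u[keep]; frame <- frame[keep]
    raw <- raw[keep, , drop = FALSE]
  }
  localization_table(x, y, frame, u, raw[[dialect$channel]], source = path)
}

#' Write a localization table as CSV
#'
#' Column order is fixed and documented:
#' `x_nm,y_nm,frame,uncertainty_nm,channel`. Numeric fields are written
#' with 17 significant digits so that write -> read round-trips every
#' double bit-for-bit.
#'
#' @param table a [localization_table()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_localizations <- function(table, path) {
  validate_localization_table(table)
  out <- data.frame(
    x_nm = sprintf("%.17g", table$x_nm),
    y_nm = sprintf("%.17g", table$y_nm),
    frame = table$frame,
    uncertainty_nm = sprintf("%.17g", table$uncertainty_nm),
    channel = table$channel,
    stringsAsFactors = FALSE
  )
  if (nrow(table) == 0L)
    out <- out[0L, , drop = FALSE]
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Filter localizations by precision
#'
#' Retains molecules whose localization precision is strictly below the
#' threshold, mirroring the convention of keeping molecules with
#' localization errors less than 20 nm. Retained/discarded counts are
#' reported via `message()`.
#'
#' @param table a [localization_table()].
#' @param max_uncertainty_nm strict upper bound in nm (default 20).
#' @param quiet suppress the count message.
#' @return The filtered [localization_table()]; the input is unmodified.
#' @export
filter_by_precision <- function(table, max_uncertainty_nm = 20,
                                quiet = FALSE) {
  if (!is.numeric(max_uncertainty_nm) || length(max_uncertainty_nm) != 1L ||
      !is.finite(max_uncertainty_nm) || max_uncertainty_nm <= 0)
    stop("max_uncertainty_nm must be a single positive number",
         call. = FALSE)
  keep <- table$uncertainty_nm < max_uncertainty_nm
  if (!quiet)
    message("precision filter (< ", max_uncertainty_nm, " nm): retained ",
            sum(keep), ", discarded ", sum(!keep))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "meta") <- attr(table, "meta")
  class(out) <- class(table)
  out
}

#' Define a single-organelle region of interest
#'
#' @param roi_id unique region identifier.
#' @param bounds either a rectangle `list(xmin=,ymin=,xmax=,ymax=)` or an
#'   n x 2 matrix of polygon vertices, all in nm.
#' @param condition condition label (e.g. `"Rab6a+GM130"`).
#' @param ref_channel label of the channel whose centroid defines the
#'   organelle center.
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(roi_id, bounds, condition = "unlabeled",
                     ref_channel) {
  if (!nzchar(ref_channel)) stop("ref_channel must be non-empty",
                                 call. = FALSE)
  if (is.list(bounds) && !is.data.frame(bounds)) {
    need <- c("xmin", "ymin", "xmax", "ymax")
    if (!all(need %in% names(bounds)))
      stop("rectangular bounds need xmin, ymin, xmax, ymax", call. = FALSE)
    if (bounds$xmax <= bounds$xmin || bounds$ymax <= bounds$ymin)
      stop("ROI bounds are degenerate (non-positive area)", call. = FALSE)
  } else {
    bounds <- as.matrix(bounds)
    if (ncol(bounds) != 2L || nrow(bounds) < 3L)
      stop("polygon bounds need an n x 2 vertex matrix, n >= 3",
           call. = FALSE)
    if (abs(polygon_area(bounds)) <= 0)
      stop("ROI polygon is degenerate (zero area)", call. = FALSE)
  }
  structure(list(roi_id = as.character(roi_id), bounds = bounds,
                 condition = as.character(condition),
                 ref_channel = as.character(ref_channel)),
            class = "roi_spec")
}

polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2
}

roi_origin <- function(roi) {
  if (is.matrix(roi$bounds)) c(min(roi$bounds[, 1L]), min(roi$bounds[, 2L]))
  else c(roi$bounds$xmin, roi$bounds$ymin)
}

points_in_roi <- function(x, y, roi) {
  b <- roi$bounds
  if (is.matrix(b)) {
    # boundary-inclusive point-in-polygon
    res <- pracma::inpolygon(x, y, b[, 1L], b[, 2L], boundary = TRUE)
    as.logical(res)
  } else {
    x >= b$xmin & x <= b$xmax & y >= b$ymin & y <= b$ymax
  }
}

#' Extract per-channel localizations inside a region of interest
#'
#' Membership is boundary inclusive on all edges. Coordinates of the
#' returned tables are re-expressed relative to the ROI origin, defined as
#' the lower-left corner of the ROI's bounding box (`(xmin, ymin)`).
#'
#' @param table a [localization_table()] (any number of channels).
#' @param roi a [roi_spec()].
#' @return Named list of per-channel `localization_table`s, one entry per
#'   channel with at least one in-ROI molecule. Errors if the reference
#'   channel has no molecules inside the ROI.
#' @export
extract_roi <- function(table, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  inside <- points_in_roi(table$x_nm, table$y_nm, roi)
  sub <- table[inside, , drop = FALSE]
  if (!any(sub$channel == roi$ref_channel))
    stop("empty reference channel '", roi$ref_channel, "' in ROI ",
         roi$roi_id, call. = FALSE)
  org <- roi_origin(roi)
  out <- lapply(split(seq_len(nrow(sub)), sub$channel), function(i) {
    localization_table(sub$x_nm[i] - org[1L], sub$y_nm[i] - org[2L],
                       sub$frame[i], sub$uncertainty_nm[i],
                       sub$channel[i],
                       source = paste0(attr(table, "meta")$source, "#",
                                       roi$roi_id))
  })
  out[order(names(out) != roi$ref_channel)]
}

#' Read / write ROI definition files
#'
#' ROI files are JSON arrays of objects
#' `{roi_id, condition, ref_channel, bounds}` where `bounds` is either
#' `{xmin, ymin, xmax, ymax}` or a list of `[x, y]` polygon vertices, all
#' in nm.
#'
#' @param path JSON file path.
#' @return `read_rois()`: a list of [roi_spec()]; `write_rois()`:
#'   invisibly, `path`.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    b <- r$bounds
    bounds <- if (!is.null(names(b)) && "xmin" %in% names(b))
      list(xmin = b$xmin, ymin = b$ymin, xmax = b$xmax, ymax = b$ymax)
    else do.call(rbind, lapply(b, unlist))
    roi_spec(r$roi_id, bounds, r$condition, r$ref_channel)
  })
}

#' @rdname read_rois
#' @param rois list of [roi_spec()] objects.
#' @export
write_rois <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    b <- if (is.matrix(r$bounds))
      lapply(seq_len(nrow(r$bounds)), function(i) as.numeric(r$bounds[i, ]))
    else r$bounds
    list(roi_id = r$roi_id, condition = r$condition,
         ref_channel = r$ref_channel, bounds = b)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
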