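#' Read and write photon-count image stacks (multi-frame TIFF)
#'
#' Stacks are stored as multi-frame grayscale 16-bit TIFF files with a JSON
#' sidecar (`<path>.json`) holding the acquisition metadata (pixel size,
#' dwell time, frame interval). `read_stack()` restores the counts exactly
#' as written; metadata may also be supplied as arguments, which override
#' the sidecar. A missing pixel size with no sidecar is an error.
#'
#' @param path TIFF file path.
#' @param pixel_size,dwell_time,frame_interval metadata overrides (um, us,
#'   s).
#' @return An [image_stack].
#' @export
read_stack <- function(path, pixel_size = NULL, dwell_time = NULL,
                       frame_interval = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (any(!vapply(frames, is.matrix, logical(1)))) {
    abort("unsupported TIFF layout: expected single-channel grayscale frames (RGB or multi-sample TIFF?).")
  }
  d <- dim(frames[[1]])
  if (any(vapply(frames, function(f) !identical(dim(f), d), logical(1)))) {
    abort("unsupported TIFF layout: frames differ in shape (multi-series TIFF?).")
  }

  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  pixel_size <- pixel_size %||% meta$pixel_size
  dwell_time <- dwell_time %||% meta$dwell_time
  frame_interval <- frame_interval %||% meta$frame_interval
  if (is.null(pixel_size)) {
    abort("missing required metadata field: pixel_size (no sidecar entry and no argument).")
  }

  image_stack(array(unlist(frames), dim = c(d[1], d[2], length(frames))),
              pixel_size = as.numeric(pixel_size),
              dwell_time = if (!is.null(dwell_time)) as.numeric(dwell_time),
              frame_interval = if (!is.null(frame_interval)) as.numeric(frame_interval))
}

#' @rdname read_stack
#' @param stack an [image_stack]; counts must fit 16 bits (0..65535) and be
#'   integer-valued (non-integer stacks, e.g. detrended ones, are rounded
#'   with a warning).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  data <- stack$data
  if (max(data) > 65535) abort("counts exceed the 16-bit TIFF range.")
  if (any(data != round(data))) {
    warn("non-integer counts rounded for 16-bit TIFF storage.")
    data <- round(data)
  }
  d <- dim(data)
  frames <- lapply(seq_len(d[3]), function(f) {
    matrix(data[, , f], d[1], d[2]) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  meta <- list(pixel_size = stack$pixel_size)
  if (!is.null(stack$dwell_time)) meta$dwell_time <- stack$dwell_time
  if (!is.null(stack$frame_interval)) meta$frame_interval <- stack$frame_interval
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# column schemas for the tabular formats
.table_schemas <- list(
  localizations = list(required = c("frame", "x_um", "y_um"),
                       optional = "intensity", unique = NULL),
  trajectories = list(required = c("track_id", "frame", "x_um", "y_um"),
                      optional = "cell_id", unique = c("track_id", "frame")),
  dwells = list(required = c("duration_s", "censored"), optional = NULL,
                unique = NULL),
  features = list(required = c("cell_id", "condition"), optional = NULL,
                  unique = "cell_id")
)

#' Read a validated analysis table (CSV)
#'
#' Reads one of the package's tabular formats and validates it against the
#' named schema: required columns must be present, unit-suffixed columns
#' (`_um`, `_s`) and other measurement columns must be numeric (an error
#' reports the first offending row), and key columns must be unique (e.g.
#' no duplicated `(track_id, frame)` pair in a trajectory table). Row order
#' is preserved.
#'
#' @param path CSV file with a header.
#' @param schema one of `"localizations"`, `"trajectories"`, `"dwells"`,
#'   `"features"`.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema = c("localizations", "trajectories",
                                        "dwells", "features")) {
  schema <- match.arg(schema)
  sc <- .table_schemas[[schema]]
  df <- utils::read.csv(path, check.names = FALSE)
  assert_columns(df, sc$required, sprintf("%s table '%s'", schema, path))

  id_like <- c("cell_id", "condition", "censored")
  must_numeric <- setdiff(
    intersect(names(df), c(sc$required, sc$optional,
                           if (schema == "features") names(df))),
    id_like
  )
  must_numeric <- c(must_numeric, grep("_um$|_s$", names(df), value = TRUE))
  for (col in unique(must_numeric)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value in column '%s' at row %d of '%s'.",
                    col, bad[1], path))
    }
    if (anyNA(df[[col]])) {
      abort(sprintf("missing value in column '%s' of '%s'.", col, path))
    }
    df[[col]] <- v
  }
  if ("censored" %in% names(df)) df$censored <- as.logical(df$censored)

  if (!is.null(sc$unique)) {
    key <- do.call(paste, c(df[sc$unique], sep = "\r"))
    if (anyDuplicated(key)) {
      abort(sprintf("duplicated (%s) pair in '%s'.",
                    paste(sc$unique, collapse = ", "), path))
    }
  }
  as_tibble(df)
}

#' Write a run manifest alongside analysis outputs
#'
#' Records the package version, the seed, a hash of the configuration, the
#' checksums of input and output files, and a timestamp, so every analysis
#' output carries the configuration and seed that produced it.
#'
#' @param path manifest JSON path.
#' @param config named list of run parameters.
#' @param seed the seed used.
#' @param inputs,outputs character vectors of file paths (hashed with MD5
#'   when they exist).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL,
                           inputs = character(), outputs = character()) {
  hash_files <- function(p) {
    p <- p[file.exists(p)]
    if (!length(p)) return(NULL)
    as.list(tools::md5sum(p))
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    tool = "tfquant",
    version = as.character(utils::packageVersion("tfquant")),
    seed = seed,
    config = config,
    config_hash = unname(tools::md5sum(tmp)),
    inputs = hash_files(inputs),
    outputs = hash_files(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
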