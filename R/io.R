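#' Write / read a channel stack as a multi-page TIFF
#'
#' Images are stored as 3-page grayscale TIFFs.  Because the available TIFF
#' writer does not persist the ImageDescription tag, the channel page order
#' and pixel scale are declared in a YAML sidecar `<path>.yml` written
#' alongside the image; `read_channel_stack()` requires the sidecar and uses
#' it to return layers in (red, green, darkfield) order regardless of the
#' on-disk page order.
#'
#' @param stack A [channel_stack()].
#' @param path Path to the `.tif` file to write or read.
#' @return `write_channel_stack()` returns `path` invisibly;
#'   `read_channel_stack()` returns a [channel_stack()] that round-trips
#'   pixel-identically.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  maxdn <- 2^stack$bit_depth - 1
  pages <- list(stack$red / maxdn, stack$green / maxdn, stack$darkfield / maxdn)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "deflate")
  yaml::write_yaml(list(channels = c("red", "green", "darkfield"),
                        pixel_scale = stack$pixel_scale,
                        bit_depth = stack$bit_depth),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_channel_stack
#' @export
read_channel_stack <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing channel metadata sidecar for '", path, "' (expected ", sc, ")",
         call. = FALSE)
  }
  meta <- yaml::read_yaml(sc)
  chans <- unlist(meta$channels)
  if (!setequal(chans, c("red", "green", "darkfield")) || length(chans) != 3L) {
    stop("invalid channel metadata in '", sc, "': need red, green, darkfield",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L) {
    stop("'", path, "' has ", length(pages), " pages; a channel stack needs 3",
         call. = FALSE)
  }
  dims <- lapply(pages, dim)
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("'", path, "' pages have mismatched shapes", call. = FALSE)
  }
  bit_depth <- if (is.null(meta$bit_depth)) 8L else as.integer(meta$bit_depth)
  maxdn <- 2^bit_depth - 1
  layers <- lapply(pages, function(p) round(p * maxdn))
  names(layers) <- chans
  channel_stack(layers$red, layers$green, layers$darkfield,
                pixel_scale = meta$pixel_scale, bit_depth = bit_depth)
}

sidecar_path <- function(path) paste0(path, ".yml")

# ---- CSV tables with schema validation --------------------------------------

table_schemas <- list(
  design = c("plant_id", "block", "accession", "inoculum", "aphid"),
  nodule_truth = c("nodule_id", "plant_id", "occupancy_kind", "true_total_area",
                   "true_partial_area_fix_plus", "true_partial_area_fix_minus",
                   "cx", "cy", "radius_px"),
  nodules = c("nodule_id", "plant_id", "cx", "cy", "area", "pct_red",
              "pct_green", "nodule_class", "occupant",
              "partial_area_fix_plus", "partial_area_fix_minus"),
  sanctions = c("plant_id", "n_single_fix_plus", "n_single_fix_minus",
                "n_mixed", "z_fix_plus_among", "z_fix_minus_among",
                "z_fix_plus_within", "z_fix_minus_within",
                "strictness_among", "strictness_within"),
  traits = c("plant_id", "shoot_mass", "spad_before", "spad_after", "pemv_titer"),
  ledger = c("n_initial_features", "n_holes_removed", "n_below_min",
             "n_above_max", "n_retained"),
  results = c("contrast", "estimate", "p", "adjusted_p", "n", "seed")
)

#' Write / read pipeline tables as CSV
#'
#' CSVs use a header row, UTF-8 and "." decimals; undefined values (e.g.
#' strictness with no nodules in a class) are written as empty fields, never
#' sentinels.  On read, the schema named by `what` is validated: missing
#' required columns fail, unknown extra columns warn.
#'
#' @param x A data frame.
#' @param path CSV file path.
#' @param what Schema name: one of `design`, `nodule_truth`, `nodules`,
#'   `sanctions`, `traits`, `ledger`, `results`.
#' @return `write_table_csv()` returns `path` invisibly; `read_table_csv()`
#'   returns a tibble.
#' @export
write_table_csv <- function(x, path, what) {
  schema <- table_schemas[[what]]
  if (is.null(schema)) stop("unknown table schema: ", what, call. = FALSE)
  missing <- setdiff(schema, names(x))
  if (length(missing)) {
    stop("cannot write ", what, " table; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path, what) {
  schema <- table_schemas[[what]]
  if (is.null(schema)) stop("unknown table schema: ", what, call. = FALSE)
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(schema, names(x))
  if (length(missing)) {
    stop("table '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(x), schema)
  if (length(unknown)) {
    warning("table '", path, "' has unknown column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  x
}
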