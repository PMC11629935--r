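## Plain-text import/export of masks, trajectories and field maps.

#' Write / read a subsampling mask as plain text
#'
#' One `0`/`1` per grid node, row-major over the scan grid (independent of
#' the trajectory order), one grid row per line.
#'
#' @param mask A [SubsamplingMask-class].
#' @param plan The [ScanPlan-class] the mask refers to.
#' @param path Output file.
#' @export
writeMask <- function(mask, plan, path) {
    ev <- scanEvents(plan)
    g <- plan@grid
    m <- matrix(0L, nrow = g@ny, ncol = g@nx)
    m[cbind(ev$row + 1L, ev$col + 1L)] <- as.integer(mask@s)
    writeLines(apply(m, 1L, paste, collapse = " "), path)
    invisible(path)
}

#' @rdname writeMask
#' @param hardware Hardware timing to attach to the imported mask.
#' @return `readMask` returns a [SubsamplingMask-class] in the scan order of
#'   `plan`.
#' @export
readMask <- function(path, plan,
                     hardware = c("beam_blanker", "scan_generator")) {
    hardware <- match.arg(hardware)
    g <- plan@grid
    m <- as.matrix(read.table(path))
    stopifnot(nrow(m) == g@ny, ncol(m) == g@nx)
    ev <- scanEvents(plan)
    s <- m[cbind(ev$row + 1L, ev$col + 1L)] != 0
    new("SubsamplingMask", s = as.logical(s), strategy = "custom",
        hardware = hardware, seed = NA_integer_)
}

#' Export mask coordinates / trajectory order as CSV
#'
#' @inheritParams writeMask
#' @export
writeMaskCoords <- function(mask, plan, path) {
    ev <- scanEvents(plan)[mask@s, c("index", "row", "col", "x", "y")]
    write.csv(ev, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMaskCoords
#' @export
writeTrajectory <- function(plan, path) {
    write.csv(scanEvents(plan)[, c("index", "row", "col", "x", "y", "t")],
              path, row.names = FALSE)
    invisible(path)
}

#' Write a field map as CSV and/or 32-bit float TIFF
#'
#' The CSV holds the raw value matrix (row 1 = top of the field of view); a
#' sidecar JSON carries pixel size, origin, units and metadata.
#'
#' @param map A [FieldMap-class].
#' @param path Output path; extension `.csv` or `.tif`/`.tiff` selects the
#'   format.
#' @param sidecar Write `<path>.json` with geometry/units/metadata.
#' @export
writeFieldMap <- function(map, path, sidecar = TRUE) {
    stopifnot(is(map, "FieldMap"))
    ext <- tolower(tools::file_ext(path))
    tiffScale <- NULL
    if (ext == "csv") {
        write.table(map@values, path, sep = ",", row.names = FALSE,
                    col.names = FALSE)
    } else if (ext %in% c("tif", "tiff")) {
        # TIFF samples must lie in [0, 1]; store values / max and record the
        # scale in the sidecar
        tiffScale <- max(map@values, 1e-300)
        tiff::writeTIFF(map@values / tiffScale, path, bits.per.sample = 32L,
                        reduce = FALSE)
    } else stop("unsupported extension: ", ext)
    if (sidecar) {
        meta <- list(pixel_nm = map@pixel, origin_nm = map@origin,
                     units = map@units, dim = dim(map@values),
                     tiff_scale = tiffScale,
                     metadata = map@metadata,
                     package = as.character(packageVersion("stemdiff")))
        jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                             digits = NA, null = "null", force = TRUE)
    }
    invisible(path)
}

#' Read a CSV field map written by [writeFieldMap()]
#'
#' @param path CSV path (a `<path>.json` sidecar restores geometry if
#'   present).
#' @return A [FieldMap-class].
#' @export
readFieldMapCsv <- function(path) {
    vals <- as.matrix(read.csv(path, header = FALSE))
    dimnames(vals) <- NULL
    side <- paste0(path, ".json")
    if (file.exists(side)) {
        meta <- jsonlite::read_json(side, simplifyVector = TRUE)
        fieldMap(vals, pixel = meta$pixel_nm, origin = meta$origin_nm,
                 units = meta$units)
    } else {
        fieldMap(vals, pixel = 1)
    }
}

#' Quick-look heat map of a field map
#'
#' @param map A [FieldMap-class].
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plotFieldMap <- function(map, main = map@metadata$kind, ...) {
    v <- map@values
    nx <- ncol(v); ny <- nrow(v)
    x <- map@origin[1] + (seq_len(nx) - 1) * map@pixel
    y <- map@origin[2] - (rev(seq_len(ny)) - 1) * map@pixel
    graphics::image(x, y, t(v[rev(seq_len(ny)), , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "x (nm)", ylab = "y (nm)",
                    main = if (is.null(main)) "" else main,
                    useRaster = TRUE, asp = 1, ...)
    invisible(map)
}
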