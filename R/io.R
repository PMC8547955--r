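#' Write a force curve to CSV
#'
#' Plain-text interchange format: commented header lines carrying the spring
#' constant (and any scalar metadata such as the simulation seed), followed
#' by \code{z_nm, deflection_nm} columns at full double precision, so a
#' write/read round trip reproduces the curve exactly.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeForceCurveCsv <- function(curve, path) {
    stopifnot(is(curve, "ForceCurve"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# spring_constant_N_per_m=%.17g", curve@springConstant),
               con)
    for (nm in names(curve@meta)) {
        v <- curve@meta[[nm]]
        if (is.numeric(v) && length(v) == 1L && is.finite(v))
            writeLines(sprintf("# %s=%.17g", nm, v), con)
    }
    writeLines("z_nm,deflection_nm", con)
    writeLines(sprintf("%.17g,%.17g", curve@z, curve@deflection), con)
    invisible(path)
}

#' Read a force curve from CSV
#'
#' Accepts the dialect written by \code{\link{writeForceCurveCsv}} (and any
#' instrument export matching it): \code{#}-commented key=value header lines
#' including \code{spring_constant_N_per_m}, then columns \code{z_nm} and
#' \code{deflection_nm}.
#'
#' @param path input file path.
#' @return a \linkS4class{ForceCurve}.
#' @export
readForceCurveCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    meta <- list()
    for (h in hdr) {
        kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
        if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- as.numeric(kv[2L])
    }
    if (is.null(meta[["spring_constant_N_per_m"]]) ||
        is.na(meta[["spring_constant_N_per_m"]]))
        stop("format error: missing header field 'spring_constant_N_per_m'")
    body <- lines[!grepl("^#", lines)]
    tab <- utils::read.csv(text = body)
    for (col in c("z_nm", "deflection_nm"))
        if (!col %in% names(tab))
            stop("format error: missing column '", col, "'")
    k <- meta[["spring_constant_N_per_m"]]
    meta[["spring_constant_N_per_m"]] <- NULL
    new("ForceCurve", z = as.numeric(tab$z_nm),
        deflection = as.numeric(tab$deflection_nm),
        springConstant = k, meta = meta)
}

sidecarPath <- function(path) paste0(path, ".json")

#' Write an image or movie as TIFF with a JSON sidecar
#'
#' Multi-page 32-bit TIFF: channels as pages for a
#' \linkS4class{FollicleImage}, frames as pages for a
#' \linkS4class{TimeLapse}. Physical metadata (pixel size, frame interval,
#' channel names) goes into a JSON sidecar next to the file rather than into
#' TIFF tags, for portability. Intensities are stored scaled into [0, 1];
#' the scale factor is recorded in the sidecar (\code{intensity_scale}) and
#' reapplied on read.
#'
#' @param x a \linkS4class{FollicleImage} or \linkS4class{TimeLapse}.
#' @param path output TIFF path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
writeTiffStack <- function(x, path) {
    if (is(x, "FollicleImage")) {
        pages <- x@channels
        scale <- max(unlist(lapply(pages, max)), 1)
        sc <- list(kind = "image", pixel_size_um = x@pixelSize,
                   channel_names = names(x@channels),
                   intensity_scale = scale)
    } else if (is(x, "TimeLapse")) {
        T <- dim(x@frames)[1L]
        pages <- lapply(seq_len(T), function(t) x@frames[t, , ])
        scale <- max(x@frames, 1)
        sc <- list(kind = "movie", pixel_size_um = x@pixelSize,
                   frame_interval_s = x@frameInterval,
                   channel_names = "pmrlc", intensity_scale = scale)
    } else stop("x must be a FollicleImage or a TimeLapse")
    tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                    bits.per.sample = 32L)
    jsonlite::write_json(sc, sidecarPath(path), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a TIFF stack with its JSON sidecar
#'
#' @param path TIFF path written by \code{\link{writeTiffStack}} (or any
#'   multi-page TIFF with a conforming sidecar).
#' @param sidecar sidecar path (default \code{paste0(path, ".json")}).
#' @return a \linkS4class{FollicleImage} (sidecar kind "image") or
#'   \linkS4class{TimeLapse} (kind "movie"; requires
#'   \code{frame_interval_s}). Masks are not stored in TIFF; attach them
#'   separately (see \code{\link{readMaskCsv}}).
#' @export
readTiffStack <- function(path, sidecar = sidecarPath(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (!file.exists(sidecar)) stop("file not found: ", sidecar)
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(sc$pixel_size_um)) stop("format error: sidecar lacks pixel_size_um")
    scale <- if (is.null(sc$intensity_scale)) 1 else sc$intensity_scale
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) p * scale)
    if (identical(sc$kind, "movie")) {
        if (is.null(sc$frame_interval_s))
            stop("format error: movie sidecar lacks frame_interval_s")
        d <- dim(pages[[1L]])
        frames <- array(0, dim = c(length(pages), d[1L], d[2L]))
        for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
        new("TimeLapse", frames = frames, frameInterval = sc$frame_interval_s,
            pixelSize = sc$pixel_size_um,
            clusterMask = matrix(TRUE, d[1L], d[2L]))
    } else {
        nms <- sc$channel_names
        if (is.null(nms) || length(nms) != length(pages))
            stop("format error: sidecar channel_names do not match TIFF pages")
        names(pages) <- nms
        new("FollicleImage", channels = pages, pixelSize = sc$pixel_size_um)
    }
}

#' Write / read a binary mask as plain-text CSV
#'
#' Run-length encoding by column-major pixel index: rows of
#' \code{start, length}, with the mask shape in a commented header.
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return \code{writeMaskCsv}: \code{path} invisibly; \code{readMaskCsv}:
#'   the logical matrix.
#' @export
writeMaskCsv <- function(mask, path) {
    stopifnot(is.logical(mask), is.matrix(mask))
    v <- as.vector(mask)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# nrow=%d", nrow(mask)), con)
    writeLines(sprintf("# ncol=%d", ncol(mask)), con)
    writeLines("start,length", con)
    writeLines(sprintf("%d,%d", starts[keep], r$lengths[keep]), con)
    invisible(path)
}

#' @rdname writeMaskCsv
#' @export
readMaskCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    getDim <- function(key) {
        h <- grep(paste0("^#\\s*", key, "="), lines, value = TRUE)
        if (!length(h)) stop("format error: missing header field '", key, "'")
        as.integer(sub(".*=", "", h[1L]))
    }
    nr <- getDim("nrow"); nc <- getDim("ncol")
    tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
    m <- logical(nr * nc)
    for (i in seq_len(nrow(tab)))
        m[tab$start[i]:(tab$start[i] + tab$length[i] - 1L)] <- TRUE
    matrix(m, nr, nc)
}
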