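#' @include methods.R
NULL

# TrackVis-style .trk container: 1000-byte header, then per-streamline an
# int32 point count followed by float32 xyz triplets.  Points are stored as
# world-mm RAS; the voxel-to-world affine travels in the vox_to_ras header
# field (version 2).

.trk_header_template <- function(nCount, affine, voxelSize, dims) {
    con <- rawConnection(raw(0), "w")
    on.exit(close(con))
    writeBin(charToRaw("TRACK"), con)
    writeBin(raw(1), con)
    writeBin(as.integer(dims), con, size = 2L)               # dim[3]
    writeBin(as.numeric(voxelSize), con, size = 4L)          # voxel_size[3]
    writeBin(numeric(3), con, size = 4L)                     # origin[3]
    writeBin(0L, con, size = 2L)                             # n_scalars
    writeBin(raw(200), con)                                  # scalar names
    writeBin(0L, con, size = 2L)                             # n_properties
    writeBin(raw(200), con)                                  # property names
    writeBin(as.numeric(t(affine)), con, size = 4L)          # vox_to_ras, rows
    writeBin(raw(444), con)                                  # reserved
    writeBin(c(charToRaw("RAS"), raw(1)), con)               # voxel_order
    writeBin(raw(4), con)                                    # pad2
    writeBin(numeric(6), con, size = 4L)                     # img orientation
    writeBin(raw(2), con)                                    # pad1
    writeBin(raw(6), con)                                    # invert/swap flags
    writeBin(as.integer(nCount), con, size = 4L)             # n_count
    writeBin(2L, con, size = 4L)                             # version
    writeBin(1000L, con, size = 4L)                          # hdr_size
    rawConnectionValue(con)
}

#' Write a fiber tract to disk
#'
#' `format = "trk"` writes a TrackVis-style binary streamline file
#' (world-mm RAS float32 coordinates, voxel-to-world affine in the
#' header) plus a JSON provenance sidecar; `format = "jsonl"` writes a
#' dependency-free JSON-lines file (provenance header line, then one JSON
#' array of points per fiber).  The format is inferred from the file
#' extension when not given.
#'
#' @param tract a [FiberTract-class].
#' @param path output path.
#' @param format `"trk"` or `"jsonl"`.
#' @param affine 4x4 voxel-to-world matrix stored in the trk header.
#' @param voxelSize,dims reference geometry stored in the trk header.
#' @return `path`, invisibly.
#' @export
writeFibers <- function(tract, path, format = NULL, affine = diag(4),
                        voxelSize = c(1, 1, 1), dims = c(0L, 0L, 0L)) {
    if (is.null(format))
        format <- if (grepl("\\.jsonl$", path)) "jsonl" else "trk"
    format <- match.arg(format, c("trk", "jsonl"))
    fibs <- lapply(tract@fibers, fiberPoints)
    if (format == "jsonl") {
        lines <- c(
            jsonlite::toJSON(list(type = "fiber-tract",
                                  provenance = tract@provenance,
                                  n = length(fibs)),
                             auto_unbox = TRUE, digits = NA),
            vapply(fibs, function(p)
                as.character(jsonlite::toJSON(unname(p), digits = NA)),
                character(1)))
        writeLines(lines, path)
        return(invisible(path))
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(.trk_header_template(length(fibs), affine, voxelSize, dims), con)
    for (p in fibs) {
        writeBin(nrow(p), con, size = 4L)
        writeBin(as.numeric(t(p)), con, size = 4L)
    }
    sidecar <- paste0(path, ".json")
    jsonlite::write_json(tract@provenance, sidecar, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

#' Read a fiber tract from disk
#'
#' Reads both formats written by [writeFibers()]; for `.trk` the
#' provenance sidecar is picked up when present.
#'
#' @param path a `.trk` or `.jsonl` file.
#' @return a [FiberTract-class].
#' @export
readFibers <- function(path) {
    if (grepl("\\.jsonl$", path)) {
        lines <- readLines(path)
        hdr <- jsonlite::fromJSON(lines[1L])
        fibs <- lapply(lines[-1L], function(l)
            matrix(jsonlite::fromJSON(l), ncol = 3L))
        return(fiberTract(fibs, provenance = as.list(hdr$provenance)))
    }
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 6L)
    if (!identical(rawToChar(magic[1:5]), "TRACK"))
        stop("not a trk streamline file: ", path)
    seek(con, 988L)
    nCount <- readBin(con, "integer", 1L, size = 4L)
    version <- readBin(con, "integer", 1L, size = 4L)
    hdrSize <- readBin(con, "integer", 1L, size = 4L)
    if (hdrSize != 1000L)
        stop("unsupported trk header size ", hdrSize, " in ", path)
    seek(con, 1000L)
    fibs <- list()
    i <- 0L
    repeat {
        if (nCount > 0L && i >= nCount) break
        n <- readBin(con, "integer", 1L, size = 4L)
        if (length(n) == 0L) break
        if (n < 0L) stop("malformed trk record ", i + 1L, " in ", path)
        xyz <- readBin(con, "numeric", 3L * n, size = 4L)
        if (length(xyz) < 3L * n)
            stop("truncated trk record ", i + 1L, " in ", path)
        fibs[[i <- i + 1L]] <- matrix(xyz, ncol = 3L, byrow = TRUE)
    }
    prov <- list()
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar))
        prov <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
    fiberTract(fibs, provenance = as.list(prov))
}
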