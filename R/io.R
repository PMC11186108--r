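#' Write a volume to NIfTI or MetaImage
#'
#' Stores the array as float64 with voxel spacing and origin in the header
#' (NIfTI: RAS+ affine; MetaImage: `ElementSpacing`/`Offset`). Round-trips
#' through [read_volume()] are bit-exact.
#'
#' @param values 3-D array.
#' @param grid the `grid_spec` the values live on.
#' @param path output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return invisibly, `path`.
#' @export
write_volume <- function(values, grid, path) {
  stopifnot(all(dim(values) == grid$shape))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(structure(values, pixdim = grid$spacing))
    xfrm <- diag(c(grid$spacing, 1))
    xfrm[1:3, 4] <- grid$origin
    RNifti::qform(img) <- structure(xfrm, code = 2L)
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.mha$", path)) {
    con <- file(path, "wb")
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False", "CompressedData = False",
             "TransformMatrix = 1 0 0 0 1 0 0 0 1",
             paste("Offset =", paste(grid$origin, collapse = " ")),
             paste("ElementSpacing =", paste(grid$spacing, collapse = " ")),
             paste("DimSize =", paste(grid$shape, collapse = " ")),
             "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
    writeLines(hdr, con)
    writeBin(as.numeric(values), con, size = 8, endian = "little")
    close(con)
  } else {
    stop("unknown volume format (use .nii, .nii.gz or .mha): ", path)
  }
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path path to a `.nii`, `.nii.gz` or `.mha` volume.
#' @return list with `values` (3-D array) and `grid` (a `grid_spec`).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    xfrm <- RNifti::xform(img)
    spacing <- RNifti::pixdim(img)
    origin <- as.numeric(xfrm[1:3, 4])
    vals <- array(as.numeric(img), dim = dim(img))
    list(values = vals, grid = grid_spec(dim(img), spacing, origin))
  } else if (grepl("\\.mha$", path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- list()
    repeat {
      line <- readLines(con, n = 1)
      kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
      hdr[[kv[1]]] <- kv[2]
      if (kv[1] == "ElementDataFile") break
    }
    if (!identical(hdr[["ElementType"]], "MET_DOUBLE"))
      stop("unsupported MetaImage element type: ", hdr[["ElementType"]])
    shape <- as.integer(strsplit(hdr[["DimSize"]], " ")[[1]])
    spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], " ")[[1]])
    origin <- as.numeric(strsplit(hdr[["Offset"]], " ")[[1]])
    vals <- readBin(con, "numeric", n = prod(shape), size = 8,
                    endian = "little")
    list(values = array(vals, dim = shape),
         grid = grid_spec(shape, spacing, origin))
  } else {
    stop("unknown volume format: ", path)
  }
}

#' Write a volume with a JSON grid sidecar
#'
#' The sidecar duplicates the grid geometry and carries free-form metadata
#' (e.g. the material density table); [read_volume_checked()] verifies the
#' sidecar against the volume header and errors on mismatch.
#'
#' @inheritParams write_volume
#' @param meta named list of extra metadata.
#' @return invisibly, the sidecar path.
#' @export
write_volume_sidecar <- function(values, grid, path, meta = list()) {
  write_volume(values, grid, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(c(list(shape = grid$shape, spacing = grid$spacing,
                              origin = grid$origin), meta),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a volume and verify its sidecar
#' @param path volume path (sidecar at `<path>.json`).
#' @return as [read_volume()], plus `meta` from the sidecar.
#' @export
read_volume_checked <- function(path) {
  vol <- read_volume(path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!isTRUE(all.equal(as.integer(meta$shape), vol$grid$shape)) ||
      !isTRUE(all.equal(as.numeric(meta$spacing), vol$grid$spacing,
                        tolerance = 1e-5)) ||
      !isTRUE(all.equal(as.numeric(meta$origin), vol$grid$origin,
                        tolerance = 1e-4)))
    stop("sidecar grid does not match volume header: ", path)
  vol$meta <- meta[setdiff(names(meta), c("shape", "spacing", "origin"))]
  vol
}
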