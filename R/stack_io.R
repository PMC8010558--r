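# Native image-stack container (self-describing binary, bit-exact
# round-trip) and frame export for inspection.

STACK_MAGIC <- "PDSTACK1"

#' Write a portal-image stack to the native container
#'
#' Single-file binary container: a magic string, a length-prefixed JSON
#' metadata block (patient id, role, per-frame gantry angles, provenance),
#' the array dimensions, and the raw little-endian doubles of the frames.
#' The round-trip through [read_stack()] is bit-exact.
#'
#' @param stack A `portal_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stop_if(!inherits(stack, "portal_stack"), "stack must be a portal_stack")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(STACK_MAGIC), con)
  prov <- lapply(stack$provenance, function(x)
    if (is.object(x)) unclass(x) else x)
  meta <- jsonlite::toJSON(list(patient_id = stack$patient_id,
                                role = stack$role,
                                gantry_deg = stack$gantry_deg,
                                provenance = prov),
                           auto_unbox = TRUE, digits = NA)
  mraw <- charToRaw(as.character(meta))
  writeBin(length(mraw), con, size = 4L, endian = "little")
  writeBin(mraw, con)
  writeBin(dim(stack$pixels), con, size = 4L, endian = "little")
  writeBin(as.vector(stack$pixels), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a portal-image stack from the native container
#'
#' @param path File written by [write_stack()].
#' @return A `portal_stack`.
#' @export
read_stack <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(STACK_MAGIC)))
  stop_if(magic != STACK_MAGIC, "not a portal stack container: ", path)
  mlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)))
  d <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  px <- array(readBin(con, "double", prod(d), size = 8L, endian = "little"), d)
  prov <- as.list(meta$provenance)
  if (!is.null(prov$error) && !is.null(prov$error$family))
    prov$error <- error_spec(prov$error$family, prov$error$magnitude)
  new_portal_stack(px, as.numeric(meta$gantry_deg), meta$role,
                   meta$patient_id, prov)
}

#' Export stack frames as 16-bit TIFF images
#'
#' Writes one 16-bit greyscale TIFF per frame for visual inspection,
#' linearly scaled to the stack maximum. Requires the `tiff` package.
#'
#' @param stack A `portal_stack`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
export_stack_tiff <- function(stack, dir) {
  stop_if(!requireNamespace("tiff", quietly = TRUE),
          "frame export requires the 'tiff' package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(stack$pixels)
  if (mx <= 0) mx <- 1
  ns <- dim(stack$pixels)[3]
  paths <- character(ns)
  for (j in seq_len(ns)) {
    paths[j] <- file.path(dir, sprintf("%s_%s_%03d.tif", stack$patient_id,
                                       stack$role, j))
    tiff::writeTIFF(stack$pixels[, , j] / mx, paths[j],
                    bits.per.sample = 16L)
  }
  invisible(paths)
}
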