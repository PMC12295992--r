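# Reading and writing the standard on-disk formats: NIfTI volumes and
# masks, centerlines as VTK PolyData (.vtp, single polyline cell) or as
# a JSON point-list dialect. All formats share one coordinate
# convention: world mm, voxel center i at origin + (i + 0.5) * spacing.
# NIfTI itself maps integer index i to its affine translation + i *
# spacing, so the stored translation is origin + 0.5 * spacing.

#' Write a volume or mask as NIfTI
#'
#' Volumes are stored as float32, binary masks as uint8. The affine is
#' diagonal (axis-aligned, positive spacing).
#'
#' @param vol an \linkS4class{ImageVolume} or \linkS4class{ProbabilityMask}.
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume") || is(vol, "ProbabilityMask"))
  vals <- vol@values
  is_mask <- is(vol, "ProbabilityMask") && all(vals %in% c(0, 1))
  affine <- diag(4)
  diag(affine)[1:3] <- vol@spacing
  affine[1:3, 4] <- vol@origin + 0.5 * vol@spacing
  img <- RNifti::asNifti(vals)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

nifti_grid <- function(img) {
  aff <- RNifti::xform(img)
  sp <- diag(aff)[1:3]
  offdiag <- aff[1:3, 1:3] - diag(sp)
  if (any(abs(offdiag) > 1e-4 * max(abs(sp))) || any(sp <= 0))
    stop("only axis-aligned NIfTI affines with positive spacing are ",
         "supported; reorient/resample the image first")
  list(spacing = sp, origin = aff[1:3, 4] - 0.5 * sp)
}

#' Read a NIfTI volume or mask
#'
#' @param path a .nii/.nii.gz file containing 3D scalar data.
#' @param as \code{"volume"} (ImageVolume) or \code{"mask"}
#'   (ProbabilityMask).
#' @return An \linkS4class{ImageVolume} or \linkS4class{ProbabilityMask}.
#' @export
readVolume <- function(path, as = c("volume", "mask")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  vals <- array(as.vector(img), dim = dim(img))
  if (length(dim(vals)) != 3L)
    stop("expected a 3D scalar NIfTI image, got ",
         length(dim(vals)), "D data")
  g <- nifti_grid(img)
  if (as == "volume")
    ImageVolume(vals, spacing = g$spacing, origin = g$origin)
  else
    ProbabilityMask(vals, spacing = g$spacing, origin = g$origin)
}

#' Write a centerline to VTP or JSON
#'
#' VTP files contain a single polyline cell in an ASCII VTK XML
#' PolyData; JSON files use \code{{"points_mm": [[x,y,z], ...]}}. The
#' format is chosen by file extension.
#'
#' @param cl a \linkS4class{Centerline}.
#' @param path output path ending in .vtp or .json.
#' @return The path, invisibly.
#' @export
writeCenterline <- function(cl, path) {
  stopifnot(is(cl, "Centerline"))
  pts <- clPoints(cl)
  if (grepl("\\.vtp$", path, ignore.case = TRUE)) {
    n <- nrow(pts)
    coord <- paste(apply(pts, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " ")),
      collapse = "\n")
    xml <- paste0(
      '<?xml version="1.0"?>\n',
      '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
      '  <PolyData>\n',
      sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="1" NumberOfStrips="0" NumberOfPolys="0">\n', n),
      '      <Points>\n',
      '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
      coord, '\n',
      '        </DataArray>\n',
      '      </Points>\n',
      '      <Lines>\n',
      '        <DataArray type="Int64" Name="connectivity" format="ascii">\n',
      paste(0:(n - 1), collapse = " "), '\n',
      '        </DataArray>\n',
      '        <DataArray type="Int64" Name="offsets" format="ascii">\n',
      n, '\n',
      '        </DataArray>\n',
      '      </Lines>\n',
      '    </Piece>\n',
      '  </PolyData>\n',
      '</VTKFile>\n')
    writeLines(xml, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(points_mm = unname(pts)), path, digits = NA)
  } else {
    stop("unsupported centerline format: ", path)
  }
  invisible(path)
}

#' Read a centerline from VTP or JSON
#'
#' @param path a .vtp (single polyline cell) or .json centerline file.
#' @return A \linkS4class{Centerline}; point order is preserved.
#' @export
readCenterline <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty or missing centerline file: ", path)
  if (grepl("\\.vtp$", path, ignore.case = TRUE)) {
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) stop("not a valid VTP file: ", path))
    pts_node <- xml2::xml_find_first(doc, ".//Points/DataArray")
    if (is.na(pts_node)) stop("VTP file has no Points array: ", path)
    coords <- scan(text = xml2::xml_text(pts_node), quiet = TRUE)
    pts <- matrix(coords, ncol = 3, byrow = TRUE)
    offs_node <- xml2::xml_find_first(
      doc, ".//Lines/DataArray[@Name='offsets']")
    conn_node <- xml2::xml_find_first(
      doc, ".//Lines/DataArray[@Name='connectivity']")
    if (is.na(offs_node) || is.na(conn_node))
      stop("VTP file has no polyline cell: ", path)
    offs <- scan(text = xml2::xml_text(offs_node), quiet = TRUE)
    if (length(offs) != 1L)
      stop("unsupported topology: VTP file contains ", length(offs),
           " line cells, expected a single polyline")
    conn <- scan(text = xml2::xml_text(conn_node), quiet = TRUE)
    pts <- pts[conn + 1L, , drop = FALSE]
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$points_mm))
      stop("JSON centerline must contain a points_mm array: ", path)
    pts <- matrix(as.numeric(obj$points_mm), ncol = 3)
  } else {
    stop("unsupported centerline format: ", path)
  }
  if (nrow(pts) < 2L)
    stop("centerline file contains fewer than 2 points: ", path)
  Centerline(pts)
}
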