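#' Read and write surface meshes
#'
#' Two surface formats are supported: ASCII Wavefront OBJ (`v`/`f` records;
#' OBJ's 1-based face indices are converted on the way in and out) and GIFTI
#' surface files (`.surf.gii`) restricted to the ASCII data encoding. GIFTI
#' triangle indices are 0-based on disk per the format and 1-based in R.
#' Meshes are validated on load; non-manifold input is rejected, not
#' repaired.
#'
#' @param path file path; format chosen by extension (`.obj` vs `.gii`).
#' @return [read_surface()] returns a [surface_mesh()].
#' @export
read_surface <- function(path) {
  if (grepl("\\.obj$", path, ignore.case = TRUE)) read_obj(path)
  else if (grepl("\\.gii$", path, ignore.case = TRUE)) read_gifti_surface(path)
  else stop("unrecognized surface extension: ", path)
}

#' @rdname read_surface
#' @param mesh a [surface_mesh()] to write.
#' @export
write_surface <- function(mesh, path) {
  if (grepl("\\.obj$", path, ignore.case = TRUE)) write_obj(mesh, path)
  else if (grepl("\\.gii$", path, ignore.case = TRUE)) write_gifti_surface(mesh, path)
  else stop("unrecognized surface extension: ", path)
}

read_obj <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  if (!length(vs) || !length(fs)) stop("OBJ file has no v/f records: ", path)
  v <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vs), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  # faces may carry v/vt/vn triplets; keep the vertex index before any '/'
  f <- do.call(rbind, lapply(strsplit(sub("^f\\s+", "", fs), "\\s+"), function(x) {
    ix <- as.integer(sub("/.*$", "", x))
    if (length(ix) != 3L) stop("only triangular faces are supported")
    ix
  }))
  surface_mesh(v, f)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# triangulated surface, mm coordinates", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}

read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(arrays)) stop("no DataArray elements in ", path)
  get_array <- function(intent) {
    hit <- arrays[xml2::xml_attr(arrays, "Intent") == intent]
    if (!length(hit)) stop("GIFTI file lacks a ", intent, " array")
    a <- hit[[1]]
    if (!identical(xml2::xml_attr(a, "Encoding"), "ASCII"))
      stop("only ASCII-encoded GIFTI data arrays are supported")
    dims <- c(as.integer(xml2::xml_attr(a, "Dim0")),
              as.integer(xml2::xml_attr(a, "Dim1")))
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(a, ".//Data")),
                 quiet = TRUE)
    order <- xml2::xml_attr(a, "ArrayIndexingOrder")
    m <- if (identical(order, "ColumnMajorOrder"))
      matrix(vals, nrow = dims[1], ncol = dims[2])
    else matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    m
  }
  v <- get_array("NIFTI_INTENT_POINTSET")
  f <- get_array("NIFTI_INTENT_TRIANGLE") + 1L
  surface_mesh(v, f)
}

gifti_data_array <- function(mat, intent, datatype) {
  rows <- apply(mat, 1L, paste, collapse = " ")
  paste0(
    '<DataArray Intent="', intent, '" DataType="', datatype,
    '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="',
    nrow(mat), '" Dim1="', ncol(mat),
    '" Encoding="ASCII" Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n',
    "<Data>\n", paste(rows, collapse = "\n"), "\n</Data>\n</DataArray>")
}

write_gifti_surface <- function(mesh, path) {
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    gifti_data_array(signif(mesh$vertices, 9), "NIFTI_INTENT_POINTSET",
                     "NIFTI_TYPE_FLOAT32"), "\n",
    gifti_data_array(mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                     "NIFTI_TYPE_INT32"), "\n",
    "</GIFTI>\n")
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Write a per-vertex scalar field as an ASCII GIFTI functional file
#'
#' @param values numeric per-vertex vector (e.g. a t field).
#' @param path output `.func.gii` path.
#' @export
write_gifti_func <- function(values, path) {
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">\n',
    gifti_data_array(matrix(signif(values, 9), ncol = 1),
                     "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32"), "\n",
    "</GIFTI>\n")
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Read and write seed-region label tables
#'
#' Label TSVs have a header `vertex_index<TAB>label`, with 0-based vertex
#' indices on disk (converted to 1-based in R).
#'
#' @param path TSV path.
#' @param mesh optional mesh for index validation.
#' @return [read_labels()]: named list of [seed_region()] objects, one per
#'   distinct label.
#' @export
read_labels <- function(path, mesh = NULL) {
  df <- read_tsv(path)
  if (!all(c("vertex_index", "label") %in% names(df)))
    stop("label TSV needs columns 'vertex_index' and 'label'")
  sp <- split(as.integer(df$vertex_index) + 1L, df$label)
  regions <- lapply(names(sp), function(nm) seed_region(nm, sp[[nm]], mesh))
  stats::setNames(regions, names(sp))
}

#' @rdname read_labels
#' @param regions list of [seed_region()] objects.
#' @export
write_labels <- function(regions, path) {
  df <- do.call(rbind, lapply(regions, function(r)
    data.frame(vertex_index = r$vertex_indices - 1L, label = r$name)))
  write_tsv(df, path)
}
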