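#' Surface and metric file I/O
#'
#' Surfaces and per-vertex metrics are serialised in the standard
#' surface-neuroimaging XML dialect (GIFTI), ASCII-encoded so files are plain
#' text: a surface file holds a POINTSET and a TRIANGLE data array (triangle
#' indices 0-based on disk, 1-based in memory), a metric file holds one shape
#' array per column. Metadata keys `hemisphere`, `feature`, `age_weeks` and
#' `role` survive the round trip. Reading validates unit norms, closedness
#' and winding for spherical geometry.
#'
#' @param mesh,surface,metric object to write.
#' @param path file path (conventionally `.surf.gii` / `.func.gii`).
#' @name surface_io
NULL

gifti_array <- function(doc, intent, dtype, M, meta = list()) {
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = dtype, ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = "2", Dim0 = as.character(nrow(M)),
    Dim1 = as.character(ncol(M)), Encoding = "ASCII", Endian = "LittleEndian")
  if (length(meta)) {
    md <- xml2::xml_add_child(da, "MetaData")
    for (nm in names(meta)) {
      e <- xml2::xml_add_child(md, "MD")
      xml2::xml_add_child(e, "Name", nm)
      xml2::xml_add_child(e, "Value", as.character(meta[[nm]]))
    }
  }
  txt <- paste(apply(M, 1, paste, collapse = " "), collapse = "\n")
  xml2::xml_add_child(da, "Data", txt)
  da
}

gifti_read_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(das, function(da) {
    dtype <- xml2::xml_attr(da, "DataType")
    d0 <- as.integer(xml2::xml_attr(da, "Dim0"))
    d1 <- as.integer(xml2::xml_attr(da, "Dim1"))
    txt <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
    vals <- scan(text = txt, quiet = TRUE)
    M <- matrix(vals, nrow = d0, ncol = d1, byrow = TRUE)
    if (grepl("INT", dtype)) storage.mode(M) <- "integer"
    meta <- list()
    for (md in xml2::xml_find_all(da, "./MetaData/MD")) {
      nm <- xml2::xml_text(xml2::xml_find_first(md, "./Name"))
      meta[[nm]] <- xml2::xml_text(xml2::xml_find_first(md, "./Value"))
    }
    list(intent = xml2::xml_attr(da, "Intent"), data = M, meta = meta)
  })
}

#' @rdname surface_io
#' @param meta named list of extra metadata strings (e.g. `age_weeks`).
#' @export
write_surface <- function(surface, path, meta = list()) {
  if (inherits(surface, "spherical_mesh")) {
    verts <- surface$vertices; tris <- surface$triangles
    meta$role <- "sphere"
    if (!is.null(surface$mirror_perm))
      meta$mirror_perm <- paste(surface$mirror_perm, collapse = " ")
    if (!is.null(attr(surface, "level")))
      meta$level <- attr(surface, "level")
  } else {
    verts <- surface$vertices; tris <- surface$mesh$triangles
    meta$role <- surface$role
  }
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "2")
  gifti_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
              format_mat(verts), meta)
  gifti_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", tris - 1L)
  xml2::write_xml(doc, path)
  invisible(path)
}

format_mat <- function(M) {
  matrix(sprintf("%.9g", M), nrow(M), ncol(M))
}

#' @rdname surface_io
#' @param mesh for anatomical files, the paired `spherical_mesh` (the
#'   triangulation is re-read from file and checked against it).
#' @export
read_surface <- function(path, mesh = NULL) {
  arrs <- gifti_read_arrays(path)
  ptr <- Find(function(a) a$intent == "NIFTI_INTENT_POINTSET", arrs)
  trr <- Find(function(a) a$intent == "NIFTI_INTENT_TRIANGLE", arrs)
  if (is.null(ptr) || is.null(trr))
    stop("read_surface: file lacks POINTSET or TRIANGLE array: ", path)
  verts <- ptr$data
  tris <- trr$data + 1L
  role <- ptr$meta$role %||% "sphere"
  if (role == "sphere") {
    mp <- NULL
    if (!is.null(ptr$meta$mirror_perm))
      mp <- as.integer(scan(text = ptr$meta$mirror_perm, quiet = TRUE))
    # re-normalise: coordinates were rounded to float precision on write
    verts <- verts / sqrt(rowSums(verts^2))
    out <- spherical_mesh(verts, tris, mirror_perm = mp)
    if (!is.null(ptr$meta$level)) attr(out, "level") <- as.integer(ptr$meta$level)
    out
  } else {
    if (is.null(mesh))
      mesh <- spherical_mesh(verts / sqrt(rowSums(verts^2)), tris,
                             validate = FALSE)
    if (nrow(verts) != mesh$V)
      stop("read_surface: file has ", nrow(verts), " vertices but mesh has ",
           mesh$V)
    check_winding(verts, tris)
    anatomical_surface(verts, mesh, role)
  }
}

#' @rdname surface_io
#' @export
write_metric <- function(metric, path, meta = list()) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "1")
  meta$hemisphere <- metric$hemisphere
  meta$feature <- metric$feature
  gifti_array(doc, "NIFTI_INTENT_SHAPE", "NIFTI_TYPE_FLOAT32",
              format_mat(cbind(metric$values)), meta)
  if (!is.null(metric$missing))
    gifti_array(doc, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32",
                cbind(as.integer(metric$missing)), list(feature = "missing"))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname surface_io
#' @param expected_vertices optional vertex count to validate against.
#' @export
read_metric <- function(path, expected_vertices = NULL) {
  arrs <- gifti_read_arrays(path)
  a <- arrs[[1]]
  vals <- as.numeric(a$data[, 1])
  if (!is.null(expected_vertices) && length(vals) != expected_vertices)
    stop("read_metric: file has ", length(vals), " vertices, expected ",
         expected_vertices)
  missing <- NULL
  if (length(arrs) > 1 && arrs[[2]]$intent == "NIFTI_INTENT_LABEL")
    missing <- as.logical(arrs[[2]]$data[, 1])
  out <- metric_map(vals, a$meta$hemisphere %||% "left",
                    a$meta$feature %||% "metric", missing)
  attr(out, "meta") <- a$meta
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

covariate_columns <- c("subject_id", "ga_weeks", "pma_weeks", "sex", "bwz",
                       "tbv_cm3", "hemi_vol_asym_cm3")

#' Read a covariate table
#'
#' Tab-separated table with one row per subject; required columns are
#' `subject_id`, `ga_weeks` (gestational age at birth), `pma_weeks`
#' (postmenstrual age at scan), `sex` (0/1), `bwz` (birthweight Z-score),
#' `tbv_cm3` (total brain volume) and `hemi_vol_asym_cm3` (left minus right
#' hemispheric volume).
#'
#' @param path TSV file path.
#' @return data.frame with the columns above.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(covariate_columns, names(df))
  if (length(miss))
    stop("read_covariates: missing required columns: ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname read_covariates
#' @param covariates data.frame to write.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
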