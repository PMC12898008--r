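#' Run the dangerous-region pipeline end to end
#'
#' Reads tumor (and optionally bone) masks from NIfTI, generates the
#' dangerous region, reconstructs its surface, checks osteotomy-plane
#' clearances if a plan file is given, and writes the dense-grid mask
#' (NIfTI), the surface (STL/PLY), and a JSON run report. The report is
#' deterministic for identical inputs and configuration (floating values
#' serialized at fixed precision); all effective defaults are recorded in it
#' for provenance.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   fields: `tumor` (NIfTI path, required), `bone` (optional path),
#'   `margin_mm` (required), `pad_mm`, `band_mm`, `dense_spacing`,
#'   `shrink`, `restrict_to_bone`, `plan` (JSON plane file), and output
#'   paths `out_mask`, `out_surface`, `out_report`.
#' @return The report, invisibly (also written to `out_report` if set).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(structure(class = c("osteomargin_missing_file", "error", "condition"),
                     list(message = sprintf("config file not found: %s", config),
                          call = sys.call(-1))))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$tumor) || is.null(config$margin_mm))
    stop("config must provide 'tumor' and 'margin_mm'")
  tumor <- read_mask(config$tumor)
  bone <- if (!is.null(config$bone)) read_mask(config$bone) else NULL
  if (!is.null(bone) && !all(bone$grid$shape == tumor$grid$shape))
    stop(structure(class = c("osteomargin_grid_mismatch", "error", "condition"),
                   list(message = "tumor and bone grids differ",
                        call = sys.call(-1))))
  margin <- as.numeric(config$margin_mm)
  pad <- if (is.null(config$pad_mm)) margin + 20 else as.numeric(config$pad_mm)
  shrink <- if (is.null(config$shrink)) 1 else as.numeric(config$shrink)

  region <- generate_dangerous_region(
    tumor, bone, margin_mm = margin,
    band_mm = if (is.null(config$band_mm)) NULL else as.numeric(config$band_mm),
    pad_mm = pad,
    dense_spacing = if (is.null(config$dense_spacing)) NULL
                    else as.numeric(config$dense_spacing),
    restrict_to_bone = isTRUE(config$restrict_to_bone))

  surface <- region_surface(region, shrink = shrink)

  clearances <- NULL
  if (!is.null(config$plan)) {
    planes <- read_plane_plan(config$plan)
    clearances <- lapply(planes, function(pl) {
      cl <- plane_clearance(region, pl)
      list(name = pl$name, clearance_mm = round(as.numeric(cl), 6),
           safe = isTRUE(attr(cl, "safe")))
    })
  }

  prov <- region$provenance
  report <- list(
    margin_mm = margin,
    pad_mm = pad,
    band_mm = round(prov$band_mm, 6),
    dense_spacing = round(prov$dense_spacing, 6),
    shrink = shrink,
    restrict_to_bone = isTRUE(config$restrict_to_bone),
    tumor_voxels = sum(tumor$values),
    region_voxels = sum(region$dense_mask$values),
    region_volume_mm3 = round(mask_volume(region$dense_mask), 6),
    n_boundary_points = nrow(region$boundary_points),
    surface_faces = nrow(surface$faces),
    surface_area_mm2 = round(surface_area(surface), 6),
    surface_volume_mm3 = round(mesh_volume(surface), 6),
    planes = clearances)

  if (!is.null(config$out_mask)) write_mask(region$dense_mask, config$out_mask)
  if (!is.null(config$out_surface)) write_surface(surface, config$out_surface)
  if (!is.null(config$out_report))
    jsonlite::write_json(report, config$out_report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(report)
}
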