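# Readers/writers for localization tables (ThunderSTORM-compatible CSV
# dialect), assay configurations (flat YAML) and cohort manifests.

# normalize a header name: lower-case, strip units/brackets/separators,
# so "x [nm]", "x_nm", "X" all map to "x"
normalizeHeader <- function(nm) {
  nm <- tolower(nm)
  nm <- gsub("\\[.*?\\]", "", nm)
  nm <- gsub("[^a-z]", "", nm)
  sub("nm$", "", nm)
}

#' Read one localization CSV file into an ROI
#'
#' Accepts ThunderSTORM-style headers (`"x [nm]"`, `"y [nm]"`, `"sigma
#' [nm]"`) as well as plain (`x`, `y`) or underscore (`x_nm`) variants,
#' case-insensitively. Rows with non-finite coordinates or coordinates
#' outside the ROI rectangle are rejected and counted; accepted plus
#' rejected always equals the total row count. Duplicate localization ids
#' are re-keyed with a warning. An empty file yields an empty ROI with a
#' warning.
#'
#' @param path CSV file path.
#' @param roiId ROI identifier.
#' @param widthNm,heightNm physical ROI dimensions in nm.
#' @param coverslipId optional coverslip identifier.
#' @return An [SmlmRoi-class]; attribute `nRejected` carries the number of
#'   dropped rows.
#' @export
readLocalizationFile <- function(path, roiId, widthNm, heightNm,
                                 coverslipId = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  if (!nrow(raw)) {
    warning("empty localization file: ", path)
    roi <- smlmRoi(roiId, widthNm, heightNm)
    attr(roi, "nRejected") <- 0L
    return(roi)
  }
  key <- normalizeHeader(names(raw))
  pick <- function(canonical) {
    hit <- which(key == canonical)
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  x <- pick("x")
  y <- pick("y")
  if (is.null(x)) stop("missing mandatory column: x", call. = FALSE)
  if (is.null(y)) stop("missing mandatory column: y", call. = FALSE)
  loc <- data.frame(x = as.numeric(x), y = as.numeric(y))
  id <- pick("id")
  loc$id <- if (!is.null(id)) as.integer(id) else seq_len(nrow(loc))
  frame <- pick("frame")
  loc$frame <- if (!is.null(frame)) as.integer(frame) else seq_len(nrow(loc))
  sigma <- pick("sigma")
  if (!is.null(sigma)) loc$sigma <- as.numeric(sigma)
  intensity <- pick("intensity")
  if (!is.null(intensity)) loc$intensity <- as.numeric(intensity)

  ok <- is.finite(loc$x) & is.finite(loc$y) &
    loc$x >= 0 & loc$x <= widthNm & loc$y >= 0 & loc$y <= heightNm
  nRejected <- sum(!ok)
  if (nRejected)
    message(nRejected, " localization(s) rejected (out of bounds or ",
            "non-finite) in ", path)
  loc <- loc[ok, , drop = FALSE]
  if (anyDuplicated(loc$id)) {
    warning("duplicate localization ids in ", path, "; re-keyed")
    loc$id <- seq_len(nrow(loc))
  }
  loc <- loc[, intersect(c("id", "frame", "x", "y", "sigma", "intensity"),
                         names(loc)), drop = FALSE]
  rownames(loc) <- NULL
  roi <- smlmRoi(roiId, widthNm, heightNm, loc, coverslipId)
  attr(roi, "nRejected") <- nRejected
  roi
}

#' Read a set of ROIs described by a manifest
#'
#' @param manifest data.frame with columns `roi_id`, `path`, `width_nm`,
#'   `height_nm` and optionally `coverslip_id`; or the path of a CSV file
#'   with those columns.
#' @return list of [SmlmRoi-class] objects, in manifest order.
#' @export
readLocalizations <- function(manifest) {
  if (is.character(manifest))
    manifest <- data.table::fread(manifest, data.table = FALSE)
  need <- c("roi_id", "path", "width_nm", "height_nm")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("ROI manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cs <- if ("coverslip_id" %in% names(manifest)) manifest$coverslip_id
        else rep(NA_character_, nrow(manifest))
  lapply(seq_len(nrow(manifest)), function(i) {
    readLocalizationFile(manifest$path[i], manifest$roi_id[i],
                         manifest$width_nm[i], manifest$height_nm[i], cs[i])
  })
}

#' Write an ROI's localizations as ThunderSTORM-dialect CSV
#'
#' Columns `id, frame, "x [nm]", "y [nm]", "sigma [nm]", intensity`;
#' coordinates are written with three decimal places.
#'
#' @param roi an [SmlmRoi-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLocalizations <- function(roi, path) {
  stopifnot(is(roi, "SmlmRoi"))
  loc <- roi@localizations
  out <- data.frame(
    id = loc$id,
    frame = loc$frame,
    x = sprintf("%.3f", loc$x),
    y = sprintf("%.3f", loc$y),
    sigma = if ("sigma" %in% names(loc)) sprintf("%.3f", loc$sigma) else "",
    intensity = if ("intensity" %in% names(loc)) loc$intensity else "",
    check.names = FALSE
  )
  names(out) <- c("id", "frame", "x [nm]", "y [nm]", "sigma [nm]", "intensity")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an assay configuration from YAML
#'
#' Flat keys: `capture_target`, `stain_panel`, `volume_raw_ul` (mandatory)
#' and `L` (default 14), `M` (default 40), `alpha` (default 0.5),
#' `sigma_default` (default 12 nm), `exclude_boundary_clusters` (default
#' true). Invariant violations raise a configuration error naming the
#' offending key.
#'
#' @param path YAML file.
#' @return A validated [AssayConfig-class].
#' @export
readAssayConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("capture_target", "stain_panel", "volume_raw_ul")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("assay config lacks key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  assayConfig(
    captureTarget = cfg$capture_target,
    stainPanel = unlist(cfg$stain_panel),
    volumeRawUl = cfg$volume_raw_ul,
    L = if (is.null(cfg$L)) 14 else cfg$L,
    M = if (is.null(cfg$M)) 40L else cfg$M,
    alpha = if (is.null(cfg$alpha)) 0.5 else cfg$alpha,
    sigmaDefaultNm = if (is.null(cfg$sigma_default)) 12 else cfg$sigma_default,
    excludeBoundaryClusters =
      if (is.null(cfg$exclude_boundary_clusters)) TRUE
      else isTRUE(cfg$exclude_boundary_clusters)
  )
}

#' Echo a simulation configuration as a YAML manifest
#'
#' @param cfg a [SimConfig-class].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
writeSimManifest <- function(cfg, path) {
  stopifnot(is(cfg, "SimConfig"))
  fields <- slotNames(cfg)
  values <- lapply(fields, function(f) {
    v <- slot(cfg, f)
    if (!is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(setNames(values, fields), path)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' One row per (animal, fluid, capture, stain) condition, pointing at the
#' ROI manifest of that condition. Columns: `animal_id`, `cohort`
#' (`test`/`control`), `fluid` (`plasma`/`CSF`), `capture_target`, `stain`,
#' `path`, `volume_raw_ul`.
#'
#' @param path manifest CSV.
#' @return validated data.frame.
#' @export
readCohortManifest <- function(path) {
  m <- data.table::fread(path, data.table = FALSE)
  need <- c("animal_id", "cohort", "fluid", "capture_target", "stain",
            "path", "volume_raw_ul")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("cohort manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(m$cohort %in% c("test", "control")))
    stop("cohort must be 'test' or 'control'", call. = FALSE)
  if (any(m$volume_raw_ul <= 0))
    stop("volume_raw_ul must be > 0", call. = FALSE)
  m
}
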