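# File formats: NIfTI for volumes and masks (spacing carried in the
# header), CSV for cohorts, JSON for models and reports.

#' Read / write a CT volume as NIfTI
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param ct A [ct_volume()].
#' @return `read_ct_volume` returns a [ct_volume()] with spacing taken
#'   from the header; `write_ct_volume` returns `path` invisibly.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  ct_volume(array(as.numeric(img), dim = dim(img)), spacing = sp[1:3])
}

#' @rdname read_ct_volume
#' @export
write_ct_volume <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  img <- RNifti::asNifti(ct$values)
  RNifti::pixdim(img) <- ct$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a segmentation set as a directory of NIfTI masks
#'
#' One file per mask (`<name>.nii.gz`); `vertebral_bodies` keeps its
#' integer labels, with the name-to-label map in a
#' `vertebra_labels.json` sidecar. On read, all masks must agree on grid
#' shape and spacing; offenders are listed.
#'
#' @param segs A [seg_set()].
#' @param dir Directory (created if needed).
#' @return `read_seg_set` returns a [seg_set()]; `write_seg_set` returns
#'   `dir` invisibly.
#' @export
write_seg_set <- function(segs, dir) {
  stopifnot(inherits(segs, "seg_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(segs$masks)) {
    v <- segs$masks[[nm]]
    img <- RNifti::asNifti(array(as.integer(v), dim = dim(v)))
    RNifti::pixdim(img) <- segs$spacing
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  if (!is.null(segs$vertebra_labels))
    jsonlite::write_json(as.list(segs$vertebra_labels),
                         file.path(dir, "vertebra_labels.json"),
                         auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_seg_set
#' @export
read_seg_set <- function(dir) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(files)) stopf("no NIfTI masks found in %s", dir)
  masks <- list()
  dims <- list()
  sps <- list()
  for (f in files) {
    nm <- sub("\\.nii(\\.gz)?$", "", basename(f))
    img <- RNifti::readNifti(f)
    dims[[nm]] <- dim(img)
    sps[[nm]] <- RNifti::pixdim(img)[1:3]
    masks[[nm]] <- if (nm == "vertebral_bodies")
      array(as.integer(img), dim = dim(img))
    else array(as.integer(img) != 0, dim = dim(img))
  }
  ref <- names(masks)[1]
  bad <- names(masks)[!vapply(names(masks), function(nm)
    all(dims[[nm]] == dims[[ref]]) &&
      all(abs(sps[[nm]] - sps[[ref]]) < 1e-6), TRUE)]
  if (length(bad))
    stopf("masks with mismatched grid/spacing: %s", paste(bad, collapse = ", "))
  labfile <- file.path(dir, "vertebra_labels.json")
  labels <- if (file.exists(labfile))
    unlist(jsonlite::read_json(labfile, simplifyVector = TRUE))
  seg_set(masks, spacing = sps[[ref]], vertebra_labels = labels)
}

#' Read / write a patient cohort as CSV
#'
#' Reading applies typed validation: `event` must be 0/1 (character
#' encodings are coerced with a warning), `followup_days` positive, and
#' any CAPRI clinical columns present are validated through
#' [encode_clinical()]. Unknown columns pass through untouched.
#'
#' @param path CSV file.
#' @param cohort `data.frame`.
#' @param require Character vector of mandatory columns.
#' @return `read_cohort` returns a validated `data.frame`;
#'   `write_cohort` returns `path` invisibly (seed attribute, when
#'   present, goes to a JSON sidecar).
#' @export
read_cohort <- function(path, require = c("followup_days", "event")) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(require, names(df))
  if (length(missing))
    stopf("cohort lacks mandatory column(s): %s", paste(missing, collapse = ", "))
  if ("event" %in% names(df)) {
    if (is.character(df$event)) {
      warnf("event column read as character; coercing to 0/1")
      df$event <- as.integer(df$event)
    }
    if (!all(df$event %in% c(0, 1))) stopf("column 'event' must be 0/1")
  }
  if ("followup_days" %in% names(df) && any(df$followup_days <= 0))
    stopf("column 'followup_days' must be strictly positive")
  encode_clinical(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  if (!is.null(attr(cohort, "seed")))
    jsonlite::write_json(list(seed = attr(cohort, "seed")),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serializes evaluation/selection reports (lists and data.frames) with
#' full numeric precision.
#'
#' @param report A list (e.g. [evaluate_scores()] output).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       dataframe = "rows")
  invisible(path)
}
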