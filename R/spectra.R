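#' DSEG spectrum of a labelled scan
#'
#' Tallies the labelled cerebrum voxels per segment and expresses each
#' segment as a percentage of cerebrum volume, in canonical segment order.
#' The 16 percentages sum to 100 and form the vector compared across scans
#' by the spectral angle.
#'
#' @param labels a [assign_segments()] result.
#' @param subject_id,visit_time identifiers carried on the spectrum.
#' @return an object of class `"dseg_spectrum"`: `values` (percentages,
#'   length k), `subject_id`, `visit_time`, `n_voxels`.
#' @export
compute_spectrum <- function(labels, subject_id = NA_character_,
                             visit_time = NA_real_) {
  stopifnot(inherits(labels, "segment_labels"))
  lab <- labels$labels[labels$mask]
  if (length(lab) == 0) stop("empty scan: no in-mask voxels")
  counts <- tabulate(lab, nbins = labels$k)
  dseg_spectrum(100 * counts / length(lab), subject_id, visit_time,
                n_voxels = length(lab))
}

#' Construct a DSEG spectrum from raw values
#'
#' @param values non-negative vector summing to 100 (within 1e-9 after the
#'   internal renormalisation check).
#' @param subject_id,visit_time identifiers.
#' @param n_voxels voxel count behind the spectrum (NA if synthetic).
#' @return an object of class `"dseg_spectrum"`.
#' @export
dseg_spectrum <- function(values, subject_id = NA_character_,
                          visit_time = NA_real_, n_voxels = NA_integer_) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("spectrum values must be non-negative")
  s <- sum(values)
  if (s <= 0) stop("spectrum must have positive total")
  if (abs(s - 100) > 1e-9) stop("spectrum values must sum to 100")
  structure(list(values = values, subject_id = subject_id,
                 visit_time = visit_time, n_voxels = n_voxels),
            class = "dseg_spectrum")
}

#' Default tissue-class map from centroid positions
#'
#' Maps each segment to one of the five classes used to annotate the
#' spectrum axis — GM, WM, CSF, GM/CSF-borderline, WMH-related — from the
#' position of its centroid in the (p,q) plane. The thresholds are a
#' documented convention (mm^2/s): high anisotropy is WM; among
#' low-anisotropy segments, isotropy separates GM, WMH-related damage,
#' borderline partial-volume tissue and CSF. The map affects only summary
#' tables, never the spectrum or theta.
#'
#' @param model a fitted `dseg_model`.
#' @param q_wm q threshold for WM (default 7e-4).
#' @param p_csf p threshold for CSF (default 3e-3).
#' @param p_borderline p threshold for GM/CSF-borderline (default 2.4e-3).
#' @param p_wmh p threshold for WMH-related tissue (default 1.75e-3).
#' @return named character vector of class `"tissue_class_map"`, one class
#'   per canonical segment.
#' @export
tissue_class_map_from_centroids <- function(model, q_wm = 7e-4,
                                            p_csf = 3e-3,
                                            p_borderline = 2.4e-3,
                                            p_wmh = 1.75e-3) {
  stopifnot(inherits(model, "dseg_model"))
  cen <- model$centroids[model$canonical_order, , drop = FALSE]
  cls <- ifelse(cen[, 2] >= q_wm, "WM",
         ifelse(cen[, 1] >= p_csf, "CSF",
         ifelse(cen[, 1] >= p_borderline, "GM/CSF-borderline",
         ifelse(cen[, 1] >= p_wmh, "WMH-related", "GM"))))
  structure(stats::setNames(cls, paste0("s", seq_len(nrow(cen)))),
            class = "tissue_class_map")
}

#' Tissue-class summary of a spectrum
#'
#' Sums spectrum percentages within each tissue class of a map. The class
#' sums total 100 whenever the map covers all segments.
#'
#' @param spec a `dseg_spectrum`.
#' @param map a character vector of length k assigning one class label per
#'   canonical segment (e.g. from [tissue_class_map_from_centroids()]).
#' @return named numeric vector of class percentages.
#' @export
tissue_class_summary <- function(spec, map) {
  stopifnot(inherits(spec, "dseg_spectrum"))
  map <- unclass(map)
  if (length(map) != length(spec$values)) {
    stop("map must assign a class to every segment")
  }
  if (any(is.na(map) | !nzchar(map))) stop("unmapped segment in map")
  out <- tapply(spec$values, map, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Write spectra to TSV
#'
#' One row per scan: `subject_id`, `visit_time`, `n_voxels`, `s01..s16`.
#'
#' @param spectra list of `dseg_spectrum` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_tsv <- function(spectra, path) {
  k <- length(spectra[[1]]$values)
  df <- do.call(rbind, lapply(spectra, function(s) {
    row <- data.frame(subject_id = s$subject_id, visit_time = s$visit_time,
                      n_voxels = s$n_voxels)
    vals <- as.data.frame(as.list(s$values))
    names(vals) <- sprintf("s%02d", seq_len(k))
    cbind(row, vals)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spectra from TSV written by [write_spectra_tsv()]
#'
#' @param path TSV path.
#' @return list of `dseg_spectrum` objects.
#' @export
read_spectra_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  vcols <- grep("^s[0-9]+$", names(df))
  lapply(seq_len(nrow(df)), function(i) {
    dseg_spectrum(as.numeric(df[i, vcols]), df$subject_id[i],
                  df$visit_time[i], df$n_voxels[i])
  })
}
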