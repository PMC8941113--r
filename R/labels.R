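## Label schemes. Functional labels come from group-ICA spatial maps, anatomical
## labels from an integer-coded lobe atlas. Multi-membership is allowed: one
## voxel can carry several labels.

#' Canonical label orders for the supported schemes
#'
#' \code{functional-15}: the fifteen group-ICA resting-state components
#' (default-mode, anterior DMN, precuneus, salience, dorsal attention,
#' left/right central executive, two sensorimotor, auditory, four visual and
#' visual attention networks). \code{functional-7}: the seven merged
#' categories. Anatomical schemes carry lobe labels and are free-form apart
#' from the scheme tag.
#'
#' @param scheme one of \code{"functional-15"}, \code{"functional-7"},
#'   \code{"anatomical-15"}, \code{"anatomical-8"}.
#' @return character vector of label names in canonical order (for anatomical
#'   schemes, \code{NULL}: caller-defined order).
#' @export
scheme_labels <- function(scheme) {
  switch(scheme,
    "functional-15" = c("DMN", "aDMN", "PCN", "SN", "DAN", "L_CEN", "R_CEN",
                        "SMN1", "SMN2", "AN", "VN1", "VN2", "VN3", "VN4", "VAN"),
    "functional-7" = c("DMN", "SN", "DAN", "CEN", "SMN", "AN", "VN"),
    "anatomical-15" = NULL,
    "anatomical-8" = NULL,
    stop_hc("unknown scheme: ", scheme))
}

## 15 -> 7 category mapping (PCN is posterior DMN).
map_15_to_7 <- c(
  DMN = "DMN", aDMN = "DMN", PCN = "DMN",
  SN = "SN", DAN = "DAN",
  L_CEN = "CEN", R_CEN = "CEN",
  SMN1 = "SMN", SMN2 = "SMN",
  AN = "AN",
  VN1 = "VN", VN2 = "VN", VN3 = "VN", VN4 = "VN", VAN = "VN")

#' Voxel label map
#'
#' Maps voxel identifiers to (possibly empty, possibly multiple) label sets
#' under a named scheme.
#'
#' @param scheme scheme tag; see \code{\link{scheme_labels}}.
#' @param membership named list: names are voxel ids (as integers coerced to
#'   character), values are character vectors of labels. Voxels with empty
#'   label sets may simply be absent.
#' @param label_order canonical ordered label vector; defaults to the scheme's
#'   canonical order, or to the sorted set of labels seen for anatomical
#'   schemes.
#' @return An object of class \code{label_map}.
#' @export
label_map <- function(scheme, membership, label_order = NULL) {
  canonical <- scheme_labels(scheme)
  if (is.null(label_order))
    label_order <- canonical %||% sort(unique(unlist(membership)))
  seen <- unique(unlist(membership))
  if (length(seen) && !all(seen %in% label_order))
    stop_hc("labels not in label_order: ",
            paste(setdiff(seen, label_order), collapse = ", "))
  structure(list(scheme = scheme, membership = membership,
                 label_order = label_order),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map [%s]: %d labelled voxels, %d labels\n",
              x$scheme, length(x$membership), length(x$label_order)))
  invisible(x)
}

## Labels of one voxel id (character(0) when unlabelled).
labels_of <- function(lm, voxel_id) {
  lm$membership[[as.character(voxel_id)]] %||% character(0)
}

#' Binarize IC spatial Z-maps into a functional label map
#'
#' A voxel belongs to an independent component iff its Z value strictly
#' exceeds \code{z_threshold} (default 6) in that component's spatial map;
#' voxels exceeding the threshold in several maps keep every membership.
#'
#' @param zmaps named list of 3D numeric arrays (or NIfTI file paths), one per
#'   IC, all on the same grid; names are the IC labels.
#' @param z_threshold strict lower bound on Z (default 6).
#' @param scheme scheme tag for the result (default \code{"functional-15"}).
#' @return A \code{\link{label_map}} keyed by 0-based C-order flat voxel index.
#' @export
binarize_ic_maps <- function(zmaps, z_threshold = 6, scheme = "functional-15") {
  arrs <- lapply(zmaps, function(z) {
    if (is.character(z)) as.array(RNifti::readNifti(z)) else as.array(z)
  })
  dims <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), dims), logical(1))))
    stop_hc("IC map grids do not match")
  trip <- grid_triples(dims)
  col_major <- trip[, 1] + dims[1] * (trip[, 2] + dims[2] * trip[, 3]) + 1L
  ids <- flat_index(trip, dims)
  hits <- lapply(arrs, function(a) as.vector(a)[col_major] > z_threshold)
  membership <- list()
  for (lab in names(arrs)) {
    for (v in ids[hits[[lab]]]) {
      key <- as.character(v)
      membership[[key]] <- c(membership[[key]], lab)
    }
  }
  label_map(scheme, membership,
            label_order = scheme_labels(scheme) %||% names(arrs))
}

#' Merge the fifteen functional components into seven categories
#'
#' DMN, anterior DMN and the precuneus network merge into DMN; left and right
#' central executive into CEN; the two sensorimotor components into SMN; the
#' four visual networks and the visual attention network into VN; SN, DAN and
#' AN stay. A voxel belonging to several constituents of one category counts
#' once in that category.
#'
#' @param labels a \code{\link{label_map}} with scheme \code{"functional-15"}.
#' @return A \code{\link{label_map}} with scheme \code{"functional-7"}.
#' @export
combine_to_seven <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  if (labels$scheme != "functional-15")
    stop_hc("combine_to_seven expects scheme functional-15")
  membership <- lapply(labels$membership, function(labs) {
    unknown <- setdiff(labs, names(map_15_to_7))
    if (length(unknown)) stop_hc("unknown source label: ",
                                 paste(unknown, collapse = ", "))
    unique(unname(map_15_to_7[labs]))
  })
  label_map("functional-7", membership)
}
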