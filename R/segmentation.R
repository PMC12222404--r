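#' Construct a segmentation set
#'
#' Named binary masks on a shared grid: tumour, whole liver (WL), whole
#' normal liver (WNL), body, and organs at risk. The WNL is always derived
#' as WL minus tumour, and every named region must be contained in the body.
#'
#' @param masks named list of logical 3D arrays on a common grid. Must
#'   contain at least `body`; if `wl` and `tumour` are present, `wnl` is
#'   (re)derived as `wl & !tumour`.
#' @param spacing voxel spacing, mm.
#' @param origin world origin, mm.
#' @param check validate the set-algebra invariants (default TRUE).
#' @return an object of class `segmentation_set`.
#' @export
segmentation_set <- function(masks, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             check = TRUE) {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.array(m) || length(dim(m)) != 3L || !identical(dim(m), d))
      stop("segmentation_set: mask '", nm, "' is not on the shared grid", call. = FALSE)
    storage.mode(masks[[nm]]) <- "logical"
  }
  if (!is.null(masks$wl) && !is.null(masks$tumour))
    masks$wnl <- masks$wl & !masks$tumour
  obj <- structure(list(masks = masks, spacing = as.numeric(spacing),
                        origin = as.numeric(origin)),
                   class = "segmentation_set")
  if (check) validate_segmentation(obj)
  obj
}

validate_segmentation <- function(set) {
  m <- set$masks
  if (!is.null(m$wl) && !is.null(m$tumour)) {
    if (any(m$tumour & !m$wl))
      stop("segmentation_set: tumour must be a subset of WL", call. = FALSE)
    if (!is.null(m$wnl) && !identical(m$wnl, m$wl & !m$tumour))
      stop("segmentation_set: WNL must equal WL minus tumour", call. = FALSE)
  }
  if (!is.null(m$body)) {
    for (nm in setdiff(names(m), "body")) {
      if (any(m[[nm]] & !m$body))
        stop("segmentation_set: region '", nm,
             "' extends outside the body mask", call. = FALSE)
    }
  }
  invisible(set)
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat("<segmentation_set>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-8s %d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}

#' Region names available in a segmentation set
#' @param set a [segmentation_set].
#' @return character vector of region names.
#' @export
region_names <- function(set) names(set$masks)

#' Extract one region mask
#' @param set a [segmentation_set].
#' @param name region name.
#' @return logical 3D array.
#' @export
region_mask <- function(set, name) {
  m <- set$masks[[name]]
  if (is.null(m)) stop("region_mask: no region named '", name, "'", call. = FALSE)
  m
}

#' Encode a segmentation set as an integer label volume
#'
#' Regions are written in the given priority order (later wins), with the
#' label table returned alongside — the on-disk representation (label volume
#' + sidecar JSON).
#'
#' @param set a [segmentation_set].
#' @param order region priority order; defaults to body first, tumour last.
#' @return list with `label_volume` (integer array) and `label_table`
#'   (named integer vector).
#' @export
encode_labels <- function(set, order = NULL) {
  nms <- names(set$masks)
  if (is.null(order)) {
    pref <- c("body", "lungs", "kidneys", "stomach", "wl", "wnl", "tumour")
    order <- c(intersect(pref, nms), setdiff(nms, pref))
  }
  lab <- array(0L, dim(set$masks[[1]]))
  table <- stats::setNames(seq_along(order), order)
  for (nm in order) lab[set$masks[[nm]]] <- table[[nm]]
  list(label_volume = lab, label_table = table)
}

#' Decode an integer label volume into a segmentation set
#'
#' Inverse of [encode_labels()] for nested anatomy: body contains everything,
#' WL contains WNL and tumour. Containment is reconstructed from the label
#' table names.
#'
#' @param label_volume integer 3D array.
#' @param label_table named integer vector mapping region name to label.
#' @param spacing,origin grid metadata.
#' @return a [segmentation_set].
#' @export
decode_labels <- function(label_volume, label_table,
                          spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  masks <- lapply(label_table, function(v) label_volume == v)
  names(masks) <- names(label_table)
  if (!is.null(masks$wnl) && !is.null(masks$tumour))
    masks$wl <- masks$wnl | masks$tumour
  if (!is.null(masks$body)) {
    inner <- setdiff(names(masks), "body")
    for (nm in inner) masks$body <- masks$body | masks[[nm]]
  }
  segmentation_set(masks, spacing = spacing, origin = origin)
}
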