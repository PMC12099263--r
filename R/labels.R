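#' Label dictionaries
#'
#' A label dictionary fixes the encoding of a multi-class label map: an
#' ordered set of distinct non-negative integer codes, a tissue name for
#' each, and exactly one background code. All metric, topology and ranking
#' functions interpret label maps through a dictionary, so the toolkit
#' generalises to any coding scheme.
#'
#' @param codes Integer vector of distinct non-negative label codes.
#' @param names Character vector of tissue names, one per code.
#' @param background Integer; the background code (must be among `codes`).
#'
#' @return An object of class `label_dictionary`.
#' @examples
#' d <- label_dictionary(0:2, c("background", "lesion", "oedema"))
#' tissue_codes(d)
#' @export
label_dictionary <- function(codes, names, background = 0L) {
  codes <- as.integer(codes)
  names <- as.character(names)
  if (length(codes) != length(names))
    stop("`codes` and `names` must have the same length")
  if (anyDuplicated(codes)) stop("label codes must be distinct")
  if (anyDuplicated(names)) stop("label names must be distinct")
  if (any(codes < 0L)) stop("label codes must be non-negative")
  background <- as.integer(background)
  if (length(background) != 1L || !background %in% codes)
    stop("`background` must be exactly one of the codes")
  structure(
    list(codes = codes, names = names, background = background),
    class = "label_dictionary"
  )
}

#' Default fetal brain tissue dictionary
#'
#' The eight-class encoding used for fetal brain MRI tissue annotation:
#' 0 = background, 1 = external cerebrospinal fluid (eCSF), 2 = cortical
#' grey matter (GM), 3 = white matter (WM), 4 = ventricles,
#' 5 = cerebellum, 6 = deep grey matter (deepGM), 7 = brainstem.
#'
#' @return A [label_dictionary()].
#' @export
fetal_tissue_dictionary <- function() {
  label_dictionary(
    codes = 0:7,
    names = c("background", "eCSF", "GM", "WM", "ventricles",
              "cerebellum", "deepGM", "brainstem"),
    background = 0L
  )
}

#' @rdname label_dictionary
#' @param dictionary A `label_dictionary`.
#' @return `tissue_codes()`: the non-background codes, named by tissue.
#' @export
tissue_codes <- function(dictionary) {
  stopifnot(inherits(dictionary, "label_dictionary"))
  keep <- dictionary$codes != dictionary$background
  setNames(dictionary$codes[keep], dictionary$names[keep])
}

#' @export
print.label_dictionary <- function(x, ...) {
  cat("Label dictionary (", length(x$codes), " codes, background = ",
      x$background, ")\n", sep = "")
  for (i in seq_along(x$codes))
    cat(sprintf("  %2d: %s\n", x$codes[i], x$names[i]))
  invisible(x)
}

#' Read a label dictionary from a YAML config
#'
#' Expected layout:
#' ```yaml
#' background: 0
#' labels:
#'   1: eCSF
#'   2: GM
#' ```
#' The background code is listed separately and named "background".
#'
#' @param path Path to a YAML file.
#' @return A [label_dictionary()].
#' @export
read_label_dictionary <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$labels)) stop("dictionary config lacks a `labels` mapping")
  bg <- as.integer(cfg$background %||% 0L)
  codes <- as.integer(names(cfg$labels))
  if (anyNA(codes)) stop("label codes in config must be integers")
  label_dictionary(
    codes = c(bg, codes),
    names = c("background", vapply(cfg$labels, as.character, "")),
    background = bg
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a label map
#'
#' A label map couples a 3D integer voxel grid with its physical voxel
#' spacing (mm) and a label dictionary. Every voxel value must appear in
#' the dictionary unless `permissive = TRUE`.
#'
#' @param grid 3D array of integer label codes (integer-valued doubles are
#'   accepted within a tolerance of 1e-6, as label volumes are frequently
#'   stored in float NIfTI datatypes).
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm;
#'   strictly positive.
#' @param dictionary A [label_dictionary()].
#' @param permissive Logical; if `TRUE`, voxel codes absent from the
#'   dictionary are tolerated (they are treated as background by
#'   [split_labels()]).
#' @param header Opaque passthrough metadata (e.g. a NIfTI header) carried
#'   along for writing; ignored by all computations.
#'
#' @return An object of class `label_map` with elements `grid`, `spacing`,
#'   `dictionary`, `header`.
#' @export
label_map <- function(grid, spacing, dictionary = fetal_tissue_dictionary(),
                      permissive = FALSE, header = NULL) {
  if (length(dim(grid)) != 3L) stop("`grid` must be a 3D array")
  if (is.double(grid)) {
    rounded <- round(grid)
    if (max(abs(grid - rounded)) > 1e-6)
      stop("grid contains non-integer voxel values")
    grid <- rounded
  }
  g <- array(as.integer(grid), dim = dim(grid))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  stopifnot(inherits(dictionary, "label_dictionary"))
  if (!permissive) {
    present <- sort(unique(as.vector(g)))
    unknown <- setdiff(present, dictionary$codes)
    if (length(unknown))
      stop("grid contains codes not in the dictionary: ",
           paste(unknown, collapse = ", "))
  }
  structure(
    list(grid = g, spacing = spacing, dictionary = dictionary, header = header),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat("Label map ", paste(dim(x$grid), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  tab <- table(factor(x$grid, levels = x$dictionary$codes,
                      labels = x$dictionary$names))
  print(tab)
  invisible(x)
}

#' Read a multi-class label map from a NIfTI file
#'
#' Voxel spacing is taken from the file header; the full NIfTI image is
#' retained as opaque header metadata so that [write_label_map()] can
#' preserve orientation. Non-integer voxel content (beyond a 1e-6
#' tolerance) is rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @inheritParams label_map
#' @return A [label_map()].
#' @export
read_label_map <- function(path, dictionary = fetal_tissue_dictionary(),
                           permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  grid <- as.array(img)
  if (length(dim(grid)) != 3L)
    stop("expected a 3D volume, got ", length(dim(grid)), " dimensions")
  spacing <- RNifti::pixdim(img)[1:3]
  label_map(grid, spacing, dictionary = dictionary, permissive = permissive,
            header = img)
}

#' Write a label map to a NIfTI file
#'
#' The voxel grid is written bit-exactly as a 32-bit integer volume with
#' the map's spacing; if the map carries a NIfTI header from
#' [read_label_map()], its orientation is reused.
#'
#' @param map A [label_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  if (!is.null(map$header)) {
    img <- RNifti::asNifti(map$grid, reference = map$header)
  } else {
    img <- RNifti::asNifti(map$grid)
  }
  RNifti::pixdim(img) <- map$spacing
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Split a label map into per-tissue binary masks
#'
#' Produces one logical mask per non-background code of the dictionary
#' (including empty masks for absent tissues). The masks are pairwise
#' disjoint and their union is the non-background voxel set.
#'
#' @param map A [label_map()].
#' @return A named list of 3D logical arrays, named by label code; the
#'   `tissue_names` attribute carries the matching tissue names and the
#'   `spacing` attribute the voxel spacing in mm.
#' @export
split_labels <- function(map) {
  stopifnot(inherits(map, "label_map"))
  codes <- tissue_codes(map$dictionary)
  masks <- lapply(codes, function(code) map$grid == code)
  names(masks) <- as.character(codes)
  attr(masks, "tissue_names") <- names(codes)
  attr(masks, "spacing") <- map$spacing
  masks
}

#' Reassemble a label map from per-tissue masks
#'
#' Inverse of [split_labels()]: paints each mask with its code onto a
#' background canvas. Overlapping masks are an error (split/merge is only
#' defined for disjoint masks).
#'
#' @param masks Named list of logical arrays as produced by
#'   [split_labels()] (names are label codes).
#' @param dictionary A [label_dictionary()].
#' @param spacing Voxel spacing in mm; defaults to the `spacing` attribute
#'   of `masks`.
#' @return A [label_map()].
#' @export
merge_labels <- function(masks, dictionary = fetal_tissue_dictionary(),
                         spacing = attr(masks, "spacing")) {
  codes <- as.integer(names(masks))
  if (anyNA(codes)) stop("`masks` must be named by integer label codes")
  d <- dim(masks[[1]])
  total <- Reduce(`+`, lapply(masks, function(m) as.integer(m)))
  if (any(total > 1L)) stop("masks overlap; cannot merge")
  grid <- array(dictionary$background, dim = d)
  for (i in seq_along(masks)) grid[masks[[i]]] <- codes[i]
  label_map(grid, spacing, dictionary = dictionary)
}

#' Read a case metadata table
#'
#' Reads a CSV with columns `case_id`, `site`, `quality`, `pathological`,
#' `sr_method` (and optionally `gestational_age`). Quality is an ordinal
#' rating: 3 = Excellent, 2 = Good, 1 = Poor.
#'
#' @param path Path to the CSV file.
#' @return A data frame, one row per case.
#' @export
read_case_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "site", "quality", "pathological", "sr_method")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  md$case_id <- as.character(md$case_id)
  md$quality <- as.integer(md$quality)
  bad <- !is.na(md$quality) & !md$quality %in% 1:3
  if (any(bad))
    stop("quality ratings must be in {1, 2, 3} (Poor, Good, Excellent)")
  md$pathological <- as.logical(md$pathological)
  md
}
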