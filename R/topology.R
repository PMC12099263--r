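#' Connected components of a 3D binary mask
#'
#' Labels maximal connected sets of foreground voxels under the stated
#' digital adjacency: 6 (shared faces), 18 (faces + edges) or 26
#' (faces + edges + corners).
#'
#' @param mask 3D logical array.
#' @param connectivity One of 6, 18, 26. Foreground topology in this
#'   package uses 26; background (cavity) labeling uses the dual 6.
#' @return A list with `count` (number of components) and `labels`
#'   (integer array assigning 1..count to foreground voxels, 0 elsewhere).
#' @export
connected_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) != 3L) stop("`mask` must be a 3D array")
  res <- cpp_label_components(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  res$labels <- array(res$labels, dim = d)
  res
}

#' Euler characteristic of a mask's cubical complex
#'
#' Treats each foreground voxel as a closed unit cube and counts the
#' distinct vertices, edges, faces and cubes of the union:
#' `chi = V - E + F - C`. For this complex `chi = b0 - b1 + b2`, which is
#' how [betti_numbers()] recovers the tunnel count.
#'
#' @param mask 3D logical array.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("`mask` must be a 3D array")
  if (!any(mask)) return(0L)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  # count cells spanning the given axes: a cell is present iff any incident
  # voxel is foreground; span = 1 fixes the axis, span = 0 scans both sides
  count_cells <- function(span) {
    g <- d + 1L - span
    acc <- array(FALSE, g)
    shifts <- lapply(span, function(s) if (s == 1L) 1L else 0:1)
    for (s1 in shifts[[1]]) for (s2 in shifts[[2]]) for (s3 in shifts[[3]]) {
      acc <- acc | p[(1:g[1]) + s1, (1:g[2]) + s2, (1:g[3]) + s3, drop = FALSE]
    }
    sum(acc)
  }
  V <- count_cells(c(0L, 0L, 0L))
  E <- count_cells(c(1L, 0L, 0L)) + count_cells(c(0L, 1L, 0L)) +
       count_cells(c(0L, 0L, 1L))
  Fc <- count_cells(c(1L, 1L, 0L)) + count_cells(c(1L, 0L, 1L)) +
        count_cells(c(0L, 1L, 1L))
  C <- sum(mask)
  as.integer(V - E + Fc - C)
}

crop_to_bbox <- function(mask) {
  # Betti numbers are invariant under translation and background padding,
  # so computing on the foreground bounding box is exact and much cheaper
  # on large canvases
  idx <- lapply(1:3, function(k) {
    r <- range(which(apply(mask, k, any)))
    r[1]:r[2]
  })
  mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

pad_mask <- function(mask, width = 1L) {
  d <- dim(mask)
  p <- array(FALSE, d + 2L * width)
  idx <- lapply(d, function(n) (width + 1L):(width + n))
  p[idx[[1]], idx[[2]], idx[[3]]] <- mask
  p
}

#' Betti numbers of a 3D binary mask
#'
#' Counts the topological features of the foreground object:
#' * `b0` — connected components (26-connectivity),
#' * `b1` — tunnels/handles,
#' * `b2` — enclosed cavities.
#'
#' Foreground uses 26-connectivity and background the dual 6-connectivity,
#' the standard pairing that avoids digital-topology paradoxes and matches
#' the union-of-closed-cubes complex of [euler_characteristic()]. Cavities
#' are bounded background components after padding with a one-voxel
#' background shell (so objects touching the grid edge create no spurious
#' cavities), and the tunnel count is derived exactly from the Euler
#' characteristic: `b1 = b0 + b2 - chi`.
#'
#' @param mask 3D logical array.
#' @return Named integer vector `c(b0, b1, b2)`; `c(0, 0, 0)` for an empty
#'   mask.
#' @seealso [betti_numbers_gf2()] for the independent boundary-matrix
#'   reference implementation.
#' @export
betti_numbers <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("`mask` must be a 3D array")
  if (!any(mask)) return(c(b0 = 0L, b1 = 0L, b2 = 0L))
  mask <- crop_to_bbox(mask)
  b0 <- connected_components(mask, 26L)$count
  p <- pad_mask(mask)
  bg <- connected_components(!p, 6L)$count
  b2 <- bg - 1L  # the padding shell guarantees exactly one unbounded component
  chi <- euler_characteristic(mask)
  b1 <- b0 + b2 - chi
  c(b0 = as.integer(b0), b1 = as.integer(b1), b2 = as.integer(b2))
}

# Cell inventory of the cubical complex, with boundary incidences, for the
# GF(2) homology reference path. Cells are keyed by their minimal vertex
# and orientation; keys are unique within base B = max(dim) + 2.
cubical_complex <- function(mask) {
  d <- dim(mask)
  vox <- which(mask)
  n <- length(vox)
  co <- arrayInd(vox, d)
  B <- max(d) + 2
  vkey <- function(x, y, z) x + B * (y + B * z)

  # vertices: 8 corners per voxel
  corners <- vector("list", 8)
  i <- 1L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    corners[[i]] <- vkey(co[, 1] + dx, co[, 2] + dy, co[, 3] + dz)
    i <- i + 1L
  }
  vkeys <- sort(unique(unlist(corners)))

  # edges: axis + min vertex
  unit <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ekey <- function(axis, vx, vy, vz) vkey(vx, vy, vz) + axis * B^3
  edges <- list()
  for (axis in 1:3) {
    others <- setdiff(1:3, axis)
    for (da in 0:1) for (db in 0:1) {
      off <- c(0, 0, 0)
      off[others[1]] <- da
      off[others[2]] <- db
      edges[[length(edges) + 1L]] <-
        ekey(axis, co[, 1] + off[1], co[, 2] + off[2], co[, 3] + off[3])
    }
  }
  ekeys <- sort(unique(unlist(edges)))

  # faces: normal axis + min vertex
  fkey <- function(normal, vx, vy, vz) vkey(vx, vy, vz) + normal * B^3
  faces <- list()
  for (normal in 1:3) {
    for (dn in 0:1) {
      off <- c(0, 0, 0)
      off[normal] <- dn
      faces[[length(faces) + 1L]] <-
        fkey(normal, co[, 1] + off[1], co[, 2] + off[2], co[, 3] + off[3])
    }
  }
  fkeys <- sort(unique(unlist(faces)))

  decode <- function(key) {
    key <- key %% B^3
    z <- key %/% (B * B)
    r <- key %% (B * B)
    cbind(r %% B, r %/% B, z)
  }

  # boundary of edges: the two endpoint vertices
  eaxis <- ekeys %/% B^3
  ev <- decode(ekeys)
  b1_pairs <- rbind(
    cbind(seq_along(ekeys), match(vkey(ev[, 1], ev[, 2], ev[, 3]), vkeys)),
    cbind(seq_along(ekeys),
          match(vkey(ev[, 1] + (eaxis == 1), ev[, 2] + (eaxis == 2),
                     ev[, 3] + (eaxis == 3)), vkeys))
  )

  # boundary of faces: four edges spanning the two in-plane axes
  fnormal <- fkeys %/% B^3
  fv <- decode(fkeys)
  b2_list <- vector("list", 4)
  slot <- 1L
  for (k in 1:2) {
    # for each face, in-plane axes depend on its normal
    ax <- vapply(fnormal, function(nrm) setdiff(1:3, nrm)[k], 0L)
    other <- vapply(fnormal, function(nrm) setdiff(1:3, nrm)[3 - k], 0L)
    for (shift in 0:1) {
      sx <- fv[, 1] + shift * (other == 1)
      sy <- fv[, 2] + shift * (other == 2)
      sz <- fv[, 3] + shift * (other == 3)
      b2_list[[slot]] <- cbind(seq_along(fkeys),
                               match(ekey(ax, sx, sy, sz), ekeys))
      slot <- slot + 1L
    }
  }
  b2_pairs <- do.call(rbind, b2_list)

  # boundary of cubes: six faces
  b3_list <- vector("list", 6)
  slot <- 1L
  for (normal in 1:3) for (shift in 0:1) {
    sx <- co[, 1] + shift * (normal == 1)
    sy <- co[, 2] + shift * (normal == 2)
    sz <- co[, 3] + shift * (normal == 3)
    b3_list[[slot]] <- cbind(seq_len(n), match(fkey(normal, sx, sy, sz), fkeys))
    slot <- slot + 1L
  }
  b3_pairs <- do.call(rbind, b3_list)

  list(
    n_cells = c(V = length(vkeys), E = length(ekeys), F = length(fkeys), C = n),
    boundary1 = b1_pairs, boundary2 = b2_pairs, boundary3 = b3_pairs
  )
}

#' Betti numbers via GF(2) cubical homology (reference path)
#'
#' Independent reference computation of the same quantities as
#' [betti_numbers()]: builds the full cubical chain complex (vertices,
#' edges, faces, cubes of the union of closed unit cubes), computes the
#' boundary-matrix ranks over GF(2), and reads off
#' `b_k = nullity(d_k) - rank(d_{k+1})`. Exact, but intended for small
#' masks; the production path derives `b1` from the Euler characteristic
#' instead of assembling boundary matrices.
#'
#' @param mask 3D logical array (small; cost grows with the cube of the
#'   cell count).
#' @return Named integer vector `c(b0, b1, b2)`.
#' @export
betti_numbers_gf2 <- function(mask) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  if (!any(mask)) return(c(b0 = 0L, b1 = 0L, b2 = 0L))
  cc <- cubical_complex(mask)
  nc <- cc$n_cells
  r1 <- cpp_gf2_rank(cc$boundary1[, 1], cc$boundary1[, 2], nc[["E"]], nc[["V"]])
  r2 <- cpp_gf2_rank(cc$boundary2[, 1], cc$boundary2[, 2], nc[["F"]], nc[["E"]])
  r3 <- cpp_gf2_rank(cc$boundary3[, 1], cc$boundary3[, 2], nc[["C"]], nc[["F"]])
  c(b0 = as.integer(nc[["V"]] - r1),
    b1 = as.integer(nc[["E"]] - r1 - r2),
    b2 = as.integer(nc[["F"]] - r2 - r3))
}

#' Expected topology table
#'
#' Anatomically expected Betti numbers per tissue. For fetal brain tissue
#' annotation the defaults are: no tunnels or cavities for any tissue
#' (`b1 = b2 = 0`), a single connected component for every tissue
#' (`b0 = 1`) except the cortical grey matter, whose two hemispheric
#' ribbons give `b0 = 2`.
#'
#' @param dictionary A [label_dictionary()]; defaults to
#'   [fetal_tissue_dictionary()].
#' @return A data frame with columns `label_code`, `label_name`, `b0`,
#'   `b1`, `b2`.
#' @export
expected_topology <- function(dictionary = fetal_tissue_dictionary()) {
  codes <- tissue_codes(dictionary)
  b0 <- ifelse(names(codes) == "GM", 2L, 1L)
  data.frame(
    label_code = unname(codes),
    label_name = names(codes),
    b0 = b0, b1 = 0L, b2 = 0L,
    stringsAsFactors = FALSE
  )
}

#' Read an expected-topology table from YAML
#'
#' Layout: a mapping from label code to a `[b0, b1, b2]` triple, e.g.
#' ```yaml
#' 1: [1, 0, 0]
#' 2: [2, 0, 0]
#' ```
#'
#' @param path Path to the YAML file.
#' @param dictionary A [label_dictionary()] used to name the codes.
#' @return A data frame as in [expected_topology()].
#' @export
read_expected_topology <- function(path,
                                   dictionary = fetal_tissue_dictionary()) {
  cfg <- yaml::read_yaml(path)
  codes <- as.integer(names(cfg))
  if (anyNA(codes)) stop("expected-topology keys must be integer label codes")
  triples <- t(vapply(cfg, function(x) as.integer(x), integer(3)))
  nm <- dictionary$names[match(codes, dictionary$codes)]
  data.frame(
    label_code = codes,
    label_name = ifelse(is.na(nm), as.character(codes), nm),
    b0 = triples[, 1], b1 = triples[, 2], b2 = triples[, 3],
    stringsAsFactors = FALSE
  )
}

#' Betti number error
#'
#' Component-wise absolute difference between a mask's Betti numbers and
#' the expected triple for its tissue: a difference metric to be
#' minimised, zero for topologically perfect segmentations.
#'
#' @param mask 3D logical array (the predicted tissue mask).
#' @param expected Expected Betti triple: either a numeric vector
#'   `c(b0, b1, b2)` or one row of [expected_topology()].
#' @return Named integer vector `c(bne0, bne1, bne2)`.
#' @export
betti_number_error <- function(mask, expected) {
  if (is.data.frame(expected)) {
    stopifnot(nrow(expected) == 1L)
    expected <- c(expected$b0, expected$b1, expected$b2)
  }
  expected <- as.integer(expected)
  stopifnot(length(expected) == 3L, all(expected >= 0L))
  bn <- betti_numbers(mask)
  setNames(abs(bn - expected), c("bne0", "bne1", "bne2"))
}
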