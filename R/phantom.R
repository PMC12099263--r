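#' Phantom specification
#'
#' Parameters of the synthetic fetal-brain-like phantom: a set of nested
#' spherical structures on a cubic canvas, engineered so every tissue mask
#' has exactly the anatomically expected topology (see
#' [expected_topology()]).
#'
#' Geometry, from outside in: an eCSF shell, a cortical GM ribbon split
#' into two hemispheres by a mid-sagittal gap (so its component count is
#' 2 under 26-connectivity), and a solid WM ball. Four interior
#' structures (ventricles, cerebellum, deep GM, brainstem) are carved out
#' of the WM as blobs, each connected to the background through a thin
#' channel running inside the sagittal gap so the WM acquires no cavity.
#' A polar plug is removed from the eCSF shell so it encloses no cavity
#' either.
#'
#' @param grid_size Voxels per axis (default 64; 256 mimics a typical
#'   challenge canvas).
#' @param spacing Voxel spacing in mm (default 0.5 isotropic).
#' @param radius_fractions Named fractions of the usable half-grid giving
#'   the outer radii of the eCSF shell, GM ribbon and WM ball; strictly
#'   decreasing inward.
#' @param gap_halfwidth Half-width (voxels) of the mid-sagittal GM gap;
#'   at least 2 so the hemispheres cannot bridge diagonally.
#' @param cap_radius_frac Radius (fraction of the usable half-grid) of the
#'   polar plug removed from the eCSF shell.
#' @param blob_offset_frac Distance of interior blob centres from the
#'   canvas centre, as a fraction of the usable half-grid.
#' @param blob_radius_fracs Named radii fractions of the four interior
#'   structures.
#' @param jitter_frac Relative jitter applied to radii and blob offsets
#'   when `randomize = TRUE` in [generate_phantom()]; cohort cases differ
#'   by this much.
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 64L,
                         spacing = c(0.5, 0.5, 0.5),
                         radius_fractions = c(eCSF = 0.95, GM = 0.82, WM = 0.68),
                         gap_halfwidth = 2,
                         cap_radius_frac = 0.22,
                         blob_offset_frac = 0.24,
                         blob_radius_fracs = c(ventricles = 0.14,
                                               cerebellum = 0.13,
                                               deepGM = 0.12,
                                               brainstem = 0.10),
                         jitter_frac = 0.04,
                         seed = 0L) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 32L) stop("grid_size below 32 cannot fit all structures")
  if (!all(diff(radius_fractions) < 0))
    stop("radius_fractions must be strictly decreasing inward")
  if (radius_fractions[1] >= 1)
    stop("outer radius must leave a background margin")
  structure(
    list(grid_size = grid_size, spacing = as.numeric(spacing),
         radius_fractions = radius_fractions,
         gap_halfwidth = gap_halfwidth,
         cap_radius_frac = cap_radius_frac,
         blob_offset_frac = blob_offset_frac,
         blob_radius_fracs = blob_radius_fracs,
         jitter_frac = jitter_frac,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a topologically correct synthetic phantom
#'
#' Builds an 8-label map containing all tissue codes of the fetal
#' dictionary, with each tissue mask satisfying the expected-topology
#' table exactly: GM has two components, every other tissue one, and no
#' tissue has tunnels or cavities. Deterministic given the spec (and its
#' seed, when `randomize = TRUE`).
#'
#' @param spec A [phantom_spec()].
#' @param randomize Logical; if `TRUE`, radii and blob offsets are
#'   jittered by `spec$jitter_frac` using `spec$seed`, which is how cohort
#'   cases are varied. The topology contract holds either way.
#' @return A [label_map()].
#' @export
generate_phantom <- function(spec = phantom_spec(), randomize = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  ctr <- (n + 1) / 2
  half <- n / 2 - 1.5  # usable half-grid: keeps a >=1 voxel background margin

  jit <- function(k) 1
  if (randomize) {
    rng <- local({
      set.seed(spec$seed)
      function() runif(1, 1 - spec$jitter_frac, 1 + spec$jitter_frac)
    })
    jit <- function(k) rng()
  }

  r_csf <- spec$radius_fractions[["eCSF"]] * half * jit()
  r_gm  <- spec$radius_fractions[["GM"]] * half * jit()
  r_wm  <- spec$radius_fractions[["WM"]] * half * jit()
  if (!(r_csf > r_gm && r_gm > r_wm))
    stop("jittered radii are no longer nested; reduce jitter_frac")

  ax <- seq_len(n) - ctr
  X <- array(ax, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  R <- sqrt(X^2 + Y^2 + Z^2)

  grid <- array(0L, c(n, n, n))
  grid[R <= r_csf] <- 1L                     # eCSF shell (outermost so far)
  grid[R <= r_gm] <- 2L                      # GM ribbon
  grid[R <= r_wm] <- 3L                      # WM ball

  # mid-sagittal gap through the GM ribbon -> two hemispheric components;
  # the vacated ring becomes background (the "gap pocket")
  gap <- abs(X) < spec$gap_halfwidth & grid == 2L
  grid[gap] <- 0L

  # polar plug removed from the eCSF shell so it encloses no cavity
  cap_r <- spec$cap_radius_frac * half
  grid[sqrt(X^2 + Y^2) < cap_r & Z > 0 & grid == 1L] <- 0L

  # interior structures: blob + escape channel inside the sagittal gap
  dirs <- list(ventricles = c(0, 0, 1), cerebellum = c(0, 1, 0),
               deepGM = c(0, 0, -1), brainstem = c(0, -1, 0))
  codes <- c(ventricles = 4L, cerebellum = 5L, deepGM = 6L, brainstem = 7L)
  off <- spec$blob_offset_frac * half
  for (tissue in names(dirs)) {
    u <- dirs[[tissue]]
    o <- off * jit()
    br <- spec$blob_radius_fracs[[tissue]] * half * jit()
    if (o + br >= r_wm - 1)
      stop("interior structure '", tissue, "' does not fit inside the WM ball")
    cx <- o * u
    blob <- sqrt((X - cx[1])^2 + (Y - cx[2])^2 + (Z - cx[3])^2) <= br
    # channel: square rod from the blob centre out to just past the WM
    # surface, confined to the gap plane so it never touches GM or eCSF
    along <- X * u[1] + Y * u[2] + Z * u[3]
    perp1 <- abs(X)  # channels run in the x = 0 plane
    perp2 <- if (u[3] != 0) abs(Y) else abs(Z)
    rod <- perp1 <= 1 & perp2 <= 1 & along >= o & along <= r_wm + 2
    claim <- (blob | rod) & grid %in% c(0L, 3L)
    grid[claim] <- codes[[tissue]]
  }

  label_map(grid, spec$spacing, fetal_tissue_dictionary())
}

#' Corruption specification
#'
#' Controlled error profile applied to a phantom ground truth to emulate a
#' team's predictions: per-label morphological perturbation, planar cuts
#' through the GM ribbon (each adds at least one spurious component),
#' tunnels drilled through and cavities injected into the WM, labels
#' dropped entirely (triggering the missing-label penalty path), and an
#' integer translation jitter.
#'
#' @param perturb_radius Morphological perturbation per label, in voxels:
#'   either a scalar applied to all tissues or a vector named by label
#'   code. Positive dilates, negative erodes, 0 leaves the label alone.
#' @param gm_cut_count Number of planar gaps cut through the GM ribbon.
#' @param tunnel_count Number of tunnels drilled through the WM.
#' @param cavity_count Number of cavities injected inside the WM.
#' @param drop_labels Integer label codes removed entirely.
#' @param jitter Integer length-3 translation (voxels).
#' @param seed Integer seed controlling defect placement.
#' @return An object of class `corruption_spec`. The default is the
#'   identity corruption (prediction equals ground truth).
#' @export
corruption_spec <- function(perturb_radius = 0, gm_cut_count = 0L,
                            tunnel_count = 0L, cavity_count = 0L,
                            drop_labels = integer(), jitter = c(0L, 0L, 0L),
                            seed = 0L) {
  stopifnot(gm_cut_count >= 0L, tunnel_count >= 0L, cavity_count >= 0L)
  drop_labels <- as.integer(drop_labels)
  if (!all(drop_labels %in% 1:7))
    stop("drop_labels must be tissue codes (1..7)")
  structure(
    list(perturb_radius = perturb_radius,
         gm_cut_count = as.integer(gm_cut_count),
         tunnel_count = as.integer(tunnel_count),
         cavity_count = as.integer(cavity_count),
         drop_labels = drop_labels,
         jitter = as.integer(jitter),
         seed = as.integer(seed)),
    class = "corruption_spec"
  )
}

dilate_mask <- function(mask, r) {
  d <- dim(mask)
  dist <- cpp_edt3d(as.logical(mask), as.integer(d), c(1, 1, 1))
  array(dist <= r, d)
}

erode_mask <- function(mask, r) {
  d <- dim(mask)
  dist <- cpp_edt3d(as.logical(!mask), as.integer(d), c(1, 1, 1))
  mask & array(dist > r, d)
}

translate_grid <- function(grid, shift, fill = 0L) {
  d <- dim(grid)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    src[[k]] <- if (s >= 0) 1:(d[k] - s) else (1 - s):d[k]
    dst[[k]] <- if (s >= 0) (1 + s):d[k] else 1:(d[k] + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- grid[src[[1]], src[[2]], src[[3]]]
  out
}

#' Corrupt a phantom ground truth into a synthetic prediction
#'
#' Applies a [corruption_spec()] to a phantom label map. Defect
#' guarantees: with `gm_cut_count = k >= 1` the GM gains at least `k`
#' extra components; each injected cavity raises the WM's `b2` by exactly
#' one; dropped labels are absent from the output. Deterministic given the
#' spec seed.
#'
#' @param gt A [label_map()] from [generate_phantom()].
#' @param spec A [corruption_spec()].
#' @return A [label_map()] with the same grid shape and spacing.
#' @export
corrupt_prediction <- function(gt, spec = corruption_spec()) {
  stopifnot(inherits(gt, "label_map"), inherits(spec, "corruption_spec"))
  set.seed(spec$seed)
  grid <- gt$grid
  n <- dim(grid)[1]
  scale <- n / 64  # defect placements are specified at the 64^3 reference size

  if (any(spec$jitter != 0L))
    grid <- translate_grid(grid, spec$jitter)

  # per-label morphological perturbation; later labels overwrite earlier
  pr <- spec$perturb_radius
  codes <- 1:7
  radii <- if (length(pr) == 1L && is.null(names(pr))) {
    setNames(rep(as.numeric(pr), 7), codes)
  } else {
    r <- setNames(numeric(7), codes)
    r[names(pr)] <- as.numeric(pr)
    r
  }
  for (code in codes) {
    r <- radii[[as.character(code)]]
    if (r == 0) next
    m <- grid == code
    if (!any(m)) next
    if (r > 0) {
      grid[dilate_mask(m, r)] <- code
    } else {
      kept <- erode_mask(m, -r)
      grid[m & !kept] <- 0L
    }
  }

  # planar cuts through the GM ribbon
  if (spec$gm_cut_count > 0L) {
    gm <- grid == 2L
    if (!any(gm)) stop("no GM voxels left to cut")
    zr <- range(which(apply(gm, 3, any)))
    lo <- zr[1] + floor(0.25 * diff(zr))
    hi <- zr[2] - ceiling(0.25 * diff(zr))
    candidates <- seq(lo, hi, by = max(4L, as.integer(4 * scale)))
    if (length(candidates) < spec$gm_cut_count)
      stop("grid too small to place ", spec$gm_cut_count, " distinct GM cuts")
    zs <- sort(sample(candidates, spec$gm_cut_count))
    for (zc in zs) {
      slab <- max(1, zc):min(dim(grid)[3], zc + 1)
      sub <- grid[, , slab, drop = FALSE]
      sub[sub == 2L] <- 0L
      grid[, , slab] <- sub
    }
  }

  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  # tunnels: drill along x through the WM at off-centre (y, z) offsets in
  # the -y half so they stay clear of cavity sites and interior blobs
  if (spec$tunnel_count > 0L) {
    angles <- seq(pi + 0.4, 2 * pi - 0.4, length.out = max(spec$tunnel_count, 2))
    radius <- 15 * scale
    if (spec$tunnel_count > length(angles))
      stop("cannot place ", spec$tunnel_count, " disjoint tunnels")
    Yg <- array(rep(ax, each = n), c(n, n, n))
    Zg <- aperm(Yg, c(1, 3, 2))
    for (t in seq_len(spec$tunnel_count)) {
      oy <- radius * cos(angles[t])
      oz <- radius * sin(angles[t])
      cyl <- (Yg - oy)^2 + (Zg - oz)^2 <= (1.6 * scale)^2
      grid[cyl & grid == 3L] <- 0L
    }
  }

  # cavities: small voids strictly inside the WM, in the +y half
  if (spec$cavity_count > 0L) {
    dirs <- list(c(1, 1, 1), c(-1, 1, 1), c(1, 1, -1), c(-1, 1, -1))
    if (spec$cavity_count > length(dirs))
      stop("cannot place ", spec$cavity_count, " disjoint cavities")
    rad <- 2 * scale
    Xg <- array(ax, c(n, n, n))
    Yg2 <- aperm(Xg, c(2, 1, 3))
    Zg2 <- aperm(Xg, c(3, 2, 1))
    for (t in seq_len(spec$cavity_count)) {
      cxyz <- dirs[[t]] / sqrt(3) * 15 * scale
      ball <- (Xg - cxyz[1])^2 + (Yg2 - cxyz[2])^2 + (Zg2 - cxyz[3])^2 <= rad^2
      if (!all(grid[ball] == 3L))
        stop("cavity site ", t, " is not strictly inside the WM")
      grid[ball] <- 0L
    }
  }

  if (length(spec$drop_labels))
    grid[grid %in% spec$drop_labels] <- 0L

  label_map(grid, gt$spacing, gt$dictionary)
}

#' Generate a synthetic mini-challenge cohort
#'
#' Produces `n_cases` randomized phantoms, per-team corrupted predictions
#' following each team's corruption profile, and a synthetic metadata
#' table (two sites, quality ratings, pathology flags, two reconstruction
#' method tags) suitable for subset rankings. Deterministic given `seed`.
#'
#' @param n_cases Number of cases (>= 1).
#' @param team_profiles Named list of [corruption_spec()] objects, one per
#'   team; names are team identifiers.
#' @param grid_size Canvas size per axis (default 64).
#' @param seed Integer master seed; per-case and per-(team, case) seeds
#'   are derived from it.
#' @return A list with class `segtopo_cohort`: `cases` (named list of
#'   ground-truth [label_map()]s), `predictions` (per team, a named list
#'   of predicted label maps), `metadata` (data frame).
#' @export
generate_cohort <- function(n_cases, team_profiles, grid_size = 64L,
                            seed = 0L) {
  stopifnot(n_cases >= 1L, length(team_profiles) >= 1L)
  if (is.null(names(team_profiles)) || any(names(team_profiles) == ""))
    stop("`team_profiles` must be a named list (names are team ids)")
  case_ids <- sprintf("case%03d", seq_len(n_cases))

  cases <- list()
  for (i in seq_len(n_cases)) {
    ps <- phantom_spec(grid_size = grid_size, seed = seed * 1000L + i)
    cases[[case_ids[i]]] <- generate_phantom(ps, randomize = TRUE)
  }

  predictions <- list()
  for (tm in names(team_profiles)) {
    prof <- team_profiles[[tm]]
    preds <- list()
    for (i in seq_len(n_cases)) {
      cs <- prof
      cs$seed <- seed * 100000L + match(tm, names(team_profiles)) * 1000L + i
      preds[[case_ids[i]]] <- corrupt_prediction(cases[[case_ids[i]]], cs)
    }
    predictions[[tm]] <- preds
  }

  set.seed(seed)
  metadata <- data.frame(
    case_id = case_ids,
    site = sample(c("siteA", "siteB"), n_cases, replace = TRUE),
    quality = sample(1:3, n_cases, replace = TRUE),
    pathological = sample(c(TRUE, FALSE), n_cases, replace = TRUE),
    sr_method = sample(c("srA", "srB"), n_cases, replace = TRUE),
    gestational_age = round(runif(n_cases, 19, 35), 1),
    stringsAsFactors = FALSE
  )

  structure(list(cases = cases, predictions = predictions,
                 metadata = metadata),
            class = "segtopo_cohort")
}
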