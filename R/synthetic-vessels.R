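#' Default per-category diameter ranges (micrometres)
#'
#' Capillaries are bounded above at 6 um (the ultrastructural definition of
#' a brain microvessel used for electron-microscopy sampling); the remaining
#' ranges follow the conventional morphological taxonomy of the cortical
#' microvascular tree.  Overlapping arteriole/venule ranges are
#' disambiguated by orientation and the arterial flag, not by diameter.
#'
#' @return named list of `c(min, max)` diameter ranges.
#' @export
defaultDiameterRanges <- function() {
  list(capillary = c(3, 6), post_capillary_venule = c(6, 10),
       penetrating_arteriole = c(10, 25), ascending_venule = c(10, 25),
       pial_arteriole = c(25, 60), pial_venule = c(25, 100))
}

#' Configuration for the synthetic vessel tree generator
#'
#' @param shape integer (nz, ny, nx) of the simulated volume.
#' @param pixelSizeUm,zStepUm voxel geometry, micrometres.
#' @param counts named integer vector: vessels to place per category.
#' @param diameterRanges named list of `c(min, max)` diameters in
#'   micrometres; see [defaultDiameterRanges()].
#' @param lengthRangeUm in-plane segment length range, micrometres.
#' @param marginPx minimum clearance (pixels) kept between distinct segments.
#' @param maxTries placement retries per vessel before failing.
#' @return config list consumed by [generateVesselTree()].
#' @export
vesselTreeConfig <- function(shape = c(8, 256, 256), pixelSizeUm = 3,
                             zStepUm = 5,
                             counts = c(pial_arteriole = 1,
                                        penetrating_arteriole = 2,
                                        capillary = 6,
                                        post_capillary_venule = 2,
                                        ascending_venule = 2,
                                        pial_venule = 1),
                             diameterRanges = defaultDiameterRanges(),
                             lengthRangeUm = c(40, 120), marginPx = 2L,
                             maxTries = 200L) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  assertScalar(pixelSizeUm, "pixelSizeUm", positive = TRUE)
  assertScalar(zStepUm, "zStepUm", positive = TRUE)
  if (length(counts) > 0 && !all(names(counts) %in% VESSEL_CATEGORIES))
    stop("unknown vessel category in 'counts'")
  list(shape = as.integer(shape), pixelSizeUm = pixelSizeUm,
       zStepUm = zStepUm, counts = counts, diameterRanges = diameterRanges,
       lengthRangeUm = lengthRangeUm, marginPx = as.integer(marginPx),
       maxTries = as.integer(maxTries))
}

## category -> orientation and arterial flag used by the generator
categoryTraits <- function(category) {
  switch(category,
    pial_arteriole = list(orientation = "in_plane", arterial = TRUE, pial = TRUE),
    pial_venule = list(orientation = "in_plane", arterial = FALSE, pial = TRUE),
    penetrating_arteriole = list(orientation = "through_plane", arterial = TRUE, pial = FALSE),
    ascending_venule = list(orientation = "through_plane", arterial = FALSE, pial = FALSE),
    capillary = list(orientation = "in_plane", arterial = NA, pial = FALSE),
    post_capillary_venule = list(orientation = "in_plane", arterial = FALSE, pial = FALSE))
}

## voxel index matrix (z, y, x) for one candidate placement; NULL if the
## candidate does not fit the volume
candidateVoxels <- function(category, dUm, cfg) {
  nz <- cfg$shape[1]; ny <- cfg$shape[2]; nx <- cfg$shape[3]
  px <- cfg$pixelSizeUm
  tr <- categoryTraits(category)
  if (tr$orientation == "through_plane") {
    r <- max(dUm / 2 / px, 0.01)
    ext <- floor(r + 0.5)
    cy <- sample(seq(1 + ext, ny - ext), 1L)
    cx <- sample(seq(1 + ext, nx - ext), 1L)
    off <- expand.grid(dy = -ext:ext, dx = -ext:ext)
    off <- off[off$dy^2 + off$dx^2 <= max(r, 0.5)^2, , drop = FALSE]
    vox <- expand.grid(z = seq_len(nz), i = seq_len(nrow(off)))
    cbind(z = vox$z, y = cy + off$dy[vox$i], x = cx + off$dx[vox$i],
          deparse.level = 0)
  } else {
    lUm <- runif(1, cfg$lengthRangeUm[1], cfg$lengthRangeUm[2])
    lpx <- max(2L, round(lUm / px))
    tpx <- max(1L, round(dUm / px))
    z <- if (tr$pial) 1L else sample(seq_len(nz), 1L)
    alongX <- runif(1) < 0.5
    if (alongX) {
      if (nx - lpx < 1 || ny - tpx < 1) return(NULL)
      y0 <- sample(seq_len(ny - tpx + 1L), 1L)
      x0 <- sample(seq_len(nx - lpx + 1L), 1L)
      g <- expand.grid(y = y0:(y0 + tpx - 1L), x = x0:(x0 + lpx - 1L))
    } else {
      if (ny - lpx < 1 || nx - tpx < 1) return(NULL)
      y0 <- sample(seq_len(ny - lpx + 1L), 1L)
      x0 <- sample(seq_len(nx - tpx + 1L), 1L)
      g <- expand.grid(y = y0:(y0 + lpx - 1L), x = x0:(x0 + tpx - 1L))
    }
    structure(cbind(z = z, y = g$y, x = g$x, deparse.level = 0),
              length_um = lpx * px)
  }
}

#' Generate a synthetic cortical vessel tree
#'
#' Places the requested number of vessels per category into an empty volume:
#' pial vessels as in-plane segments on the surface plane, penetrating
#' arterioles and ascending venules as through-plane cylinders, capillaries
#' and post-capillary venules as thin in-plane segments at random depth.
#' Segment masks are pairwise disjoint with a configurable clearance margin;
#' placement is uniform-random with rejection and fails informatively when a
#' category cannot be placed within the retry budget.  Deterministic under
#' `seed`.
#'
#' @param config from [vesselTreeConfig()].
#' @param seed integer RNG seed.
#' @return a [VesselTree-class].
#' @export
generateVesselTree <- function(config = vesselTreeConfig(), seed = 1L) {
  withSeed(seed, {
    nz <- config$shape[1]; ny <- config$shape[2]; nx <- config$shape[3]
    labels <- array(0L, dim = c(nz, ny, nx))
    rows <- list()
    counts <- config$counts
    counts <- counts[counts > 0]
    ## place large vessels first to improve packing
    ord <- names(counts)[order(-vapply(names(counts), function(cat)
      mean(config$diameterRanges[[cat]]), numeric(1)))]
    id <- 0L
    m <- config$marginPx
    ## disjointness is enforced on the 2D projection (with a lateral
    ## clearance margin): vessels at different depths must not overlap in
    ## the projected view either, so traces and puncta are attributable
    occ2d <- matrix(FALSE, ny, nx)
    for (cat in ord) {
      rng <- config$diameterRanges[[cat]]
      if (is.null(rng)) stop("no diameter range configured for ", cat)
      for (i in seq_len(counts[[cat]])) {
        placed <- FALSE
        for (try in seq_len(config$maxTries)) {
          dUm <- runif(1, rng[1], rng[2])
          vox <- candidateVoxels(cat, dUm, config)
          if (is.null(vox)) next
          ## clearance check: expand the footprint laterally by the margin
          off <- expand.grid(dy = -m:m, dx = -m:m)
          exp_y <- outer(vox[, 2], off$dy, `+`)
          exp_x <- outer(vox[, 3], off$dx, `+`)
          keep <- exp_y >= 1 & exp_y <= ny & exp_x >= 1 & exp_x <= nx
          idx2d <- cbind(exp_y[keep], exp_x[keep])
          if (any(occ2d[idx2d])) next
          id <- id + 1L
          labels[vox] <- id
          occ2d[vox[, 2:3, drop = FALSE]] <- TRUE
          tr <- categoryTraits(cat)
          lUm <- if (tr$orientation == "through_plane") nz * config$zStepUm
                 else attr(vox, "length_um")
          rows[[id]] <- data.frame(id = id, category = cat,
                                   diameter_um = dUm, length_um = lUm,
                                   orientation = tr$orientation,
                                   arterial = tr$arterial)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("placement failure: could not place a '", cat,
               "' segment without overlap after ", config$maxTries, " tries")
      }
    }
    seg <- if (length(rows)) do.call(rbind, rows)
           else data.frame(id = integer(), category = character(),
                           diameter_um = numeric(), length_um = numeric(),
                           orientation = character(), arterial = logical())
    new("VesselTree", segments = seg, labels = labels,
        pixelSizeUm = config$pixelSizeUm, zStepUm = config$zStepUm)
  })
}
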