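#' Periodic Voronoi tessellation of one leaflet
#'
#' Builds the 2D Voronoi diagram of the phosphorus reference sites of one
#' leaflet under periodic boundary conditions.  Periodicity is imposed by
#' tiling the generators over a 3x3 array of image boxes, tessellating the
#' tiled set (Delaunay/Dirichlet via \pkg{deldir}) and keeping the cells of
#' the central copy; this is exact for generator separations below half the
#' box and the central cells tile the box, so their areas sum to Lx*Ly.
#' Coincident generators are jittered once by 1e-6 Angstrom and retried.
#'
#' @param frame a [boxed_frame].
#' @param gmap a [group_map].
#' @param leaflet "upper" or "lower".
#' @return An object of class `voronoi_result`: list with `cells` (data
#'   frame `mol`, `species`, `area` in Angstrom^2), `polygons` (list of
#'   data frames with `x`, `y` vertices per cell), `leaflet`, `box_area`,
#'   and `species_summary` (mean and median cell area per species).
#' @export
voronoi_leaflet <- function(frame, gmap, leaflet = "upper") {
  part <- assign_leaflets(frame, gmap)
  ref <- reference_sites(frame, gmap, part, leaflet)
  n <- nrow(ref)
  if (n < 3L) stop("need at least three lipids in the leaflet")
  Lx <- frame$box[1]; Ly <- frame$box[2]
  # wrap generators into the box
  px <- ref$x - Lx * floor(ref$x / Lx)
  py <- ref$y - Ly * floor(ref$y / Ly)

  tessellate <- function(px, py) {
    shifts <- expand.grid(sx = -1:1, sy = -1:1)
    # central copy first so its generators occupy indices 1..n
    ord <- order(shifts$sx != 0 | shifts$sy != 0)
    gx <- as.vector(outer(px, shifts$sx[ord] * Lx, "+"))
    gy <- as.vector(outer(py, shifts$sy[ord] * Ly, "+"))
    dd <- deldir::deldir(gx, gy,
                         rw = c(-Lx, 2 * Lx, -Ly, 2 * Ly),
                         suppressMsge = TRUE)
    deldir::tile.list(dd)
  }

  has_dup <- anyDuplicated(cbind(px, py)) > 0
  if (has_dup) {
    jit <- 1e-6
    px <- px + stats::runif(n, -jit, jit)
    py <- py + stats::runif(n, -jit, jit)
    if (anyDuplicated(cbind(px, py)) > 0)
      stop("coincident generator points persist after jitter")
  }
  tiles <- tessellate(px, py)
  # tile.list drops duplicated points; map back through ptNum
  ptnum <- vapply(tiles, function(t) t$ptNum, integer(1))
  central <- which(ptnum <= n)
  if (length(central) != n)
    stop("tessellation lost central generators (coincident points?)")
  tiles <- tiles[central][order(ptnum[central])]
  areas <- vapply(tiles, function(t) t$area, numeric(1))
  polys <- lapply(tiles, function(t) data.frame(x = t$x, y = t$y))
  cells <- data.frame(mol = ref$mol, species = ref$species, area = areas)
  smry <- do.call(rbind, lapply(split(cells$area, cells$species), function(a)
    data.frame(mean_area = mean(a), median_area = stats::median(a))))
  smry <- cbind(species = rownames(smry), smry)
  rownames(smry) <- NULL
  structure(list(cells = cells, polygons = polys, leaflet = leaflet,
                 box_area = Lx * Ly, species_summary = smry),
            class = "voronoi_result")
}

#' @export
print.voronoi_result <- function(x, ...) {
  cat(sprintf("voronoi_result: %d cells (%s leaflet), sum area %.3f of box %.3f A^2\n",
              nrow(x$cells), x$leaflet, sum(x$cells$area), x$box_area))
  print(x$species_summary)
  invisible(x)
}

#' Write a species-colored SVG diagram of a Voronoi tessellation
#'
#' @param vr a [voronoi_result].
#' @param path output SVG path.
#' @param colors named vector of fill colors by species (defaults supplied).
#' @return `path`, invisibly.
#' @export
voronoi_svg <- function(vr, path, colors = NULL) {
  sp <- unique(vr$cells$species)
  if (is.null(colors))
    colors <- stats::setNames(
      rep(c("#e08214", "#7fbc41", "#8073ac", "#de77ae"), length.out = length(sp)),
      sp)
  xr <- range(unlist(lapply(vr$polygons, `[[`, "x")))
  yr <- range(unlist(lapply(vr$polygons, `[[`, "y")))
  w <- 500; h <- 500 * diff(yr) / diff(xr)
  sx <- function(x) (x - xr[1]) / diff(xr) * w
  sy <- function(y) h - (y - yr[1]) / diff(yr) * h
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g">', w, h))
  for (i in seq_along(vr$polygons)) {
    p <- vr$polygons[[i]]
    pts <- paste(sprintf("%.2f,%.2f", sx(p$x), sy(p$y)), collapse = " ")
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="%s" stroke="black" stroke-width="0.5"/>',
      pts, colors[[vr$cells$species[i]]]))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
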