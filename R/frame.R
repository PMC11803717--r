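#' Construct a single simulation frame
#'
#' A `boxed_frame` holds one snapshot of a bilayer system: site coordinates,
#' species and molecule labels, the orthorhombic box, and optionally the
#' diagonal of the pressure tensor.  All coordinates are in Angstrom and
#' pressures in bar; readers convert on ingest.
#'
#' @param coords numeric matrix, one row per site, columns x/y/z in Angstrom.
#' @param site_species character vector of species labels, one per site.
#' @param site_molecule integer vector of molecule indices, one per site.
#'   All sites of one molecule must share one species label.
#' @param site_name character vector of site labels (e.g. "P", "PO4", "GL1").
#' @param box numeric length-3 vector of box edge lengths (Lx, Ly, Lz), Angstrom.
#' @param pressure optional numeric length-3 vector (Pxx, Pyy, Pzz), bar.
#' @param time frame time in ns (default 0).
#'
#' @return An object of class `boxed_frame`.
#' @export
boxed_frame <- function(coords, site_species, site_molecule, site_name,
                        box, pressure = NULL, time = 0) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (ncol(coords) != 3L)
    stop("coords must have three columns (x, y, z)")
  n <- nrow(coords)
  if (length(site_species) != n || length(site_molecule) != n ||
      length(site_name) != n)
    stop("site_species, site_molecule and site_name must match nrow(coords)")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive finite edge lengths")
  if (!is.null(pressure)) {
    pressure <- as.numeric(pressure)
    if (length(pressure) != 3L || any(!is.finite(pressure)))
      stop("pressure must be three finite values (Pxx, Pyy, Pzz) in bar")
  }
  site_molecule <- as.integer(site_molecule)
  # one species per molecule
  sp_by_mol <- tapply(as.character(site_species), site_molecule,
                      function(s) length(unique(s)))
  if (any(sp_by_mol != 1L))
    stop("all sites of one molecule must share one species label")
  structure(
    list(coords = coords,
         site_species = as.character(site_species),
         site_molecule = site_molecule,
         site_name = as.character(site_name),
         box = box,
         pressure = pressure,
         time = as.numeric(time)),
    class = "boxed_frame")
}

#' @export
print.boxed_frame <- function(x, ...) {
  cat(sprintf("boxed_frame: %d sites, %d molecules, %d species\n",
              nrow(x$coords), length(unique(x$site_molecule)),
              length(unique(x$site_species))))
  cat(sprintf("  box: %.2f x %.2f x %.2f A, t = %g ns\n",
              x$box[1], x$box[2], x$box[3], x$time))
  if (!is.null(x$pressure))
    cat(sprintf("  pressure diag: (%.3f, %.3f, %.3f) bar\n",
                x$pressure[1], x$pressure[2], x$pressure[3]))
  invisible(x)
}

#' Minimum-image displacement under periodic boundary conditions
#'
#' Computes the displacement `a - b`, wrapped component-wise into
#' `[-L/2, L/2)` for an orthorhombic box.  In `mode = "xy"` only the two
#' lateral components are wrapped, which is appropriate for leaflet-internal
#' distances in a planar bilayer.
#'
#' @param a,b numeric 3-vectors or n-by-3 matrices, Angstrom.
#' @param box numeric length-3 box edge lengths, Angstrom.
#' @param mode "xyz" (wrap all components) or "xy" (wrap lateral only).
#' @return Displacement(s) with the same shape as the inputs.
#' @export
minimum_image_displacement <- function(a, b, box, mode = c("xyz", "xy")) {
  mode <- match.arg(mode)
  box <- as.numeric(box)
  if (any(box <= 0)) stop("box lengths must be positive")
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- a - b
  wrap <- if (mode == "xy") 1:2 else 1:3
  for (k in wrap) {
    L <- box[k]
    d[, k] <- d[, k] - L * floor(d[, k] / L + 0.5)
  }
  if (nrow(d) == 1L) drop(d) else d
}

# Lateral (xy) minimum-image distance matrix between two point sets.
# p, q: matrices with >=2 columns. Returns nrow(p) x nrow(q) matrix.
min_image_dist_matrix <- function(p, q, box, mode = c("xyz", "xy")) {
  mode <- match.arg(mode)
  ncomp <- if (mode == "xy") 2L else 3L
  d2 <- matrix(0, nrow(p), nrow(q))
  for (k in seq_len(ncomp)) {
    L <- box[k]
    dk <- outer(p[, k], q[, k], "-")
    dk <- dk - L * floor(dk / L + 0.5)
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}
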