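#' Assign lipid molecules to bilayer leaflets
#'
#' Each lipid is assigned to the upper or lower leaflet by comparing the z
#' coordinate of its phosphorus reference site (P atom or PO4 bead, as
#' designated in the group map) with the global phosphorus midplane, the
#' mean z over all phosphorus sites in the frame.  This is appropriate for
#' the planar bilayers the package targets; no clustering is attempted.
#' Ions and any species absent from the group map are left unassigned.
#'
#' @param frame a [boxed_frame].
#' @param gmap a [group_map]; every lipid species in the frame must have an
#'   entry with a `phosphorus_site`.
#' @param on_single_leaflet "error" (default) or "warn": what to do when all
#'   phosphorus sites fall on one side of the midplane.
#' @return An object of class `leaflet_partition`: a list with `assignment`
#'   (character vector "upper"/"lower" named by molecule index) and
#'   `midplane_z` (Angstrom).
#' @export
assign_leaflets <- function(frame, gmap, on_single_leaflet = c("error", "warn")) {
  on_single_leaflet <- match.arg(on_single_leaflet)
  lip <- lipid_species(gmap)
  present <- unique(frame$site_species)
  lip_present <- intersect(present, lip)
  missing <- setdiff(setdiff(present, ion_species(gmap)), names(gmap))
  # species not in the map at all are treated as solvent/other and skipped;
  # but a species mapped as a lipid must carry a phosphorus designation
  for (sp in lip_present) {
    if (is.null(gmap[[sp]]$phosphorus_site))
      stop(sprintf("species %s has no phosphorus_site in the group map", sp))
  }
  if (!length(lip_present))
    stop("no lipid species of the group map present in the frame")

  is_p <- frame$site_species %in% lip_present &
    frame$site_name == vapply(frame$site_species, function(sp) {
      if (sp %in% lip_present) gmap[[sp]]$phosphorus_site else ""
    }, character(1))
  pz <- frame$coords[is_p, 3]
  pmol <- frame$site_molecule[is_p]
  if (length(unique(pmol)) < 2L)
    stop("need at least two lipids to partition into leaflets")
  midplane <- mean(pz)
  side <- ifelse(pz > midplane, "upper", "lower")
  assignment <- stats::setNames(side, pmol)
  if (length(unique(side)) < 2L) {
    msg <- "all phosphorus sites fall in a single leaflet"
    if (on_single_leaflet == "error") stop(msg) else warning(msg)
  }
  structure(list(assignment = assignment, midplane_z = midplane),
            class = "leaflet_partition")
}

#' @export
print.leaflet_partition <- function(x, ...) {
  cat(sprintf("leaflet_partition: %d upper, %d lower; midplane z = %.2f A\n",
              sum(x$assignment == "upper"), sum(x$assignment == "lower"),
              x$midplane_z))
  invisible(x)
}

# molecule indices of lipids in one leaflet
leaflet_molecules <- function(partition, leaflet) {
  as.integer(names(partition$assignment)[partition$assignment == leaflet])
}
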