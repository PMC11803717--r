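# phosphorus (or GL1) site positions of the lipids of one leaflet,
# as a data.frame with mol, species, x, y, z
reference_sites <- function(frame, gmap, partition, leaflet,
                            site = c("phosphorus", "gl1")) {
  site <- match.arg(site)
  mols <- leaflet_molecules(partition, leaflet)
  keep <- logical(nrow(frame$coords))
  for (sp in intersect(unique(frame$site_species), lipid_species(gmap))) {
    lab <- if (site == "phosphorus") gmap[[sp]]$phosphorus_site else gmap[[sp]]$gl1_site
    if (is.null(lab))
      stop(sprintf("species %s has no %s site designated", sp,
                   if (site == "phosphorus") "phosphorus" else "GL1"))
    keep <- keep | (frame$site_species == sp & frame$site_name == lab)
  }
  keep <- keep & frame$site_molecule %in% mols
  data.frame(mol = frame$site_molecule[keep],
             species = frame$site_species[keep],
             x = frame$coords[keep, 1],
             y = frame$coords[keep, 2],
             z = frame$coords[keep, 3])
}

#' Lipid spacing distribution
#'
#' Probability histogram of the distances between the phosphorus reference
#' sites of two (possibly identical) species within one leaflet, pooled over
#' frames.  Distances are lateral (xy) minimum-image by default, a proxy
#' for in-plane spacing in planar bilayers; set `metric = "xyz"` for full
#' 3D distances.  Bins cover [0, min(Lx, Ly)/2].
#'
#' @param frames list of [boxed_frame] objects.
#' @param gmap a [group_map].
#' @param leaflet "upper" or "lower".
#' @param species_pair character vector of length 1 or 2.
#' @param bin_width bin width in Angstrom (default 1).
#' @param metric "xy" (default) or "xyz".
#' @return An object of class `spacing_histogram`: list with `species_pair`,
#'   `bin_edges`, `probability`, `counts`, `n_pairs`.
#' @export
lipid_spacing_distribution <- function(frames, gmap, leaflet = "upper",
                                       species_pair, bin_width = 1,
                                       metric = c("xy", "xyz")) {
  metric <- match.arg(metric)
  if (inherits(frames, "boxed_frame")) frames <- list(frames)
  species_pair <- rep(as.character(species_pair), length.out = 2)
  rmax <- min(frames[[1]]$box[1:2]) / 2
  edges <- seq(0, rmax + bin_width, by = bin_width)
  counts <- numeric(length(edges) - 1L)
  npairs <- 0L
  for (fr in frames) {
    part <- assign_leaflets(fr, gmap)
    ref <- reference_sites(fr, gmap, part, leaflet)
    a <- ref[ref$species == species_pair[1], c("x", "y", "z"), drop = FALSE]
    b <- ref[ref$species == species_pair[2], c("x", "y", "z"), drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    D <- min_image_dist_matrix(as.matrix(a), as.matrix(b), fr$box, mode = metric)
    d <- if (identical(species_pair[1], species_pair[2])) {
      D[upper.tri(D)]
    } else as.vector(D)
    d <- d[d <= edges[length(edges)]]
    if (!length(d)) next
    counts <- counts + tabulate(findInterval(d, edges,
                                             rightmost.closed = TRUE),
                                nbins = length(edges) - 1L)
    npairs <- npairs + length(d)
  }
  if (npairs == 0L)
    stop("no ", paste(species_pair, collapse = "-"),
         " pairs found in leaflet ", leaflet)
  structure(list(species_pair = species_pair, bin_edges = edges,
                 probability = counts / sum(counts), counts = counts,
                 n_pairs = npairs),
            class = "spacing_histogram")
}

#' Mixed-contact fraction of a binary bilayer
#'
#' Two lipids are in contact when their phosphorus reference sites (PO4
#' beads in coarse-grained models) lie within the cutoff, 11 Angstrom by
#' default, using 3D minimum-image distances within one leaflet.  Counting
#' contacts from the primary species' perspective -- each primary-primary
#' pair contributes two primary contacts, each mixed pair one -- the mixed
#' fraction is
#' \deqn{f_{mix} = 100 \, C_{AB} / (C_{AA} + C_{AB}),}
#' the percentage of a primary lipid's contacts made with the secondary
#' species.  Under ideal random mixing this converges to the secondary
#' mole percentage.  Reported as mean and sd over frames, leaflets pooled.
#'
#' @param frames list of [boxed_frame] objects.
#' @param gmap a [group_map] with exactly two lipid species present.
#' @param cutoff contact cutoff in Angstrom (default 11).
#' @param primary primary species label; defaults to the more abundant one.
#' @param metric "xyz" (default) or "xy".
#' @return An object of class `mixing_stats`: list with `f_mix`, `sd`,
#'   `C_AA`, `C_AB` (mean per-frame primary-centric contact counts),
#'   `primary`, `secondary`, and the per-frame table `per_frame`.
#' @export
mixed_contact_fraction <- function(frames, gmap, cutoff = 11.0,
                                   primary = NULL, metric = c("xyz", "xy")) {
  metric <- match.arg(metric)
  if (inherits(frames, "boxed_frame")) frames <- list(frames)
  sp_present <- intersect(unique(frames[[1]]$site_species), lipid_species(gmap))
  if (length(sp_present) < 1L || length(sp_present) > 2L)
    stop("mixed-contact fraction requires one or two lipid species; found ",
         length(sp_present))
  if (is.null(primary)) {
    cnt <- table(frames[[1]]$site_species[
      !duplicated(frames[[1]]$site_molecule)])
    primary <- names(which.max(cnt[sp_present]))
  }
  secondary <- setdiff(sp_present, primary)
  if (!primary %in% sp_present) stop("primary species not present: ", primary)
  if (!length(secondary)) secondary <- NA_character_

  per_frame <- t(vapply(frames, function(fr) {
    part <- assign_leaflets(fr, gmap)
    caa <- 0; cab <- 0
    for (lf in c("upper", "lower")) {
      ref <- reference_sites(fr, gmap, part, lf)
      if (nrow(ref) < 2L) next
      xyz <- as.matrix(ref[, c("x", "y", "z")])
      D <- min_image_dist_matrix(xyz, xyz, fr$box, mode = metric)
      isA <- ref$species == primary
      contact <- D < cutoff & upper.tri(D)
      caa <- caa + 2 * sum(contact[isA, isA])
      cab <- cab + sum(contact[isA, !isA]) + sum(contact[!isA, isA])
    }
    if (caa + cab == 0)
      c(f = NA_real_, C_AA = caa, C_AB = cab)
    else
      c(f = 100 * cab / (caa + cab), C_AA = caa, C_AB = cab)
  }, c(f = 0, C_AA = 0, C_AB = 0)))
  f <- per_frame[, "f"]
  if (all(is.na(f))) stop("no contacts found within the cutoff")
  structure(list(f_mix = mean(f, na.rm = TRUE),
                 sd = if (sum(!is.na(f)) > 1L) stats::sd(f, na.rm = TRUE) else 0,
                 C_AA = mean(per_frame[, "C_AA"]),
                 C_AB = mean(per_frame[, "C_AB"]),
                 primary = primary, secondary = secondary,
                 per_frame = as.data.frame(per_frame)),
            class = "mixing_stats")
}

#' @export
print.mixing_stats <- function(x, ...) {
  cat(sprintf("f_mix (%s primary vs %s) = %.2f %% +/- %.2f\n",
              x$primary, x$secondary, x$f_mix, x$sd))
  invisible(x)
}

#' Neighbor counts and composition around each lipid species
#'
#' Two same-leaflet lipids are neighbors when their GL1 reference sites
#' (first tail-linker bead) are within the cutoff, 15 Angstrom by default,
#' inclusive.  For each center species the mean number of neighbors of each
#' species is reported together with the percentage composition; sds are
#' over frames.
#'
#' @param frames list of [boxed_frame] objects.
#' @param gmap a [group_map]; every lipid species needs a `gl1_site`.
#' @param cutoff neighbor cutoff in Angstrom (default 15, inclusive).
#' @return A data frame of class `neighbor_table` with columns
#'   `center_species`, `neighbor_species`, `mean_count`, `sd_count`,
#'   `percent`.
#' @export
neighbor_composition <- function(frames, gmap, cutoff = 15.0) {
  if (inherits(frames, "boxed_frame")) frames <- list(frames)
  sp_all <- sort(intersect(unique(frames[[1]]$site_species),
                           lipid_species(gmap)))
  per_frame <- lapply(frames, function(fr) {
    part <- assign_leaflets(fr, gmap)
    acc <- matrix(0, length(sp_all), length(sp_all),
                  dimnames = list(sp_all, sp_all))
    ncenter <- stats::setNames(numeric(length(sp_all)), sp_all)
    for (lf in c("upper", "lower")) {
      ref <- reference_sites(fr, gmap, part, lf, site = "gl1")
      if (nrow(ref) < 2L) next
      xyz <- as.matrix(ref[, c("x", "y", "z")])
      D <- min_image_dist_matrix(xyz, xyz, fr$box, mode = "xyz")
      nb <- D <= cutoff
      diag(nb) <- FALSE
      for (cs in sp_all) {
        ic <- ref$species == cs
        if (!any(ic)) next
        ncenter[cs] <- ncenter[cs] + sum(ic)
        for (ns in sp_all)
          acc[cs, ns] <- acc[cs, ns] + sum(nb[ic, ref$species == ns])
      }
    }
    sweep(acc, 1, pmax(ncenter, 1), "/")
  })
  arr <- array(unlist(per_frame),            # species x species x frames
               dim = c(length(sp_all), length(sp_all), length(per_frame)),
               dimnames = list(sp_all, sp_all, NULL))
  mean_counts <- apply(arr, c(1, 2), mean)
  sd_counts <- apply(arr, c(1, 2), function(v)
    if (length(v) > 1L) stats::sd(v) else 0)
  rows <- expand.grid(center_species = sp_all, neighbor_species = sp_all,
                      stringsAsFactors = FALSE)
  rows$mean_count <- mean_counts[cbind(rows$center_species,
                                       rows$neighbor_species)]
  rows$sd_count <- sd_counts[cbind(rows$center_species,
                                   rows$neighbor_species)]
  totals <- rowSums(mean_counts)
  rows$percent <- 100 * rows$mean_count / totals[rows$center_species]
  rows <- rows[order(rows$center_species, rows$neighbor_species), ]
  rownames(rows) <- NULL
  class(rows) <- c("neighbor_table", "data.frame")
  rows
}
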