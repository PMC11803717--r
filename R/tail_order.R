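# site-position lookup for one molecule: named matrix rows by site label
mol_site_xyz <- function(frame, mol, sites) {
  sel <- which(frame$site_molecule == mol & frame$site_name %in% sites)
  m <- frame$coords[sel, , drop = FALSE]
  rownames(m) <- frame$site_name[sel]
  m[sites[sites %in% rownames(m)], , drop = FALSE]
}

#' Skeletal chain vector at one carbon position
#'
#' The orientation of the acyl chain at carbon i is taken as the
#' minimum-image displacement from carbon C(i-1) to C(i+1), so the vector
#' is defined for interior positions 2 .. n-1 of an n-carbon chain.
#'
#' @param frame a [boxed_frame].
#' @param gmap a [group_map] with the chain site labels of the molecule's
#'   species.
#' @param mol molecule index.
#' @param chain "SN1" or "SN2".
#' @param i carbon position along the chain (glycerol end = 1).
#' @return Numeric 3-vector, Angstrom.
#' @export
chain_vector <- function(frame, gmap, mol, chain = c("SN1", "SN2"), i) {
  chain <- match.arg(chain)
  sp <- unique(frame$site_species[frame$site_molecule == mol])
  if (!length(sp)) stop("molecule ", mol, " not present in frame")
  labels <- gmap[[sp]]$chains[[chain]]
  if (is.null(labels)) stop("no ", chain, " chain defined for species ", sp)
  n <- length(labels)
  if (i < 2L || i > n - 1L)
    stop(sprintf("carbon index %d is terminal for a %d-carbon chain", i, n))
  xyz <- mol_site_xyz(frame, mol, labels[c(i - 1L, i + 1L)])
  if (nrow(xyz) != 2L)
    stop(sprintf("sites %s/%s of molecule %d not found",
                 labels[i - 1L], labels[i + 1L], mol))
  minimum_image_displacement(xyz[2, ], xyz[1, ], frame$box, mode = "xyz")
}

#' Carbon-carbon order parameter profile
#'
#' Computes, for every interior carbon position i of the named chain,
#' \deqn{S_C(i) = \langle (3 \cos^2 \theta_i - 1)/2 \rangle,}
#' where theta_i is the angle between the membrane normal (the +z axis)
#' and the minimum-image vector joining carbons C(i-1) and C(i+1), averaged
#' over all molecules of the species and over frames.  Both leaflets are
#' pooled (the cosine enters squared, so the lower leaflet needs no sign
#' flip).  S_C = 1 for chains aligned with the normal, -0.5 for chains in
#' the membrane plane and 0 for isotropic orientations.  The standard
#' error per position is the autocorrelation-corrected error of the
#' per-frame means (plain sd/sqrt(n) when fewer than 10 frames).
#'
#' @param frames list of [boxed_frame] objects.
#' @param gmap a [group_map].
#' @param species lipid species to profile.
#' @param chain "SN1" or "SN2".
#' @return Data frame with columns `species`, `chain`, `carbon_index`,
#'   `S_C`, `se`.
#' @export
order_parameter_profile <- function(frames, gmap, species,
                                    chain = c("SN1", "SN2")) {
  chain <- match.arg(chain)
  if (inherits(frames, "boxed_frame")) frames <- list(frames)
  if (!length(frames)) stop("at least one frame is required")
  labels <- gmap[[species]]$chains[[chain]]
  if (is.null(labels))
    stop("no ", chain, " chain defined for species ", species)
  n <- length(labels)
  idx <- 2:(n - 1L)

  per_frame <- lapply(frames, function(fr) {
    sel <- fr$site_species == species & fr$site_name %in% labels
    if (!any(sel)) stop("species ", species, " absent from frame")
    mols <- fr$site_molecule[sel]
    pos_in_chain <- match(fr$site_name[sel], labels)
    # positions matrix [molecule, chain position, xyz]
    umol <- unique(mols)
    key <- cbind(match(mols, umol), pos_in_chain)
    P <- array(NA_real_, c(length(umol), n, 3))
    for (k in 1:3) P[cbind(key, k)] <- fr$coords[sel, k]
    v <- P[, idx + 1L, , drop = FALSE] - P[, idx - 1L, , drop = FALSE]
    for (k in 1:3) {
      L <- fr$box[k]
      v[, , k] <- v[, , k] - L * floor(v[, , k] / L + 0.5)
    }
    cos2 <- v[, , 3]^2 / (v[, , 1]^2 + v[, , 2]^2 + v[, , 3]^2)
    sc <- (3 * cos2 - 1) / 2                    # molecules x positions
    colMeans(matrix(sc, ncol = length(idx)), na.rm = TRUE)
  })
  M <- do.call(rbind, per_frame)               # frames x positions
  est <- apply(M, 2, function(col) {
    if (length(col) >= 10L) {
      a <- autocorr_sem(col); c(a$mean, a$sem)
    } else if (length(col) > 1L) {
      c(mean(col), stats::sd(col) / sqrt(length(col)))
    } else c(col, NA_real_)
  })
  data.frame(species = species, chain = chain, carbon_index = idx,
             S_C = est[1, ], se = est[2, ], row.names = NULL)
}
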