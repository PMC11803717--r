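COULOMB_K <- 332.0636  # kcal A / (mol e^2)

#' Nonbonded interaction scheme
#'
#' Defines how pairwise Lennard-Jones and Coulomb energies are evaluated:
#' LJ with Lorentz-Berthelot combining rules, smoothly switched to zero
#' between `lj_switch_on` and `cutoff`; electrostatics either as a
#' potential-shifted Coulomb (zero at the cutoff) or as a reaction field
#' with dielectric `epsilon_rf` beyond the cutoff sphere (the usual choice
#' for Martini-style coarse-grained models, default dielectric 15).  Both
#' modes are continuous at the cutoff and zero beyond it.
#'
#' @param lj_switch_on LJ switching onset, Angstrom (default 10).
#' @param cutoff nonbonded cutoff, Angstrom (default 12).
#' @param coulomb_mode "shifted" or "reaction_field".
#' @param epsilon_rf reaction-field dielectric (default 15).
#' @return An object of class `nonbonded_scheme`.
#' @export
nonbonded_scheme <- function(lj_switch_on = 10, cutoff = 12,
                             coulomb_mode = c("shifted", "reaction_field"),
                             epsilon_rf = 15) {
  coulomb_mode <- match.arg(coulomb_mode)
  if (!(lj_switch_on > 0 && lj_switch_on < cutoff))
    stop("need 0 < lj_switch_on < cutoff")
  structure(list(lj_switch_on = lj_switch_on, cutoff = cutoff,
                 coulomb_mode = coulomb_mode, epsilon_rf = epsilon_rf,
                 coulomb_constant = COULOMB_K),
            class = "nonbonded_scheme")
}

# vectorized components; dr, qi, qj, eps_i, eps_j, sig_i, sig_j same length
pair_energy_components <- function(dr, qi, qj, eps_i, eps_j, sig_i, sig_j,
                                   scheme) {
  if (any(dr <= 0)) stop("overlapping sites: pair distance must be positive")
  rc <- scheme$cutoff
  ron <- scheme$lj_switch_on
  inside <- dr < rc
  lj <- numeric(length(dr))
  coul <- numeric(length(dr))
  if (any(inside)) {
    r <- dr[inside]
    eps <- sqrt(eps_i[inside] * eps_j[inside])
    sig <- (sig_i[inside] + sig_j[inside]) / 2
    sr6 <- (sig / r)^6
    v <- 4 * eps * (sr6^2 - sr6)
    # smooth energy switch between ron and rc
    sw <- rep(1, length(r))
    mid <- r > ron
    if (any(mid)) {
      r2 <- r[mid]^2; rc2 <- rc^2; ron2 <- ron^2
      sw[mid] <- ((rc2 - r2)^2 * (rc2 + 2 * r2 - 3 * ron2)) / (rc2 - ron2)^3
    }
    lj[inside] <- v * sw
    qq <- COULOMB_K * qi[inside] * qj[inside]
    if (scheme$coulomb_mode == "shifted") {
      coul[inside] <- qq * (1 / r - 1 / rc)
    } else {
      krf <- (scheme$epsilon_rf - 1) / ((2 * scheme$epsilon_rf + 1) * rc^3)
      crf <- 1 / rc + krf * rc^2
      coul[inside] <- qq * (1 / r + krf * r^2 - crf)
    }
  }
  list(lj = lj, coulomb = coul)
}

#' Pairwise nonbonded energy of two sites
#'
#' @param dr site-site distance, Angstrom (> 0; vectorized).
#' @param q_i,q_j partial charges, e.
#' @param lj_i,lj_j length-2 vectors `(epsilon, sigma)` in kcal/mol and
#'   Angstrom.
#' @param scheme a [nonbonded_scheme].
#' @return Total LJ + Coulomb energy in kcal/mol (zero beyond the cutoff).
#' @export
pair_energy <- function(dr, q_i, q_j, lj_i = c(0, 1), lj_j = c(0, 1),
                        scheme = nonbonded_scheme()) {
  n <- length(dr)
  comp <- pair_energy_components(dr,
                                 rep_len(q_i, n), rep_len(q_j, n),
                                 rep_len(lj_i[1], n), rep_len(lj_j[1], n),
                                 rep_len(lj_i[2], n), rep_len(lj_j[2], n),
                                 scheme)
  comp$lj + comp$coulomb
}

# per-site parameter table for a frame: group, charge, eps, sigma, is_ion
site_parameters <- function(frame, gmap) {
  n <- nrow(frame$coords)
  group <- character(n); charge <- numeric(n)
  eps <- numeric(n); sig <- rep(1, n)
  known <- logical(n)
  for (sp in names(gmap)) {
    e <- gmap[[sp]]
    sel <- frame$site_species == sp
    if (!any(sel)) next
    if (isTRUE(e$ion)) {
      group[sel] <- "ion"
    } else {
      g <- e$site_group[frame$site_name[sel]]
      if (anyNA(g))
        stop(sprintf("species %s: site(s) missing from site_group: %s", sp,
                     paste(unique(frame$site_name[sel][is.na(g)]), collapse = ", ")))
      group[sel] <- g
    }
    if (!is.null(e$charges)) {
      q <- e$charges[frame$site_name[sel]]
      q[is.na(q)] <- 0
      charge[sel] <- q
    }
    if (!is.null(e$lj)) {
      m <- match(frame$site_name[sel], e$lj$site)
      eps[sel] <- ifelse(is.na(m), 0, e$lj$epsilon[m])
      sig[sel] <- ifelse(is.na(m), 1, e$lj$sigma[m])
    }
    known[sel] <- TRUE
  }
  data.frame(species = frame$site_species, name = frame$site_name,
             mol = frame$site_molecule, group = group, charge = charge,
             eps = eps, sigma = sig, known = known)
}

# all intermolecular site-pair energies within the cutoff between two site
# index sets (or within one when jdx is NULL); returns a data.frame
site_pair_energies <- function(frame, pars, scheme, idx, jdx = NULL) {
  within <- is.null(jdx)
  if (within) jdx <- idx
  D <- min_image_dist_matrix(frame$coords[idx, , drop = FALSE],
                             frame$coords[jdx, , drop = FALSE],
                             frame$box, mode = "xyz")
  keep <- D < scheme$cutoff
  same_mol <- outer(frame$site_molecule[idx], frame$site_molecule[jdx], "==")
  keep <- keep & !same_mol
  if (within) keep <- keep & upper.tri(D)
  w <- which(keep, arr.ind = TRUE)
  if (!nrow(w))
    return(data.frame(i = integer(), j = integer(), r = numeric(),
                      lj = numeric(), coulomb = numeric()))
  i <- idx[w[, 1]]; j <- jdx[w[, 2]]
  comp <- pair_energy_components(D[w], pars$charge[i], pars$charge[j],
                                 pars$eps[i], pars$eps[j],
                                 pars$sigma[i], pars$sigma[j], scheme)
  data.frame(i = i, j = j, r = D[w], lj = comp$lj, coulomb = comp$coulomb)
}

#' Group-pair decomposition of the lipid-lipid interaction energy
#'
#' Sums pairwise nonbonded energies over all intermolecular site pairs of
#' the lipid species and accumulates them into cells indexed by the
#' unordered (species, subunit) pair of the interacting sites, where the
#' subunits are the four lipid groups head, phosphate, glycol and tail.
#' Intramolecular pairs are excluded entirely; each unordered site pair is
#' counted once.  Ions are left out of this matrix (see
#' [ion_lipid_energies]).
#'
#' @param frame a [boxed_frame].
#' @param gmap a [group_map] with groups, charges and LJ parameters for
#'   every lipid site.
#' @param scheme a [nonbonded_scheme].
#' @return An object of class `group_energy_matrix`: a data frame with
#'   columns `species_i`, `group_i`, `species_j`, `group_j`, `lj`,
#'   `coulomb`, `energy` (kcal/mol), one row per occupied cell.
#' @export
group_pair_energies <- function(frame, gmap, scheme = nonbonded_scheme()) {
  pars <- site_parameters(frame, gmap)
  lip <- which(pars$known & pars$group != "ion")
  if (!length(lip)) stop("no lipid sites with parameters in the frame")
  pe <- site_pair_energies(frame, pars, scheme, lip)
  if (nrow(pe)) {
    ki <- paste(pars$species[pe$i], pars$group[pe$i], sep = "\r")
    kj <- paste(pars$species[pe$j], pars$group[pe$j], sep = "\r")
    lo <- pmin(ki, kj); hi <- pmax(ki, kj)
    key <- paste(lo, hi, sep = "\n")
    agg <- rowsum(cbind(lj = pe$lj, coulomb = pe$coulomb), key)
    parts <- do.call(rbind, strsplit(rownames(agg), "[\n\r]"))
    out <- data.frame(species_i = parts[, 1], group_i = parts[, 2],
                      species_j = parts[, 3], group_j = parts[, 4],
                      lj = agg[, "lj"], coulomb = agg[, "coulomb"],
                      row.names = NULL)
  } else {
    out <- data.frame(species_i = character(), group_i = character(),
                      species_j = character(), group_j = character(),
                      lj = numeric(), coulomb = numeric())
  }
  out$energy <- out$lj + out$coulomb
  class(out) <- c("group_energy_matrix", "data.frame")
  out
}

#' Total and partial interaction energies from a group-pair matrix
#'
#' The total interaction energy sums every cell of the group-pair matrix.
#' The partial interaction energy removes all like-group cells -- head-head,
#' phosphate-phosphate, glycol-glycol and tail-tail pairs between any two
#' molecules of the same or different species -- keeping only unlike-group
#' contributions.
#'
#' @param matrix a [group_pair_energies] result.
#' @return A list with `total` and `partial` (kcal/mol).
#' @export
total_and_partial <- function(matrix) {
  total <- sum(matrix$energy)
  like <- matrix$group_i == matrix$group_j
  list(total = total, partial = total - sum(matrix$energy[like]))
}

#' Interaction energies decomposed by species pair
#'
#' Splits the total and partial lipid-lipid interaction energies by the
#' unordered species pair of the interacting molecules (primary-primary,
#' primary-secondary, secondary-secondary for a binary mixture).  The
#' components sum to the overall totals by construction.
#'
#' @inheritParams group_pair_energies
#' @return A data frame with columns `species_i`, `species_j`, `total`,
#'   `partial` (kcal/mol).
#' @export
species_decomposition <- function(frame, gmap, scheme = nonbonded_scheme()) {
  mat <- group_pair_energies(frame, gmap, scheme)
  lo <- pmin(mat$species_i, mat$species_j)
  hi <- pmax(mat$species_i, mat$species_j)
  key <- paste(lo, hi, sep = "\n")
  like <- mat$group_i == mat$group_j
  tot <- rowsum(mat$energy, key)
  par_ <- rowsum(mat$energy * !like, key)
  parts <- do.call(rbind, strsplit(rownames(tot), "\n"))
  data.frame(species_i = parts[, 1], species_j = parts[, 2],
             total = tot[, 1], partial = par_[, 1], row.names = NULL)
}

#' Ion to lipid head and phosphate group interaction energies
#'
#' Sums pairwise nonbonded energies between every ion site (species marked
#' `ion = TRUE` in the group map, e.g. Na+ and Cl-) and every site of the
#' target lipid species belonging to its head group (respectively its
#' phosphate group).  Species whose head group is empty (a phosphatidic
#' acid whose "headgroup" is a lone hydrogen folded into the phosphate
#' subunit) simply yield zero for the head term.
#'
#' @param frame a [boxed_frame].
#' @param gmap a [group_map].
#' @param scheme a [nonbonded_scheme].
#' @param species target lipid species; defaults to the only lipid species
#'   present, or errors if ambiguous.
#' @return A list with `ion_head` and `ion_phosphate` (kcal/mol).
#' @export
ion_lipid_energies <- function(frame, gmap, scheme = nonbonded_scheme(),
                               species = NULL) {
  pars <- site_parameters(frame, gmap)
  ions <- which(pars$group == "ion")
  if (!length(ions)) {
    warning("no ion sites present; ion-lipid energies are zero")
    return(list(ion_head = 0, ion_phosphate = 0))
  }
  if (is.null(species)) {
    sp <- intersect(unique(frame$site_species), lipid_species(gmap))
    if (length(sp) != 1L)
      stop("specify `species`: frame contains ", length(sp), " lipid species")
    species <- sp
  }
  out <- lapply(c(head = "head", phosphate = "phosphate"), function(g) {
    tgt <- which(pars$species == species & pars$group == g)
    if (!length(tgt)) return(0)
    pe <- site_pair_energies(frame, pars, scheme, ions, tgt)
    sum(pe$lj + pe$coulomb)
  })
  list(ion_head = out$head, ion_phosphate = out$phosphate)
}
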