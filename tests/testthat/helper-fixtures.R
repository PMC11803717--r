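# shared fixtures and independent oracles -------------------------------

# minimal bilayer of point lipids: each lipid has PO4 and GL1 sites.
# xy: n x 2 matrix of lateral positions (used for both leaflets unless
# xy_lower given); species: length-n labels.
make_point_bilayer <- function(xy, species, box, xy_lower = xy,
                               species_lower = species, zoff = 18) {
  build <- function(xy, species, side, mol0) {
    n <- nrow(xy)
    zP <- box[3] / 2 + side * zoff
    coords <- do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(c(xy[i, 1], xy[i, 2], zP),
            c(xy[i, 1], xy[i, 2], zP - side * 2))
    }))
    list(coords = coords,
         species = rep(species, each = 2),
         mol = rep(mol0 + seq_len(n), each = 2),
         name = rep(c("PO4", "GL1"), n))
  }
  up <- build(xy, species, 1, 0)
  lo <- build(xy_lower, species_lower, -1, nrow(xy))
  boxed_frame(rbind(up$coords, lo$coords),
              c(up$species, lo$species),
              c(up$mol, lo$mol),
              c(up$name, lo$name),
              box = box)
}

# group map for point lipids (PO4/GL1 only)
point_group_map <- function(species = c("DOPC", "DSPG")) {
  e <- list(site_group = c(PO4 = "phosphate", GL1 = "glycol"),
            phosphorus_site = "PO4", gl1_site = "GL1",
            charges = c(PO4 = -1, GL1 = 0),
            lj = data.frame(site = c("PO4", "GL1"), epsilon = 0.1, sigma = 4))
  group_map(stats::setNames(rep(list(e), length(species)), species))
}

# brute-force minimum image over all 27 periodic images
oracle_min_image <- function(a, b, box) {
  best <- NULL; bestn <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (a - b) + c(ix, iy, iz) * box
    if (sum(d^2) < bestn) { bestn <- sum(d^2); best <- d }
  }
  best
}

# scalar re-implementation of the nonbonded model for the energy oracle;
# deliberately written long-hand and independent of the package internals
oracle_pair_energy <- function(r, qi, qj, ei, ej, si, sj, scheme) {
  if (r >= scheme$cutoff) return(c(lj = 0, coulomb = 0))
  eps <- sqrt(ei * ej); sig <- (si + sj) / 2
  lj <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
  if (r > scheme$lj_switch_on) {
    rc2 <- scheme$cutoff^2; ron2 <- scheme$lj_switch_on^2; r2 <- r^2
    lj <- lj * ((rc2 - r2)^2 * (rc2 + 2 * r2 - 3 * ron2)) / (rc2 - ron2)^3
  }
  k <- 332.0636
  if (scheme$coulomb_mode == "shifted") {
    coul <- k * qi * qj * (1 / r - 1 / scheme$cutoff)
  } else {
    rc <- scheme$cutoff
    krf <- (scheme$epsilon_rf - 1) / ((2 * scheme$epsilon_rf + 1) * rc^3)
    coul <- k * qi * qj * (1 / r + krf * r^2 - (1 / rc + krf * rc^2))
  }
  c(lj = lj, coulomb = coul)
}

# site lookup tables for the oracle
oracle_site_params <- function(frame, gmap) {
  n <- nrow(frame$coords)
  out <- data.frame(species = frame$site_species, name = frame$site_name,
                    mol = frame$site_molecule, group = NA_character_,
                    q = 0, eps = 0, sig = 1)
  for (i in seq_len(n)) {
    e <- gmap[[out$species[i]]]
    if (is.null(e)) next
    out$group[i] <- if (isTRUE(e$ion)) "ion" else
      unname(e$site_group[out$name[i]])
    if (!is.null(e$charges)) {
      q <- e$charges[out$name[i]]; if (!is.na(q)) out$q[i] <- q
    }
    if (!is.null(e$lj)) {
      m <- match(out$name[i], e$lj$site)
      if (!is.na(m)) { out$eps[i] <- e$lj$epsilon[m]; out$sig[i] <- e$lj$sigma[m] }
    }
  }
  out
}

# O(N^2) double loop over intermolecular site pairs; returns per-pair rows
oracle_energy_table <- function(frame, gmap, scheme) {
  p <- oracle_site_params(frame, gmap)
  n <- nrow(frame$coords)
  cap <- n * (n - 1) / 2
  ii <- integer(cap); jj <- integer(cap)
  lj <- numeric(cap); coul <- numeric(cap)
  k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (p$mol[i] == p$mol[j]) next
    d <- oracle_min_image(frame$coords[i, ], frame$coords[j, ], frame$box)
    r <- sqrt(sum(d^2))
    e <- oracle_pair_energy(r, p$q[i], p$q[j], p$eps[i], p$eps[j],
                            p$sig[i], p$sig[j], scheme)
    k <- k + 1L
    ii[k] <- i; jj[k] <- j; lj[k] <- e[["lj"]]; coul[k] <- e[["coulomb"]]
  }
  idx <- seq_len(k)
  data.frame(i = ii[idx], j = jj[idx],
             species_i = p$species[ii[idx]], species_j = p$species[jj[idx]],
             group_i = p$group[ii[idx]], group_j = p$group[jj[idx]],
             mol_i = p$mol[ii[idx]], mol_j = p$mol[jj[idx]],
             lj = lj[idx], coulomb = coul[idx])
}

# nearest-generator rasterization of a periodic 2D Voronoi tessellation
oracle_voronoi_raster <- function(px, py, Lx, Ly, grid = 512L) {
  gx <- (seq_len(grid) - 0.5) * Lx / grid
  gy <- (seq_len(grid) - 0.5) * Ly / grid
  counts <- numeric(length(px))
  dx <- outer(gx, px, "-"); dx <- dx - Lx * floor(dx / Lx + 0.5)
  dx2 <- dx^2
  for (row in seq_len(grid)) {
    dy <- gy[row] - py;       dy <- dy - Ly * floor(dy / Ly + 0.5)
    d2 <- sweep(dx2, 2, dy^2, "+")
    nearest <- max.col(-d2, ties.method = "first")
    counts <- counts + tabulate(nearest, nbins = length(px))
  }
  counts * (Lx * Ly) / grid^2
}
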