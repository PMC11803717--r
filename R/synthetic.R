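# evaluate code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic bilayer study
#'
#' Collects the parameters of the synthetic generators.  The defaults
#' mirror the scale of the atomistic systems the analyses target: 100
#' lipids per leaflet at a 65:35 primary:secondary composition on a
#' jittered square lattice at the zero-tension DOPC area per lipid of
#' 66.3 Angstrom^2 (box ~ 81 x 81 Angstrom), a true area compressibility
#' modulus of 245.81 mN/m probed at imposed tensions -7, 0, 7 and 15 mN/m,
#' and AR(1)-correlated area fluctuations.
#'
#' @param n_per_leaflet lipids per leaflet (default 100).
#' @param composition primary-species mole fraction in (0, 1) (default 0.65).
#' @param A0 reference area per lipid at zero tension, Angstrom^2
#'   (default 66.3).
#' @param lattice_spacing lattice constant, Angstrom (default `sqrt(A0)`).
#' @param jitter sd of the lateral lattice jitter, Angstrom (default 0.8;
#'   must stay below half the lattice spacing).
#' @param tilt_model list with `type` ("fixed", "vonmises" or "isotropic"),
#'   `theta_deg` (fixed tilt, degrees) and `kappa` (von Mises-Fisher
#'   concentration of the tail axis about the inward normal).
#' @param true_KA planted area compressibility modulus, mN/m
#'   (default 245.81).
#' @param gammas imposed surface tensions, mN/m (must include 0).
#' @param n_frames frames per series (default 100, minimum 10).
#' @param ar1_phi AR(1) coefficient of the area noise in [0, 1)
#'   (default 0.8).
#' @param noise_sd stationary sd of the per-frame area-per-lipid noise,
#'   Angstrom^2 (default 0.8).
#' @param clustering species-label layout: "random", "checkerboard" or
#'   "blocks".
#' @param species length-2 character vector of primary and secondary
#'   species labels.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_leaflet = 100, composition = 0.65,
                           A0 = 66.3, lattice_spacing = sqrt(A0),
                           jitter = 0.8,
                           tilt_model = list(type = "vonmises", theta_deg = 0,
                                             kappa = 8),
                           true_KA = 245.81, gammas = c(-7, 0, 7, 15),
                           n_frames = 100, ar1_phi = 0.8, noise_sd = 0.8,
                           clustering = c("random", "checkerboard", "blocks"),
                           species = c("DOPC", "DSPG"), seed = 1L) {
  clustering <- match.arg(clustering)
  if (composition <= 0 || composition >= 1)
    stop("composition must be in (0, 1)")
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must be in [0, 1)")
  if (n_frames < 10L) stop("n_frames must be at least 10")
  if (jitter >= lattice_spacing / 2)
    stop("jitter must be below half the lattice spacing (overlap risk)")
  if (!is.list(tilt_model) ||
      !tilt_model$type %in% c("fixed", "vonmises", "isotropic"))
    stop("tilt_model$type must be 'fixed', 'vonmises' or 'isotropic'")
  structure(list(n_per_leaflet = as.integer(n_per_leaflet),
                 composition = composition, A0 = A0,
                 lattice_spacing = lattice_spacing, jitter = jitter,
                 tilt_model = tilt_model, true_KA = true_KA,
                 gammas = gammas, n_frames = as.integer(n_frames),
                 ar1_phi = ar1_phi, noise_sd = noise_sd,
                 clustering = clustering, species = species,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Group map matching the synthetic bilayer geometry
#'
#' Each synthetic lipid carries a head site `HD` (+1 e), a phosphate site
#' `PO4` (-1 e), a glycol/linker site `GL1` and two 18-carbon tails
#' `A1..A18` (SN1) and `B1..B18` (SN2); monovalent ions `NA` and `CL` are
#' included as ion species.
#'
#' @param species length-2 character vector of lipid species labels.
#' @return A [group_map].
#' @export
synthetic_group_map <- function(species = c("DOPC", "DSPG")) {
  sn1 <- paste0("A", 1:18)
  sn2 <- paste0("B", 1:18)
  sites <- c("HD", "PO4", "GL1", sn1, sn2)
  sg <- stats::setNames(c("head", "phosphate", "glycol",
                          rep("tail", 36)), sites)
  charges <- stats::setNames(c(1, -1, rep(0, 37)), sites)
  lj <- data.frame(site = sites, epsilon = 0.1, sigma = 4)
  lipid <- list(site_group = sg, phosphorus_site = "PO4", gl1_site = "GL1",
                chains = list(SN1 = sn1, SN2 = sn2),
                charges = charges, lj = lj)
  entries <- stats::setNames(rep(list(lipid), length(species)), species)
  entries[["NA"]] <- list(ion = TRUE,
                          charges = c(ION = 1),
                          site_group = c(ION = "ion"),
                          lj = data.frame(site = "ION", epsilon = 0.1, sigma = 3))
  entries[["CL"]] <- list(ion = TRUE,
                          charges = c(ION = -1),
                          site_group = c(ION = "ion"),
                          lj = data.frame(site = "ION", epsilon = 0.1, sigma = 4))
  group_map(entries)
}

# sample the polar angle of a von Mises-Fisher direction about the mean
rvmf_polar <- function(n, kappa) {
  u <- stats::runif(n)
  if (kappa < 1e-8) return(acos(1 - 2 * u))
  acos(pmin(1, pmax(-1, 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa)))
}

sample_tilts <- function(n, tilt_model) {
  theta <- switch(tilt_model$type,
                  fixed = rep(tilt_model$theta_deg * pi / 180, n),
                  vonmises = rvmf_polar(n, tilt_model$kappa),
                  isotropic = acos(stats::runif(n, -1, 1)))
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Generate frames of a synthetic planar bilayer
#'
#' Places `n_per_leaflet` lipids per leaflet on a jittered square lattice
#' (fresh jitter every frame; species labels fixed over time), with each
#' lipid carrying head, phosphate and glycol sites and two straight
#' 18-carbon tails whose axes are drawn from the tilt model about the
#' inward membrane normal (1.27 Angstrom per carbon).  Species labels
#' follow the clustering mode: independent draws at the prescribed
#' composition, a checkerboard, or contiguous blocks.  Bit-reproducible
#' for a given spec seed.
#'
#' @param spec a [synthetic_spec].
#' @param n_frames number of frames (defaults to `min(spec$n_frames, 10)`;
#'   full-resolution series belong to [gen_gamma_area_series], not to
#'   coordinate frames).
#' @return A list of [boxed_frame] objects.
#' @export
gen_leaflet_frames <- function(spec, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- min(spec$n_frames, 10L)
  n <- spec$n_per_leaflet
  a <- spec$lattice_spacing
  m <- ceiling(sqrt(n))
  Lx <- Ly <- m * a
  Lz <- 100
  zoff <- 18            # phosphate plane offset from the midplane
  grid <- expand.grid(ix = seq_len(m) - 0.5, iy = seq_len(m) - 0.5)[seq_len(n), ]

  labels_for <- function() {
    switch(spec$clustering,
           random = ifelse(stats::runif(n) < spec$composition,
                           spec$species[1], spec$species[2]),
           checkerboard = ifelse((round(grid$ix - 0.5) +
                                  round(grid$iy - 0.5)) %% 2 == 0,
                                 spec$species[1], spec$species[2]),
           blocks = ifelse(seq_len(n) <= round(spec$composition * n),
                           spec$species[1], spec$species[2]))
  }

  with_seed(spec$seed, {
    lab_upper <- labels_for()
    lab_lower <- labels_for()
    frames <- lapply(seq_len(n_frames), function(f) {
      coords <- list(); species <- list(); molecule <- list(); name <- list()
      mol0 <- 0L
      for (lf in c("upper", "lower")) {
        lab <- if (lf == "upper") lab_upper else lab_lower
        outward <- if (lf == "upper") 1 else -1
        zP <- Lz / 2 + outward * zoff
        x <- grid$ix * a + stats::rnorm(n, 0, spec$jitter)
        y <- grid$iy * a + stats::rnorm(n, 0, spec$jitter)
        d1 <- sample_tilts(n, spec$tilt_model)
        d2 <- sample_tilts(n, spec$tilt_model)
        # tail axes point inward: fold the sampled z toward the midplane
        # (S_C only sees cos^2, so folding leaves the order parameter alone)
        d1[, 3] <- -outward * abs(d1[, 3])
        d2[, 3] <- -outward * abs(d2[, 3])
        for (i in seq_len(n)) {
          p <- c(x[i], y[i], zP)
          hd <- p + c(0, 0, outward * 2.5)
          gl <- p - c(0, 0, outward * 2.5)
          t1 <- sweep(outer(1:18, d1[i, ]) * 1.27, 2, gl + c(0.8, 0, 0), "+")
          t2 <- sweep(outer(1:18, d2[i, ]) * 1.27, 2, gl - c(0.8, 0, 0), "+")
          coords[[length(coords) + 1L]] <- rbind(hd, p, gl, t1, t2)
          species[[length(species) + 1L]] <- rep(lab[i], 39)
          molecule[[length(molecule) + 1L]] <- rep(mol0 + i, 39)
          name[[length(name) + 1L]] <- c("HD", "PO4", "GL1",
                                         paste0("A", 1:18), paste0("B", 1:18))
        }
        mol0 <- mol0 + n
      }
      boxed_frame(coords = do.call(rbind, coords),
                  site_species = unlist(species),
                  site_molecule = unlist(molecule),
                  site_name = unlist(name),
                  box = c(Lx, Ly, Lz),
                  time = f - 1)
    })
    frames
  })
}

#' Redraw species labels of a synthetic frame at random
#'
#' Reassigns the species label of every lipid molecule independently at
#' random with probability `p_primary` for the primary label, leaving
#' coordinates untouched.  Useful for label-randomization experiments on a
#' fixed geometry.
#'
#' @param frame a [boxed_frame].
#' @param p_primary probability of the primary label.
#' @param species length-2 character vector (primary, secondary); molecules
#'   currently carrying either label are relabeled.
#' @param seed integer seed.
#' @return The relabeled [boxed_frame].
#' @export
relabel_species <- function(frame, p_primary = 0.65,
                            species = c("DOPC", "DSPG"), seed = 1L) {
  mols <- unique(frame$site_molecule[frame$site_species %in% species])
  with_seed(seed, {
    new <- ifelse(stats::runif(length(mols)) < p_primary,
                  species[1], species[2])
    idx <- match(frame$site_molecule, mols)
    sel <- !is.na(idx)
    frame$site_species[sel] <- new[idx[sel]]
    frame
  })
}

# stationary AR(1) series
gen_ar1 <- function(n, mean, sd, phi) {
  if (phi == 0 || sd == 0) return(mean + stats::rnorm(n, 0, sd))
  innov_sd <- sd * sqrt(1 - phi^2)
  x0 <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n, 0, innov_sd)
  mean + as.numeric(stats::filter(innov, phi, "recursive", init = x0))
}

#' Generate per-tension area series with a planted K_A
#'
#' For each imposed tension gamma the mean area per lipid is
#' `A0 * (1 + gamma / true_KA)` (the linear tension-strain relation
#' inverted) and per-frame areas follow a stationary AR(1) process around
#' that mean with sd `noise_sd` and coefficient `ar1_phi`.
#'
#' @param spec a [synthetic_spec]; `gammas` must include 0.
#' @return A [gamma_area_series] with attribute `truth` (list with
#'   `true_KA` and `A0`).
#' @export
gen_gamma_area_series <- function(spec) {
  if (!0 %in% spec$gammas) stop("gammas must include 0")
  if (spec$true_KA <= 0) stop("true_KA must be positive")
  series <- with_seed(spec$seed, {
    lapply(spec$gammas, function(g)
      gen_ar1(spec$n_frames, spec$A0 * (1 + g / spec$true_KA),
              spec$noise_sd, spec$ar1_phi))
  })
  out <- gamma_area_series(spec$gammas, series)
  attr(out, "truth") <- list(true_KA = spec$true_KA, A0 = spec$A0)
  out
}

#' Generate a pressure-tensor record with a target surface tension
#'
#' Holds the normal component at Pzz = 1 bar and draws the lateral
#' components around `Pzz - gamma_target / (0.01 * Lz)` so that the
#' per-frame surface tension has mean `gamma_target`.
#'
#' @param gamma_target target surface tension, mN/m.
#' @param Lz box height, Angstrom.
#' @param n_frames number of frames.
#' @param noise_sd sd of the lateral-pressure noise, bar (default 0).
#' @param seed integer seed.
#' @return A data frame with columns `frame,Pxx_bar,Pyy_bar,Pzz_bar,Lz_A`.
#' @export
gen_pressure_record <- function(gamma_target, Lz, n_frames,
                                noise_sd = 0, seed = 1L) {
  if (Lz <= 0) stop("Lz must be positive")
  base <- 1 - gamma_target / (0.01 * Lz)
  with_seed(seed, {
    data.frame(frame = seq_len(n_frames) - 1L,
               Pxx_bar = base + stats::rnorm(n_frames, 0, noise_sd),
               Pyy_bar = base + stats::rnorm(n_frames, 0, noise_sd),
               Pzz_bar = rep(1, n_frames),
               Lz_A = rep(Lz, n_frames))
  })
}

#' Generate a charged toy particle system for energy oracles
#'
#' Builds `n` small multi-site molecules of two template species (four and
#' three sites, with head/phosphate/glycol/tail group labels, random
#' partial charges and LJ parameters), plus optional monovalent ions,
#' uniformly placed in an orthorhombic box.  The returned group map makes
#' the system directly consumable by the energy decomposition.
#'
#' @param n number of molecules (>= 2).
#' @param box length-3 box, Angstrom (default 30^3).
#' @param charge_model "random" or "neutral" (all charges zero).
#' @param n_ions number of additional single-site ions (alternating +1/-1).
#' @param seed integer seed.
#' @return A list with `frame` (a [boxed_frame]) and `gmap` (a
#'   [group_map]).
#' @export
gen_charged_toy_system <- function(n, box = c(30, 30, 30),
                                   charge_model = c("random", "neutral"),
                                   n_ions = 0, seed = 1L) {
  charge_model <- match.arg(charge_model)
  if (n < 2L) stop("need at least two molecules")
  with_seed(seed, {
    templates <- list(
      TOYA = list(sites = paste0("S", 1:4),
                  groups = c("head", "phosphate", "glycol", "tail")),
      TOYB = list(sites = paste0("S", 1:3),
                  groups = c("head", "glycol", "tail")))
    gm <- lapply(templates, function(tp) {
      k <- length(tp$sites)
      q <- if (charge_model == "neutral") rep(0, k) else
        stats::runif(k, -1, 1)
      list(site_group = stats::setNames(tp$groups, tp$sites),
           phosphorus_site = if ("phosphate" %in% tp$groups)
             tp$sites[match("phosphate", tp$groups)] else NULL,
           charges = stats::setNames(q, tp$sites),
           lj = data.frame(site = tp$sites,
                           epsilon = stats::runif(k, 0.05, 0.3),
                           sigma = stats::runif(k, 3, 5)))
    })
    gm[["NA"]] <- list(ion = TRUE, site_group = c(ION = "ion"),
                       charges = c(ION = 1),
                       lj = data.frame(site = "ION", epsilon = 0.1, sigma = 3))
    gm[["CL"]] <- list(ion = TRUE, site_group = c(ION = "ion"),
                       charges = c(ION = -1),
                       lj = data.frame(site = "ION", epsilon = 0.1, sigma = 4))
    gmap <- group_map(gm)

    coords <- list(); species <- character(0); mol <- integer(0)
    name <- character(0)
    for (i in seq_len(n)) {
      sp <- names(templates)[1 + (i %% 2)]
      k <- length(templates[[sp]]$sites)
      center <- stats::runif(3) * box
      coords[[i]] <- sweep(matrix(stats::runif(3 * k, -2, 2), ncol = 3),
                           2, center, "+")
      species <- c(species, rep(sp, k))
      mol <- c(mol, rep(i, k))
      name <- c(name, templates[[sp]]$sites)
    }
    if (n_ions > 0) {
      for (i in seq_len(n_ions)) {
        coords[[n + i]] <- matrix(stats::runif(3) * box, ncol = 3)
        species <- c(species, if (i %% 2 == 1) "NA" else "CL")
        mol <- c(mol, n + i)
        name <- c(name, "ION")
      }
    }
    list(frame = boxed_frame(do.call(rbind, coords), species, mol, name,
                             box = box),
         gmap = gmap)
  })
}
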