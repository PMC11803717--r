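test_that("spacing histogram puts a lone pair in the right bin", {
  gm <- point_group_map("DOPC")
  fr <- make_point_bilayer(rbind(c(10, 10), c(40, 10)), rep("DOPC", 2),
                           c(80, 80, 100))
  h <- lipid_spacing_distribution(list(fr), gm, "upper", "DOPC")
  expect_equal(sum(h$probability), 1, tolerance = 1e-9)
  occupied <- which(h$probability > 0)
  expect_length(occupied, 1)
  expect_true(h$bin_edges[occupied] <= 30 && 30 <= h$bin_edges[occupied + 1])
})

test_that("spacing uses lateral minimum-image distances", {
  gm <- point_group_map("DOPC")
  # across the x boundary: true lateral separation 2 A, naive 78 A
  fr <- make_point_bilayer(rbind(c(79, 10), c(1, 10)), rep("DOPC", 2),
                           c(80, 80, 100))
  h <- lipid_spacing_distribution(list(fr), gm, "upper", "DOPC")
  expect_equal(which(h$probability > 0), 3)  # bin [2, 3)
})

test_that("a jittered square lattice peaks at the lattice constant", {
  spec <- synthetic_spec(n_per_leaflet = 64, jitter = 0.3, seed = 4)
  frames <- gen_leaflet_frames(spec, n_frames = 2)
  gm <- synthetic_group_map()
  h <- lipid_spacing_distribution(frames, gm, "upper", "DOPC")
  a <- spec$lattice_spacing
  # the nearest-neighbor shell starts at the lattice constant: the first
  # occupied bin sits just below a (lattice jitter), nothing below it
  first_bin <- which(h$probability > 0)[1]
  expect_gt(h$bin_edges[first_bin + 1], a - 2)
  expect_lt(h$bin_edges[first_bin], a + 0.5)
  # brute-force oracle: recompute the same histogram by pair enumeration
  part <- assign_leaflets(frames[[1]], gm)
  keep <- frames[[1]]$site_name == "PO4" &
    frames[[1]]$site_species == "DOPC" &
    as.character(frames[[1]]$site_molecule) %in%
      names(part$assignment)[part$assignment == "upper"]
  P <- frames[[1]]$coords[keep, ]
  d <- c()
  for (i in 1:(nrow(P) - 1)) for (j in (i + 1):nrow(P)) {
    dd <- P[i, 1:2] - P[j, 1:2]
    dd <- dd - frames[[1]]$box[1:2] * floor(dd / frames[[1]]$box[1:2] + 0.5)
    d <- c(d, sqrt(sum(dd^2)))
  }
  h1 <- lipid_spacing_distribution(list(frames[[1]]), gm, "upper", "DOPC")
  want <- tabulate(findInterval(d[d <= max(h1$bin_edges)], h1$bin_edges),
                   nbins = length(h1$bin_edges) - 1)
  expect_equal(h1$counts, want)
})

test_that("spacing histogram is invariant under rigid translation", {
  spec <- synthetic_spec(n_per_leaflet = 25, seed = 6)
  fr <- gen_leaflet_frames(spec, n_frames = 1)[[1]]
  gm <- synthetic_group_map()
  h <- lipid_spacing_distribution(list(fr), gm, "upper", "DOPC")
  fr2 <- fr
  fr2$coords <- sweep(fr$coords, 2, c(13.7, -5.1, 0), "+")
  h2 <- lipid_spacing_distribution(list(fr2), gm, "upper", "DOPC")
  expect_equal(h2$counts, h$counts)
})

test_that("Voronoi cells of a perfect square lattice all have area a^2", {
  a <- 8
  xy <- as.matrix(expand.grid(x = (0:4 + 0.5) * a, y = (0:4 + 0.5) * a))
  gm <- point_group_map("DOPC")
  fr <- make_point_bilayer(xy, rep("DOPC", 25), c(5 * a, 5 * a, 100))
  v <- voronoi_leaflet(fr, gm, "upper")
  expect_equal(v$cells$area, rep(a^2, 25), tolerance = 1e-9)
})

test_that("Voronoi areas tile the box exactly for random configurations", {
  gm <- point_group_map(c("DOPC", "DSPG"))
  set.seed(31)
  for (k in 1:20) {
    n <- sample(10:60, 1)
    box <- c(runif(1, 40, 90), runif(1, 40, 90), 100)
    xy <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]))
    sp <- sample(c("DOPC", "DSPG"), n, replace = TRUE, prob = c(0.65, 0.35))
    fr <- make_point_bilayer(xy, sp, box)
    v <- voronoi_leaflet(fr, gm, "upper")
    expect_lt(abs(sum(v$cells$area) - box[1] * box[2]) / (box[1] * box[2]),
              1e-6)
    expect_true(all(v$cells$area > 0))
  }
})

test_that("Voronoi areas match the rasterization oracle", {
  gm <- point_group_map(c("DOPC", "DSPG"))
  set.seed(12)
  n <- 30
  box <- c(70, 70, 100)
  xy <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]))
  fr <- make_point_bilayer(xy, rep(c("DOPC", "DSPG"), length.out = n), box)
  v <- voronoi_leaflet(fr, gm, "upper")
  want <- oracle_voronoi_raster(xy[, 1], xy[, 2], box[1], box[2], grid = 512L)
  expect_equal(v$cells$area, want, tolerance = 0.02)
})

test_that("coincident Voronoi generators are jittered then rejected", {
  gm <- point_group_map("DOPC")
  xy <- rbind(c(10, 10), c(10, 10), c(30, 30), c(50, 50))
  fr <- make_point_bilayer(xy, rep("DOPC", 4), c(60, 60, 100))
  v <- voronoi_leaflet(fr, gm, "upper")
  expect_equal(nrow(v$cells), 4)
  expect_lt(abs(sum(v$cells$area) - 3600) / 3600, 1e-6)
})

test_that("single-species systems have zero mixed contacts", {
  spec <- synthetic_spec(n_per_leaflet = 16, composition = 0.99, seed = 5)
  frames <- gen_leaflet_frames(spec, n_frames = 1)
  frames[[1]]$site_species[] <- "DOPC"
  fm <- mixed_contact_fraction(frames, synthetic_group_map())
  expect_equal(fm$f_mix, 0)
  expect_equal(fm$C_AB, 0)
})

test_that("a 50:50 checkerboard with first-shell contacts is fully mixed", {
  spec <- synthetic_spec(n_per_leaflet = 36, composition = 0.5,
                         clustering = "checkerboard", jitter = 0.05, seed = 2)
  frames <- gen_leaflet_frames(spec, n_frames = 2)
  # lattice constant 8.14: first shell 8.14 < 11 < 11.5 diagonal
  fm <- mixed_contact_fraction(frames, synthetic_group_map())
  expect_equal(fm$f_mix, 100)
  expect_equal(fm$sd, 0)
})

test_that("random labeling converges to the secondary mole percentage", {
  gm <- synthetic_group_map()
  for (q in c(0.2, 0.35, 0.5)) {
    spec <- synthetic_spec(n_per_leaflet = 400, composition = 1 - q,
                           seed = round(100 * q))
    frames <- gen_leaflet_frames(spec, n_frames = 2)
    fm <- mixed_contact_fraction(frames, gm, primary = "DOPC")
    expect_lt(abs(fm$f_mix - 100 * q), 3)
  }
})

test_that("species-swapped f_mix matches oracle contact counting", {
  spec <- synthetic_spec(n_per_leaflet = 64, seed = 19)
  fr <- gen_leaflet_frames(spec, n_frames = 1)[[1]]
  gm <- synthetic_group_map()
  # oracle: enumerate same-leaflet phosphate pairs under the cutoff
  part <- assign_leaflets(fr, gm)
  counts <- c(AA = 0, AB = 0, BB = 0)
  for (lf in c("upper", "lower")) {
    mols <- as.integer(names(part$assignment)[part$assignment == lf])
    keep <- fr$site_name == "PO4" & fr$site_molecule %in% mols
    P <- fr$coords[keep, ]; sp <- fr$site_species[keep]
    for (i in 1:(nrow(P) - 1)) for (j in (i + 1):nrow(P)) {
      d <- oracle_min_image(P[i, ], P[j, ], fr$box)
      if (sqrt(sum(d^2)) < 11) {
        key <- paste(sort(c(sp[i], sp[j])), collapse = "")
        key <- c(DOPCDOPC = "AA", DOPCDSPG = "AB", DSPGDSPG = "BB")[key]
        counts[key] <- counts[key] + 1
      }
    }
  }
  fmA <- mixed_contact_fraction(list(fr), gm, primary = "DOPC")
  expect_equal(fmA$f_mix,
               100 * counts["AB"] / (2 * counts["AA"] + counts["AB"]),
               ignore_attr = TRUE)
  fmB <- mixed_contact_fraction(list(fr), gm, primary = "DSPG")
  expect_equal(fmB$f_mix,
               100 * counts["AB"] / (2 * counts["BB"] + counts["AB"]),
               ignore_attr = TRUE)
})

test_that("hexagonal first-shell packing gives six neighbors each", {
  a <- 9
  ncol_ <- 6; nrow_ <- 6
  pts <- do.call(rbind, lapply(seq_len(nrow_) - 1, function(r)
    cbind((seq_len(ncol_) - 1) * a + (r %% 2) * a / 2,
          r * a * sqrt(3) / 2)))
  box <- c(ncol_ * a, nrow_ * a * sqrt(3) / 2, 100)
  gm <- point_group_map("DOPC")
  fr <- make_point_bilayer(pts, rep("DOPC", nrow(pts)), box)
  # cutoff 15 captures the first shell (9) but not the second (15.59)
  nb <- neighbor_composition(list(fr), gm, cutoff = 15)
  expect_equal(nb$mean_count[nb$center_species == "DOPC"], 6)
  expect_equal(nb$percent[nb$center_species == "DOPC"], 100)
})

test_that("isolated lipids have empty neighborhoods", {
  gm <- point_group_map("DOPC")
  fr <- make_point_bilayer(rbind(c(10, 10), c(50, 50), c(90, 90)),
                           rep("DOPC", 3), c(120, 120, 100))
  nb <- neighbor_composition(list(fr), gm, cutoff = 15)
  expect_equal(nb$mean_count, 0)
})

test_that("random 65:35 mixtures have composition-like neighborhoods", {
  spec <- synthetic_spec(n_per_leaflet = 400, seed = 23)
  frames <- gen_leaflet_frames(spec, n_frames = 2)
  nb <- neighbor_composition(frames, synthetic_group_map())
  for (cs in c("DOPC", "DSPG")) {
    row <- nb[nb$center_species == cs, ]
    expect_equal(sum(row$percent), 100, tolerance = 1e-9)
    expect_lt(abs(row$percent[row$neighbor_species == "DOPC"] - 65), 4)
    expect_lt(abs(row$percent[row$neighbor_species == "DSPG"] - 35), 4)
  }
})
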