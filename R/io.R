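#' Read bilayer structures or trajectories into frames
#'
#' Supported formats: GROMACS `.gro` (fixed-column, nm; multi-frame
#' concatenation accepted), PDB (`MODEL`/`ENDMDL` multi-frame, parsed with
#' \pkg{bio3d}; box taken from the `CRYST1` record, which must be
#' orthorhombic), and the package's frames-table CSV dialect (one row per
#' site per frame, columns `frame,time_ns,mol,species,site,x,y,z,Lx,Ly,Lz`,
#' coordinates already in Angstrom).  All coordinates are returned in
#' Angstrom; GRO input is converted from nm on ingest.  Molecule indices
#' are renumbered consecutively within each frame.
#'
#' @param path input file path.
#' @param format one of "auto", "gro", "pdb", "frames".  "auto" dispatches
#'   on the file extension (`.gro`, `.pdb`, anything else is read as a
#'   frames table).
#' @return A list of [boxed_frame] objects, one per frame/model.
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb", "frames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb", "frames")
  }
  switch(format,
         gro = read_gro(path),
         pdb = read_pdb_frames(path),
         frames = read_frames_table(path))
}

# --- GRO ------------------------------------------------------------------

read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines))
      stop(sprintf("GRO parse error at line %d: truncated frame header", i))
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms <= 0L)
      stop(sprintf("GRO parse error at line %d: bad atom count '%s'",
                   i + 1L, trimws(lines[i + 1L])))
    if (i + 1L + natoms + 1L > length(lines))
      stop(sprintf("GRO parse error: frame starting at line %d is truncated", i))
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]
    resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
    resname <- trimws(substr(atom_lines, 6, 10))
    atname <- trimws(substr(atom_lines, 11, 15))
    x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      stop(sprintf("GRO parse error at line %d: malformed atom record",
                   i + 1L + bad[1]))
    box <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
    if (length(box) < 3L || any(is.na(box[1:3])))
      stop(sprintf("GRO parse error at line %d: missing or malformed box line",
                   i + 2L + natoms))
    if (length(box) > 3L && any(abs(box[4:length(box)]) > 1e-9))
      stop("triclinic GRO boxes are not supported; orthorhombic only")
    tm <- fidx
    m <- regmatches(title, regexpr("t=\\s*[0-9.eE+-]+", title))
    if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m)) / 1000  # ps -> ns
    mol <- match(resid, unique(resid))  # consecutive within frame
    frames[[length(frames) + 1L]] <- boxed_frame(
      coords = cbind(x, y, z) * 10,           # nm -> Angstrom
      site_species = resname,
      site_molecule = mol,
      site_name = atname,
      box = box[1:3] * 10,
      time = tm)
    fidx <- fidx + 1L
    i <- i + 2L + natoms + 1L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("no frames found in GRO file: ", path)
  frames
}

# --- PDB ------------------------------------------------------------------

read_pdb_frames <- function(path) {
  # box from CRYST1 (bio3d does not expose it)
  cl <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cl))
    stop("PDB file has no CRYST1 record; the box is required")
  abc <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33)))
  ang <- as.numeric(c(substr(cl[1], 34, 40), substr(cl[1], 41, 47),
                      substr(cl[1], 48, 54)))
  if (any(is.na(abc)))
    stop("malformed CRYST1 record in ", path)
  if (any(abs(ang - 90) > 1e-6))
    stop("triclinic PDB boxes are not supported; orthorhombic only")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nframes <- nrow(pdb$xyz)
  mol <- match(paste(at$chain, at$resno), unique(paste(at$chain, at$resno)))
  lapply(seq_len(nframes), function(f) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    boxed_frame(coords = xyz,
                site_species = at$resid,
                site_molecule = mol,
                site_name = at$elety,
                box = abc,
                time = f - 1L)
  })
}

# --- frames-table CSV -----------------------------------------------------

frames_table_cols <- c("frame", "time_ns", "mol", "species", "site",
                       "x", "y", "z", "Lx", "Ly", "Lz")

#' Read a frames-table CSV into frames
#'
#' @param path CSV with columns `frame,time_ns,mol,species,site,x,y,z,Lx,Ly,Lz`
#'   (coordinates and box in Angstrom).
#' @return A list of [boxed_frame] objects.
#' @export
read_frames_table <- function(path) {
  # na.strings = "": sodium ions are conventionally labeled "NA", which must
  # survive as a literal species string
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(frames_table_cols, names(df))
  if (length(missing))
    stop("frames table is missing column(s): ", paste(missing, collapse = ", "))
  lapply(split(df, df$frame), function(d) {
    boxed_frame(coords = cbind(d$x, d$y, d$z),
                site_species = d$species,
                site_molecule = match(d$mol, unique(d$mol)),
                site_name = d$site,
                box = c(d$Lx[1], d$Ly[1], d$Lz[1]),
                time = d$time_ns[1])
  })
}

#' Write frames to a frames-table CSV
#'
#' @param frames a list of [boxed_frame] objects (or a single frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames_table <- function(frames, path) {
  if (inherits(frames, "boxed_frame")) frames <- list(frames)
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    data.frame(frame = i - 1L, time_ns = fr$time, mol = fr$site_molecule,
               species = fr$site_species, site = fr$site_name,
               x = fr$coords[, 1], y = fr$coords[, 2], z = fr$coords[, 3],
               Lx = fr$box[1], Ly = fr$box[2], Lz = fr$box[3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- pressure record ------------------------------------------------------

#' Read a per-frame pressure-tensor record
#'
#' @param path CSV with columns `frame,Pxx_bar,Pyy_bar,Pzz_bar,Lz_A`.
#' @return A data frame with those columns.
#' @export
read_pressure_record <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "Pxx_bar", "Pyy_bar", "Pzz_bar", "Lz_A")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("pressure record is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}
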