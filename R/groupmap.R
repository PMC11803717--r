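#' Construct a group map for one or more species
#'
#' The group map assigns every site label of every lipid species to one of
#' the four lipid subunits (head, phosphate, glycol, tail), designates the
#' phosphorus reference site (the P atom in atomistic models, the PO4 bead
#' in coarse-grained ones) and the first tail-linker site (GL1), lists the
#' ordered carbon labels of the two acyl chains, and optionally carries
#' per-site partial charges and Lennard-Jones parameters for the energy
#' decomposition.  Monatomic ion species are marked with `ion = TRUE`.
#'
#' @param species named list; each element describes one species with fields
#'   `site_group` (named character vector mapping site label to one of
#'   "head", "phosphate", "glycol", "tail", "ion"), `phosphorus_site`,
#'   `gl1_site`, `chains` (list with ordered character vectors `SN1`, `SN2`,
#'   glycerol end first), `charges` (named numeric, e), `lj` (data frame with
#'   columns site, epsilon, sigma in kcal/mol and Angstrom), and logical
#'   `ion`.  All fields except `site_group` are optional for species that do
#'   not take part in a given analysis.
#' @return An object of class `group_map`.
#' @export
group_map <- function(species) {
  if (is.null(names(species)) || any(names(species) == ""))
    stop("species list must be named by species label")
  groups <- c("head", "phosphate", "glycol", "tail", "ion")
  for (sp in names(species)) {
    e <- species[[sp]]
    if (!is.null(e$site_group)) {
      sg <- unlist(e$site_group)
      if (is.null(names(sg))) stop("site_group must be named by site label")
      bad <- setdiff(unique(sg), groups)
      if (length(bad))
        stop(sprintf("species %s: unknown group(s): %s", sp,
                     paste(bad, collapse = ", ")))
      species[[sp]]$site_group <- sg
    }
    if (!is.null(e$chains)) {
      if (length(intersect(e$chains$SN1, e$chains$SN2)))
        stop(sprintf("species %s: SN1 and SN2 chains must be disjoint", sp))
    }
    if (is.null(e$ion)) species[[sp]]$ion <- FALSE
    if (!is.null(e$charges)) species[[sp]]$charges <- unlist(e$charges)
  }
  structure(species, class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  cat(sprintf("group_map: %d species (%s)\n", length(x),
              paste(names(x), collapse = ", ")))
  for (sp in names(x)) {
    e <- x[[sp]]
    if (isTRUE(e$ion)) {
      cat(sprintf("  %s: ion\n", sp))
    } else {
      cat(sprintf("  %s: %d sites, P site %s, GL1 site %s\n", sp,
                  length(e$site_group),
                  e$phosphorus_site %||% "-", e$gl1_site %||% "-"))
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a group map from a JSON or YAML configuration file
#'
#' The file is a mapping keyed by species label; each entry may contain
#' `site_group`, `phosphorus_site`, `gl1_site`, `chains` (with `SN1`, `SN2`),
#' `charges`, `lj` (mapping site label to `[epsilon, sigma]`), and `ion`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `group_map` object.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("group map file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (sp in names(raw)) {
    if (!is.null(raw[[sp]]$lj)) {
      lj <- raw[[sp]]$lj
      if (!is.data.frame(lj)) {
        lj <- data.frame(site = names(lj),
                         epsilon = vapply(lj, function(v) as.numeric(v[[1]]), 0),
                         sigma = vapply(lj, function(v) as.numeric(v[[2]]), 0),
                         row.names = NULL)
      }
      raw[[sp]]$lj <- lj
    }
  }
  group_map(raw)
}

#' Write a group map to JSON
#'
#' @param gmap a `group_map` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(gmap, path) {
  out <- lapply(unclass(gmap), function(e) {
    if (!is.null(e$site_group)) e$site_group <- as.list(e$site_group)
    if (!is.null(e$charges)) e$charges <- as.list(e$charges)
    if (!is.null(e$lj) && is.data.frame(e$lj)) {
      lj <- stats::setNames(
        lapply(seq_len(nrow(e$lj)), function(i) c(e$lj$epsilon[i], e$lj$sigma[i])),
        e$lj$site)
      e$lj <- lj
    }
    e
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# species labels in a frame that the group map treats as lipids
lipid_species <- function(gmap) {
  names(gmap)[!vapply(gmap, function(e) isTRUE(e$ion), logical(1))]
}

ion_species <- function(gmap) {
  names(gmap)[vapply(gmap, function(e) isTRUE(e$ion), logical(1))]
}
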