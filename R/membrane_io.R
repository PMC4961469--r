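#' Default residue/atom-name mapping for bead models
#'
#' Maps MARTINI-style residue names to species and atom names to bead
#' classes. Polar beads are written as `PO4` (phospholipids) or `ROH`
#' (cholesterol); aliphatic beads as `C1A`/`C2A` (`R1` for cholesterol).
#'
#' @return A list with `residues` (named character vector, residue name
#'   -> species) and `polar_atoms` (atom names classed as polar).
#' @export
default_bead_mapping <- function() {
  sp <- c("DPPC", "POPC", "DOPC", "DPPE", "POPE", "DOPE", "CHOL")
  list(residues = stats::setNames(sp, sp),
       polar_atoms = c("PO4", "ROH"))
}

atom_name_for <- function(bead_class, species, slot) {
  ifelse(bead_class == "polar",
         ifelse(species == "CHOL", "ROH", "PO4"),
         ifelse(species == "CHOL", "R1", paste0("C", slot, "A")))
}

config_meta_string <- function(config) {
  dims <- paste(names(config$dimensions), unlist(config$dimensions),
                sep = "=", collapse = " ")
  paste0("alpscan geometry=", config$geometry, " ", dims,
         " apl=", config$area_per_lipid,
         " h=", config$half_thickness)
}

parse_meta_string <- function(line) {
  if (!grepl("alpscan geometry=", line)) return(NULL)
  kv <- regmatches(line, gregexpr("[A-Za-z]+=[-0-9.A-Za-z]+", line))[[1]]
  vals <- sub("^[A-Za-z]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  out <- as.list(vals)
  for (f in setdiff(names(out), "geometry")) {
    out[[f]] <- as.numeric(out[[f]])
  }
  out
}

# per-lipid slot index (1, 2, ...) for aliphatic atom naming
bead_slots <- function(beads) {
  slot <- integer(nrow(beads))
  ali <- beads$bead_class == "aliphatic"
  slot[ali] <- stats::ave(rep(1L, sum(ali)), beads$lipid_id[ali],
                          FUN = seq_along)
  slot
}

#' Write a membrane configuration to GRO or PDB
#'
#' GRO files use the standard fixed-column format (coordinates in nm,
#' 0.001 nm precision) with the geometry metadata stored in the title
#' line; PDB files (0.001 Angstrom precision) carry the metadata in a
#' `REMARK 250` line and the leaflet in the chain identifier (`A` =
#' upper/outer, `B` = lower/inner).
#'
#' @param config A `membrane_config`.
#' @param path Output path.
#' @param format `"gro"` or `"pdb"`; guessed from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_configuration <- function(config, path, format = NULL) {
  stopifnot(inherits(config, "membrane_config"))
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(tolower(format), c("gro", "pdb"))
  b <- config$beads
  slot <- bead_slots(b)
  anames <- atom_name_for(b$bead_class, b$species, slot)
  n <- nrow(b)
  if (format == "gro") {
    lines <- c(config_meta_string(config), sprintf("%5d", n))
    if (n > 0) {
      lines <- c(lines, sprintf(
        "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
        b$lipid_id %% 100000L, b$species, anames,
        seq_len(n) %% 100000L, b$x / 10, b$y / 10, b$z / 10))
    }
    box <- switch(config$geometry,
      flat = c(config$dimensions$Lx, config$dimensions$Ly,
               4 * config$half_thickness),
      sphere = rep(2 * (config$dimensions$radius +
                          config$half_thickness) + 20, 3),
      cylinder = c(rep(2 * (config$dimensions$radius +
                              config$half_thickness) + 20, 2),
                   config$dimensions$length))
    lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1] / 10,
                              box[2] / 10, box[3] / 10))
  } else {
    chain <- ifelse(b$leaflet %in% c("upper", "outer"), "A", "B")
    lines <- c(paste0("REMARK 250 ", config_meta_string(config)))
    if (n > 0) {
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        seq_len(n) %% 100000L, anames, b$species, chain,
        b$lipid_id %% 10000L, b$x, b$y, b$z, 1, 0))
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a membrane configuration from GRO or PDB
#'
#' PDB files are parsed with [bio3d::read.pdb()]; GRO files with the
#' fixed-column convention (velocities, when present, are ignored).
#' Species and bead classes are recovered through `mapping`; unknown
#' residue names are rejected with a message listing the offenders.
#' Leaflet labels are reconstructed geometrically (flat: side of the
#' mid-plane; sphere/cylinder: radial distance against the mid-gap),
#' which reproduces the labels alpscan writes; geometry and dimensions
#' are taken from the metadata line written by [write_configuration()]
#' unless supplied explicitly.
#'
#' @param path Input file.
#' @param format `"gro"` or `"pdb"`; guessed from the extension.
#' @param mapping Residue/atom mapping, see [default_bead_mapping()].
#' @param geometry,dimensions,area_per_lipid,half_thickness Optional
#'   overrides for files lacking alpscan metadata.
#' @return A `membrane_config`.
#' @export
read_configuration <- function(path, format = NULL,
                               mapping = default_bead_mapping(),
                               geometry = NULL, dimensions = NULL,
                               area_per_lipid = NULL,
                               half_thickness = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("gro", "pdb"))
  if (format == "gro") {
    lines <- readLines(path)
    if (length(lines) < 2) stop("empty or truncated GRO file: ", path)
    meta <- parse_meta_string(lines[1])
    natoms <- suppressWarnings(as.integer(trimws(lines[2])))
    if (is.na(natoms)) stop("malformed GRO atom count line")
    if (length(lines) < 2 + natoms + 1) stop("truncated GRO file: ", path)
    al <- lines[2 + seq_len(natoms)]
    resid <- trimws(substr(al, 6, 10))
    aname <- trimws(substr(al, 11, 15))
    resnum <- as.integer(trimws(substr(al, 1, 5)))
    x <- as.numeric(substr(al, 21, 28)) * 10
    y <- as.numeric(substr(al, 29, 36)) * 10
    z <- as.numeric(substr(al, 37, 44)) * 10
    chain <- rep(NA_character_, natoms)
  } else {
    pdb <- bio3d::read.pdb(path)
    meta <- NULL
    for (ln in attr(pdb, "remark50") %||% character(0)) {
      m <- parse_meta_string(ln)
      if (!is.null(m)) meta <- m
    }
    if (is.null(meta)) {
      raw <- readLines(path)
      rem <- grep("^REMARK", raw, value = TRUE)
      for (ln in rem) {
        m <- parse_meta_string(ln)
        if (!is.null(m)) { meta <- m; break }
      }
    }
    a <- pdb$atom
    if (nrow(a) == 0) stop("empty PDB file: ", path)
    resid <- a$resid
    aname <- a$elety
    resnum <- a$resno
    x <- a$x; y <- a$y; z <- a$z
    chain <- a$chain
  }
  unknown <- setdiff(unique(resid), names(mapping$residues))
  if (length(unknown) > 0) {
    stop("unmapped residue name(s): ", paste(unknown, collapse = ", "))
  }
  species <- unname(mapping$residues[resid])
  bead_class <- ifelse(aname %in% mapping$polar_atoms,
                       "polar", "aliphatic")
  geometry <- geometry %||% meta$geometry
  if (is.null(geometry)) {
    stop("geometry not found in file metadata; pass `geometry` explicitly")
  }
  area_per_lipid <- area_per_lipid %||% meta$apl %||% 70
  half_thickness <- half_thickness %||% meta$h %||% 20
  dims <- dimensions %||% switch(geometry,
    flat = list(Lx = meta$Lx, Ly = meta$Ly),
    sphere = list(radius = meta$radius),
    cylinder = list(radius = meta$radius, length = meta$length))
  if (is.null(dims) || any(vapply(dims, is.null, logical(1)))) {
    stop("dimensions not found in file metadata; pass `dimensions`")
  }
  # leaflet reconstruction
  leaflet <- if (!all(is.na(chain))) {
    ifelse(chain == "A",
           if (geometry == "flat") "upper" else "outer",
           if (geometry == "flat") "lower" else "inner")
  } else if (geometry == "flat") {
    ifelse(z >= 0, "upper", "lower")
  } else if (geometry == "sphere") {
    r <- sqrt(x^2 + y^2 + z^2)
    ifelse(r >= dims$radius, "outer", "inner")
  } else {
    r <- sqrt(x^2 + y^2)
    ifelse(r >= dims$radius, "outer", "inner")
  }
  comp_cr <- stats::setNames(
    ifelse(species == "CHOL", 4.5, 6.0), NULL)
  beads <- data.frame(x = x, y = y, z = z, bead_class = bead_class,
                      species = species, leaflet = leaflet,
                      lipid_id = resnum,
                      cover_radius = ifelse(bead_class == "polar",
                                            comp_cr, NA_real_),
                      stringsAsFactors = FALSE)
  new_membrane_config(geometry, dims, beads, area_per_lipid,
                      half_thickness)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
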