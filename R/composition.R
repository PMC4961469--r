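#' Lipid species and bilayer composition
#'
#' A composition is a table of coarse-grained lipid species, one row per
#' species, with a mole fraction and the radius of the interfacial
#' occlusion disc its polar bead carries. Species are classified by
#' headgroup (`"PC"`, `"PE"` or `"sterol"`) and acyl-chain profile
#' (`"di-saturated"` 16:0-16:0, `"mixed"` 16:0-18:1, `"di-monounsaturated"`
#' 18:1-18:1, or `"none"` for sterols).
#'
#' @param name Character vector of species names (e.g. `"POPC"`).
#' @param headgroup One of `"PC"`, `"PE"`, `"sterol"` per species.
#' @param chains Chain profile per species; sterols must use `"none"`.
#' @param fraction Mole fractions; must be non-negative and sum to 1
#'   within 1e-9.
#' @param cover_radius Radius (Angstrom) of the interfacial occlusion disc
#'   of each species' polar bead. Defaults to 6.0 for phospholipids
#'   (the in-plane footprint of the stacked headgroup + glycerol + upper
#'   chain beads, sized so that a defect-free flat bilayer at 70
#'   Angstrom^2 per lipid is almost fully covered, as real flat bilayers
#'   are) and 4.5 for sterols, whose hydroxyl sits lower in the
#'   interface.
#' @return An object of class `lipid_composition` (a data frame).
#' @examples
#' copi_composition()
#' @export
lipid_composition <- function(name, headgroup, chains, fraction,
                              cover_radius = NULL) {
  headgroup <- match.arg(headgroup, c("PC", "PE", "sterol"),
                         several.ok = TRUE)
  chains <- match.arg(chains,
                      c("di-saturated", "mixed", "di-monounsaturated",
                        "none"), several.ok = TRUE)
  n <- length(name)
  if (length(headgroup) != n || length(chains) != n ||
      length(fraction) != n) {
    stop("name, headgroup, chains and fraction must have equal length")
  }
  if (any(fraction < 0)) stop("mole fractions must be non-negative")
  if (abs(sum(fraction) - 1) > 1e-9) {
    stop("mole fractions must sum to 1 (got ", sum(fraction), ")")
  }
  if (any((headgroup == "sterol") != (chains == "none"))) {
    stop("sterol species (and only sterol species) must have chains = 'none'")
  }
  if (is.null(cover_radius)) {
    cover_radius <- ifelse(headgroup == "sterol", 4.5, 6.0)
  }
  if (any(cover_radius <= 0)) stop("cover_radius must be > 0")
  out <- data.frame(name = as.character(name), headgroup = headgroup,
                    chains = chains, fraction = fraction,
                    cover_radius = cover_radius,
                    stringsAsFactors = FALSE)
  class(out) <- c("lipid_composition", "data.frame")
  out
}

#' COPI-like cis-Golgi bilayer composition
#'
#' Built-in composition used for the model cis-Golgi membranes: 60 mol%
#' PC, 30 mol% PE and 10 mol% cholesterol, with the PC/PE acyl chains
#' split 6% di-saturated (16:0-16:0), 59% mixed (16:0-18:1) and 35%
#' di-monounsaturated (18:1-18:1), matching the lipidomics of COPI
#' vesicles.
#'
#' @param cover_radius_phospholipid,cover_radius_sterol Occlusion disc
#'   radii (Angstrom).
#' @return A [lipid_composition()].
#' @export
copi_composition <- function(cover_radius_phospholipid = 6.0,
                             cover_radius_sterol = 4.5) {
  head_frac <- c(PC = 0.60, PE = 0.30)
  chain_frac <- c("di-saturated" = 0.06, "mixed" = 0.59,
                  "di-monounsaturated" = 0.35)
  nm <- c(DPPC = "PC", POPC = "PC", DOPC = "PC",
          DPPE = "PE", POPE = "PE", DOPE = "PE")
  ch <- rep(names(chain_frac), 2)
  frac <- as.numeric(head_frac[nm] * chain_frac[ch])
  lipid_composition(
    name = c(names(nm), "CHOL"),
    headgroup = c(unname(nm), "sterol"),
    chains = c(ch, "none"),
    fraction = c(frac, 0.10),
    cover_radius = c(rep(cover_radius_phospholipid, 6),
                     cover_radius_sterol))
}

#' Read a composition from a YAML or JSON file
#'
#' The file must contain a `species` list whose entries carry `name`,
#' `headgroup`, `chains` and `fraction` (and optionally `cover_radius`).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [lipid_composition()].
#' @export
composition_from_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  sp <- raw$species
  if (is.null(sp)) stop("composition file must contain a 'species' list")
  get <- function(field, default = NULL) {
    vals <- lapply(sp, `[[`, field)
    if (any(vapply(vals, is.null, logical(1)))) {
      if (is.null(default)) stop("species entry missing field '", field, "'")
      return(default)
    }
    unlist(vals)
  }
  lipid_composition(name = get("name"), headgroup = get("headgroup"),
                    chains = get("chains"),
                    fraction = as.numeric(get("fraction")),
                    cover_radius = {
                      cr <- lapply(sp, `[[`, "cover_radius")
                      if (all(vapply(cr, is.null, logical(1)))) NULL
                      else as.numeric(unlist(cr))
                    })
}

#' @export
print.lipid_composition <- function(x, ...) {
  cat("Lipid composition (", nrow(x), " species)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Chain-profile fractions of a composition
#'
#' Mole fractions of the acyl-chain profiles among the phospholipid
#' (PC + PE) species, renormalized to sum to 1.
#'
#' @param comp A [lipid_composition()].
#' @return Named numeric vector over chain profiles.
#' @export
chain_fractions <- function(comp) {
  stopifnot(inherits(comp, "lipid_composition"))
  pl <- comp[comp$headgroup != "sterol", ]
  tot <- sum(pl$fraction)
  if (tot == 0) return(stats::setNames(numeric(0), character(0)))
  c(tapply(pl$fraction, pl$chains, sum) / tot)
}
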