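#' Calibration parameters for liposome-capture counting
#'
#' Bundles the scalars that convert a Golgi-region fluorescence signal
#' into a captured-liposome count: the fluorescence-to-concentration
#' conversion factor `k` (fluorescence units per micromolar lipid,
#' default 100, from imaging liposome suspensions of known
#' concentration), the Golgi-region volume `V` (litres, default 3e-13,
#' an order-of-magnitude estimate of a 10 x 10 x 3 micrometre region),
#' the area per lipid `s` (nm^2, default 0.7), and the Avogadro
#' constant. Because `V` is an order-of-magnitude estimate, any count
#' derived from it inherits that uncertainty; the result object carries
#' a provenance note saying so.
#'
#' @param k Fluorescence units per micromolar lipid (> 0).
#' @param V Golgi-region volume in litres (> 0).
#' @param s Area per lipid in nm^2 (> 0).
#' @param N_av Avogadro constant (mol^-1).
#' @return A `calibration_params` list.
#' @export
calibration_params <- function(k = 100, V = 3e-13, s = 0.7,
                               N_av = 6.02214076e23) {
  if (any(c(k, V, s, N_av) <= 0)) {
    stop("all calibration parameters must be strictly positive")
  }
  structure(list(k = k, V = V, s = s, N_av = N_av),
            class = "calibration_params")
}

#' Convert fluorescence to lipid concentration
#'
#' `C = F / k`, using the linear fluorescence-concentration calibration.
#'
#' @param F_signal Mean fluorescence intensity (FU, >= 0).
#' @param k Conversion factor (FU per micromolar, > 0).
#' @return Lipid concentration in micromolar.
#' @export
fluorescence_to_concentration <- function(F_signal, k = 100) {
  if (k <= 0) stop("k must be > 0")
  if (any(F_signal < 0)) stop("fluorescence must be >= 0")
  F_signal / k
}

#' Number of lipids in a volume
#'
#' `count = C * 1e-6 * V * N_av` for a concentration `C` in micromolar
#' and a volume `V` in litres.
#'
#' @param C Lipid concentration (micromolar, >= 0).
#' @param V Volume (litres, >= 0).
#' @param N_av Avogadro constant.
#' @return Lipid count.
#' @export
lipids_in_volume <- function(C, V = 3e-13, N_av = 6.02214076e23) {
  if (any(C < 0) || V < 0) stop("C and V must be >= 0")
  C * 1e-6 * V * N_av
}

#' Number of lipids in a liposome
#'
#' Both-leaflet equal-radius approximation `2 * 4 * pi * R^2 / s`; an
#' optional refinement uses the true inner-leaflet radius
#' `R - bilayer_thickness`, giving `4 * pi * (R^2 + R_in^2) / s`.
#'
#' @param R Liposome radius (nm, > 0).
#' @param s Area per lipid (nm^2, > 0).
#' @param bilayer_thickness Optional bilayer thickness (nm); when
#'   supplied, the inner leaflet is counted at `R - bilayer_thickness`.
#' @return Lipid count.
#' @export
lipids_per_liposome <- function(R, s = 0.7, bilayer_thickness = NULL) {
  if (R <= 0 || s <= 0) stop("R and s must be > 0")
  if (is.null(bilayer_thickness)) {
    2 * 4 * pi * R^2 / s
  } else {
    R_in <- R - bilayer_thickness
    if (R_in <= 0) stop("bilayer_thickness must be smaller than R")
    4 * pi * (R^2 + R_in^2) / s
  }
}

#' Captured-liposome count from Golgi fluorescence
#'
#' Chains the calibration: fluorescence -> concentration (`F/k`) ->
#' lipid count in the Golgi volume (`C * V * N_av`) -> number of
#' liposomes (divide by lipids per liposome of radius `R`).
#' `rounding = "paper"` reproduces the printed back-of-envelope
#' arithmetic by rounding the lipid count to two significant figures
#' and the per-liposome count to one (3e4 for R = 30 nm, s = 0.7 nm^2)
#' before dividing, so that F = 2000 and 5000 FU give 120 and 300
#' liposomes; `rounding = "exact"` keeps full precision throughout
#' (112 and 280 for the same inputs).
#'
#' @param F_signal Golgi-region fluorescence (FU).
#' @param params A [calibration_params()].
#' @param R Liposome radius (nm).
#' @param rounding `"paper"` or `"exact"`.
#' @return A `capture_count` list with the final `count` and all
#'   intermediates (`concentration_uM`, `n_lipids`,
#'   `lipids_per_liposome`, plus their rounded forms under paper
#'   rounding) and a `provenance` note on the volume estimate.
#' @export
captured_liposome_count <- function(F_signal,
                                    params = calibration_params(),
                                    R = 30,
                                    rounding = c("paper", "exact")) {
  stopifnot(inherits(params, "calibration_params"))
  rounding <- match.arg(rounding)
  C <- fluorescence_to_concentration(F_signal, params$k)
  n_lip <- lipids_in_volume(C, params$V, params$N_av)
  per_lipo <- lipids_per_liposome(R, params$s)
  if (rounding == "paper") {
    n_lip_r <- signif(n_lip, 2)
    per_lipo_r <- signif(per_lipo, 1)
    count <- round(n_lip_r / per_lipo_r)
  } else {
    n_lip_r <- n_lip
    per_lipo_r <- per_lipo
    count <- n_lip / per_lipo
  }
  structure(list(count = count, concentration_uM = C,
                 n_lipids = n_lip, n_lipids_used = n_lip_r,
                 lipids_per_liposome = per_lipo,
                 lipids_per_liposome_used = per_lipo_r,
                 R = R, rounding = rounding, params = params,
                 provenance = paste(
                   "Golgi volume V is an order-of-magnitude estimate;",
                   "the liposome count inherits this uncertainty")),
            class = "capture_count")
}

#' @export
print.capture_count <- function(x, ...) {
  cat("Captured liposomes: ", signif(x$count, 4), " (rounding = ",
      x$rounding, ")\n", sep = "")
  cat("  C = ", x$concentration_uM, " uM -> ", signif(x$n_lipids, 4),
      " lipids; ", signif(x$lipids_per_liposome, 5),
      " lipids per liposome (R = ", x$R, " nm)\n", sep = "")
  cat("  note: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Liposome preparation metadata
#'
#' Records how a liposome suspension was produced (sequential extrusion
#' through a polycarbonate filter of pore diameter 200, 100, 50 or
#' 30 nm, or tip sonication) together with its measured hydrodynamic
#' radius. The nominal pore radius is metadata only; all geometry
#' calculations use the measured `Rh`.
#'
#' @param method `"extrusion"` or `"sonication"`.
#' @param Rh Hydrodynamic radius from dynamic light scattering (nm,
#'   > 0).
#' @param filter_pore_diameter Pore diameter (nm); required for
#'   extrusion, one of 200, 100, 50, 30.
#' @return A `liposome_prep` list.
#' @export
liposome_prep <- function(method = c("extrusion", "sonication"), Rh,
                          filter_pore_diameter = NULL) {
  method <- match.arg(method)
  if (Rh <= 0) stop("Rh must be > 0")
  if (method == "extrusion") {
    if (is.null(filter_pore_diameter) ||
        !filter_pore_diameter %in% c(200, 100, 50, 30)) {
      stop("extrusion requires filter_pore_diameter in ",
           "{200, 100, 50, 30} nm")
    }
  } else if (!is.null(filter_pore_diameter)) {
    stop("sonicated preparations take no filter pore size")
  }
  structure(list(method = method, Rh = Rh,
                 filter_pore_diameter = filter_pore_diameter),
            class = "liposome_prep")
}
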