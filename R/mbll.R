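#' Optical channel geometry
#'
#' Describes a continuous-wave NIRS channel: the two emitter wavelengths, the
#' source-detector separation and the participant age (which sets the
#' differential pathlength factor). The conventional deep configuration uses a
#' 4 cm separation (banana-shaped path sampling visual cortex); the shallow
#' configuration uses 1 cm (extracranial tissue only).
#'
#' @param wavelengths_nm numeric pair of distinct centre wavelengths (nm).
#' @param separation_cm source-detector distance in cm (> 0).
#' @param age_years participant age in years (>= 0).
#' @return an object of class `optical_geometry`.
#' @export
#' @examples
#' optical_geometry()                      # deep, 4 cm
#' optical_geometry(separation_cm = 1)     # shallow, 1 cm
optical_geometry <- function(wavelengths_nm = c(764, 859),
                             separation_cm = 4.0,
                             age_years = 25) {
  stopifnot(length(wavelengths_nm) == 2, is.numeric(wavelengths_nm))
  if (wavelengths_nm[1] == wavelengths_nm[2])
    stop("wavelengths must be distinct")
  stopifnot(is.numeric(separation_cm), length(separation_cm) == 1,
            separation_cm > 0)
  stopifnot(is.numeric(age_years), length(age_years) == 1, age_years >= 0)
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         separation_cm = as.numeric(separation_cm),
         age_years = as.numeric(age_years)),
    class = "optical_geometry")
}

#' Specific extinction coefficient table
#'
#' Loads a wavelength-indexed table of decadic molar extinction coefficients
#' for oxy- and deoxyhaemoglobin and converts them to per-cm per-microMolar
#' units. The shipped default is an approximate compilation (see the file
#' header for provenance); any CSV with columns
#' `wavelength_nm,eps_o2hb_cm1_M1,eps_hhb_cm1_M1` can be substituted.
#'
#' @param path CSV file; default is the table shipped with the package.
#' @return an object of class `extinction_table` with a `citation` attribute.
#' @export
extinction_table <- function(path = system.file("extdata",
                                                "extinction_coefficients.csv",
                                                package = "nirsbp")) {
  tab <- read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "eps_o2hb_cm1_M1", "eps_hhb_cm1_M1")
  if (!all(need %in% names(tab)))
    stop("extinction table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$eps_o2hb_cm1_M1 <= 0) || any(tab$eps_hhb_cm1_M1 <= 0))
    stop("all extinction coefficients must be positive")
  tab <- tab[order(tab$wavelength_nm), ]
  structure(tab, class = c("extinction_table", "data.frame"),
            citation = readLines(path, n = 1))
}

#' Extinction coefficients at a wavelength
#'
#' Linear interpolation of the table to the requested wavelength, in
#' cm^-1 uM^-1 (decadic).
#'
#' @param ext an [extinction_table()].
#' @param wavelength_nm wavelength(s) within the tabulated range.
#' @return matrix with one row per wavelength, columns `o2hb`, `hhb`.
#' @export
extinction_at <- function(ext, wavelength_nm) {
  rng <- range(ext$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop(sprintf("wavelength outside tabulated range [%g, %g] nm",
                 rng[1], rng[2]))
  o2 <- approx(ext$wavelength_nm, ext$eps_o2hb_cm1_M1, xout = wavelength_nm)$y
  hh <- approx(ext$wavelength_nm, ext$eps_hhb_cm1_M1, xout = wavelength_nm)$y
  cbind(o2hb = o2 * 1e-6, hhb = hh * 1e-6)  # cm^-1 M^-1 -> cm^-1 uM^-1
}

#' Differential pathlength factor model
#'
#' Loads per-wavelength coefficients of the age-dependence form
#' `DPF(age) = a + b * age^c`. The shipped default carries the published
#' cranial coefficients plus derived rows at 764 and 859 nm (see file header).
#'
#' @param path CSV with columns `wavelength_nm,a,b,c`.
#' @return an object of class `dpf_model`.
#' @export
dpf_model <- function(path = system.file("extdata", "dpf_duncan.csv",
                                         package = "nirsbp")) {
  tab <- read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "a", "b", "c")
  if (!all(need %in% names(tab)))
    stop("DPF model must have columns: ", paste(need, collapse = ", "))
  if (any(tab$a <= 0)) stop("DPF intercept a must be positive")
  structure(tab, class = c("dpf_model", "data.frame"),
            citation = readLines(path, n = 1))
}

#' Differential pathlength factor at a given age and wavelength
#'
#' Evaluates `DPF(age) = a + b * age^c` with the coefficients stored for that
#' wavelength. The DPF converts the geometric source-detector distance into
#' the effective (scattering-lengthened) photon path.
#'
#' @param age_years age in years (>= 0).
#' @param wavelength_nm a wavelength present in the model table (0.5 nm
#'   matching tolerance).
#' @param model a [dpf_model()].
#' @return dimensionless pathlength factor.
#' @export
#' @examples
#' dpf(25, 764)
dpf <- function(age_years, wavelength_nm, model = dpf_model()) {
  stopifnot(all(age_years >= 0))
  i <- which(abs(model$wavelength_nm - wavelength_nm) < 0.5)
  if (length(i) != 1)
    stop(sprintf(
      "no DPF coefficients for %g nm; available wavelengths: %s",
      wavelength_nm, paste(model$wavelength_nm, collapse = ", ")))
  model$a[i] + model$b[i] * age_years^model$c[i]
}

# 2x2 extinction matrix for a geometry; rows = wavelengths, cols = (o2hb, hhb)
extinction_matrix <- function(ext, wavelengths_nm, cond_limit = 1e6) {
  E <- extinction_at(ext, wavelengths_nm)
  if (!is.finite(kappa(E)) || kappa(E) > cond_limit)
    stop(sprintf(
      "extinction matrix is singular/ill-conditioned at wavelengths %g/%g nm",
      wavelengths_nm[1], wavelengths_nm[2]))
  E
}

#' Raw two-wavelength optical recording
#'
#' Container for optical-density change traces (dimensionless decadic
#' attenuation change) of one or more channels sharing a geometry.
#'
#' @param time_s uniformly sampled time axis (s).
#' @param od data.frame with columns `<channel>_od_w1`, `<channel>_od_w2`.
#' @param geometry an [optical_geometry()].
#' @param channels channel labels; default derived from `od` column names.
#' @return object of class `raw_optical_recording`.
#' @export
raw_optical_recording <- function(time_s, od, geometry,
                                  channels = NULL) {
  stopifnot(inherits(geometry, "optical_geometry"))
  od <- as.data.frame(od)
  if (is.null(channels))
    channels <- unique(sub("_od_w[12]$", "", names(od)))
  for (ch in channels) {
    for (w in c("_od_w1", "_od_w2")) {
      cl <- paste0(ch, w)
      if (!cl %in% names(od)) stop("missing OD column: ", cl)
      if (length(od[[cl]]) != length(time_s))
        stop("OD column length mismatch: ", cl)
    }
  }
  check_uniform_time(time_s)
  structure(list(time_s = time_s, od = od, geometry = geometry,
                 channels = channels),
            class = "raw_optical_recording")
}

#' Chromophore concentration recording
#'
#' Oxy-/deoxyhaemoglobin concentration change traces in uM, on the same
#' sampling grid as the optical recording they derive from.
#'
#' @param time_s time axis (s).
#' @param conc data.frame with columns `<channel>_o2hb`, `<channel>_hhb` (uM).
#' @param geometry the source [optical_geometry()] (optional, carried along).
#' @param channels channel labels.
#' @return object of class `chromophore_recording`.
#' @export
chromophore_recording <- function(time_s, conc, geometry = NULL,
                                  channels = NULL) {
  conc <- as.data.frame(conc)
  if (is.null(channels))
    channels <- unique(sub("_(o2hb|hhb)$", "", names(conc)))
  for (ch in channels) {
    for (w in c("_o2hb", "_hhb")) {
      cl <- paste0(ch, w)
      if (!cl %in% names(conc)) stop("missing concentration column: ", cl)
      if (length(conc[[cl]]) != length(time_s))
        stop("concentration column length mismatch: ", cl)
    }
  }
  check_uniform_time(time_s)
  structure(list(time_s = time_s, conc = conc, geometry = geometry,
                 channels = channels),
            class = "chromophore_recording")
}

check_uniform_time <- function(time_s, tol = 1e-6) {
  if (length(time_s) > 2) {
    dt <- diff(time_s)
    if (max(abs(dt - dt[1])) > tol)
      stop("time axis is not uniformly sampled (tolerance 1e-6 s)")
  }
  invisible(TRUE)
}

#' Optical densities to chromophore concentrations (modified Beer-Lambert law)
#'
#' Per sample, solves the 2x2 linear system
#' `dOD(lambda_i) = (eps_o2hb(lambda_i) * dC_o2hb + eps_hhb(lambda_i) * dC_hhb)
#'  * d * DPF(lambda_i, age)`
#' for the concentration changes (uM), where `d` is the source-detector
#' separation (cm) and DPF the age- and wavelength-dependent differential
#' pathlength factor.
#'
#' @param raw a [raw_optical_recording()].
#' @param ext an [extinction_table()].
#' @param dpfm a [dpf_model()].
#' @return a [chromophore_recording()].
#' @export
od_to_conc <- function(raw, ext = extinction_table(), dpfm = dpf_model()) {
  stopifnot(inherits(raw, "raw_optical_recording"))
  g <- raw$geometry
  E <- extinction_matrix(ext, g$wavelengths_nm)
  D <- vapply(g$wavelengths_nm, function(wl) dpf(g$age_years, wl, dpfm),
              numeric(1))
  Einv <- solve(E)
  conc <- list()
  for (ch in raw$channels) {
    od1 <- raw$od[[paste0(ch, "_od_w1")]] / (g$separation_cm * D[1])
    od2 <- raw$od[[paste0(ch, "_od_w2")]] / (g$separation_cm * D[2])
    C <- Einv %*% rbind(od1, od2)
    conc[[paste0(ch, "_o2hb")]] <- C[1, ]
    conc[[paste0(ch, "_hhb")]] <- C[2, ]
  }
  chromophore_recording(raw$time_s, as.data.frame(conc), geometry = g,
                        channels = raw$channels)
}

#' Chromophore concentrations to optical densities (forward model)
#'
#' Exact algebraic inverse of [od_to_conc()]; used by the synthetic generator
#' to emit the raw two-wavelength optical densities a continuous-wave device
#' would record for known concentration traces.
#'
#' @param conc a [chromophore_recording()] with a geometry attached.
#' @param ext an [extinction_table()].
#' @param dpfm a [dpf_model()].
#' @param geometry optional [optical_geometry()] overriding `conc$geometry`.
#' @return a [raw_optical_recording()].
#' @export
conc_to_od <- function(conc, ext = extinction_table(), dpfm = dpf_model(),
                       geometry = NULL) {
  stopifnot(inherits(conc, "chromophore_recording"))
  g <- if (is.null(geometry)) conc$geometry else geometry
  if (is.null(g)) stop("a geometry is required for the forward model")
  E <- extinction_matrix(ext, g$wavelengths_nm)
  D <- vapply(g$wavelengths_nm, function(wl) dpf(g$age_years, wl, dpfm),
              numeric(1))
  od <- list()
  for (ch in conc$channels) {
    C <- rbind(conc$conc[[paste0(ch, "_o2hb")]],
               conc$conc[[paste0(ch, "_hhb")]])
    OD <- E %*% C
    od[[paste0(ch, "_od_w1")]] <- OD[1, ] * g$separation_cm * D[1]
    od[[paste0(ch, "_od_w2")]] <- OD[2, ] * g$separation_cm * D[2]
  }
  raw_optical_recording(conc$time_s, as.data.frame(od), geometry = g,
                        channels = conc$channels)
}
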