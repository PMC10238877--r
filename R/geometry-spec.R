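# Parametric description of a (possibly stenosed) carotid bifurcation lumen.
# Coordinate convention: the CCA axis is +z with the bifurcation apex at the
# origin; the ICA branches toward +x, the ECA toward -x; all lengths in mm.

#' Parametric carotid bifurcation specification
#'
#' Radii, segment lengths and branch angles of an idealized carotid
#' bifurcation. This is the synthetic stand-in for a segmented patient lumen.
#'
#' @param r_cca,r_ica,r_eca Lumen radii (mm). Branch radii may not exceed the
#'   CCA radius.
#' @param len_cca,len_ica,len_eca Segment lengths (mm), measured along the CCA
#'   axis (CCA) or along the branch centerline from the bifurcation (ICA/ECA).
#'   Defaults follow the usual imaging extents: about 5 cm of CCA and ECA; the
#'   ICA is followed somewhat further toward the skull base (60 mm default,
#'   a convention of this package).
#' @param angle_ica,angle_eca Branch angles from the CCA axis (degrees),
#'   strictly between 0 and 90.
#' @return An object of class `bifurcation_spec`.
#' @export
bifurcation_spec <- function(r_cca = 3.5, r_ica = 2.5, r_eca = 2.0,
                             len_cca = 50, len_ica = 60, len_eca = 50,
                             angle_ica = 25, angle_eca = 25) {
  for (nm in c("r_cca", "r_ica", "r_eca", "len_cca", "len_ica", "len_eca",
               "angle_ica", "angle_eca")) {
    v <- get(nm)
    abort_if(!is_number(v) || v <= 0, paste0("`", nm, "` must be a positive number"))
  }
  abort_if(r_ica > r_cca, "`r_ica` must not exceed `r_cca`")
  abort_if(r_eca > r_cca, "`r_eca` must not exceed `r_cca`")
  abort_if(angle_ica >= 90 || angle_eca >= 90,
           "branch angles must lie strictly between 0 and 90 degrees")
  structure(list(r_cca = r_cca, r_ica = r_ica, r_eca = r_eca,
                 len_cca = len_cca, len_ica = len_ica, len_eca = len_eca,
                 angle_ica = angle_ica, angle_eca = angle_eca),
            class = "bifurcation_spec")
}

#' Stenosis specification
#'
#' Axisymmetric lumen narrowing on one branch, placed by arclength along the
#' branch centerline and graded by NASCET percent diameter reduction relative
#' to the branch's distal (normal) diameter.
#'
#' @param branch One of `"cca"`, `"ica"`, `"eca"`.
#' @param degree_nascet Percent diameter reduction, in `[0, 100)`. Total
#'   occlusion (100%) is excluded.
#' @param center_s Arclength position of the stenosis center along the branch
#'   (mm; for branches, measured from the bifurcation apex).
#' @param length Stenosis length (mm), positive.
#' @param profile Lumen narrowing shape: `"cosine"` (smooth cosine-squared
#'   bump, the default) or `"gaussian"`.
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(branch = c("ica", "eca", "cca"), degree_nascet,
                          center_s, length = 10,
                          profile = c("cosine", "gaussian")) {
  branch <- match.arg(branch)
  profile <- match.arg(profile)
  abort_if(!is_number(degree_nascet) || degree_nascet < 0,
           "`degree_nascet` must be a number in [0, 100)")
  abort_if(degree_nascet >= 100,
           "degree_nascet >= 100 (occlusion) is excluded from the model")
  abort_if(!is_number(center_s), "`center_s` must be a number (mm)")
  abort_if(!is_number(length) || length <= 0, "`length` must be positive (mm)")
  structure(list(branch = branch, degree_nascet = degree_nascet,
                 center_s = center_s, length = length, profile = profile),
            class = "stenosis_spec")
}

# Multiplicative diameter factor of a stenosis at arclength s (vectorized).
stenosis_scale <- function(sten, s) {
  d <- sten$degree_nascet / 100
  u <- (s - sten$center_s) / sten$length
  inside <- abs(u) <= 0.5
  k <- rep(1, length(s))
  if (sten$profile == "cosine") {
    k[inside] <- 1 - d * cos(pi * u[inside])^2
  } else {
    sigma <- 1 / 6  # support truncated at +-3 sigma
    k[inside] <- 1 - d * exp(-0.5 * (u[inside] / sigma)^2)
  }
  k
}

#' NASCET degree of stenosis
#'
#' Percent diameter reduction `100 * (1 - d_min / d_distal)` of the minimal
#' stenotic lumen diameter relative to the normal distal ICA diameter.
#'
#' @param d_min Minimal lumen diameter in the stenosis (mm).
#' @param d_distal_ica Normal distal ICA diameter (mm), positive.
#' @return Degree of stenosis (percent).
#' @export
nascet_degree <- function(d_min, d_distal_ica) {
  abort_if(!all(is.finite(d_min)) || any(d_min < 0), "`d_min` must be non-negative")
  abort_if(!is_number(d_distal_ica) || d_distal_ica <= 0,
           "`d_distal_ica` must be positive")
  abort_if(any(d_min > d_distal_ica * (1 + 1e-12)),
           "`d_min` exceeds the distal reference diameter (negative degree)")
  100 * (1 - d_min / d_distal_ica)
}

#' Classify a NASCET degree of stenosis
#'
#' Left-closed severity bands: free of stenosis below 10%, mild 10-49%,
#' moderate 50-69%, severe 70-99%.
#'
#' @param degree Degree of stenosis (percent), in `[0, 100)`; vectorized.
#' @return A factor with levels `free`, `mild`, `moderate`, `severe`.
#' @export
classify_nascet <- function(degree) {
  abort_if(any(!is.finite(degree)) || any(degree < 0) || any(degree >= 100),
           "`degree` must lie in [0, 100)")
  cut(degree, breaks = c(-Inf, 10, 50, 70, Inf), right = FALSE,
      labels = c("free", "mild", "moderate", "severe"))
}

nascet_band <- function(grade) {
  switch(as.character(grade),
         free = c(0, 10), mild = c(10, 50), moderate = c(50, 70),
         severe = c(70, 99.999),
         rlang::abort(paste0("unknown grade: ", grade)))
}
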