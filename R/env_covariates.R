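#' Environmental profile for one sample
#'
#' Bundles the depth-resolved nutrient measurements and surface
#' hydrography attached to a sample: depths (m, strictly increasing),
#' nitrate / phosphate / silicate concentrations (uM) at each depth, sea
#' surface temperature (degC), sea surface salinity (practical salinity)
#' and mixed layer depth (m).
#'
#' @param depths Strictly increasing depths (m); the shallowest must lie
#'   at or above the mixed layer depth.
#' @param no3,po4,sio3 Nutrient concentrations (uM) at each depth
#'   (non-negative).
#' @param sst,sss,mld Surface temperature, surface salinity, mixed layer
#'   depth.
#' @return An object of class `env_profile`.
#' @export
env_profile <- function(depths, no3, po4, sio3, sst, sss, mld) {
  if (any(diff(depths) <= 0)) {
    stop("depths must be strictly increasing", call. = FALSE)
  }
  for (nm in c("no3", "po4", "sio3")) {
    v <- get(nm)
    if (length(v) != length(depths)) {
      stop(nm, " must have one value per depth", call. = FALSE)
    }
    if (any(v < 0)) stop(nm, " concentrations must be non-negative", call. = FALSE)
  }
  if (mld <= 0) stop("mixed layer depth must be positive", call. = FALSE)
  if (min(depths) > mld) {
    stop("no measurements above the mixed layer depth", call. = FALSE)
  }
  structure(
    list(depths = depths, no3 = no3, po4 = po4, sio3 = sio3,
         sst = sst, sss = sss, mld = mld),
    class = "env_profile"
  )
}

#' Depth-integrated nutrient concentration above the mixed layer
#'
#' Trapezoidal integral of the concentration profile from the shallowest
#' measurement down to the mixed layer depth, divided by the integration
#' span — i.e. a depth-weighted *mean* concentration (uM), so that it is
#' directly comparable with surface concentrations in regressions. If the
#' profile extends below the MLD, the concentration at exactly the MLD is
#' obtained by linear interpolation; a constant profile returns that
#' constant.
#'
#' @param profile An [env_profile()].
#' @param nutrient One of `"no3"`, `"po4"`, `"sio3"`.
#' @return Depth-weighted mean concentration (uM) over 0 - MLD.
#' @export
depth_integrated_nutrient <- function(profile, nutrient = c("no3", "po4", "sio3")) {
  stopifnot(inherits(profile, "env_profile"))
  nutrient <- match.arg(nutrient)
  d <- profile$depths
  v <- profile[[nutrient]]
  mld <- profile$mld
  above <- d <= mld
  if (!any(above)) {
    stop("no measurements above the mixed layer depth", call. = FALSE)
  }
  dd <- d[above]
  vv <- v[above]
  if (any(!above) && max(dd) < mld) {
    # interpolate the profile to the MLD itself
    vmld <- approx(d, v, xout = mld)$y
    dd <- c(dd, mld)
    vv <- c(vv, vmld)
  }
  if (length(dd) == 1L) {
    warning("single measurement above the MLD; returning it unintegrated",
            call. = FALSE)
    return(vv)
  }
  pracma::trapz(dd, vv) / (max(dd) - min(dd))
}

#' Log-transform nutrient concentrations
#'
#' Natural log of `value + offset`, where the offset is zero when all
#' values are strictly positive and otherwise the smallest positive value
#' present (a detection-limit style floor, reported loudly). The transform
#' is monotone, so sample orderings are preserved.
#'
#' @param values Non-negative concentrations.
#' @return Numeric vector of transformed values, with the offset used
#'   attached as attribute `offset`.
#' @export
log_transform_nutrients <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (any(values < 0)) {
    stop("negative nutrient concentrations are invalid", call. = FALSE)
  }
  offset <- 0
  if (any(values == 0)) {
    pos <- values[values > 0]
    if (!length(pos)) {
      stop("all values are zero; log transform undefined", call. = FALSE)
    }
    offset <- min(pos)
    message(sprintf(
      "log_transform_nutrients: zeros present; offsetting by smallest positive value %g",
      offset))
  }
  out <- log(values + offset)
  attr(out, "offset") <- offset
  out
}
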