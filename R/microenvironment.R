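#' Define the 3D bone-marrow lattice domain
#'
#' A rectangular lattice (one cell diameter per site) with an inscribed
#' cylindrical mask (axis along z) of valid agent sites, reconciling the
#' cylindrical marrow geometry with the rectangular grid.
#'
#' @param nx,ny,nz Lattice dimensions (each >= 3; default 50).
#' @param spacing Site spacing in cell diameters (default 1).
#' @return List with dims, spacing and the logical `mask` array.
#' @export
habm_domain <- function(nx = 50, ny = 50, nz = 50, spacing = 1) {
  if (min(nx, ny, nz) < 3) stop("domain dimensions must each be >= 3")
  if (spacing <= 0) stop("spacing must be > 0")
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r <- min(nx, ny) / 2
  d2 <- outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+")
  mask <- array(rep(d2 <= r^2, nz), dim = c(nx, ny, nz))
  list(nx = nx, ny = ny, nz = nz, spacing = spacing, mask = mask)
}

#' Create a concentration field
#'
#' A 3D scalar grid in relative concentration units with a diffusion
#' coefficient and a Dirichlet boundary value applied on the box faces.
#'
#' @param domain A [habm_domain()].
#' @param value Initial uniform value (default the boundary value).
#' @param D Diffusion coefficient in sites^2 per hour.
#' @param boundary Dirichlet boundary value (default 0, a sink-like
#'   marrow edge).
#' @return A `conc_field`: numeric 3D array with attributes `D` and
#'   `boundary`.
#' @export
conc_field <- function(domain, value = boundary, D = 2, boundary = 0) {
  f <- array(value, dim = c(domain$nx, domain$ny, domain$nz))
  attr(f, "D") <- D
  attr(f, "boundary") <- boundary
  class(f) <- c("conc_field", class(f))
  f
}

#' Explicit diffusion step
#'
#' One forward-Euler step of the 7-point-stencil discrete Laplacian with
#' Dirichlet boundary (out-of-box neighbors held at the boundary value).
#' The explicit scheme requires `D * dt / dx^2 <= 1/6`; longer intervals
#' must be sub-stepped (see `substeps`).
#'
#' @param field A `conc_field`.
#' @param dt Time step in hours.
#' @param substeps Number of equal sub-steps to divide `dt` into
#'   (default 1). Each sub-step must satisfy the stability bound.
#' @return The updated `conc_field`.
#' @export
diffuse <- function(field, dt, substeps = 1) {
  D <- attr(field, "D")
  h <- dt / substeps
  if (D * h > 1 / 6 + 1e-12)
    stop(sprintf(
      "explicit-scheme stability violated (D*dt = %.3f > 1/6); use substeps >= %d",
      D * h, ceiling(6 * D * dt)))
  dm <- dim(field)
  out <- diffuse_steps_cpp(field, dm[1], dm[2], dm[3], D, h, substeps,
                           attr(field, "boundary"))
  attributes(out) <- attributes(field)
  out
}

#' Number of stable sub-steps for a diffusion interval
#' @param D Diffusion coefficient (sites^2/h).
#' @param dt Interval in hours.
#' @return Smallest sub-step count satisfying the stability bound.
#' @export
diffusion_substeps <- function(D, dt) max(1L, as.integer(ceiling(6 * D * dt)))

#' Deposit secreted cytokine at agent sites
#'
#' Adds `rate * dt` at the site of every secreting agent. SDF-1 is
#' secreted by MIC agents only; TGF-beta by BMSC and MM agents only; all
#' other kinds contribute nothing.
#'
#' @param field A `conc_field`.
#' @param agents Data frame with columns `kind` (character) and `x`, `y`,
#'   `z` (lattice coordinates).
#' @param rate_map Named vector of secretion rates (units per hour) keyed
#'   by agent kind; kinds absent from the map secrete nothing.
#' @param dt Step length in hours.
#' @return The updated `conc_field`.
#' @export
secrete <- function(field, agents, rate_map, dt) {
  if (!nrow(agents)) return(field)
  bad <- setdiff(names(rate_map), c("BMSC", "MIC", "MM", "CD8", "TREG"))
  if (length(bad)) stop("unknown agent kinds in rate_map: ",
                        paste(bad, collapse = ", "))
  r <- rate_map[agents$kind]
  sel <- !is.na(r) & r > 0
  if (any(sel)) {
    dm <- dim(field)
    idx <- agents$x[sel] + dm[1] * (agents$y[sel] - 1) +
      dm[1] * dm[2] * (agents$z[sel] - 1)
    add <- tapply(r[sel] * dt, idx, sum)
    field[as.integer(names(add))] <- field[as.integer(names(add))] + add
  }
  field
}

#' Drug treatment regimen
#'
#' Per-drug dose levels and a treatment window. Doses are spatially
#' uniform; no pharmacokinetics are modeled.
#'
#' @param btz_nM Bortezomib dose in nM.
#' @param len_uM Lenalidomide dose in uM.
#' @param thal_uM Thalidomide dose in uM.
#' @param start_h Treatment start (hours, default 0).
#' @param duration_h Treatment duration (hours, default 144 = 6 days).
#' @return A `drug_regimen` list.
#' @export
drug_regimen <- function(btz_nM = 0, len_uM = 0, thal_uM = 0,
                         start_h = 0, duration_h = 144) {
  if (min(btz_nM, len_uM, thal_uM) < 0) stop("doses must be >= 0")
  structure(list(btz_nM = btz_nM, len_uM = len_uM, thal_uM = thal_uM,
                 start_h = start_h, duration_h = duration_h),
            class = "drug_regimen")
}

#' Drug level at a given time
#'
#' Full dose inside the half-open treatment window
#' `[start, start + duration)`, zero outside; spatially uniform.
#'
#' @param regimen A [drug_regimen()].
#' @param drug One of `"btz"`, `"len"`, `"thal"`.
#' @param t Time in hours (>= 0).
#' @return Dose (nM for btz, uM otherwise).
#' @export
drug_level <- function(regimen, drug = c("btz", "len", "thal"), t) {
  drug <- match.arg(drug)
  if (any(t < 0)) stop("t must be >= 0")
  dose <- switch(drug, btz = regimen$btz_nM, len = regimen$len_uM,
                 thal = regimen$thal_uM)
  ifelse(t >= regimen$start_h & t < regimen$start_h + regimen$duration_h,
         dose, 0)
}

#' Local niche stiffness at a lattice site
#'
#' The stiffness (Pa) of the BMSC agent at the site or within its Moore
#' neighborhood (the maximum if several), else the soft-ECM floor of
#' 100 Pa.
#'
#' @param bmsc Data frame of BMSC agents with columns `x`, `y`, `z`,
#'   `stiffness_pa`.
#' @param site Integer vector `c(x, y, z)`.
#' @param floor_pa Soft-ECM stiffness floor (default 100 Pa).
#' @return Stiffness in Pa.
#' @export
local_stiffness <- function(bmsc, site, floor_pa = 100) {
  if (!nrow(bmsc)) return(floor_pa)
  near <- abs(bmsc$x - site[1]) <= 1 & abs(bmsc$y - site[2]) <= 1 &
    abs(bmsc$z - site[3]) <= 1
  if (!any(near)) return(floor_pa)
  max(bmsc$stiffness_pa[near])
}

#' Export a field snapshot as a data frame
#' @param field A `conc_field`.
#' @return Data frame with columns `x`, `y`, `z`, `value`.
#' @export
field_frame <- function(field) {
  dm <- dim(field)
  g <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                   z = seq_len(dm[3]))
  g$value <- as.vector(field)
  g
}
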