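#' Logistic NTCP model parameters for brain radionecrosis
#'
#' Pooled-literature logistic model of normal-tissue complication
#' probability (radionecrosis) after single-fraction cranial
#' radiosurgery, driven by the absolute brain volume receiving at least
#' `x` Gy.  Defaults: x = 14 Gy, volume at 50% risk `vx50` = 45.8 cc,
#' slope `gamma50` = 0.88.
#'
#' @param x dose level in Gy defining the Vx metric (default 14).
#' @param vx50 volume in cc at 50% complication risk (> 0, default 45.8).
#' @param gamma50 dimensionless slope parameter (> 0, default 0.88).
#' @return An object of class `ntcp_params`.
#' @export
ntcp_params <- function(x = 14, vx50 = 45.8, gamma50 = 0.88) {
  if (vx50 <= 0) stop("vx50 must be > 0")
  if (gamma50 <= 0) stop("gamma50 must be > 0")
  structure(list(x = x, vx50 = vx50, gamma50 = gamma50),
            class = "ntcp_params")
}

#' @export
print.ntcp_params <- function(x, ...) {
  cat(sprintf("<ntcp_params> V%g Gy: vx50 = %.1f cc, gamma50 = %.2f\n",
              x$x, x$vx50, x$gamma50))
  invisible(x)
}

#' Normal-tissue complication probability
#'
#' `NTCP = 1 / (1 + (vx50 / vx)^(4 * gamma50))`, the logistic risk of
#' brain radionecrosis as a function of the brain Vx volume.  Defined as
#' 0 at `vx = 0` (the limit); strictly increasing on (0, Inf) with
#' `ntcp(vx50) = 0.5` exactly.
#'
#' @param vx brain volume in cc receiving at least x Gy (>= 0; vectorised).
#' @param params an [ntcp_params()].
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' ntcp(45.8)            # 0.5 by construction
#' ntcp(c(0, 30, 91.6))
ntcp <- function(vx, params = ntcp_params()) {
  stopifnot(inherits(params, "ntcp_params"))
  if (any(vx < 0)) stop("vx must be non-negative")
  p <- ifelse(vx == 0, 0, 1 / (1 + (params$vx50 / vx)^(4 * params$gamma50)))
  as.numeric(p)
}

#' NTCP change between a reference and a perturbed dose
#'
#' Computes the brain Vx (default V14Gy) of both dose grids via [v_x()],
#' maps each through [ntcp()], and reports the absolute difference in
#' percentage points and the relative (percent) difference.  Both styles
#' are reported because small absolute changes can still be a few percent
#' in relative terms.
#'
#' @param dose_ref,dose_perturbed [dose_grid()] objects on one lattice.
#' @param brain non-empty brain [structure_mask()]; by convention the
#'   whole brain with GTVs included (a GTV-excluded brain mask may be
#'   passed instead where that convention is preferred).
#' @param params an [ntcp_params()].
#' @return List with `vx_ref`, `vx_perturbed` (cc), `ntcp_ref`,
#'   `ntcp_perturbed` (probabilities), `abs_diff_pct` (percentage
#'   points), `rel_diff_pct` (percent; `NA` with `rel_diff_defined =
#'   FALSE` when the reference NTCP is 0).
#' @export
ntcp_delta <- function(dose_ref, dose_perturbed, brain,
                       params = ntcp_params()) {
  stopifnot(inherits(brain, "structure_mask"))
  .check_same_lattice(dose_ref, dose_perturbed, "reference and perturbed dose")
  if (!any(brain$voxels)) stop("brain mask is empty")
  v1 <- v_x(dose_ref, brain, params$x)
  v2 <- v_x(dose_perturbed, brain, params$x)
  p1 <- ntcp(v1, params)
  p2 <- ntcp(v2, params)
  rel_ok <- p1 > 0
  list(vx_ref = v1, vx_perturbed = v2,
       ntcp_ref = p1, ntcp_perturbed = p2,
       abs_diff_pct = 100 * (p2 - p1),
       rel_diff_pct = if (rel_ok) 100 * (p2 - p1) / p1 else NA_real_,
       rel_diff_defined = rel_ok)
}
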