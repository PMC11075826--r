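#' Cardiac output from stroke volume and heart rate
#'
#' @param sv Stroke volume in mL (non-negative).
#' @param hr Heart rate in beats per minute (positive).
#' @return Cardiac output in L/min.
#' @examples
#' cardiac_output(70, 60) # 4.2 L/min
#' @export
cardiac_output <- function(sv, hr) {
  stopifnot(is.numeric(sv), is.numeric(hr))
  if (any(sv < 0)) stop("stroke volume must be non-negative")
  if (any(hr <= 0)) stop("heart rate must be positive")
  sv * hr / 1000
}

#' Systemic vascular resistance
#'
#' SVR = (MAP - CVP) / CO. Central venous pressure is taken as a constant
#' 0 mmHg by default, so the default is simply MAP divided by cardiac
#' output; a `cvp` argument is provided for sensitivity analyses.
#'
#' @param map Mean arterial pressure in mmHg.
#' @param co Cardiac output in L/min (positive).
#' @param cvp Central venous pressure in mmHg (default 0).
#' @return SVR in mmHg·min·L^-1.
#' @examples
#' svr(90, 5) # 18
#' @export
svr <- function(map, co, cvp = 0) {
  stopifnot(is.numeric(map), is.numeric(co))
  if (any(co <= 0)) stop("cardiac output must be positive")
  (map - cvp) / co
}

#' Body surface area
#'
#' Du Bois formula by default (0.007184 * height^0.725 * weight^0.425),
#' with Mosteller as an alternative.
#'
#' @param height_cm Height in cm (positive).
#' @param weight_kg Weight in kg (positive).
#' @param formula One of `"dubois"` or `"mosteller"`.
#' @return Body surface area in m^2.
#' @examples
#' bsa(180, 75)
#' @export
bsa <- function(height_cm, weight_kg, formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive")
  }
  switch(formula,
    dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425,
    mosteller = sqrt(height_cm * weight_kg / 3600)
  )
}

#' Body-surface-area-indexed stroke volume
#'
#' @param sv Stroke volume in mL.
#' @param bsa_m2 Body surface area in m^2 (positive).
#' @return Indexed stroke volume in mL/m^2.
#' @export
sv_indexed <- function(sv, bsa_m2) {
  if (any(bsa_m2 <= 0)) stop("body surface area must be positive")
  sv / bsa_m2
}

#' Isometric-handgrip target force
#'
#' Maximal voluntary contraction (MVC) is the mean of exactly three
#' attempts; the handgrip target is a fixed fraction of MVC (40% by
#' default).
#'
#' @param mvc_attempts Numeric vector of exactly three positive forces
#'   in newtons.
#' @param fraction Fraction of MVC to hold (default 0.40).
#' @return Target force in newtons.
#' @examples
#' target_force(c(250, 310, 290)) # 113.33 N
#' @export
target_force <- function(mvc_attempts, fraction = 0.40) {
  if (length(mvc_attempts) != 3) stop("exactly three MVC attempts required")
  if (any(mvc_attempts <= 0)) stop("MVC attempts must be positive")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  fraction * mean(mvc_attempts)
}

#' Predicted change in the between-method difference for an SVR excursion
#'
#' Multiplies a fitted SVR coefficient (mL per mmHg·min·L^-1) by an SVR
#' excursion to give the implied change in the PWA-minus-ultrasound
#' stroke-volume difference.
#'
#' @param beta_svr Coefficient in mL per mmHg·min·L^-1.
#' @param delta_svr SVR excursion in mmHg·min·L^-1.
#' @return Change in the between-method difference, mL.
#' @examples
#' predicted_difference_change(0.60, 10) # 6 mL
#' @export
predicted_difference_change <- function(beta_svr, delta_svr) {
  stopifnot(is.finite(beta_svr), is.finite(delta_svr))
  beta_svr * delta_svr
}

#' Left-ventricular-outflow-tract cross-sectional area
#'
#' The LVOT is assumed circular; its diameter is measured inner edge to
#' inner edge.
#'
#' @param diameter_cm LVOT diameter in cm (positive).
#' @return Area in cm^2.
#' @examples
#' lvot_area(2.0) # pi
#' @export
lvot_area <- function(diameter_cm) {
  if (any(diameter_cm <= 0)) stop("LVOT diameter must be positive")
  pi * (diameter_cm / 2)^2
}

#' Stroke volume from a velocity-time integral
#'
#' @param vti Velocity-time integral in cm (non-negative).
#' @param area_cm2 LVOT area in cm^2 (positive).
#' @return Stroke volume in mL (1 cm^3 = 1 mL).
#' @examples
#' sv_from_vti(20, 3.5) # 70 mL
#' @export
sv_from_vti <- function(vti, area_cm2) {
  if (any(vti < 0)) stop("velocity-time integral must be non-negative")
  if (any(area_cm2 <= 0)) stop("LVOT area must be positive")
  vti * area_cm2
}
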