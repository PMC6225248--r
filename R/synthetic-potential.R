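#' Define a one-dimensional reference potential along the reaction coordinate
#'
#' The synthetic umbrella-sampling generator draws biased samples from a known
#' potential of mean force along the centre-of-mass separation coordinate, so
#' that WHAM reconstruction can be checked against ground truth. Four shapes
#' cover the cases of interest:
#'
#' * `"flat"` — constant potential; the biased density is then exactly the
#'   Gaussian of the harmonic restraint.
#' * `"harmonic"` — `U(x) = kappa/2 (x - center)^2`.
#' * `"double_well"` — two Gaussian wells of depths `depth1`, `depth2`
#'   (kJ/mol, measured from the flat baseline at 0) centred at `center1`,
#'   `center2`, separated by a Gaussian barrier of height `barrier` at their
#'   midpoint, all of width `width` (nm); mimics a bound state separated
#'   from a shallower encounter minimum by an association barrier. The
#'   difference between the highest point (the barrier top) and the lowest
#'   (the deep well) plays the role of the binding free energy, here
#'   `depth1 + barrier` (40 kJ/mol at the defaults).
#' * `"tabulated"` — energies interpolated linearly from a user grid.
#'
#' @param kind One of `"flat"`, `"harmonic"`, `"double_well"`, `"tabulated"`.
#' @param domain Numeric length-2, the (min, max) of the coordinate in nm.
#' @param kappa,center Harmonic stiffness (kJ/(mol nm^2)) and centre (nm).
#' @param center1,center2,depth1,depth2,barrier,width Double-well
#'   parameters: well centres (nm), well depths below baseline (kJ/mol),
#'   barrier height above baseline at the midpoint (kJ/mol), feature width
#'   (nm).
#' @param x,u Grids for `kind = "tabulated"`: strictly increasing `x` (nm)
#'   and finite `u` (kJ/mol).
#' @return An object of class `potential_spec`: a list with the shape,
#'   parameters, domain, and an energy function `U(x)`.
#' @examples
#' pot <- potential_spec("double_well", domain = c(0.2, 2.2),
#'                       center1 = 0.6, center2 = 1.4,
#'                       depth1 = 32, depth2 = 12, barrier = 8, width = 0.08)
#' pot$U(c(0.6, 1.0, 1.4, 2.0))
#' @export
potential_spec <- function(kind = c("flat", "harmonic", "double_well", "tabulated"),
                           domain = c(0, 2),
                           kappa = 500, center = mean(domain),
                           center1 = NULL, center2 = NULL,
                           depth1 = 32, depth2 = 12, barrier = 8, width = 0.08,
                           x = NULL, u = NULL) {
  kind <- match.arg(kind)
  domain <- as.numeric(domain)
  if (length(domain) != 2 || !all(is.finite(domain)) || domain[1] >= domain[2])
    abort("`domain` must be finite (min, max) with min < max.")

  U <- switch(kind,
    flat = function(xx) rep(0, length(xx)),
    harmonic = {
      if (!is.finite(kappa) || kappa <= 0) abort("harmonic `kappa` must be > 0.")
      force(center)
      function(xx) 0.5 * kappa * (xx - center)^2
    },
    double_well = {
      if (is.null(center1)) center1 <- domain[1] + 0.25 * diff(domain)
      if (is.null(center2)) center2 <- domain[1] + 0.60 * diff(domain)
      if (any(!is.finite(c(center1, center2, depth1, depth2, barrier, width))) ||
            width <= 0)
        abort("double-well parameters must be finite with width > 0.")
      mid <- (center1 + center2) / 2
      function(xx) {
        -depth1 * exp(-(xx - center1)^2 / (2 * width^2)) -
          depth2 * exp(-(xx - center2)^2 / (2 * width^2)) +
          barrier * exp(-(xx - mid)^2 / (2 * width^2))
      }
    },
    tabulated = {
      if (is.null(x) || is.null(u)) abort("tabulated potential needs `x` and `u`.")
      if (any(diff(x) <= 0)) abort("tabulated grid `x` must be strictly increasing.")
      if (!all(is.finite(u))) abort("tabulated energies must be finite.")
      force(x); force(u)
      function(xx) approx(x, u, xout = xx, rule = 2)$y
    }
  )

  structure(
    list(kind = kind, domain = domain, U = U,
         parameters = switch(kind,
           flat = list(),
           harmonic = list(kappa = kappa, center = center),
           double_well = list(center1 = center1, center2 = center2,
                              depth1 = depth1, depth2 = depth2,
                              barrier = barrier, width = width),
           tabulated = list(x = x, u = u))),
    class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("<potential_spec> kind =", x$kind,
      " domain = [", x$domain[1], ",", x$domain[2], "] nm\n")
  invisible(x)
}
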