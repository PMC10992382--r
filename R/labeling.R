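#' Flux partition of the capture network
#'
#' The xylose consumption `xyl_total` splits between the pentose phosphate
#' pathway (`x1`) and the PRK/Rubisco bypass (`x2`); `x2` equals the
#' CO2-uptake flux on a molar basis because each RuBP carboxylation fixes one
#' CO2. Carbon rearrangement through the pentose phosphate pathway yields
#' 5/6 F6P per xylose, each F6P giving two G3P, so the G3P flux is
#' `x3 = (5/3) x1 + gly_total`. Each carboxylation produces two 3PGA of which
#' exactly one carries the labeled carboxyl carbon, so the labeled fraction
#' of the 3PGA pool (inherited unchanged by lactate) is
#' `r_3pga = x2 / (x3 + 2 x2)`.
#'
#' Objects of class `flux_partition` hold `x1`, `x2`, `x3`, `r_3pga`,
#' `xyl_total` and `gly_total`, all fluxes in mmol gDCW^-1 h^-1.
#'
#' @name flux_partition
NULL

new_flux_partition <- function(x1, x2, x3, r_3pga, xyl_total, gly_total) {
  structure(list(x1 = x1, x2 = x2, x3 = x3, r_3pga = r_3pga,
                 xyl_total = xyl_total, gly_total = gly_total),
            class = "flux_partition")
}

#' Forward model: labeled fraction from a known bypass flux
#'
#' Given the bypass (CO2-uptake) flux `x2` and the total xylose and glycerol
#' fluxes, computes the full partition and the labeled-lactate fraction the
#' model predicts.
#'
#' @param x2 bypass flux, `0 <= x2 <= xyl_total`, mmol gDCW^-1 h^-1.
#' @param xyl_total,gly_total total xylose and glycerol consumption fluxes.
#' @return A `flux_partition` (see [flux_partition]).
#' @examples
#' p <- forward_label_fraction(0.18, 0.50, 0.46)
#' p$r_3pga # 0.1330
#' @export
forward_label_fraction <- function(x2, xyl_total, gly_total) {
  stopifnot(is.numeric(x2), is.numeric(xyl_total), is.numeric(gly_total))
  if (x2 < 0 || xyl_total < 0 || gly_total < 0)
    stop("fluxes must be non-negative")
  if (x2 > xyl_total * (1 + 1e-12))
    stop("x2 exceeds total xylose flux")
  x1 <- xyl_total - x2
  x3 <- (5 / 3) * x1 + gly_total
  denom <- x3 + 2 * x2
  if (denom <= 0) stop("label fraction undefined: all fluxes are zero")
  new_flux_partition(x1, x2, x3, x2 / denom, xyl_total, gly_total)
}

#' Inverse model: bypass flux from the measured labeled fraction
#'
#' Inverts the labeling relation in closed form. Substituting
#' `x1 = xyl_total - x2` and `x3 = (5/3) x1 + gly_total` into
#' `r = x2 / (x3 + 2 x2)` gives
#' `x2 = r ((5/3) xyl_total + gly_total) / (1 - r/3)`.
#' The forward model applied to the result reproduces `r` to machine
#' precision.
#'
#' @param xyl_total,gly_total total consumption fluxes, mmol gDCW^-1 h^-1.
#' @param r_lactate background-corrected fraction of 13C-labeled lactate,
#'   in `[0, 1)`.
#' @return A `flux_partition` (see [flux_partition]).
#' @examples
#' infer_flux_partition(0.50, 0.46, 0.1330)$x2 # 0.18
#' @export
infer_flux_partition <- function(xyl_total, gly_total, r_lactate) {
  stopifnot(is.numeric(xyl_total), is.numeric(gly_total),
            is.numeric(r_lactate))
  if (r_lactate < 0 || r_lactate >= 1)
    stop("r_lactate must lie in [0, 1)")
  if (xyl_total < 0 || gly_total < 0) stop("fluxes must be non-negative")
  if (xyl_total <= 0 && gly_total <= 0)
    stop("at least one substrate flux must be positive")
  if (xyl_total <= 0 && r_lactate > 0)
    stop("label fraction inconsistent with substrate supply: no xylose flux")
  x2 <- r_lactate * ((5 / 3) * xyl_total + gly_total) / (1 - r_lactate / 3)
  if (x2 > xyl_total * (1 + 1e-9))
    stop("label fraction inconsistent with substrate supply: ",
         "inferred x2 = ", signif(x2, 4), " exceeds xylose flux ",
         signif(xyl_total, 4))
  forward_label_fraction(min(x2, xyl_total), xyl_total, gly_total)
}

#' Fraction of xylose routed through the bypass
#'
#' @param p a `flux_partition`.
#' @return `x2 / xyl_total` as a percentage.
#' @examples
#' bypass_fraction(forward_label_fraction(0.18, 0.50, 0.46)) # 36
#' @export
bypass_fraction <- function(p) {
  stopifnot(inherits(p, "flux_partition"))
  if (p$xyl_total <= 0) stop("xyl_total is zero; bypass fraction undefined")
  p$x2 / p$xyl_total * 100
}

#' @export
print.flux_partition <- function(x, ...) {
  cat("Flux partition (mmol gDCW^-1 h^-1):\n")
  cat(sprintf("  PPP xylose flux (x1)     %8.4f\n", x$x1))
  cat(sprintf("  bypass / CO2 uptake (x2) %8.4f\n", x$x2))
  cat(sprintf("  G3P flux (x3)            %8.4f\n", x$x3))
  cat(sprintf("  labeled 3PGA fraction    %8.4f\n", x$r_3pga))
  cat(sprintf("  bypass fraction of xylose %6.1f%%\n",
              x$x2 / x$xyl_total * 100))
  invisible(x)
}
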