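# Physical constants and magnetic-field unit handling.
#
# Internal convention: SI everywhere (fields as B = mu0*H in tesla when a
# "field" is quoted in T/mT, A/m when it enters a constitutive law).  The
# oersted and the centimetre appear only inside the magnetoelectric
# coefficient, which the literature quotes in mV Oe^-1 cm^-1.

#' Vacuum permeability (H/m)
#' @keywords internal
MU0 <- 4e-7 * pi

#' Vacuum permittivity (F/m)
#' @keywords internal
EPS0 <- 8.8541878128e-12

#' Convert a magnetic field magnitude between unit systems
#'
#' Supported units are `"T"`, `"mT"`, `"Oe"` and `"A/m"`.  Conversions use the
#' vacuum identification B = mu0 H, so 1 mT = 10 Oe, 1 T = 1e4 Oe and
#' H\[A/m\] = B\[T\]/mu0.
#'
#' @param value numeric vector of field magnitudes.
#' @param from,to unit labels, one of `"T"`, `"mT"`, `"Oe"`, `"A/m"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_field_units(300, "mT", "Oe")   # 3000
#' convert_field_units(4, "T", "Oe")      # 40000
#' convert_field_units(300, "mT", "A/m")  # 0.3/mu0
#' @export
convert_field_units <- function(value, from, to) {
  stopifnot(is.numeric(value))
  to_tesla <- function(v, u) {
    switch(u,
      "T"   = v,
      "mT"  = v * 1e-3,
      "Oe"  = v * 1e-4,
      "A/m" = v * MU0,
      stop("unknown field unit label: '", u, "'", call. = FALSE)
    )
  }
  from_tesla <- function(v, u) {
    switch(u,
      "T"   = v,
      "mT"  = v * 1e3,
      "Oe"  = v * 1e4,
      "A/m" = v / MU0,
      stop("unknown field unit label: '", u, "'", call. = FALSE)
    )
  }
  from_tesla(to_tesla(value, from), to)
}
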