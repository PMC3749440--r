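#' Thermal energy scale
#'
#' @param kT Thermal energy in pN nm. The default 4.18 pN nm corresponds to
#'   30 degrees C, the temperature at which the assays this package emulates
#'   are run.
#' @return An object of class `thermal`.
#' @export
thermal <- function(kT = 4.18) {
  stopifnot(is.numeric(kT), length(kT) == 1L, is.finite(kT), kT > 0)
  structure(list(kT = kT), class = "thermal")
}

#' Polymer elasticity model for one tether element
#'
#' Constructs a parametric force-extension law for a single element of a
#' tether: a worm-like chain (`wlc`), an extensible worm-like chain (`ewlc`),
#' an extensible freely-jointed chain (`efjc`), or a Hookean spring
#' (`hooke`, mainly for testing). The eFJC with `n_segments = 2` is the
#' model of a rigid multi-helix DNA bundle: two stiff arms joined at a
#' flexible vertex, with an enthalpic stretch term.
#'
#' @param kind One of `"wlc"`, `"ewlc"`, `"efjc"`, `"hooke"`.
#' @param L Contour length, nm (not used for `hooke`).
#' @param p Persistence length, nm (`wlc`/`ewlc` only).
#' @param K Stretch modulus, pN (`ewlc`/`efjc`; `Inf` allowed and is the
#'   inextensible limit).
#' @param n_segments Number of Kuhn segments (`efjc` only); the Kuhn length
#'   is `L / n_segments`.
#' @param k Spring constant, pN/nm (`hooke` only).
#' @return An object of class `polymer_model`.
#' @examples
#' polymer_model("ewlc", L = 530, p = 50, K = 1000)   # dsDNA linker
#' polymer_model("efjc", L = 485, K = 10000, n_segments = 2)  # ten-helix bundle
#' polymer_model("wlc", L = 15, p = 1)                # ssDNA attachment strand
#' @export
polymer_model <- function(kind = c("wlc", "ewlc", "efjc", "hooke"),
                          L = NULL, p = NULL, K = NULL, n_segments = NULL,
                          k = NULL) {
  kind <- match.arg(kind)
  if (kind != "hooke") {
    stopifnot(is.numeric(L), length(L) == 1L, is.finite(L), L > 0)
  }
  if (kind %in% c("wlc", "ewlc")) {
    stopifnot(is.numeric(p), length(p) == 1L, is.finite(p), p > 0)
  }
  if (kind == "wlc" && is.null(K)) K <- Inf
  if (kind %in% c("ewlc", "efjc")) {
    stopifnot(is.numeric(K), length(K) == 1L, K > 0)
  }
  if (kind == "efjc") {
    if (is.null(n_segments) || n_segments < 1 || n_segments != round(n_segments))
      stop("efjc requires an integer n_segments >= 1", call. = FALSE)
  }
  if (kind == "hooke") {
    stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0)
    L <- Inf
  }
  structure(list(kind = kind, L = L, p = p, K = K,
                 n_segments = n_segments, k = k),
            class = "polymer_model")
}

#' @export
print.polymer_model <- function(x, ...) {
  par_str <- switch(x$kind,
    wlc   = sprintf("p = %g nm, L = %g nm", x$p, x$L),
    ewlc  = sprintf("p = %g nm, L = %g nm, K = %g pN", x$p, x$L, x$K),
    efjc  = sprintf("L = %g nm, K = %g pN, %d segments", x$L, x$K, x$n_segments),
    hooke = sprintf("k = %g pN/nm", x$k))
  cat(sprintf("<polymer_model %s: %s>\n", x$kind, par_str))
  invisible(x)
}

# Marko-Siggia interpolation in relative extension z = x/L:
# F = (kT/p) * (1/(4(1-z)^2) - 1/4 + z)
ms_rel_force <- function(z) 1 / (4 * (1 - z)^2) - 0.25 + z

# Inverse of the Marko-Siggia interpolation: relative extension at reduced
# force f = F p / kT. Newton with bisection safeguard; f is vectorised.
ms_rel_extension <- function(f) {
  vapply(f, function(fi) {
    if (fi <= 0) return(0)
    lo <- 0; hi <- 1 - 1e-14
    # Newton from a heuristic start, falling back to bisection
    z <- if (fi < 1) fi / 1.5 else 1 - 0.5 / sqrt(fi)
    for (i in 1:100) {
      g <- ms_rel_force(z) - fi
      if (g > 0) hi <- z else lo <- z
      dg <- 1 / (2 * (1 - z)^3) + 1
      znew <- z - g / dg
      if (!is.finite(znew) || znew <= lo || znew >= hi) znew <- (lo + hi) / 2
      if (abs(znew - z) < 1e-15) { z <- znew; break }
      z <- znew
    }
    z
  }, numeric(1))
}

#' Worm-like chain force at a given extension
#'
#' The Marko-Siggia interpolation formula
#' \deqn{F(x) = \frac{k_BT}{p}\left[\frac{1}{4(1-x/L)^2} - \frac14 +
#'   \frac{x}{L}\right].}
#' The chain is inextensible: `x` must lie in `[0, L)`.
#'
#' @param x Extension, nm (vectorised).
#' @param model A `polymer_model` of kind `"wlc"`.
#' @param thermal A [thermal()] object.
#' @return Force in pN.
#' @export
wlc_force <- function(x, model, thermal = rigidlink::thermal()) {
  stopifnot(inherits(model, "polymer_model"), model$kind == "wlc")
  if (any(x < 0)) stop("wlc_force: extension must be >= 0", call. = FALSE)
  if (any(x >= model$L))
    stop("wlc_force: extension must be below the contour length", call. = FALSE)
  (thermal$kT / model$p) * ms_rel_force(x / model$L)
}

#' Extensible worm-like chain extension at a given force
#'
#' Inverts the extensible Marko-Siggia relation written with the substitution
#' `l = x/L - F/K`: the entropic part follows the worm-like chain in `l` and
#' the enthalpic term `F/K` adds on top, so `x = L (l(F) + F/K)`.
#'
#' @param F Force, pN (vectorised, non-negative).
#' @param model A `polymer_model` of kind `"ewlc"` (or `"wlc"`, treated as
#'   the inextensible `K = Inf` limit).
#' @param thermal A [thermal()] object.
#' @return Extension in nm, accurate to better than 1e-9 relative.
#' @export
ewlc_extension <- function(F, model, thermal = rigidlink::thermal()) {
  stopifnot(inherits(model, "polymer_model"), model$kind %in% c("ewlc", "wlc"))
  if (any(F < 0)) stop("ewlc_extension: force must be >= 0", call. = FALSE)
  K <- if (is.null(model$K) || !is.finite(model$K)) Inf else model$K
  z <- ms_rel_extension(F * model$p / thermal$kT)
  model$L * (z + if (is.finite(K)) F / K else 0)
}

#' Extensible freely-jointed chain extension at a given force
#'
#' The Langevin-function FJC with Kuhn length `b = L / n_segments` and an
#' enthalpic stretch factor:
#' \deqn{x(F) = L\left[\coth\frac{Fb}{k_BT} - \frac{k_BT}{Fb}\right]
#'   \left(1 + \frac{F}{K}\right).}
#' With `n_segments = 2` this is the two-element chain used for rigid
#' multi-helix DNA bundles.
#'
#' @param F Force, pN (vectorised, non-negative).
#' @param model A `polymer_model` of kind `"efjc"`.
#' @param thermal A [thermal()] object.
#' @return Extension in nm.
#' @export
efjc_extension <- function(F, model, thermal = rigidlink::thermal()) {
  stopifnot(inherits(model, "polymer_model"), model$kind == "efjc")
  if (any(F < 0)) stop("efjc_extension: force must be >= 0", call. = FALSE)
  b <- model$L / model$n_segments
  u <- F * b / thermal$kT
  lang <- ifelse(u == 0, 0,
                 ifelse(u > 350, 1 - 1 / u, 1 / tanh(u) - 1 / u))
  model$L * lang * (1 + F / model$K)
}

#' Extension of a single element at a given force
#'
#' Dispatches to the closed-form extension law of the element kind. For the
#' inextensible WLC the Marko-Siggia interpolation is inverted numerically.
#'
#' @inheritParams ewlc_extension
#' @param model A `polymer_model` of any kind.
#' @return Extension in nm.
#' @export
model_extension <- function(F, model, thermal = rigidlink::thermal()) {
  switch(model$kind,
    wlc   = ewlc_extension(F, model, thermal),
    ewlc  = ewlc_extension(F, model, thermal),
    efjc  = efjc_extension(F, model, thermal),
    hooke = F / model$k)
}

#' Force of a single element at a given extension
#'
#' Closed form for `wlc` and `hooke`; numerical inversion of the extension
#' law for `ewlc` and `efjc`.
#'
#' @param x Extension, nm (vectorised).
#' @inheritParams wlc_force
#' @param model A `polymer_model`.
#' @param f_max Upper bracket for the numerical inversion, pN.
#' @return Force in pN.
#' @export
model_force <- function(x, model, thermal = rigidlink::thermal(),
                        f_max = 1e4) {
  if (model$kind == "wlc") return(wlc_force(x, model, thermal))
  if (model$kind == "hooke") return(model$k * x)
  vapply(x, function(xi) {
    if (xi < 0) stop("model_force: extension must be >= 0", call. = FALSE)
    if (xi == 0) return(0)
    r <- uniroot(function(F) model_extension(F, model, thermal) - xi,
                 lower = 0, upper = f_max, tol = 1e-12, extendInt = "upX")
    r$root
  }, numeric(1))
}

#' Series extension of a tether chain
#'
#' Elements in mechanical series share a common tension; the total extension
#' is the sum of the element extensions at that tension.
#'
#' @param F Force, pN (vectorised).
#' @param chain A list of `polymer_model` objects.
#' @param thermal A [thermal()] object.
#' @return Total extension in nm.
#' @export
series_extension <- function(F, chain, thermal = rigidlink::thermal()) {
  if (inherits(chain, "polymer_model")) chain <- list(chain)
  stopifnot(length(chain) >= 1L)
  Reduce(`+`, lapply(chain, function(m) model_extension(F, m, thermal)))
}

#' Tension of a tether chain at a given total extension
#'
#' Numerically inverts [series_extension()].
#'
#' @param x Total extension, nm (vectorised).
#' @inheritParams series_extension
#' @param f_max Upper bracket, pN.
#' @return Common tension in pN.
#' @export
series_force <- function(x, chain, thermal = rigidlink::thermal(),
                         f_max = 1e4) {
  if (inherits(chain, "polymer_model")) chain <- list(chain)
  vapply(x, function(xi) {
    if (xi <= 0) return(0)
    uniroot(function(F) series_extension(F, chain, thermal) - xi,
            lower = 0, upper = f_max, tol = 1e-12, extendInt = "upX")$root
  }, numeric(1))
}

#' Stretching free energy of a tether element
#'
#' `E(x) = integral of F dx'` from 0 to `x`. Closed form for `wlc` and
#' `hooke`; for the extensible models the Legendre identity
#' `E(x) = F x - integral of x(F') dF'` is used with adaptive quadrature,
#' which needs only the explicit extension law.
#'
#' @param x Extension, nm (scalar or vector).
#' @param model A `polymer_model`.
#' @param thermal A [thermal()] object.
#' @return Energy in pN nm.
#' @export
stretch_energy <- function(x, model, thermal = rigidlink::thermal()) {
  vapply(x, function(xi) {
    if (xi < 0) stop("stretch_energy: extension must be >= 0", call. = FALSE)
    if (xi == 0) return(0)
    switch(model$kind,
      hooke = 0.5 * model$k * xi^2,
      wlc = {
        if (xi >= model$L)
          stop("stretch_energy: extension beyond contour length", call. = FALSE)
        z <- xi / model$L
        (thermal$kT * model$L / model$p) *
          (1 / (4 * (1 - z)) - 0.25 - z / 4 + z^2 / 2)
      },
      {
        Fx <- model_force(xi, model, thermal)
        if (Fx == 0) return(0)
        iq <- integrate(function(f) model_extension(f, model, thermal),
                        0, Fx, rel.tol = 1e-10, abs.tol = 1e-12)
        Fx * xi - iq$value
      })
  }, numeric(1))
}

#' Expected axial stiffness of an N-helix parallel bundle
#'
#' For `N` double helices of stretch modulus `K` each, cross-linked in
#' parallel over contour length `L`, the expected enthalpic stiffness is
#' `N K / L`.
#'
#' @param N Number of helices.
#' @param K Stretch modulus of one helix, pN.
#' @param L Contour length of the bundle, nm.
#' @return Stiffness in pN/nm.
#' @examples
#' expected_stiffness(10, 1000, 250)  # 40 pN/nm
#' @export
expected_stiffness <- function(N, K, L) {
  stopifnot(N > 0, K > 0, L > 0)
  N * K / L
}

# Tabulated stretch energy of a series chain on a uniform extension grid,
# for O(1) lookup inside the Monte-Carlo inner loop. Built parametrically in
# force: x(F) is explicit per element, E accumulates via the trapezoid rule
# of F dx along the curve, then both are re-gridded to uniform dx.
#
# Returns list(x0, dx, E, x_max).
build_energy_table <- function(chain, thermal = rigidlink::thermal(),
                               f_max = 200, n_f = 6000, dx = 0.02) {
  if (inherits(chain, "polymer_model")) chain <- list(chain)
  # dense near zero force where entropic laws curve most
  Fgrid <- c(seq(0, 2, length.out = ceiling(n_f / 3))[-1],
             exp(seq(log(2), log(f_max), length.out = ceiling(2 * n_f / 3))))
  Fgrid <- sort(unique(c(0, Fgrid)))
  xg <- series_extension(Fgrid, chain, thermal)
  Eg <- cumsum(c(0, 0.5 * (Fgrid[-1] + Fgrid[-length(Fgrid)]) * diff(xg)))
  xu <- seq(0, max(xg), by = dx)
  Eu <- approx(xg, Eg, xout = xu, rule = 2)$y
  list(x0 = 0, dx = dx, E = Eu, x_max = max(xg))
}
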