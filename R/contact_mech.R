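# Conformal-contact mechanics of a thin electrode laminate on rough skin.
# The skin surface is modeled as a sinusoid of wavelength lambda_rough and
# peak-to-peak amplitude h_rough; the laminate is a composite beam with
# effective bending stiffness EI per unit width. Conformal contact requires
# the elastomer's work of adhesion to exceed the sum of the film's bending
# energy and the skin's elastic deformation energy per unit area:
#
#   gamma_elastomer > 1/(1-alpha) * [ pi^4 EI h^2 / lambda^4
#       + pi E_skin (h_rough - h)^2 / (16 lambda) * (1 + pi^2 h^2 / (4 lambda^2)) ]
#
# with the equilibrium sagging amplitude
#
#   h = E_skin h_rough / (16 pi^3 EI / lambda^3 + E_skin),
#
# the minimizer of the bending-plus-skin energy, and alpha the areal fraction
# of the stiff PI/Au mesh. The (1 + pi^2 h^2 / 4 lambda^2) factor is the
# arc-length correction of the conformed sinusoidal interface.

#' Laminate stack description
#'
#' @param layers Data.frame (or list of vectors) with columns `name`,
#'   `thickness` (m) and `modulus` (Pa), ordered bottom (skin side) to top.
#' @param alpha Areal fraction of the PI/Au mesh, in `[0, 1)`.
#' @return An object of class `laminate_stack`.
#' @export
laminate_stack <- function(layers, alpha = 0) {
  layers <- as.data.frame(layers)
  stopifnot(all(c("name", "thickness", "modulus") %in% names(layers)))
  if (nrow(layers) < 1) stop("need at least one layer")
  if (any(layers$thickness <= 0)) stop("zero or negative layer thickness")
  if (any(layers$modulus <= 0)) stop("layer modulus must be positive")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  structure(list(layers = layers, alpha = alpha), class = "laminate_stack")
}

#' Default electrode laminate
#'
#' Au/Cr/PI thin-film electrode on a 500 um elastomer substrate. Thicknesses
#' and moduli are representative literature values for this construction
#' (the Au/PI electrode film is ~1.2 um thick in total); override any field
#' for a specific device.
#'
#' @param e_elastomer Elastomer Young's modulus, Pa.
#' @param t_elastomer Elastomer thickness, m.
#' @param alpha Areal fraction of the PI/Au mesh.
#' @return A [laminate_stack()].
#' @export
default_stack <- function(e_elastomer = 7.85e3, t_elastomer = 500e-6,
                          alpha = 0.25) {
  laminate_stack(data.frame(
    name = c("elastomer", "PI", "Cr", "Au"),
    thickness = c(t_elastomer, 1.1e-6, 10e-9, 100e-9),
    modulus = c(e_elastomer, 2.5e9, 279e9, 78e9)), alpha = alpha)
}

#' Skin surface model
#'
#' @param E_skin Effective skin modulus, Pa.
#' @param lambda_rough Roughness wavelength, m.
#' @param h_rough Roughness amplitude (peak to peak), m.
#' @return An object of class `skin_model`. Defaults are representative
#'   literature values for human epidermis (130 kPa, 140 um, 50 um) and
#'   should be overridden when measured values are available.
#' @export
skin_model <- function(E_skin = 130e3, lambda_rough = 140e-6,
                       h_rough = 50e-6) {
  if (E_skin <= 0 || lambda_rough <= 0 || h_rough < 0)
    stop("skin parameters must be positive (h_rough >= 0)")
  structure(list(E_skin = E_skin, lambda_rough = lambda_rough,
                 h_rough = h_rough), class = "skin_model")
}

#' Effective bending stiffness of a laminate (per unit width)
#'
#' Transformed-section composite-beam theory: the neutral axis sits at the
#' modulus-weighted centroid and `EI = sum_i E_i * I_i` about it.
#'
#' @param stack A [laminate_stack()].
#' @return Bending stiffness in N m (per unit width).
#' @export
effective_bending_stiffness <- function(stack) {
  stopifnot(inherits(stack, "laminate_stack"))
  t <- stack$layers$thickness
  E <- stack$layers$modulus
  top <- cumsum(t)
  bot <- top - t
  mid <- (top + bot) / 2
  z_na <- sum(E * t * mid) / sum(E * t)
  sum(E * (t^3 / 12 + t * (mid - z_na)^2))
}

#' Equilibrium sagging amplitude of the film on rough skin
#'
#' `h = E_skin h_rough / (16 pi^3 EI / lambda^3 + E_skin)` — the amplitude
#' minimizing bending plus skin elastic energy. Limits: `h -> h_rough` as
#' `EI -> 0` (a floppy film conforms fully), `h -> 0` as `EI -> Inf`.
#'
#' @param EI Bending stiffness, N m.
#' @param skin A [skin_model()].
#' @return Sag amplitude in m, in `[0, h_rough]`.
#' @export
sag_amplitude <- function(EI, skin) {
  stopifnot(inherits(skin, "skin_model"), EI >= 0)
  skin$E_skin * skin$h_rough /
    (16 * pi^3 * EI / skin$lambda_rough^3 + skin$E_skin)
}

#' Critical work of adhesion for conformal contact
#'
#' Evaluates the conformal-contact criterion for a laminate on rough skin:
#' the returned `gamma_crit` is the minimum elastomer work of adhesion
#' (J m^-2) for gapless lamination. When `gamma_elastomer` is supplied the
#' result also reports the margin and the conformal verdict (strict
#' inequality: a candidate sitting exactly on the boundary is
#' non-conformal).
#'
#' @param stack A [laminate_stack()].
#' @param skin A [skin_model()].
#' @param gamma_elastomer Optional measured work of adhesion, J m^-2.
#' @return An object of class `contact_result`: `gamma_crit`, `h`, `EI`,
#'   and (when `gamma_elastomer` is given) `margin` and `conformal`.
#' @export
critical_adhesion <- function(stack, skin, gamma_elastomer = NULL) {
  stopifnot(inherits(stack, "laminate_stack"), inherits(skin, "skin_model"))
  EI <- effective_bending_stiffness(stack)
  lam <- skin$lambda_rough
  h <- sag_amplitude(EI, skin)
  bending <- pi^4 * EI * h^2 / lam^4
  skin_el <- pi * skin$E_skin * (skin$h_rough - h)^2 / (16 * lam) *
    (1 + pi^2 * h^2 / (4 * lam^2))
  gamma_crit <- (bending + skin_el) / (1 - stack$alpha)
  res <- list(gamma_crit = gamma_crit, h = h, EI = EI)
  if (!is.null(gamma_elastomer)) {
    res$margin <- gamma_elastomer - gamma_crit
    res$conformal <- res$margin > 0
  }
  structure(res, class = "contact_result")
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("<contact_result> gamma_crit %.4g J/m^2, sag %.3g um, EI %.3g N m\n",
              x$gamma_crit, x$h * 1e6, x$EI))
  if (!is.null(x$conformal))
    cat(sprintf("  %s (margin %.4g J/m^2)\n",
                if (x$conformal) "CONFORMAL" else "non-conformal", x$margin))
  invisible(x)
}

#' Classify candidate elastomers as conformal or non-conformal
#'
#' For each candidate `(name, E, gamma)` the stack's elastomer layer modulus
#' is replaced by the candidate's, the critical adhesion is evaluated, and
#' the candidate is labeled by the sign of its margin
#' `gamma - gamma_crit` (strict inequality at the boundary). Candidates
#' without a measured `gamma` are skipped with a warning.
#'
#' @param candidates Data.frame with columns `name`, `E` (Pa) and `gamma`
#'   (J m^-2; `NA` allowed).
#' @param stack A [laminate_stack()] whose layer named `"elastomer"` is
#'   swapped per candidate.
#' @param skin A [skin_model()].
#' @return Data.frame ordered by decreasing margin: name, E, gamma,
#'   gamma_crit, margin, conformal.
#' @export
classify_elastomers <- function(candidates, stack = default_stack(),
                                skin = skin_model()) {
  candidates <- as.data.frame(candidates)
  stopifnot(all(c("name", "E", "gamma") %in% names(candidates)))
  el <- which(stack$layers$name == "elastomer")
  if (!length(el)) stop("stack has no layer named 'elastomer'")
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    if (is.na(candidates$gamma[i])) {
      warning("candidate '", candidates$name[i],
              "' has no measured gamma; skipped")
      return(NULL)
    }
    st <- stack
    st$layers$modulus[el] <- candidates$E[i]
    cr <- critical_adhesion(st, skin, candidates$gamma[i])
    data.frame(name = candidates$name[i], E = candidates$E[i],
               gamma = candidates$gamma[i], gamma_crit = cr$gamma_crit,
               margin = cr$margin, conformal = cr$conformal)
  })
  out <- do.call(rbind, rows)
  out[order(out$margin, decreasing = TRUE), , drop = FALSE]
}

#' Critical-adhesion boundary curve over an elastomer-modulus grid
#'
#' @param e_grid Elastomer moduli, Pa.
#' @param stack,skin As in [classify_elastomers()].
#' @return Data.frame `E`, `gamma_crit` tracing the conformal boundary.
#' @export
critical_boundary_curve <- function(e_grid, stack = default_stack(),
                                    skin = skin_model()) {
  el <- which(stack$layers$name == "elastomer")
  gc <- vapply(e_grid, function(E) {
    st <- stack
    st$layers$modulus[el] <- E
    critical_adhesion(st, skin)$gamma_crit
  }, 0)
  data.frame(E = e_grid, gamma_crit = gc)
}

#' Work of adhesion from the zero-speed intercept of peel-energy data
#'
#' Rolling-cylinder experiments give the effective peel energy change
#' `delta_gamma` at several speeds; the work of adhesion is the y-intercept
#' of a least-squares polynomial fit (default linear) in speed.
#'
#' @param points Data.frame with columns `speed` and `delta_gamma`.
#' @param degree Polynomial degree of the fit.
#' @return List: `gamma_0` (intercept), `se` (its standard error), `fit`
#'   (the `lm` object).
#' @export
work_of_adhesion_intercept <- function(points, degree = 1) {
  points <- as.data.frame(points)
  stopifnot(all(c("speed", "delta_gamma") %in% names(points)))
  if (length(unique(points$speed)) < 2)
    stop("need at least 2 distinct speeds")
  fit <- stats::lm(delta_gamma ~ poly(speed, degree, raw = TRUE),
                   data = points)
  list(gamma_0 = unname(coef(fit)[1]),
       se = sqrt(stats::vcov(fit)[1, 1]), fit = fit)
}

#' Total peel energy from a force-displacement curve
#'
#' Trapezoidal integral of peel force over displacement.
#'
#' @param curve Data.frame with columns `displacement` (m, strictly
#'   increasing) and `force` (N).
#' @return Energy in J.
#' @export
peel_energy <- function(curve) {
  curve <- as.data.frame(curve)
  stopifnot(all(c("displacement", "force") %in% names(curve)))
  d <- curve$displacement; f <- curve$force
  if (any(diff(d) <= 0)) stop("displacement must be strictly increasing")
  sum(diff(d) * (head(f, -1) + tail(f, -1)) / 2)
}
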