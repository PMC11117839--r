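#' Reduced-polynomial hyperelastic model
#'
#' Incompressible reduced-polynomial strain energy
#' \deqn{W = \sum_{i=1}^{N} C_{i0} (\bar I_1 - 3)^i,}
#' depending only on the first deviatoric invariant.  Defaults follow the
#' modeling convention used for ocular tissues here: order 2 for scleral
#' regions, order 1 (neo-Hookean) for the ON and its sheath; Poisson ratio
#' 0.495 is carried as near-incompressibility metadata for downstream FEM
#' use.
#'
#' @param coefficients numeric vector C_i0, i = 1..N (MPa), N in 1..3.
#' @param region_label tissue region.
#' @param poisson Poisson ratio metadata.
#' @return object of class `reduced_polynomial_model`.
#' @export
reduced_polynomial_model <- function(coefficients, region_label = "sclera",
                                     poisson = 0.495) {
  coefficients <- as.numeric(coefficients)
  N <- length(coefficients)
  if (N < 1 || N > 3) stop("model order must be 1, 2 or 3")
  if (coefficients[1] <= 0)
    stop("C_10 must be positive (got ", coefficients[1], ")")
  structure(list(order = N, coefficients = coefficients,
                 region = region_label, poisson = poisson),
            class = "reduced_polynomial_model")
}

#' @export
print.reduced_polynomial_model <- function(x, ...) {
  cat("reduced-polynomial model (", x$region, "), order ", x$order,
      ": C_i0 = ", paste(format(x$coefficients, digits = 5),
                         collapse = ", "), " MPa\n", sep = "")
  invisible(x)
}

#' Uniaxial nominal stress of a reduced-polynomial material
#'
#' For an incompressible uniaxial stretch lambda = 1 + strain, the first
#' deviatoric invariant is I1 = lambda^2 + 2/lambda and the nominal
#' (engineering) stress is
#' \deqn{P(\lambda) = 2 (\lambda - \lambda^{-2})
#'       \sum_i i\, C_{i0} (\bar I_1 - 3)^{i-1}.}
#' The small-strain slope is dP/d(eps) = 6 C_10 at eps = 0 (E = 3 mu with
#' mu = 2 C_10).
#'
#' @param model a `reduced_polynomial_model`.
#' @param strain engineering strain(s), > -1.
#' @return nominal stress (MPa).
#' @export
uniaxial_nominal_stress <- function(model, strain) {
  if (any(strain <= -1)) stop("strain must exceed -1")
  lam <- 1 + strain
  i1 <- lam^2 + 2 / lam
  s <- 0
  for (i in seq_len(model$order))
    s <- s + i * model$coefficients[i] * (i1 - 3)^(i - 1)
  2 * (lam - lam^-2) * s
}

#' Fit a reduced-polynomial model to uniaxial stress-strain data
#'
#' The nominal stress is linear in the coefficients C_i0, so the fit is an
#' ordinary least-squares regression of stress on the order-wise basis
#' responses 2 i (lambda - lambda^-2)(I1 - 3)^(i-1), without intercept.
#' Deterministic; fails with diagnostics when the leading coefficient
#' comes out non-positive.
#'
#' @param curve a `stress_strain_curve`.
#' @param order model order 1..3.
#' @return a `reduced_polynomial_model` with attributes `r_squared` and
#'   `residual_rms`.
#' @export
fit_reduced_polynomial <- function(curve, order = 2) {
  stopifnot(order >= 1, order <= 3)
  eps <- curve$strain; sig <- curve$stress
  keep <- eps > -1
  eps <- eps[keep]; sig <- sig[keep]
  if (length(eps) < order + 1) stop("too few samples for order ", order)
  lam <- 1 + eps
  i1 <- lam^2 + 2 / lam
  B <- sapply(seq_len(order), function(i)
    2 * i * (lam - lam^-2) * (i1 - 3)^(i - 1))
  B <- cbind(B)
  cf <- qr.solve(B, sig)
  if (cf[1] <= 0)
    stop("fit failure: C_10 = ", format(cf[1], digits = 4),
         " MPa is not positive; the data do not resemble a ",
         "strain-stiffening incompressible solid at order ", order)
  pred <- as.numeric(B %*% cf)
  sst <- sum((sig - mean(sig))^2)
  r2 <- if (sst > 0) 1 - sum((sig - pred)^2) / sst else NA_real_
  m <- reduced_polynomial_model(cf, region_label = curve$region)
  attr(m, "r_squared") <- r2
  attr(m, "residual_rms") <- sqrt(mean((sig - pred)^2))
  m
}

#' Pre-stretch specification
#'
#' Baseline tension of the ON and its sheath at the adduction tethering
#' threshold, modeled as a rigid translation of the stress-strain curve
#' along the strain axis toward higher strains.
#'
#' @param shift strain-fraction shift (default 0.05).
#' @return object of class `prestretch_spec`.
#' @export
prestretch_spec <- function(shift = 0.05) {
  stopifnot(shift >= 0)
  structure(list(shift = shift), class = "prestretch_spec")
}

#' Translate a stress-strain curve along the strain axis
#'
#' Applies the pre-stretch: every strain sample is increased by the shift,
#' stresses unchanged.  Applying 0.025 twice equals applying 0.05 once.
#'
#' @param curve a `stress_strain_curve`.
#' @param spec a [prestretch_spec()].
#' @return the shifted `stress_strain_curve`.
#' @export
apply_prestretch <- function(curve, spec = prestretch_spec()) {
  stopifnot(inherits(spec, "prestretch_spec"))
  out <- curve
  out$strain <- curve$strain + spec$shift
  out
}

#' Lamina cribrosa curve as the ON / peripapillary-sclera average
#'
#' The lamina cribrosa is too small for direct tensile testing; its curve
#' is constructed as the pointwise mean of the ON and peripapillary scleral
#' stresses on a common strain grid (linear interpolation, 200 uniform
#' points over the overlap of the two strain ranges).
#'
#' @param on,pps `stress_strain_curve`s for the optic nerve and
#'   peripapillary sclera.
#' @param n_grid number of grid points.
#' @return a `stress_strain_curve` labelled "lamina_cribrosa".
#' @export
lamina_curve <- function(on, pps, n_grid = 200) {
  lo <- max(min(on$strain), min(pps$strain))
  hi <- min(max(on$strain), max(pps$strain))
  if (hi <= lo) stop("strain ranges do not overlap")
  grid <- seq(lo, hi, length.out = n_grid)
  s1 <- stats::approx(on$strain, on$stress, grid)$y
  s2 <- stats::approx(pps$strain, pps$stress, grid)$y
  stress_strain_curve(grid, (s1 + s2) / 2, "lamina_cribrosa")
}

#' Serialize a material model as JSON / a plain-text material card
#'
#' @param model a `reduced_polynomial_model`.
#' @param path output path.
#' @export
write_material_json <- function(model, path) {
  jsonlite::write_json(list(region = model$region, order = model$order,
                            coefficients = model$coefficients,
                            poisson = model$poisson,
                            r_squared = attr(model, "r_squared")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_material_json
#' @param strain_max,n_samples tabulation range for the material card.
#' @export
write_material_card <- function(model, path, strain_max = 0.1,
                                n_samples = 50) {
  eps <- seq(0, strain_max, length.out = n_samples)
  lines <- c(sprintf("* reduced polynomial, order %d, region %s",
                     model$order, model$region),
             sprintf("* C_%d0 = %.8g MPa", seq_len(model$order),
                     model$coefficients),
             sprintf("* poisson = %g", model$poisson),
             "strain,stress_mpa",
             sprintf("%.10g,%.10g", eps,
                     uniaxial_nominal_stress(model, eps)))
  writeLines(lines, path)
  invisible(path)
}
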