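#' Raw uniaxial tensile record
#'
#' Force and grip-separation samples from a uniaxial pull (5 Hz in the
#' physical rig), plus the specimen cross-section.  The strain reference is
#' the grip separation at the preload force (0.02 N by default); this
#' choice shifts all strains and therefore the tangent moduli, so it is
#' stated prominently here.
#'
#' @param force force samples (N).
#' @param grip_length grip separation samples (mm).
#' @param width,thickness specimen cross-section (mm).
#' @param region_label one of "anterior", "equatorial", "posterior",
#'   "peripapillary", "ON", "ON_sheath".
#' @param preload preload force (N) defining the strain reference.
#' @param sample_rate_hz sampling rate (metadata).
#' @return object of class `tensile_record`.
#' @export
tensile_record <- function(force, grip_length, width, thickness,
                           region_label = "ON_sheath", preload = 0.02,
                           sample_rate_hz = 5) {
  stopifnot(length(force) == length(grip_length), width > 0,
            thickness > 0, preload >= 0)
  region_label <- match.arg(region_label,
                            c("anterior", "equatorial", "posterior",
                              "peripapillary", "ON", "ON_sheath",
                              "lamina_cribrosa"))
  structure(list(force = as.numeric(force),
                 grip_length = as.numeric(grip_length),
                 width = width, thickness = thickness,
                 region = region_label, preload = preload,
                 sample_rate_hz = sample_rate_hz),
            class = "tensile_record")
}

#' Engineering stress-strain curve
#'
#' @param strain engineering strain samples (dimensionless, from 0).
#' @param stress engineering stress samples (MPa).
#' @param region_label tissue region.
#' @param truncation index at which the record was truncated (rupture), or
#'   NA.
#' @return object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(strain, stress, region_label = "ON_sheath",
                                truncation = NA_integer_) {
  stopifnot(length(strain) == length(stress))
  structure(list(strain = as.numeric(strain), stress = as.numeric(stress),
                 region = region_label, truncation = truncation),
            class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat("stress-strain curve (", x$region, "): ", length(x$strain),
      " samples, strain 0..", format(max(x$strain), digits = 3),
      ", peak stress ", format(max(x$stress), digits = 4), " MPa\n",
      sep = "")
  invisible(x)
}

#' Convert a force-elongation record to engineering stress-strain
#'
#' Engineering strain is (L - L0)/L0 with L0 the grip separation at the
#' preload force; engineering stress is F / (width x thickness).  Samples
#' before the preload is reached are dropped; samples after the force
#' maximum (rupture) are truncated.  The preload stress is NOT subtracted:
#' the curve starts at sigma(0) = preload / (width x thickness).
#'
#' @param rec a [tensile_record()].
#' @return a `stress_strain_curve`.
#' @export
to_stress_strain <- function(rec) {
  stopifnot(inherits(rec, "tensile_record"))
  area <- rec$width * rec$thickness
  if (area <= 0) stop("zero cross-section")
  i0 <- which(rec$force >= rec$preload)[1]
  if (is.na(i0)) stop("record never reaches the preload force")
  L0 <- rec$grip_length[i0]
  if (L0 <= 0) stop("non-positive gauge length at preload")
  idx <- i0:length(rec$force)
  F <- rec$force[idx]; L <- rec$grip_length[idx]
  if (any(diff(L) < 0))
    warning("non-monotonic grip length; samples kept as recorded")
  i_rup <- which.max(F)
  trunc <- if (i_rup < length(F)) i_rup else NA_integer_
  keep <- seq_len(i_rup)
  stress_strain_curve(strain = (L[keep] - L0) / L0,
                      stress = F[keep] / area,
                      region_label = rec$region,
                      truncation = trunc)
}

#' Tangent moduli from a polynomial fit
#'
#' Fits the stress-strain curve with a polynomial whose order (3 to 5 by
#' default) is chosen by adjusted R^2 (ties go to the lowest order; a fixed
#' `order` overrides the selection), then evaluates the derivative
#' d(sigma)/d(epsilon) at the requested strains.  Strain points beyond the
#' data range are flagged and return NA.
#'
#' @param curve a `stress_strain_curve`.
#' @param strain_points strains at which to evaluate the modulus.
#' @param order_range candidate polynomial orders.
#' @param order optional fixed order (manual override).
#' @return data.frame with columns strain, modulus_mpa, in_range; the
#'   chosen order and the fit are attached as attributes `order` and
#'   `coefficients`.
#' @export
fit_tangent_moduli <- function(curve, strain_points = c(0.03, 0.06, 0.07),
                               order_range = 3:5, order = NULL) {
  eps <- curve$strain; sig <- curve$stress
  n <- length(eps)
  if (is.null(order)) {
    adj <- sapply(order_range, function(k) {
      if (n <= k + 1) return(-Inf)
      fit <- stats::lm(sig ~ stats::poly(eps, k, raw = TRUE))
      sse <- sum(stats::residuals(fit)^2)
      sst <- sum((sig - mean(sig))^2)
      if (sst <= 0) return(-Inf)
      1 - (sse / sst) * (n - 1) / (n - k - 1)
    })
    # lowest order within numerical tie of the best
    best <- max(adj)
    order <- order_range[which(adj >= best - 1e-9)[1]]
  }
  fit <- stats::lm(sig ~ stats::poly(eps, order, raw = TRUE))
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  dcf <- cf[-1] * seq_len(order)  # derivative coefficients
  modulus <- sapply(strain_points, function(e)
    sum(dcf * e^(seq_len(order) - 1)))
  in_range <- strain_points >= min(eps) & strain_points <= max(eps)
  modulus[!in_range] <- NA_real_
  out <- data.frame(strain = strain_points, modulus_mpa = modulus,
                    in_range = in_range)
  attr(out, "order") <- order
  attr(out, "coefficients") <- cf
  out
}

#' Bilinear log-log regression for toe-region detection
#'
#' Transforms the curve to (log strain, log stress), then exhaustively
#' searches every interior breakpoint (each sample index with at least
#' `min_seg` points per segment), fits an independent ordinary
#' least-squares line to each segment, and keeps the split minimizing the
#' total squared error.  The transition strain is the abscissa of the two
#' lines' intersection, exponentiated back to strain units.  Natural logs
#' are used; the base affects neither the slopes' ratio nor the transition.
#'
#' @param curve a `stress_strain_curve`.
#' @param min_seg minimum samples per segment.
#' @param slope_tol slopes closer than this are declared degenerate (a
#'   single power law).
#' @return object of class `bilinear_fit` with `transition_strain`,
#'   `slope_low`, `slope_high`, `intercept_low`, `intercept_high`,
#'   `r2_low`, `r2_high`, `sse_total`, `degenerate`, `out_of_range`,
#'   `break_index`, and the candidate SSE profile `sse_by_break`.
#' @export
bilinear_loglog <- function(curve, min_seg = 4, slope_tol = 0.05) {
  ok <- curve$strain > 0 & curve$stress > 0
  x <- log(curve$strain[ok]); y <- log(curve$stress[ok])
  n <- length(x)
  if (n < 8) stop("need at least 8 samples with positive stress and strain")
  if (n < 2 * min_seg)
    stop("no interior breakpoint leaves ", min_seg, " points per segment")
  ls_line <- function(xx, yy) {
    mx <- mean(xx); my <- mean(yy)
    sxx <- sum((xx - mx)^2)
    b <- sum((xx - mx) * (yy - my)) / sxx
    a <- my - b * mx
    res <- yy - a - b * xx
    sst <- sum((yy - my)^2)
    list(slope = b, intercept = a, sse = sum(res^2),
         r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_)
  }
  cand <- min_seg:(n - min_seg)
  sse <- rep(NA_real_, length(cand))
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    k <- cand[i]
    f1 <- ls_line(x[1:k], y[1:k])
    f2 <- ls_line(x[(k + 1):n], y[(k + 1):n])
    sse[i] <- f1$sse + f2$sse
    fits[[i]] <- list(f1, f2)
  }
  ib <- which.min(sse)
  f1 <- fits[[ib]][[1]]; f2 <- fits[[ib]][[2]]
  degenerate <- abs(f2$slope - f1$slope) < slope_tol
  x_star <- if (degenerate) NA_real_ else
    (f1$intercept - f2$intercept) / (f2$slope - f1$slope)
  transition <- exp(x_star)
  out_of_range <- !degenerate &&
    (x_star < min(x) || x_star > max(x))
  structure(list(transition_strain = transition,
                 slope_low = f1$slope, slope_high = f2$slope,
                 intercept_low = f1$intercept,
                 intercept_high = f2$intercept,
                 r2_low = f1$r2, r2_high = f2$r2,
                 sse_total = sse[ib], degenerate = degenerate,
                 out_of_range = out_of_range,
                 break_index = cand[ib],
                 sse_by_break = stats::setNames(sse, cand)),
            class = "bilinear_fit")
}

#' @export
print.bilinear_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("bilinear log-log fit: degenerate (single power law), slopes ",
        format(x$slope_low, digits = 4), " / ",
        format(x$slope_high, digits = 4), "\n", sep = "")
  } else {
    cat("bilinear log-log fit: transition at ",
        format(100 * x$transition_strain, digits = 3), "% strain; slopes ",
        format(x$slope_low, digits = 4), " -> ",
        format(x$slope_high, digits = 4), "; R2 ",
        format(x$r2_low, digits = 3), " / ",
        format(x$r2_high, digits = 3),
        if (x$out_of_range) " (intersection outside data range)" else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Plot a stress-strain curve with its bilinear log-log fit
#'
#' @param curve a `stress_strain_curve`.
#' @param fit optional `bilinear_fit` to overlay (log-log panel).
#' @param path optional PNG output path.
#' @export
plot_tensile <- function(curve, fit = NULL, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 450)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(curve$strain, curve$stress, type = "l",
                 xlab = "engineering strain",
                 ylab = "engineering stress (MPa)", main = curve$region)
  ok <- curve$strain > 0 & curve$stress > 0
  graphics::plot(curve$strain[ok], curve$stress[ok], log = "xy",
                 type = "p", pch = 20, cex = 0.5,
                 xlab = "strain (log)", ylab = "stress (log, MPa)",
                 main = "log-log")
  if (!is.null(fit) && !fit$degenerate) {
    xx <- range(log(curve$strain[ok]))
    lo <- seq(xx[1], log(fit$transition_strain), length.out = 20)
    hi <- seq(log(fit$transition_strain), xx[2], length.out = 20)
    graphics::lines(exp(lo), exp(fit$intercept_low + fit$slope_low * lo),
                    col = 2)
    graphics::lines(exp(hi), exp(fit$intercept_high + fit$slope_high * hi),
                    col = 4)
    graphics::abline(v = fit$transition_strain, lty = 3)
  }
  invisible(NULL)
}

#' Read a tensile record from CSV plus a YAML sidecar
#'
#' CSV columns: time_s, force_N, length_mm.  The YAML sidecar supplies
#' width_mm, thickness_mm, region, and optionally preload_N.
#'
#' @param csv_path record CSV.
#' @param yaml_path sidecar with specimen dimensions.
#' @return a `tensile_record`.
#' @export
read_tensile_csv <- function(csv_path, yaml_path) {
  d <- utils::read.csv(csv_path)
  stopifnot(all(c("force_N", "length_mm") %in% names(d)))
  meta <- yaml::read_yaml(yaml_path)
  tensile_record(force = d$force_N, grip_length = d$length_mm,
                 width = meta$width_mm, thickness = meta$thickness_mm,
                 region_label = meta$region,
                 preload = if (!is.null(meta$preload_N)) meta$preload_N
                           else 0.02)
}
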