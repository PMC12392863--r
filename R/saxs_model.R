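#' SAXS curve container
#'
#' A measured or synthetic small-angle scattering curve: momentum transfer
#' `q = 4 pi sin(theta) / lambda` (nm^-1, strictly increasing), intensity
#' `I` and, when available, pointwise uncertainties `sigma > 0`.
#'
#' @param q strictly increasing positive scattering vector, nm^-1.
#' @param I intensities.
#' @param sigma optional positive uncertainties, same length as `q`.
#' @return an object of class `saxs_curve` (a data frame).
#' @export
saxs_curve <- function(q, I, sigma = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("q and I must have equal length", call. = FALSE)
  if (any(q <= 0) || any(diff(q) <= 0))
    stop("q must be positive and strictly increasing", call. = FALSE)
  d <- data.frame(q = q, I = I)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q) || any(sigma <= 0))
      stop("sigma must be positive and match q in length", call. = FALSE)
    d$sigma <- sigma
  }
  class(d) <- c("saxs_curve", "data.frame")
  d
}

#' Read a 3-column SAXS data file
#'
#' Whitespace- or comma-separated text with columns q, I, sigma. Leading
#' header/comment lines (starting with `#` or non-numeric) are skipped.
#' `q` in Angstrom^-1 can be converted with `q_unit = "A"`.
#'
#' @param path file path.
#' @param q_unit `"nm"` (default) or `"A"`; Angstrom^-1 input is multiplied
#'   by 10 to give nm^-1.
#' @return a [saxs_curve()].
#' @export
read_saxs_curve <- function(path, q_unit = c("nm", "A")) {
  q_unit <- match.arg(q_unit)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "[[:space:],]+")
  numeric_row <- vapply(fields, function(f)
    length(f) >= 2 && !anyNA(suppressWarnings(as.numeric(f[1:2]))), logical(1))
  fields <- fields[numeric_row]
  if (!length(fields)) stop("no numeric data rows in ", path, call. = FALSE)
  mat <- t(vapply(fields, function(f)
    suppressWarnings(as.numeric(f[1:3])), numeric(3)))
  q <- mat[, 1]
  if (q_unit == "A") q <- q * 10
  sig <- if (all(is.finite(mat[, 3]))) mat[, 3] else NULL
  saxs_curve(q, mat[, 2], sig)
}

#' Gaussian-chain (Debye) form factor
#'
#' Normalized form factor of a Gaussian polymer chain with radius of
#' gyration `Rg`: `P(x) = 2 (exp(-x) - 1 + x) / x^2` with `x = q^2 Rg^2`.
#' A series expansion is used for `x < 1e-4` so that `P(0) = 1` exactly.
#'
#' @param q scattering vector, nm^-1 (vector).
#' @param Rg radius of gyration, nm; > 0.
#' @return P(q) in \[0, 1\].
#' @export
debye_chain_ff <- function(q, Rg) {
  stop_scalar(Rg, "Rg", positive = TRUE)
  x <- (q * Rg)^2
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 12
  out[!small] <- 2 * (exp(-x[!small]) - 1 + x[!small]) / x[!small]^2
  out
}

# Gauss-Legendre nodes for the orientation average. The axial factor
# sinc(q L cos(alpha) / 2) oscillates ~ q L / (2 pi) times over the alpha
# domain, so the alpha node count is scaled with max(q) * L.
ecyl_nodes <- function(q_max, L, n_alpha = NULL, n_phi = 32) {
  if (is.null(n_alpha))
    n_alpha <- min(4096, max(128L, ceiling(0.5 * q_max * L + 40)))
  list(alpha = pracma::gaussLegendre(n_alpha, 0, pi / 2),
       phi = pracma::gaussLegendre(n_phi, 0, pi / 2))
}

#' Elliptical-cylinder form factor with graded surface
#'
#' Orientation-averaged normalized form factor of a cylinder of length `L`
#' with elliptical cross-section (semi-minor axis `R`, semi-major
#' `eps * R`) and a diffuse surface of grading length `sigma_surf`.
#' The amplitude at tilt `alpha` and cross-section azimuth `phi` is
#' `A = [2 J1(u)/u] * sinc(q L cos(alpha)/2) * exp(-(q sin(alpha))^2 sigma_surf^2 / 2)`
#' with `u = q sin(alpha) r(phi)` and
#' `r(phi) = R sqrt(cos^2(phi) + eps^2 sin^2(phi))`; `P(q)` is the average
#' of `A^2` over `alpha` (weight `sin(alpha)`) and `phi`, normalized so
#' that `P(0) = 1`. The average is computed by Gauss-Legendre quadrature on
#' the symmetry-reduced domain `alpha, phi in [0, pi/2]`; alpha node counts
#' scale with `q L` to resolve the axial oscillations.
#'
#' @param q scattering vector, nm^-1 (vector; zeros allowed and mapped to 1).
#' @param R semi-minor cross-section axis, nm; > 0.
#' @param eps axis ratio >= 1 (semi-major = eps * R).
#' @param L cylinder length, nm; > 0.
#' @param sigma_surf surface grading length, nm; >= 0.
#' @param n_alpha,n_phi quadrature node counts; `n_alpha = NULL` picks
#'   `max(128, 0.5 * max(q) * L + 40)`.
#' @return P(q) in \[0, 1\].
#' @export
elliptical_cylinder_ff <- function(q, R, eps, L, sigma_surf = 0,
                                   n_alpha = NULL, n_phi = 32) {
  stop_scalar(R, "R", positive = TRUE)
  stop_scalar(eps, "eps")
  if (eps < 1) stop("'eps' must be >= 1", call. = FALSE)
  stop_scalar(L, "L", positive = TRUE)
  stop_scalar(sigma_surf, "sigma_surf")
  if (sigma_surf < 0) stop("'sigma_surf' must be >= 0", call. = FALSE)
  nodes <- ecyl_nodes(max(q), L, n_alpha, n_phi)
  a <- nodes$alpha$x; wa <- nodes$alpha$w
  ph <- nodes$phi$x; wp <- nodes$phi$w
  sa <- sin(a); ca <- cos(a)
  r_phi <- R * sqrt(cos(ph)^2 + eps^2 * sin(ph)^2)
  # weight including the sin(alpha) orientation measure; total weight pi/2
  w_alpha <- wa * sa
  norm <- sum(w_alpha) * sum(wp)
  # 2 J1(u)/u is needed on n_q * n_alpha * n_phi products; tabulating it on
  # a dense grid and interpolating with a cubic spline (error ~ h^4, i.e.
  # ~1e-12 at h = 1e-3) is much cheaper than per-element Bessel calls
  u_max <- max(q) * max(r_phi) * (1 + 1e-9)
  n_el <- length(q) * length(a) * length(ph)
  amp_fun <- if (n_el > 50000) {
    ug <- seq(0, u_max, length.out = max(2001L, ceiling(u_max / 1e-3) + 1L))
    gv <- c(1, 2 * besselJ(ug[-1], 1) / ug[-1])
    stats::splinefun(ug, gv, method = "fmm")
  } else {
    function(u) {
      g <- 2 * besselJ(u, 1) / u
      g[u < 1e-12] <- 1
      g
    }
  }
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    qi <- q[i]
    if (qi == 0) { out[i] <- 1; next }
    axial <- sinc(qi * L * ca / 2) * exp(-(qi * sa)^2 * sigma_surf^2 / 2)
    u <- (qi * sa) %o% r_phi          # always > 0 on interior GL nodes
    amp <- amp_fun(u)
    A2 <- (amp * axial)^2
    dim(A2) <- dim(u)
    out[i] <- as.numeric(w_alpha %*% A2 %*% wp) / norm
  }
  out
}

#' Elliptical-cylinder model parameters
#'
#' Parameter set of the two-component fibril scattering model: a cylinder
#' with elliptical cross-section representing the fibril core plus a
#' Gaussian-chain term for disordered regions (linkers, termini) and a flat
#' background,
#' `I(q) = S_cyl P_cyl(q; R, eps, L, sigma_surf) + S_pol P_pol(q; Rg) + b`.
#' The length is fixed by default at 100 nm (long enough not to influence
#' the cross-section q range) and the surface grading at 0.5 nm.
#'
#' @param R semi-minor cross-section axis, nm.
#' @param eps axis ratio >= 1; the full cross-section is `2R x 2*eps*R`.
#' @param L cylinder length, nm (default 100, conventionally fixed).
#' @param sigma_surf surface grading, nm (default 0.5, conventionally fixed).
#' @param S_cyl,S_pol nonnegative scale factors of the two terms.
#' @param Rg polymer radius of gyration, nm; > 0.
#' @param b residual background.
#' @return an object of class `cylinder_params`.
#' @export
cylinder_params <- function(R, eps, L = 100, sigma_surf = 0.5,
                            S_cyl = 1, S_pol = 0, Rg = 2, b = 0) {
  stop_scalar(R, "R", positive = TRUE)
  stop_scalar(eps, "eps")
  if (eps < 1) stop("'eps' must be >= 1", call. = FALSE)
  stop_scalar(L, "L", positive = TRUE)
  stop_scalar(sigma_surf, "sigma_surf")
  stop_scalar(S_cyl, "S_cyl"); stop_scalar(S_pol, "S_pol")
  if (S_cyl < 0 || S_pol < 0) stop("scales must be >= 0", call. = FALSE)
  stop_scalar(Rg, "Rg", positive = TRUE)
  stop_scalar(b, "b")
  structure(list(R = R, eps = eps, L = L, sigma_surf = sigma_surf,
                 S_cyl = S_cyl, S_pol = S_pol, Rg = Rg, b = b),
            class = "cylinder_params")
}

#' @export
print.cylinder_params <- function(x, ...) {
  cs <- cross_section_report(x)
  cat(sprintf(
    "cylinder model: cross-section %.2f x %.2f nm (R %.3f, eps %.3f), L %.4g nm, grading %.2f nm\n",
    cs[["minor_nm"]], cs[["major_nm"]], x$R, x$eps, x$L, x$sigma_surf))
  cat(sprintf("  S_cyl %.4g, S_pol %.4g, Rg %.3f nm, b %.4g\n",
              x$S_cyl, x$S_pol, x$Rg, x$b))
  invisible(x)
}

#' Model intensity of the cylinder + polymer model
#'
#' @param q scattering vector, nm^-1.
#' @param p a [cylinder_params()] object.
#' @param n_alpha,n_phi quadrature controls passed to
#'   [elliptical_cylinder_ff()].
#' @return intensity vector over `q`.
#' @export
model_intensity <- function(q, p, n_alpha = NULL, n_phi = 32) {
  stopifnot(inherits(p, "cylinder_params"))
  p$S_cyl * elliptical_cylinder_ff(q, p$R, p$eps, p$L, p$sigma_surf,
                                   n_alpha = n_alpha, n_phi = n_phi) +
    p$S_pol * debye_chain_ff(q, p$Rg) + p$b
}

#' Full cross-section axes of a cylinder model
#'
#' Reports the cross-section as full axes, `(2R, 2 eps R)` in nm — the
#' convention in which fibril cross-sections such as 3.4 x 11.3 nm^2 are
#' quoted.
#'
#' @param p a [cylinder_params()] object.
#' @return named numeric vector `c(minor_nm, major_nm)`.
#' @export
cross_section_report <- function(p) {
  stopifnot(inherits(p, "cylinder_params"))
  c(minor_nm = 2 * p$R, major_nm = 2 * p$eps * p$R)
}

# Profile the linear parameters (S_cyl, S_pol, b) by weighted least squares
# given the two form-factor columns; scales clamped at zero (active-set on
# the nonnegativity constraints, at most 2 of them).
profile_linear <- function(Pcyl, Ppol, I, w, fit_b = TRUE,
                           fixed = list()) {
  cols <- list()
  if (is.null(fixed$S_cyl)) cols$S_cyl <- Pcyl
  if (is.null(fixed$S_pol)) cols$S_pol <- Ppol
  if (fit_b && is.null(fixed$b)) cols$b <- rep(1, length(I))
  y <- I -
    (if (!is.null(fixed$S_cyl)) fixed$S_cyl * Pcyl else 0) -
    (if (!is.null(fixed$S_pol)) fixed$S_pol * Ppol else 0) -
    (if (!is.null(fixed$b)) fixed$b else 0)
  est <- c(S_cyl = fixed$S_cyl, S_pol = fixed$S_pol, b = fixed$b)
  solve_subset <- function(active) {
    if (!length(active)) return(numeric(0))
    X <- do.call(cbind, cols[active])
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% y),
                     error = function(e) rep(0, length(active)))
    drop(beta)
  }
  active <- names(cols)
  repeat {
    beta <- solve_subset(active)
    names(beta) <- active
    neg <- active[active %in% c("S_cyl", "S_pol") & beta < 0]
    if (!length(neg)) break
    active <- setdiff(active, neg[which.min(beta[neg])])
  }
  out <- c(S_cyl = 0, S_pol = 0, b = 0)
  out[names(beta)] <- beta
  if (!is.null(fixed$S_cyl)) out["S_cyl"] <- fixed$S_cyl
  if (!is.null(fixed$S_pol)) out["S_pol"] <- fixed$S_pol
  if (!is.null(fixed$b)) out["b"] <- fixed$b
  out
}

#' Fit the cylinder + polymer model to a SAXS curve
#'
#' Weighted least squares minimizing `sum(((I_model - I) / sigma)^2)`. The
#' shape parameters (`R`, `eps`, `Rg`, and optionally `L`, `sigma_surf`)
#' are optimized by a Nelder-Mead start followed by a BFGS polish in a
#' log-transformed space that enforces `R, Rg, L > 0` and `eps >= 1`; the
#' scale factors and background are profiled out at every step by
#' closed-form weighted linear least squares with the scales clamped
#' nonnegative. `L` and `sigma_surf` are fixed by default. The fit is
#' deterministic given the initial values.
#'
#' @param curve a [saxs_curve()] with uncertainties.
#' @param init a [cylinder_params()] object with starting values.
#' @param fixed character vector of parameter names held at their `init`
#'   values; any of `"R"`, `"eps"`, `"Rg"`, `"L"`, `"sigma_surf"`,
#'   `"S_cyl"`, `"S_pol"`, `"b"`. Default fixes `L` and `sigma_surf`.
#' @param n_alpha,n_phi quadrature controls for the cylinder form factor.
#' @return a list of class `saxs_fit` with elements `params`
#'   (fitted [cylinder_params()]), `fixed`, `chi2`, `chi2_red`, `n_points`,
#'   `n_free`, `converged` and `fitted` (model curve at the data `q`).
#' @export
fit_cylinder_model <- function(curve, init, fixed = c("L", "sigma_surf"),
                               n_alpha = NULL, n_phi = 32) {
  stopifnot(inherits(curve, "saxs_curve"), inherits(init, "cylinder_params"))
  if (is.null(curve$sigma)) stop("curve must carry uncertainties", call. = FALSE)
  all_names <- c("R", "eps", "Rg", "L", "sigma_surf", "S_cyl", "S_pol", "b")
  fixed <- as.character(fixed)
  if (length(bad <- setdiff(fixed, all_names)))
    stop("unknown parameter in 'fixed': ", paste(bad, collapse = ", "),
         call. = FALSE)
  shape_all <- c("R", "eps", "Rg", "L", "sigma_surf")
  shape_free <- setdiff(shape_all, fixed)
  lin_fixed <- list()
  for (nm in intersect(c("S_cyl", "S_pol", "b"), fixed))
    lin_fixed[[nm]] <- init[[nm]]
  n_free <- length(shape_free) + length(setdiff(c("S_cyl", "S_pol", "b"), fixed))
  if (nrow(curve) <= n_free)
    stop("need more data points than free parameters", call. = FALSE)

  w <- 1 / curve$sigma^2
  nodes_n_alpha <- if (is.null(n_alpha))
    min(4096, max(128L, ceiling(0.5 * max(curve$q) * init$L + 40))) else n_alpha

  to_theta <- function(p) {
    th <- c(R = log(p$R), eps = log(max(p$eps - 1, 1e-6)), Rg = log(p$Rg),
            L = log(p$L), sigma_surf = log(max(p$sigma_surf, 1e-6)))
    th[shape_free]
  }
  from_theta <- function(th) {
    p <- init
    if ("R" %in% shape_free) p$R <- exp(th[["R"]])
    if ("eps" %in% shape_free) p$eps <- 1 + exp(th[["eps"]])
    if ("Rg" %in% shape_free) p$Rg <- exp(th[["Rg"]])
    if ("L" %in% shape_free) p$L <- exp(th[["L"]])
    if ("sigma_surf" %in% shape_free) p$sigma_surf <- exp(th[["sigma_surf"]])
    p
  }
  eval_fit <- function(th, na = nodes_n_alpha, np = n_phi) {
    p <- from_theta(th)
    Pcyl <- elliptical_cylinder_ff(curve$q, p$R, p$eps, p$L, p$sigma_surf,
                                   n_alpha = na, n_phi = np)
    Ppol <- debye_chain_ff(curve$q, p$Rg)
    lin <- profile_linear(Pcyl, Ppol, curve$I, w, fixed = lin_fixed)
    Imod <- lin[["S_cyl"]] * Pcyl + lin[["S_pol"]] * Ppol + lin[["b"]]
    list(chi2 = sum(w * (Imod - curve$I)^2), p = p, lin = lin, Imod = Imod)
  }
  make_objective <- function(na, np) function(th) {
    names(th) <- shape_free
    # extreme line-search steps can under/overflow the log transform;
    # treat any invalid trial point as a very poor fit
    val <- tryCatch(eval_fit(th, na, np)$chi2, error = function(e) Inf)
    if (!is.finite(val)) 1e300 else val
  }

  converged <- TRUE
  if (length(shape_free)) {
    th0 <- to_theta(init)
    # coarse quadrature localizes the optimum cheaply ...
    coarse <- make_objective(min(nodes_n_alpha, 96L), min(n_phi, 16L))
    o1 <- stats::optim(th0, coarse, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-9))
    # ... then polish at full accuracy
    fine <- make_objective(nodes_n_alpha, n_phi)
    o2 <- suppressWarnings(
      stats::optim(o1$par, fine, method = "BFGS",
                   control = list(maxit = 30, reltol = 1e-14)))
    # restarted simplexes until the fine objective stagnates; chi2 changes
    # are judged on the natural chi2 scale (~ n_points for a noise-matched
    # fit)
    best <- o2
    converged <- FALSE
    for (restart in 1:3) {
      o3 <- stats::optim(best$par, fine, method = "Nelder-Mead",
                         control = list(maxit = 200, reltol = 1e-12))
      stalled <- abs(o3$value - best$value) <= 1e-6 * nrow(curve)
      if (o3$value <= best$value) best <- o3
      if (o3$convergence == 0 || stalled) { converged <- TRUE; break }
    }
    th <- best$par
    names(th) <- shape_free
  } else th <- numeric(0)

  final <- eval_fit(th)
  p <- final$p
  p$S_cyl <- final$lin[["S_cyl"]]; p$S_pol <- final$lin[["S_pol"]]
  p$b <- final$lin[["b"]]
  structure(list(
    params = p, fixed = fixed, chi2 = final$chi2,
    chi2_red = final$chi2 / (nrow(curve) - n_free),
    n_points = nrow(curve), n_free = n_free, converged = converged,
    fitted = saxs_curve(curve$q, final$Imod)
  ), class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("cylinder-model fit: chi2_red = %.4g (%d points, %d free)%s\n",
              x$chi2_red, x$n_points, x$n_free,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$params)
  invisible(x)
}

# Excess X-ray scattering lengths at q = 0 in electron units:
# f = Z - rho_solvent * V_displaced, with rho = 0.334 e/A^3 and
# single-atom displaced volumes (A^3) from standard solvent-excluded
# tabulations. vdw radii (A) are used for hydration-shell placement.
element_table <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "S", "P"),
    Z = c(1, 6, 7, 8, 16, 15),
    V_disp = c(5.15, 16.44, 2.49, 9.13, 19.86, 5.73),
    r_vdw = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80),
    stringsAsFactors = FALSE
  )
}

model_scattering_lengths <- function(model, rho_solvent = 0.334) {
  if (!is.null(model$f)) return(model$f)
  tab <- element_table()
  idx <- match(toupper(model$element), tab$element)
  if (anyNA(idx))
    stop("no scattering-length entry for element(s): ",
         paste(unique(model$element[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  tab$Z[idx] - rho_solvent * tab$V_disp[idx]
}

# Place hydration-shell beads on a cubic grid: grid points whose distance to
# the nearest atom lies between that atom's vdw radius and radius + thickness.
hydration_beads <- function(model, thickness_A = 3, grid_A = 2,
                            excess_frac = 0.10, rho_water = 0.334) {
  xyz <- coords_matrix(model)
  tab <- element_table()
  rv <- tab$r_vdw[match(toupper(model$element), tab$element)]
  rv[is.na(rv)] <- 1.7
  pad <- max(rv) + thickness_A
  gx <- seq(min(xyz[, 1]) - pad, max(xyz[, 1]) + pad, by = grid_A)
  gy <- seq(min(xyz[, 2]) - pad, max(xyz[, 2]) + pad, by = grid_A)
  gz <- seq(min(xyz[, 3]) - pad, max(xyz[, 3]) + pad, by = grid_A)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  keep <- logical(nrow(grid))
  inside <- logical(nrow(grid))
  # chunked distance evaluation to bound memory
  chunk <- 20000L
  for (start in seq(1L, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(grid))
    d2 <- outer(rowSums(grid[idx, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * grid[idx, , drop = FALSE] %*% t(xyz)
    d <- sqrt(pmax(d2, 0))
    dist_surf <- sweep(d, 2, rv)             # distance beyond each vdw surface
    min_surf <- apply(dist_surf, 1, min)
    keep[idx] <- min_surf > 0 & min_surf <= thickness_A
    inside[idx] <- min_surf <= 0
  }
  beads <- grid[keep & !inside, , drop = FALSE]
  f_bead <- excess_frac * rho_water * grid_A^3
  list(xyz = beads, f = rep(f_bead, nrow(beads)))
}

#' Scattering intensity of an atomic model by the Debye equation
#'
#' `I(q) = sum_i sum_j f_i f_j sinc(q r_ij)` over all scatterer pairs, with
#' per-atom excess scattering lengths (element X-ray scattering factors at
#' q = 0 minus displaced-solvent contribution) or user-supplied `f`. An
#' optional hydration layer adds shell beads on a cubic grid within a fixed
#' thickness of the van der Waals surface, with excess scattering density a
#' configurable fraction of bulk water. For large models a pair-distance
#' histogram approximation (bin width `bin_A`, default 0.1 Angstrom) is
#' available; at that bin width it agrees with the exact double sum to well
#' under 0.5% for q <= 5 nm^-1.
#'
#' @param model an [atomic_model()]; coordinates in Angstrom.
#' @param q_grid scattering vector, nm^-1.
#' @param hydration list of options: `enabled` (default FALSE),
#'   `thickness_A` (3), `grid_A` (2), `excess_frac` (0.10).
#' @param method `"exact"` double sum or `"histogram"` approximation.
#' @param bin_A histogram bin width in Angstrom.
#' @return a [saxs_curve()] (no uncertainties).
#' @export
atomic_debye_intensity <- function(model, q_grid,
                                   hydration = list(enabled = FALSE),
                                   method = c("exact", "histogram"),
                                   bin_A = 0.1) {
  stopifnot(inherits(model, "atomic_model"))
  method <- match.arg(method)
  if (nrow(model) < 1) stop("empty model", call. = FALSE)
  f <- model_scattering_lengths(model)
  xyz <- coords_matrix(model)
  if (isTRUE(hydration$enabled)) {
    hb <- do.call(hydration_beads, c(list(model = model),
                                     hydration[setdiff(names(hydration), "enabled")]))
    if (nrow(hb$xyz)) {
      xyz <- rbind(xyz, hb$xyz)
      f <- c(f, hb$f)
    }
  }
  n <- nrow(xyz)
  q_A <- q_grid / 10  # coordinates are in Angstrom; q supplied in nm^-1
  I <- numeric(length(q_grid))
  if (method == "exact") {
    D <- as.matrix(stats::dist(xyz))
    ff <- outer(f, f)
    for (i in seq_along(q_A)) I[i] <- sum(ff * sinc(q_A[i] * D))
  } else {
    d <- stats::dist(xyz)
    # pair weights f_i f_j accumulated into distance bins; dist() stores
    # pairs (i, j), i > j, column by column
    jj <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    ii <- sequence((n - 1L):1L, from = 2L:n)
    fw <- f[ii] * f[jj]
    bins <- pmax(1L, ceiling(as.numeric(d) / bin_A))
    w_b <- rowsum(fw, bins)
    r_b <- (as.numeric(rownames(w_b)) - 0.5) * bin_A
    self <- sum(f^2)
    for (i in seq_along(q_A))
      I[i] <- self + 2 * sum(w_b * sinc(q_A[i] * r_b))
  }
  saxs_curve(q_grid, I)
}

#' Scale and offset fit between a model curve and data
#'
#' Closed-form weighted linear least squares for `I_data ~ scale * I_model
#' + const`, as used when comparing a computed scattering curve with a
#' measured one; returns the reduced chi-square with 2 free parameters.
#'
#' @param model_curve a [saxs_curve()] (or numeric vector of model
#'   intensities on the data grid).
#' @param data a [saxs_curve()] with uncertainties.
#' @return list with `scale`, `const`, `chi2_red`, `n_points`, and standard
#'   errors `se_scale`, `se_const`.
#' @export
fit_scale_offset <- function(model_curve, data) {
  stopifnot(inherits(data, "saxs_curve"))
  if (is.null(data$sigma)) stop("data must carry uncertainties", call. = FALSE)
  Im <- if (inherits(model_curve, "saxs_curve")) {
    if (!isTRUE(all.equal(model_curve$q, data$q)))
      stop("model and data q grids differ; interpolate first", call. = FALSE)
    model_curve$I
  } else as.numeric(model_curve)
  n <- nrow(data)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(Im) < 1e-12 * max(abs(Im), 1))
    stop("model curve is constant: scale and offset are not identifiable",
         call. = FALSE)
  w <- 1 / data$sigma^2
  X <- cbind(Im, 1)
  XtW <- t(X * w)
  A <- XtW %*% X
  beta <- solve(A, XtW %*% data$I)
  resid <- data$I - X %*% beta
  chi2 <- sum(w * resid^2)
  covb <- solve(A)
  list(scale = beta[1], const = beta[2],
       chi2_red = chi2 / (n - 2), n_points = n,
       se_scale = sqrt(covb[1, 1]), se_const = sqrt(covb[2, 2]))
}
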