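#' Helical symmetry parameters
#'
#' A fibril's helical symmetry is the screw operation relating consecutive
#' subunits: an axial translation (`rise_A`, in Angstrom) combined with a
#' rotation about the fibril axis (`twist_deg`, in degrees). Negative twist
#' denotes a left-handed helix (rotation clockwise when viewed from +z),
#' positive twist a right-handed one. The twist is stored wrapped to
#' (-180, 180].
#'
#' @param rise_A axial rise per symmetry unit, Angstrom; must be > 0.
#' @param twist_deg rotation per symmetry unit, degrees. Stored as given
#'   (so e.g. 360 means one unit per full turn); composition via
#'   [compose_symmetry()] wraps to (-180, 180].
#' @return an object of class `helical_params` with fields `rise_A`,
#'   `twist_deg` and `handedness` (`"left"`, `"right"` or `"none"`).
#' @examples
#' helical_params(4.8, -2)
#' @export
helical_params <- function(rise_A, twist_deg) {
  stop_scalar(rise_A, "rise_A", positive = TRUE)
  stop_scalar(twist_deg, "twist_deg")
  structure(
    list(
      rise_A = rise_A,
      twist_deg = twist_deg,
      handedness = if (twist_deg < 0) "left" else if (twist_deg > 0) "right" else "none"
    ),
    class = "helical_params"
  )
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("helical symmetry: rise %.3f Angstrom, twist %.3f deg (%s-handed)\n",
              x$rise_A, x$twist_deg, x$handedness))
  if (x$twist_deg != 0)
    cat(sprintf("  crossover %.2f Angstrom (%.2f nm), half-period %.2f nm\n",
                crossover_distance(x), crossover_distance(x) / 10, half_period(x)))
  invisible(x)
}

#' Crossover distance of a twisted fibril
#'
#' Axial length over which the fibril completes a full 360 degree turn:
#' `rise_A * 360 / |twist_deg|`. Defined only for nonzero twist.
#'
#' @param p a [helical_params()] object.
#' @return crossover distance in Angstrom.
#' @examples
#' crossover_distance(helical_params(4.8, -2))   # 864
#' crossover_distance(helical_params(14.4, -6))  # 864
#' @export
crossover_distance <- function(p) {
  stopifnot(inherits(p, "helical_params"))
  if (p$twist_deg == 0)
    stop("crossover distance is undefined for zero twist", call. = FALSE)
  p$rise_A * 360 / abs(p$twist_deg)
}

#' Half-twist period in nanometres
#'
#' A twisted fibril adsorbed flat on a surface shows an apparent height
#' modulation with period equal to half the crossover distance (the fibril
#' silhouette repeats every 180 degrees of twist). Returned in nm, the unit
#' in which AFM periodicity is conventionally reported.
#'
#' @inheritParams crossover_distance
#' @return half the crossover distance, nm.
#' @examples
#' half_period(helical_params(4.8, -2))  # 43.2 nm
#' @export
half_period <- function(p) {
  crossover_distance(p) / 2 / 10
}

#' Compose a helical symmetry over n units
#'
#' The symmetry relating subunits k and k+n is the n-fold composition of the
#' one-unit screw: rise multiplied by n, twist multiplied by n and wrapped
#' to (-180, 180]. Composition leaves the crossover distance unchanged as
#' long as the composed twist magnitude does not exceed 180 degrees (beyond
#' that the wrapped generator is a different screw with the same rotation).
#'
#' @inheritParams crossover_distance
#' @param n_units number of units composed; integer >= 1.
#' @return a new [helical_params()] object.
#' @examples
#' compose_symmetry(helical_params(4.8, -2), 3)  # rise 14.4, twist -6
#' @export
compose_symmetry <- function(p, n_units) {
  stopifnot(inherits(p, "helical_params"))
  stop_scalar(n_units, "n_units")
  if (n_units < 1 || n_units != round(n_units))
    stop("'n_units' must be an integer >= 1", call. = FALSE)
  helical_params(p$rise_A * n_units, wrap_angle(p$twist_deg * n_units))
}

#' Atomic model container
#'
#' A light container for point-scatterer structures: one row per atom with
#' element, residue id, chain id, Cartesian coordinates in Angstrom, and an
#' optional excess scattering length `f` (electrons) used by
#' [atomic_debye_intensity()].
#'
#' @param element character vector of element symbols.
#' @param resid integer residue ids.
#' @param chain character chain ids.
#' @param x,y,z coordinates in Angstrom.
#' @param f optional per-atom excess scattering length (electron units).
#' @return an object of class `atomic_model` (a data frame).
#' @export
atomic_model <- function(element, resid, chain, x, y, z, f = NULL) {
  n <- length(x)
  if (n < 1) stop("an atomic model needs at least one atom", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("coordinates must be finite", call. = FALSE)
  d <- data.frame(
    element = rep_len(as.character(element), n),
    resid = rep_len(as.integer(resid), n),
    chain = rep_len(as.character(chain), n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  if (!is.null(f)) {
    stopifnot(length(f) == n)
    d$f <- as.numeric(f)
  }
  class(d) <- c("atomic_model", "data.frame")
  d
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic model: %d atoms, %d chains, extent %.1f Angstrom along z\n",
              nrow(x), length(unique(x$chain)), diff(range(x$z))))
  invisible(x)
}

coords_matrix <- function(m) {
  stopifnot(inherits(m, "atomic_model") || (is.matrix(m) && ncol(m) == 3))
  if (inherits(m, "atomic_model")) cbind(m$x, m$y, m$z) else m
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3, 3)
}

#' Build a fibril by repeated helical symmetry
#'
#' Copy k (k = 0 .. n_copies - 1) of the monomer is rotated about the z axis
#' by `k * twist_deg` (positive twist = right-handed rotation viewed from
#' +z) and translated by `k * rise_A` along z. The caller is responsible for
#' aligning the fibril axis with z beforehand (see [align_principal_axis()]).
#' Chain ids are suffixed per copy so every copy is distinguishable.
#'
#' @param monomer an [atomic_model()].
#' @param p a [helical_params()] object.
#' @param n_copies number of symmetry copies; integer >= 1.
#' @return an [atomic_model()] of `n_copies * nrow(monomer)` atoms with an
#'   integer `copy` column (1-based).
#' @export
build_helical_assembly <- function(monomer, p, n_copies) {
  stopifnot(inherits(monomer, "atomic_model"), inherits(p, "helical_params"))
  if (!is.numeric(n_copies) || length(n_copies) != 1 || n_copies < 1 ||
      n_copies != round(n_copies))
    stop("'n_copies' must be an integer >= 1", call. = FALSE)
  xyz <- coords_matrix(monomer)
  pieces <- vector("list", n_copies)
  for (k in seq_len(n_copies) - 1L) {
    rot <- xyz %*% t(rotation_z(k * p$twist_deg))
    rot[, 3] <- rot[, 3] + k * p$rise_A
    piece <- monomer
    piece$x <- rot[, 1]; piece$y <- rot[, 2]; piece$z <- rot[, 3]
    piece$chain <- paste0(monomer$chain, ".", k + 1L)
    piece$copy <- k + 1L
    pieces[[k + 1L]] <- piece
  }
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  class(out) <- c("atomic_model", "data.frame")
  out
}

#' Optimal superposition RMSD (Kabsch)
#'
#' Minimal root-mean-square deviation between two equally sized point sets
#' over all rigid-body superpositions. The optimal rotation is obtained from
#' the singular value decomposition of the cross-covariance matrix with the
#' determinant sign corrected so that only proper rotations are allowed.
#'
#' @param a,b [atomic_model()] objects or n x 3 coordinate matrices.
#' @param pairing optional list with integer vectors `a` and `b` selecting
#'   and ordering matched atoms; by default atoms are paired by position.
#' @return the minimal RMSD in the coordinate units of the inputs.
#' @export
kabsch_rmsd <- function(a, b, pairing = NULL) {
  A <- coords_matrix(a)
  B <- coords_matrix(b)
  if (!is.null(pairing)) {
    A <- A[pairing$a, , drop = FALSE]
    B <- B[pairing$b, , drop = FALSE]
  }
  if (nrow(A) != nrow(B))
    stop("point sets must have equal size after pairing", call. = FALSE)
  if (nrow(A) < 3)
    stop("at least 3 paired atoms are required", call. = FALSE)
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  # collinear or degenerate sets have a rank-<2 covariance: no unique fit
  if (qr(Ac)$rank < 2 || qr(Bc)$rank < 2)
    stop("degenerate (collinear) point set: superposition is not unique",
         call. = FALSE)
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diffs <- Bc - Ac %*% t(R)
  sqrt(mean(rowSums(diffs^2)))
}

#' Align the principal axis of a model with z
#'
#' Convenience helper for [build_helical_assembly()]: rotates the model so
#' that the largest principal axis of its coordinate covariance lies along
#' +z, and centres it at the origin.
#'
#' @param model an [atomic_model()].
#' @return the rotated, centred [atomic_model()].
#' @export
align_principal_axis <- function(model) {
  xyz <- coords_matrix(model)
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr)
  ev <- eigen(cov(xyz), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  z <- c(0, 0, 1)
  v <- pracma::cross(axis, z)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    R <- if (sum(axis * z) > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    c_ <- sum(axis * z)
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  }
  rot <- xyz %*% t(R)
  model$x <- rot[, 1]; model$y <- rot[, 2]; model$z <- rot[, 3]
  model
}

#' Read an atomic model from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] keeping element, residue, chain
#' and coordinates.
#'
#' @param path path to a PDB file.
#' @return an [atomic_model()].
#' @export
read_model_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  atomic_model(element = trimws(elem), resid = at$resno, chain = at$chain,
               x = at$x, y = at$y, z = at$z)
}

#' Write an atomic model to a PDB file
#'
#' Chain ids longer than one character (as produced by
#' [build_helical_assembly()]) are recoded to single characters cycling
#' through A-Z, a-z, 0-9.
#'
#' @param model an [atomic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  pool <- c(LETTERS, letters, as.character(0:9))
  ch <- factor(model$chain, levels = unique(model$chain))
  ch1 <- pool[(as.integer(ch) - 1L) %% length(pool) + 1L]
  xyz <- as.vector(t(coords_matrix(model)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = model$resid, chain = ch1,
                   resid = rep("GLY", nrow(model)),
                   elety = rep("CA", nrow(model)),
                   elesy = model$element)
  invisible(path)
}
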