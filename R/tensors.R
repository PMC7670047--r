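#' Elastin deposition stretch tensor
#'
#' Diagonal, unit-determinant deposition stretch of elastin in the local
#' (radial, circumferential, axial) frame: `diag(1/(lt*lz), lt, lz)`.
#'
#' @param lt Circumferential deposition stretch (> 0).
#' @param lz Axial deposition stretch (> 0).
#' @return A 3x3 matrix with determinant 1.
#' @export
deposition_stretch_elastin <- function(lt, lz) {
  if (!is.finite(lt) || !is.finite(lz) || lt <= 0 || lz <= 0) {
    stop("Deposition stretches must be positive and finite.", call. = FALSE)
  }
  diag(c(1 / (lt * lz), lt, lz))
}

#' Fiber deposition stretch tensor
#'
#' Volume-preserving stretch `l0` along the fiber direction `a0` with
#' `1/sqrt(l0)` transversely: `l0 a0(x)a0 + (1/sqrt(l0)) (I - a0(x)a0)`.
#'
#' @param l0 Deposition stretch along the fiber (> 0).
#' @param a0 Unit fiber direction (length-3 vector).
#' @return A 3x3 matrix with determinant 1.
#' @export
deposition_stretch_fiber <- function(l0, a0) {
  if (!is.finite(l0) || l0 <= 0) {
    stop("`l0` must be positive and finite.", call. = FALSE)
  }
  n <- sqrt(sum(a0^2))
  if (!is.finite(n) || n < 1e-12) {
    stop("`a0` must be a nonzero direction vector.", call. = FALSE)
  }
  a <- a0 / n
  P <- outer(a, a)
  l0 * P + (1 / sqrt(l0)) * (diag(3) - P)
}

#' Remodeling deformation tensor from its along-fiber stretch
#'
#' `lambda_r a0(x)a0 + (1/sqrt(lambda_r)) (I - a0(x)a0)`; the inelastic
#' turnover-mediated re-setting of a fiber constituent's natural
#' configuration. At deposition `lambda_r = 1/lambda0` so that the elastic
#' deformation starts at the deposition stretch.
#'
#' @param lambda_r Along-fiber remodeling stretch (> 0).
#' @param a0 Unit fiber direction.
#' @return A 3x3 matrix with determinant 1.
#' @export
remodeling_tensor <- function(lambda_r, a0) {
  deposition_stretch_fiber(lambda_r, a0)
}

#' Elastic part of a constituent's deformation gradient
#'
#' Multiplicative split `F = F_el F_r F_g`, hence
#' `F_el = F F_g^-1 F_r^-1`. At the initial time `F_r = G_h^-1`, so a fresh
#' constituent under `F = I` carries `F_el = G_h` (its deposition stretch).
#'
#' @param F Total deformation gradient (3x3, positive determinant).
#' @param F_g Growth deformation gradient (3x3), default identity.
#' @param F_r Remodeling deformation gradient (3x3), default identity.
#' @return The elastic deformation gradient `F_el` (3x3).
#' @export
elastic_deformation <- function(F, F_g = diag(3), F_r = diag(3)) {
  dg <- det(F_g)
  if (!is.finite(dg) || abs(dg) < 1e-14) {
    stop("`F_g` is singular.", call. = FALSE)
  }
  F %*% solve(F_g) %*% solve(F_r)
}

#' Fourth invariant of a fiber constituent
#'
#' Squared elastic fiber stretch: `I4 = C_el : (a (x) a)` with `a` the unit
#' pushed-forward fiber direction `F_gr a0 / |F_gr a0|`, which reduces to
#' `|F a0|^2 / |F_gr a0|^2`.
#'
#' @param F Total deformation gradient (3x3).
#' @param a0 Unit reference fiber direction.
#' @param F_g,F_r Growth and remodeling parts (3x3), default identity.
#' @return The scalar fourth invariant.
#' @export
fiber_fourth_invariant <- function(F, a0, F_g = diag(3), F_r = diag(3)) {
  a0 <- a0 / sqrt(sum(a0^2))
  Fgr <- F_r %*% F_g
  sum((F %*% a0)^2) / sum((Fgr %*% a0)^2)
}
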