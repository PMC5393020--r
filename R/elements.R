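# Flexible elements of the multibody model.
#
# Every element connects two rigid bodies (or one body and the ground) and
# produces generalized forces (force + torque about the body origin, world
# frame) on each. Attachments are stored in body-local coordinates, so the
# world attachment point of body b is x_b + R_b %*% a.
#
# Element types:
#  - "cable":   tension-only translational spring (ligaments, screw-rod
#               pull-in). Force magnitude max(0, k (L - L0)), along the
#               chord; exactly zero at or below the rest length.
#  - "spring6": six-dimensional general spring (intervertebral disc, facet
#               capsule, rod beam segment, locked screw). Deformation is
#               measured co-rotationally in the attachment frame of body i;
#               wrench = K %*% c(dt, dr) with K in N/mm and N.mm/rad.
#               Optional bilinear coronal-bending stiffness (direction-
#               dependent, used by patient calibration).
#  - "ground":  weak 6-D grounding of one body to its reference placement
#               (numerical stabilization of otherwise free rod bodies).

new_cable <- function(name, body_i, body_j, a_i, a_j, k, L0,
                      fsu = NA_character_, ramp = FALSE, L0_end = L0) {
  list(type = "cable", name = name, body_i = body_i, body_j = body_j,
       a_i = a_i, a_j = a_j, k = k, L0 = L0, L0_end = L0_end, ramp = ramp,
       fsu = fsu)
}

new_spring6 <- function(name, body_i, body_j, a_i, a_j, B_i, B_j, K,
                        dt0 = c(0, 0, 0), D0 = diag(3),
                        fsu = NA_character_, bilinear = NULL,
                        D0_ramp = NULL) {
  stopifnot(all(dim(K) == c(6, 6)))
  list(type = "spring6", name = name, body_i = body_i, body_j = body_j,
       a_i = a_i, a_j = a_j, B_i = B_i, B_j = B_j, K = K,
       dt0 = dt0, D0 = D0, fsu = fsu, bilinear = bilinear,
       D0_ramp = D0_ramp)
}

# rest rotation of a spring6, optionally ramped along the load schedule
.spring6_D0 <- function(el, ramp_s) {
  if (is.null(el$D0_ramp)) return(el$D0)
  el$D0 %*% rotvec_to_matrix(ramp_s * el$D0_ramp)
}

# Screw-to-rod pull-in element: penalizes the distance between the screw
# axis line (point a_i on the vertebra, direction dir_i in the vertebra
# frame) and the rod axis line (through the rod node along its local z).
# Models an unlocked polyaxial, dorsally height-adjustable head with the
# rod free to slide in the saddle: the rod may sit anywhere along the
# screw axis (dorsal height) and the screw anywhere along the rod; only
# the line-to-line gap beyond the (ramped) rest distance is pulled in,
# tension-only.
new_rodline <- function(name, body_i, body_j, a_i, dir_i, k, L0,
                        L0_end = 0, s_max = 16, t_max = 20,
                        fsu = NA_character_) {
  list(type = "rodline", name = name, body_i = body_i, body_j = body_j,
       a_i = a_i, a_j = c(0, 0, 0), dir_i = dir_i, axis_j = c(0, 0, 1),
       k = k, L0 = L0, L0_end = L0_end, s_max = s_max, t_max = t_max,
       ramp = TRUE, fsu = fsu)
}

# closest points between the screw-axis and rod-axis lines; returns NULL
# when slack or degenerate
.rodline_geom <- function(el, x, Rl, ramp_s) {
  bi <- el$body_i; bj <- el$body_j
  pi_ <- as.numeric(x[bi, ] + Rl[[bi]] %*% el$a_i)
  pj_ <- as.numeric(x[bj, ] + Rl[[bj]] %*% el$a_j)
  u <- as.numeric(Rl[[bi]] %*% el$dir_i)
  v <- as.numeric(Rl[[bj]] %*% el$axis_j)
  r <- pj_ - pi_
  b <- sum(u * v)
  den <- 1 - b^2
  s_ <- if (abs(den) < 1e-8) sum(r * u) else
    (sum(r * u) - b * sum(r * v)) / den
  # the head can sit only within the dorsal-height range of the screw
  s_ <- min(max(s_, 0), el$s_max)
  ci_ <- pi_ + s_ * u
  t_ <- sum((ci_ - pj_) * v)
  t_ <- min(max(t_, -el$t_max), el$t_max)   # stay near this rod segment
  cj_ <- pj_ + t_ * v
  w <- cj_ - ci_
  L <- vnorm(w)
  L0 <- el$L0 + ramp_s * (el$L0_end - el$L0)
  if (L <= L0 || L < 1e-9) return(NULL)
  list(ci = ci_, cj = cj_, w = w, L = L, L0 = L0, u = u, v = v)
}

new_ground <- function(name, body_i, k_t, k_r, X0, R0) {
  list(type = "ground", name = name, body_i = body_i, body_j = NA_integer_,
       k_t = k_t, k_r = k_r, X0 = X0, R0 = R0, fsu = NA_character_)
}

#' Tension-only cable force law
#'
#' Linear in elongation above the rest length; identically zero in
#' shortening (the cable cannot push).
#'
#' @param element A cable element (as stored in a `multibody_model`), or
#'   any list with fields `k` and `L0`.
#' @param length Current chord length, mm (> 0).
#' @return Tension magnitude, N.
#' @export
#' @examples
#' cbl <- list(k = 23.6, L0 = 10)
#' cable_force(cbl, 11)   # 23.6 N
#' cable_force(cbl, 8)    # 0 N: no compression
cable_force <- function(element, length) {
  if (any(length <= 0)) stop("cable length must be positive", call. = FALSE)
  pmax(0, element$k * (length - element$L0))
}

# C1-smoothed tension law used inside the solver: exactly zero at and
# below the rest length (rest assembly stays force-free), a cubic blend
# over the first 2*eps of elongation, and exactly the hard law k*e
# beyond. The smoothing keeps Newton iterations from chattering on the
# slack/taut switch without changing equilibria outside the 0.04 mm band.
.smooth_tension <- function(k, e, eps = 0.02) {
  if (e <= 0) return(c(f = 0, df = 0))
  if (e >= 2 * eps) return(c(f = k * e, df = k))
  c(f = k * e^2 / eps - k * e^3 / (4 * eps^2),
    df = 2 * k * e / eps - 3 * k * e^2 / (4 * eps^2))
}

# effective coronal-bending stiffness entry of a bilinear spring6;
# the switch is smoothed over ~0.1 deg to keep Newton iterations stable
# when a joint sits at its rest rotation
.bilinear_k44 <- function(el, dr1) {
  b <- el$bilinear
  k <- el$K[4, 4]
  if (is.null(b)) return(k)
  w <- tanh(dr1 * b$sign / 0.002)
  k * b$ratio^w
}

# Generalized forces of one element given current body placements.
# Returns list(i =, j =) of 6-vectors (force N, torque N.mm, world frame)
# or NULL for a slack / zero-force element.
element_forces <- function(el, x, Rl, ramp_s = 1) {
  if (el$type == "ground") {
    b <- el$body_i
    dv <- x[b, ] - el$X0
    rv <- matrix_to_rotvec(Rl[[b]] %*% t(el$R0))
    return(list(i = c(-el$k_t * dv, -el$k_r * rv), j = NULL))
  }
  bi <- el$body_i; bj <- el$body_j
  pi_ <- x[bi, ] + Rl[[bi]] %*% el$a_i
  pj_ <- x[bj, ] + Rl[[bj]] %*% el$a_j
  if (el$type == "rodline") {
    gm <- .rodline_geom(el, x, Rl, ramp_s)
    if (is.null(gm)) return(NULL)
    ft <- .smooth_tension(el$k, gm$L - gm$L0)
    if (ft[["f"]] == 0) return(NULL)
    f <- ft[["f"]] * (gm$w / gm$L)               # pull axis toward the rod
    ci <- gm$ci - x[bi, ]; cj <- gm$cj - x[bj, ]
    return(list(i = c(f, c(ci[2] * f[3] - ci[3] * f[2],
                           ci[3] * f[1] - ci[1] * f[3],
                           ci[1] * f[2] - ci[2] * f[1])),
                j = c(-f, -c(cj[2] * f[3] - cj[3] * f[2],
                             cj[3] * f[1] - cj[1] * f[3],
                             cj[1] * f[2] - cj[2] * f[1]))))
  }
  if (el$type == "cable") {
    d <- pj_ - pi_
    L <- sqrt(sum(d * d))
    L0 <- if (isTRUE(el$ramp)) el$L0 + ramp_s * (el$L0_end - el$L0) else el$L0
    if (L < 1e-9) return(NULL)
    ft <- .smooth_tension(el$k, L - L0)
    if (ft[["f"]] == 0) return(NULL)
    f <- ft[["f"]] * (d / L)              # pull on body i toward j
    ci <- pi_ - x[bi, ]; cj <- pj_ - x[bj, ]
    return(list(i = c(f, c(ci[2] * f[3] - ci[3] * f[2],
                           ci[3] * f[1] - ci[1] * f[3],
                           ci[1] * f[2] - ci[2] * f[1])),
                j = c(-f, -c(cj[2] * f[3] - cj[3] * f[2],
                             cj[3] * f[1] - cj[1] * f[3],
                             cj[1] * f[2] - cj[2] * f[1]))))
  }
  # spring6
  Ai <- Rl[[bi]] %*% el$B_i
  Aj <- Rl[[bj]] %*% el$B_j
  dt <- as.numeric(t(Ai) %*% (pj_ - pi_)) - el$dt0
  Dd <- t(Ai) %*% Aj %*% t(.spring6_D0(el, ramp_s))
  dr <- matrix_to_rotvec(Dd)
  K <- el$K
  if (!is.null(el$bilinear)) {
    K[4, 4] <- .bilinear_k44(el, dr[1])
  }
  w <- K %*% c(dt, dr)
  f <- as.numeric(Ai %*% w[1:3])
  tau <- as.numeric(Ai %*% w[4:6])
  m <- (pi_ + pj_) / 2                     # wrench transmitted at midpoint
  ri <- m - x[bi, ]; rj <- m - x[bj, ]
  Fi <- c(f, tau + c(ri[2] * f[3] - ri[3] * f[2],
                     ri[3] * f[1] - ri[1] * f[3],
                     ri[1] * f[2] - ri[2] * f[1]))
  Fj <- c(-f, -tau - c(rj[2] * f[3] - rj[3] * f[2],
                       rj[3] * f[1] - rj[1] * f[3],
                       rj[1] * f[2] - rj[2] * f[1]))
  list(i = Fi, j = Fj)
}

# Elastic energy of one element (N.mm); used by the energy-consistency
# diagnostics.
element_energy <- function(el, x, Rl, ramp_s = 1) {
  if (el$type == "ground") {
    b <- el$body_i
    dv <- x[b, ] - el$X0
    rv <- matrix_to_rotvec(Rl[[b]] %*% t(el$R0))
    return(0.5 * el$k_t * sum(dv^2) + 0.5 * el$k_r * sum(rv^2))
  }
  bi <- el$body_i; bj <- el$body_j
  pi_ <- x[bi, ] + Rl[[bi]] %*% el$a_i
  pj_ <- x[bj, ] + Rl[[bj]] %*% el$a_j
  if (el$type == "rodline") {
    gm <- .rodline_geom(el, x, Rl, ramp_s)
    if (is.null(gm)) return(0)
    return(0.5 * el$k * (gm$L - gm$L0)^2)
  }
  if (el$type == "cable") {
    L <- vnorm(pj_ - pi_)
    L0 <- if (isTRUE(el$ramp)) el$L0 + ramp_s * (el$L0_end - el$L0) else el$L0
    e <- max(0, L - L0)
    return(0.5 * el$k * e^2)
  }

  Ai <- Rl[[bi]] %*% el$B_i
  Aj <- Rl[[bj]] %*% el$B_j
  dt <- as.numeric(t(Ai) %*% (pj_ - pi_)) - el$dt0
  dr <- matrix_to_rotvec(t(Ai) %*% Aj %*% t(.spring6_D0(el, ramp_s)))
  K <- el$K
  if (!is.null(el$bilinear)) K[4, 4] <- .bilinear_k44(el, dr[1])
  d <- c(dt, dr)
  0.5 * sum(d * (K %*% d))
}

# Approximate 12x12 tangent stiffness of one element (exact for the
# leading small-increment terms; used only inside Newton, the converged
# residual is exact). Returns list(Kii, Kij, Kjj) blocks or NULL.
element_tangent <- function(el, x, Rl, ramp_s = 1) {
  if (el$type == "ground") {
    return(list(Kii = diag(c(rep(el$k_t, 3), rep(el$k_r, 3))),
                Kij = NULL, Kjj = NULL))
  }
  bi <- el$body_i; bj <- el$body_j
  pi_ <- x[bi, ] + Rl[[bi]] %*% el$a_i
  pj_ <- x[bj, ] + Rl[[bj]] %*% el$a_j
  ci <- as.numeric(pi_ - x[bi, ]); cj <- as.numeric(pj_ - x[bj, ])
  if (el$type == "rodline") {
    gm <- .rodline_geom(el, x, Rl, ramp_s)
    if (is.null(gm)) return(NULL)
    e <- gm$w / gm$L
    ft <- .smooth_tension(el$k, gm$L - gm$L0)
    if (ft[["df"]] == 0 && ft[["f"]] == 0) return(NULL)
    # material term only: with the dorsal-height and sliding clamps the
    # geometric term is not guaranteed PSD, which would break the
    # descent property of the damped Newton direction
    Kt <- ft[["df"]] * tcrossprod(e)
    M <- cbind(-diag(3), skew3(gm$ci - x[bi, ]),
               diag(3), -skew3(gm$cj - x[bj, ]))
    Kfull <- t(M) %*% Kt %*% M
    return(list(Kii = Kfull[1:6, 1:6], Kij = Kfull[1:6, 7:12],
                Kjj = Kfull[7:12, 7:12]))
  }
  if (el$type == "cable") {
    d <- as.numeric(pj_ - pi_)
    L <- vnorm(d)
    L0 <- if (isTRUE(el$ramp)) el$L0 + ramp_s * (el$L0_end - el$L0) else el$L0
    if (L < 1e-9) return(NULL)
    ft <- .smooth_tension(el$k, L - L0)
    if (ft[["df"]] == 0 && ft[["f"]] == 0) return(NULL)
    u <- d / L
    # material + geometric stiffness in the relative-translation space,
    # mapped through M: relative velocity of the attachment points
    Kt <- ft[["df"]] * tcrossprod(u) +
      (ft[["f"]] / L) * (diag(3) - tcrossprod(u))
    M <- cbind(-diag(3), skew3(ci), diag(3), -skew3(cj))
    Kfull <- t(M) %*% Kt %*% M
    return(list(Kii = Kfull[1:6, 1:6], Kij = Kfull[1:6, 7:12],
                Kjj = Kfull[7:12, 7:12]))
  }
  Ai <- Rl[[bi]] %*% el$B_i
  K <- el$K
  if (!is.null(el$bilinear)) {
    Aj <- Rl[[bj]] %*% el$B_j
    dr <- matrix_to_rotvec(t(Ai) %*% Aj %*% t(.spring6_D0(el, ramp_s)))
    K[4, 4] <- .bilinear_k44(el, dr[1])
  }
  tAi <- t(Ai)
  Bi <- matrix(0, 6, 6); Bj <- matrix(0, 6, 6)
  Bi[1:3, 1:3] <- -tAi
  # d(dt)/d(wi): attachment-point motion plus rotation of the measuring
  # frame A_i combine into the arm from body i's origin to p_j
  Bi[1:3, 4:6] <- tAi %*% skew3(as.numeric(pj_ - x[bi, ]))
  Bi[4:6, 4:6] <- -tAi
  Bj[1:3, 1:3] <- tAi
  Bj[1:3, 4:6] <- -tAi %*% skew3(cj)
  Bj[4:6, 4:6] <- tAi
  KBi <- K %*% Bi; KBj <- K %*% Bj
  list(Kii = t(Bi) %*% KBi, Kij = t(Bi) %*% KBj, Kjj = t(Bj) %*% KBj)
}
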