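#' @title Quasistatic equilibrium solver
#' @description
#' The numerical core of every simulation: Newton iteration on the
#' generalized coordinates of all free rigid bodies (3 translations, 3
#' incremental rotation parameters per body), with incremental application
#' of external loads and element schedules, analytic element tangents
#' re-linearized each iteration, step halving on divergence, and exact
#' residual re-evaluation at convergence.
#'
#' Rotations are handled with per-body rotation matrices updated by
#' left-multiplied incremental rotation vectors, which is robust for the
#' sub-90-degree rotations occurring in spine correction.
#' @name solver
NULL

# state: list(x = n x 3 matrix of body origins, R = list of 3x3 matrices)
model_state <- function(model) {
  n <- length(model$bodies)
  x <- t(vapply(model$bodies, function(b) b$X0, numeric(3)))
  R <- lapply(model$bodies, function(b) b$R0)
  list(x = x, R = R)
}

#' Generalized force residual of a model state
#'
#' Sums element forces and external loads on every body. At an unloaded
#' rest configuration the residual is exactly zero.
#'
#' @param model A `multibody_model`.
#' @param state Optional state (defaults to the reference configuration).
#' @param loads List of loads, each `list(body =, force =, torque =)`
#'   (N, N.mm, world frame, acting at the body origin).
#' @param load_scale Scale factor applied to loads and element schedules.
#' @return n x 6 matrix of generalized forces (Fx, Fy, Fz, Mx, My, Mz) per
#'   body; rows of fixed DOFs are reported too (they are the boundary
#'   reactions with sign reversed).
#' @export
residual <- function(model, state = NULL, loads = list(), load_scale = 1) {
  if (is.null(state)) state <- model_state(model)
  n <- length(model$bodies)
  if (isTRUE(getOption("scolisim.use_compiled", TRUE))) {
    Fg <- residual_packed(pack_model(model), state, load_scale)
  } else {
    Fg <- matrix(0, n, 6)
    for (el in model$elements) {
      fe <- element_forces(el, state$x, state$R, ramp_s = load_scale)
      if (is.null(fe)) next
      Fg[el$body_i, ] <- Fg[el$body_i, ] + fe$i
      if (!is.null(fe$j)) Fg[el$body_j, ] <- Fg[el$body_j, ] + fe$j
    }
  }
  for (ld in loads) {
    b <- if (is.character(ld$body)) model$body_index[[ld$body]] else ld$body
    if (!is.null(ld$force)) Fg[b, 1:3] <- Fg[b, 1:3] + load_scale * ld$force
    if (!is.null(ld$torque)) Fg[b, 4:6] <- Fg[b, 4:6] + load_scale * ld$torque
  }
  Fg
}

# Total elastic energy (N.mm) minus load potential; used in diagnostics.
total_energy <- function(model, state = NULL, loads = list(), load_scale = 1) {
  if (is.null(state)) state <- model_state(model)
  e <- 0
  for (el in model$elements) {
    e <- e + element_energy(el, state$x, state$R, ramp_s = load_scale)
  }
  e
}

assemble_tangent <- function(model, state, load_scale = 1) {
  n <- length(model$bodies)
  J <- matrix(0, 6 * n, 6 * n)
  for (el in model$elements) {
    kt <- element_tangent(el, state$x, state$R, ramp_s = load_scale)
    if (is.null(kt)) next
    ii <- (el$body_i - 1) * 6 + 1:6
    J[ii, ii] <- J[ii, ii] + kt$Kii
    if (!is.null(kt$Kij)) {
      jj <- (el$body_j - 1) * 6 + 1:6
      J[ii, jj] <- J[ii, jj] + kt$Kij
      J[jj, ii] <- J[jj, ii] + t(kt$Kij)
      J[jj, jj] <- J[jj, jj] + kt$Kjj
    }
  }
  J
}

max_residuals <- function(Fg, free) {
  Ff <- Fg; Ff[!free] <- 0
  c(force = max(abs(Ff[, 1:3]), 0), torque = max(abs(Ff[, 4:6]), 0))
}

#' Solve quasistatic equilibrium
#'
#' Applies loads (and any element schedules such as screw pull-in ramps)
#' over `nsteps` increments, re-equilibrating at each with Newton
#' iterations. Diverging increments are bisected (up to `max_halvings`).
#' Convergence requires the maximum force residual below `ftol` (N) and
#' torque residual below `ttol` (N.mm) on all free DOFs, verified by
#' direct residual re-evaluation.
#'
#' @param model A `multibody_model`.
#' @param loads Load list (see [residual()]).
#' @param nsteps Number of load increments.
#' @param ftol,ttol Residual tolerances (N, N.mm) of the final state.
#' @param ftol_path,ttol_path Tolerances for intermediate increments
#'   (default: same as final; loosening them speeds long schedules
#'   without changing the converged end state).
#' @param max_iter Newton iterations per increment.
#' @param max_halvings Increment bisection limit on divergence.
#' @param state0 Optional warm-start state.
#' @param reg Symmetric regularization added to the tangent diagonal.
#' @return A `configuration`: final state, per-body displacements
#'   (mm / deg), convergence log, and `converged` flag.
#' @export
solve_equilibrium <- function(model, loads = list(), nsteps = 1,
                              ftol = 0.5, ttol = 50, ftol_path = ftol,
                              ttol_path = ttol, max_iter = 60,
                              max_halvings = 6, state0 = NULL, reg = 1e-8) {
  n <- length(model$bodies)
  free <- !model$fixed
  idx_free <- which(as.vector(t(free)))   # body-major global dof indices
  state <- if (is.null(state0)) model_state(model) else state0
  log_rows <- list()
  packed <- pack_model(model)
  # viscous-relaxation anchor: when an increment hits a snap-through,
  # temporary grounds to the increment-start state are added and ramped
  # off, letting the solver traverse the instability quasistatically
  relax <- list(active = FALSE, kt = 0, kr = 0, anchor = NULL)
  res_fun <- function(state, s) {
    Fg <- residual_packed(packed, state, s)
    for (ld in loads) {
      b <- if (is.character(ld$body)) model$body_index[[ld$body]] else ld$body
      if (!is.null(ld$force)) Fg[b, 1:3] <- Fg[b, 1:3] + s * ld$force
      if (!is.null(ld$torque)) Fg[b, 4:6] <- Fg[b, 4:6] + s * ld$torque
    }
    if (relax$active) {
      anc <- relax$anchor
      Fg[, 1:3] <- Fg[, 1:3] - relax$kt * (state$x - anc$x)
      for (b in seq_len(n)) {
        rv <- matrix_to_rotvec(state$R[[b]] %*% t(anc$R[[b]]))
        Fg[b, 4:6] <- Fg[b, 4:6] - relax$kr * rv
      }
    }
    Fg
  }
  tan_fun <- function(state, s) {
    J <- tangent_packed(packed, state, s)
    if (relax$active) {
      d <- rep(c(rep(relax$kt, 3), rep(relax$kr, 3)), n)
      diag(J) <- diag(J) + d
    }
    J
  }

  take_step <- function(state, dmat, alpha) {
    cand <- state
    cand$x <- state$x + alpha * dmat[, 1:3, drop = FALSE]
    for (b in seq_len(n)) {
      w <- alpha * dmat[b, 4:6]
      if (any(w != 0)) cand$R[[b]] <- rotvec_to_matrix(w) %*% state$R[[b]]
    }
    cand
  }

  newton <- function(state, s, ft = ftol, tt = ttol) {
    lambda <- reg
    for (it in seq_len(max_iter)) {
      Fg <- res_fun(state, s)
      mr <- max_residuals(Fg, free)
      if (mr["force"] <= ft && mr["torque"] <= tt) {
        return(list(state = state, iters = it, res = mr, ok = TRUE))
      }
      J <- tan_fun(state, s)
      r <- as.vector(t(Fg))[idx_free]
      Jf <- J[idx_free, idx_free, drop = FALSE]
      base_norm <- sqrt(sum(r^2))
      improved <- FALSE
      for (damp in 1:5) {
        Jd <- Jf
        diag(Jd) <- diag(Jd) + lambda * (1 + abs(diag(Jf)))
        dq <- tryCatch(solve(Jd, r), error = function(e) NULL)
        if (is.null(dq)) { lambda <- lambda * 100; next }
        full <- numeric(6 * n); full[idx_free] <- dq
        dmat <- matrix(full, n, 6, byrow = TRUE)
        # per-body trust region (mm / rad) so that a runaway increment of
        # a weakly-constrained body does not throttle the others
        for (b in seq_len(n)) {
          capb <- max(max(abs(dmat[b, 1:3])) / 25,
                      max(abs(dmat[b, 4:6])) / 0.25, 1)
          if (capb > 1) dmat[b, ] <- dmat[b, ] / capb
        }
        alpha <- 1
        for (ls in 1:6) {
          cand <- take_step(state, dmat, alpha)
          Fc <- res_fun(cand, s)
          cn <- sqrt(sum((as.vector(t(Fc))[idx_free])^2))
          if (is.finite(cn) &&
              (cn <= base_norm * (1 - 1e-4 * alpha) || cn < 1e-12)) {
            improved <- TRUE
            break
          }
          alpha <- alpha / 2
        }
        if (improved) {
          state <- cand
          lambda <- max(lambda / 4, reg)
          break
        }
        lambda <- lambda * 50      # Levenberg-Marquardt style damping
      }
      if (!improved) {
        if (isTRUE(getOption("scolisim.debug"))) {
          cat(sprintf("[newton fail] s=%.4f it=%d base_norm=%.4g lambda=%.3g maxF=%.3g maxT=%.3g finite=%s\n",
                      s, it, base_norm, lambda, mr["force"], mr["torque"],
                      all(is.finite(r))))
        }
        return(list(state = state, iters = it, res = mr, ok = FALSE))
      }
    }
    Fg <- res_fun(state, s)
    mr <- max_residuals(Fg, free)
    list(state = state, iters = max_iter, res = mr,
         ok = mr["force"] <= ft && mr["torque"] <= tt)
  }

  relax_through <- function(state, s1, ft, tt) {
    start <- state
    for (kappa in c(10, 1, 0.1, 0)) {
      relax <<- list(active = kappa > 0, kt = kappa, kr = 400 * kappa,
                     anchor = start)
      res <- newton(state, s1, ft, tt)
      state <- res$state
      if (kappa == 0 && res$ok) {
        relax <<- list(active = FALSE, kt = 0, kr = 0, anchor = NULL)
        return(list(state = state, res = res, ok = TRUE))
      }
    }
    relax <<- list(active = FALSE, kt = 0, kr = 0, anchor = NULL)
    list(state = state, res = res, ok = FALSE)
  }

  advance <- function(state, s0, s1, depth) {
    final <- s1 >= 1 - 1e-12
    ft <- if (final) ftol else ftol_path
    tt <- if (final) ttol else ttol_path
    res <- newton(state, s1, ft, tt)
    if (!res$ok && depth >= 2) {
      # persistent failure inside bisection: try viscous relaxation
      rl <- relax_through(state, s1, ft, tt)
      if (rl$ok) res <- rl$res
    }
    if (res$ok) {
      log_rows[[length(log_rows) + 1]] <<- data.frame(
        load_scale = s1, iterations = res$iters,
        max_force_residual = unname(res$res["force"]),
        max_torque_residual = unname(res$res["torque"]))
      return(res$state)
    }
    if (depth >= max_halvings) {
      stop(sprintf(paste0("equilibrium solve failed at load scale %.4f after %d",
                          " halvings (residual %.3g N / %.3g N.mm)"),
                   s1, depth, res$res["force"], res$res["torque"]),
           call. = FALSE)
    }
    sm <- (s0 + s1) / 2
    state <- advance(state, s0, sm, depth + 1)
    advance(state, sm, s1, depth + 1)
  }

  ok <- TRUE
  err <- NULL
  sseq <- seq_len(nsteps) / nsteps
  s_prev <- 0
  for (s in sseq) {
    state <- tryCatch(advance(state, s_prev, s, 0),
                      error = function(e) { ok <<- FALSE; err <<- e; state })
    if (!ok) break
    s_prev <- s
  }

  disp <- matrix(0, n, 6)
  X0 <- t(vapply(model$bodies, function(b) b$X0, numeric(3)))
  disp[, 1:3] <- state$x - X0
  for (b in seq_len(n)) {
    disp[b, 4:6] <- rad2deg(matrix_to_rotvec(state$R[[b]] %*% t(model$bodies[[b]]$R0)))
  }
  rownames(disp) <- vapply(model$bodies, `[[`, "", "name")
  out <- list(state = state, displacement = disp,
              log = if (length(log_rows)) do.call(rbind, log_rows) else
                data.frame(load_scale = numeric(), iterations = integer(),
                           max_force_residual = numeric(),
                           max_torque_residual = numeric()),
              converged = ok,
              error = if (!ok) conditionMessage(err) else NULL)
  class(out) <- "configuration"
  out
}

#' @export
print.configuration <- function(x, ...) {
  cat("<configuration>", if (x$converged) "converged" else
    paste("NOT converged:", x$error), "\n")
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  %d increments, last: %d iterations, residual %.3g N / %.3g N.mm\n",
                nrow(x$log), last$iterations, last$max_force_residual,
                last$max_torque_residual))
  }
  cat(sprintf("  max |translation| %.2f mm, max |rotation| %.2f deg\n",
              max(abs(x$displacement[, 1:3])), max(abs(x$displacement[, 4:6]))))
  invisible(x)
}

#' Apply a solved configuration to a spine geometry
#'
#' Transfers the final body placements of vertebra bodies (and the pelvis)
#' back onto a `spine_geometry`, so clinical indices can be measured on
#' the deformed spine.
#'
#' @param geometry The `spine_geometry` the model was assembled from.
#' @param model The `multibody_model`.
#' @param configuration A `configuration` from [solve_equilibrium()].
#' @return A deformed `spine_geometry`.
#' @export
apply_configuration <- function(geometry, model, configuration) {
  st <- configuration$state
  g <- geometry
  for (lv in names(g$vertebrae)) {
    b <- model$body_index[[lv]]
    if (is.null(b)) next
    g$vertebrae[[lv]]$center <- st$x[b, ]
    g$vertebrae[[lv]]$R <- st$R[[b]]
  }
  if (!is.null(model$body_index[["pelvis"]])) {
    b <- model$body_index[["pelvis"]]
    g$pelvis$center <- st$x[b, ]
    g$pelvis$R <- st$R[[b]]
  }
  g
}
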