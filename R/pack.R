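# Pack a multibody model's elements into flat column-per-element tables
# for the compiled residual / tangent kernels. Packing happens once per
# equilibrium solve; the kernels are then called every Newton iteration.

pack_model <- function(model) {
  cab <- list(); rod <- list(); spr <- list(); grd <- list()
  for (el in model$elements) {
    switch(el$type,
           cable = { cab[[length(cab) + 1]] <- el },
           rodline = { rod[[length(rod) + 1]] <- el },
           spring6 = { spr[[length(spr) + 1]] <- el },
           ground = { grd[[length(grd) + 1]] <- el })
  }
  col3 <- function(lst, field) {
    if (length(lst) == 0) return(matrix(0, 3, 0))
    vapply(lst, function(e) as.numeric(e[[field]]), numeric(3))
  }
  col9 <- function(lst, field) {
    if (length(lst) == 0) return(matrix(0, 9, 0))
    vapply(lst, function(e) as.numeric(e[[field]]), numeric(9))
  }
  idx2 <- function(lst) {
    if (length(lst) == 0) return(matrix(0L, 2, 0))
    vapply(lst, function(e) c(as.integer(e$body_i), as.integer(e$body_j)),
           integer(2))
  }
  list(
    c_idx = idx2(cab),
    c_ai = col3(cab, "a_i"), c_aj = col3(cab, "a_j"),
    c_par = if (length(cab) == 0) matrix(0, 4, 0) else
      vapply(cab, function(e) c(e$k, e$L0, e$L0_end,
                                as.numeric(isTRUE(e$ramp))), numeric(4)),
    r_idx = idx2(rod),
    r_ai = col3(rod, "a_i"), r_aj = col3(rod, "a_j"),
    r_dir = col3(rod, "dir_i"),
    r_par = if (length(rod) == 0) matrix(0, 5, 0) else
      vapply(rod, function(e) c(e$k, e$L0, e$L0_end, e$s_max, e$t_max),
             numeric(5)),
    s_idx = idx2(spr),
    s_ai = col3(spr, "a_i"), s_aj = col3(spr, "a_j"),
    s_Bi = col9(spr, "B_i"), s_Bj = col9(spr, "B_j"),
    s_dt0 = col3(spr, "dt0"), s_D0 = col9(spr, "D0"),
    s_K = if (length(spr) == 0) matrix(0, 36, 0) else
      vapply(spr, function(e) as.numeric(e$K), numeric(36)),
    s_bil = if (length(spr) == 0) matrix(0, 2, 0) else
      vapply(spr, function(e) {
        if (is.null(e$bilinear)) c(0, 1) else
          c(e$bilinear$sign, e$bilinear$ratio)
      }, numeric(2)),
    s_ramp = if (length(spr) == 0) matrix(0, 4, 0) else
      vapply(spr, function(e) {
        if (is.null(e$D0_ramp)) c(0, 0, 0, 0) else c(e$D0_ramp, 1)
      }, numeric(4)),
    g_idx = if (length(grd) == 0) integer(0) else
      vapply(grd, function(e) as.integer(e$body_i), integer(1)),
    g_par = if (length(grd) == 0) matrix(0, 2, 0) else
      vapply(grd, function(e) c(e$k_t, e$k_r), numeric(2)),
    g_X0 = col3(grd, "X0"), g_R0 = col9(grd, "R0")
  )
}

# state rotation list -> 9 x n matrix for the kernels
state_rmat <- function(state) {
  vapply(state$R, as.numeric, numeric(9))
}

# compiled residual: element forces only (loads added by the caller)
residual_packed <- function(packed, state, ramp_s) {
  .residual_cpp(t(state$x), state_rmat(state), packed, ramp_s)
}

tangent_packed <- function(packed, state, ramp_s) {
  .tangent_cpp(t(state$x), state_rmat(state), packed, ramp_s)
}
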