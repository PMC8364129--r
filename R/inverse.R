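#' Build the inverse-inference MILP
#'
#' One mixed-integer program combining, for each supplied predictor, an exact
#' big-M encoding of its ReLU network with the target window
#' \eqn{(1-\varepsilon) y^* \le \psi(x) \le (1+\varepsilon) y^*} (block C1),
#' the applicability-domain box on the shared descriptor variables, and a
#' graph-existence block (C2) whose binary variables select a subgraph of the
#' scheme graph: a branch-tree inside the base tree
#' `T_B = T(d_max, d_max - 1, bh*)` (a pair of `T(d_max - 1, d_max - 1, bh*)`
#' trees joined at the roots when `dia*` is odd), link-path windows that
#' subdivide branch-tree edges, and a fringe-tree skeleton of height `k*` at
#' every spine vertex. Counting rows tie the selection to every descriptor,
#' so the model is feasible exactly when a chemical acyclic graph in the
#' target class realises the descriptor vector.
#'
#' Supported branch-parameters are `k*` in \{1, 2\} (the 2-fringe size rule
#' is enforced for `k* = 2` only).
#'
#' @param predictors list of `trained_predictor` objects sharing one
#'   descriptor spec, each with attributes `y_star` and `eps` attached via
#'   the `targets` argument.
#' @param spec a [target_spec()].
#' @param ad an [ad_bounds()] or `NULL` to omit the AD box.
#' @param targets tibble/data.frame with one row per predictor: `y_star`,
#'   `eps`. Defaults `eps = 0.02`.
#' @param fix_x optional named numeric vector (a feature vector): fixes the
#'   descriptor variables, turning the model into a pure existence check.
#' @return object of class `inverse_milp`.
#' @export
build_milp <- function(predictors = list(), spec, ad = NULL, targets = NULL,
                       fix_x = NULL) {
  stopifnot(inherits(spec, "target_spec"))
  if (!(spec$k_star %in% c(1L, 2L))) stop("the MILP encoder supports k* in {1, 2}")
  if (length(predictors)) {
    if (is.null(targets) || nrow(targets) != length(predictors)) {
      stop("targets (y_star, eps) must have one row per predictor")
    }
    if (any(targets$eps < 0)) stop("eps must be >= 0")
    for (p in predictors) {
      if (!identical(p$spec$names, as_descriptor_spec(spec)$names)) {
        stop("predictor/spec descriptor mismatch")
      }
    }
  }
  dspec <- as_descriptor_spec(spec)
  m <- milp_new()
  ctx <- build_c2(m, spec, dspec)
  add_descriptor_rows(m, ctx)
  if (!is.null(ad)) add_ad_rows(m, ctx, ad)
  if (!is.null(spec$ac_bounds)) add_ac_bound_rows(m, ctx, spec$ac_bounds)
  if (!is.null(fix_x)) fix_x_vars(m, ctx, fix_x)
  ys <- character(0)
  if (length(predictors)) {
    for (pi in seq_along(predictors)) {
      ys <- c(ys, add_c1(m, ctx, predictors[[pi]], targets$y_star[pi], targets$eps[pi], pi))
    }
  }
  structure(list(milp = m, ctx = ctx, spec = spec, dspec = dspec,
                 y_vars = ys, n_predictors = length(predictors)),
            class = "inverse_milp")
}

#' @export
print.inverse_milp <- function(x, ...) {
  cat("<inverse_milp>", length(x$milp$var_names), "variables,",
      length(x$milp$row_lb), "constraints,", x$n_predictors, "predictor block(s)\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# C2: graph existence

#' @noRd
build_c2 <- function(m, spec, dspec) {
  d_max <- spec$d_max; k_star <- spec$k_star
  el <- spec$elements; gam <- spec$gamma; bc <- dspec$bc
  pair_mode <- spec$dia_star %% 2L == 1L
  sides <- if (pair_mode) {
    list(t_abc(d_max - 1L, d_max - 1L, spec$bh_star),
         t_abc(d_max - 1L, d_max - 1L, spec$bh_star))
  } else {
    list(t_abc(d_max, d_max - 1L, spec$bh_star))
  }
  n_roots <- length(sides)
  t_star <- max(0L, min(spec$n_star - spec$bl_star - 1L,
                        spec$n_star - n_roots - spec$bl_star * (k_star + 1L)))

  # --- slot registry -------------------------------------------------------
  # B vertices: global index over non-root vertices of all sides
  Bv <- list()
  for (sd in seq_along(sides)) {
    tb <- sides[[sd]]
    loc2glob <- integer(tb$n)
    for (i in 2:tb$n) {
      gi <- length(Bv) + 1L
      loc2glob[i] <- gi
      Bv[[gi]] <- list(side = sd, loc = i, dep = tb$depth[i],
                       par_loc = tb$parent[i], par_glob = NA_integer_,
                       children = integer(0))
    }
    for (i in 2:tb$n) {
      gi <- loc2glob[i]
      p <- tb$parent[i]
      Bv[[gi]]$par_glob <- if (p == 1L) 0L else loc2glob[p]  # 0 = root of side
      if (p != 1L) Bv[[loc2glob[p]]]$children <- c(Bv[[loc2glob[p]]]$children, gi)
    }
    # record each side root's depth-1 children
    attr(Bv, paste0("dir", sd)) <- loc2glob[sides[[sd]]$children[[1]]]
  }
  nB <- length(Bv)

  slot_names <- c(paste0("R", seq_len(n_roots)),
                  paste0("B", seq_len(nB)),
                  if (t_star > 0) paste0("P", seq_len(t_star)) else character(0))
  # fringe skeleton sizes per spine slot
  fringe_c <- function(sname) {
    if (startsWith(sname, "P")) max(d_max - 2L, 0L) else d_max - 1L
  }
  fringe_g <- if (k_star >= 2L) d_max - 1L else 0L

  ctx <- new.env(parent = emptyenv())
  ctx$spec <- spec; ctx$dspec <- dspec; ctx$pair_mode <- pair_mode
  ctx$sides <- sides; ctx$Bv <- Bv; ctx$nB <- nB; ctx$t_star <- t_star
  ctx$n_roots <- n_roots
  ctx$spine_slots <- slot_names
  ctx$fringe_slots <- character(0)
  ctx$sel <- list()        # slot -> selection expression (list(idx, coef, const))
  ctx$incid <- list()      # slot -> incident edge-selection expression
  ctx$mult <- list()       # slot -> incident multiplicity expression sum m * mu
  ctx$edges <- list()      # edge registry
  ctx$al <- list(); ctx$dl <- list()

  const_expr <- function(k) list(idx = integer(0), coef = numeric(0), const = k)
  var_expr <- function(i) list(idx = i, coef = 1, const = 0)

  # --- selection variables -------------------------------------------------
  u <- integer(nB); lam <- integer(nB)
  for (j in seq_len(nB)) {
    u[j] <- milp_var(m, paste0("u[", j, "]"))
    lam[j] <- milp_var(m, paste0("lam[", j, "]"))
  }
  w <- if (t_star > 0) vapply(seq_len(t_star), function(h) milp_var(m, paste0("w[", h, "]")), integer(1)) else integer(0)
  s_ <- a_ <- b_ <- pe_ <- matrix(0L, nrow = nB, ncol = max(t_star, 1L))
  d_ <- integer(nB)
  for (j in seq_len(nB)) {
    d_[j] <- milp_var(m, paste0("d[", j, "]"))
    if (t_star > 0) {
      for (h in seq_len(t_star)) {
        s_[j, h] <- milp_var(m, paste0("s[", j, ",", h, "]"))
        a_[j, h] <- milp_var(m, paste0("a[", j, ",", h, "]"))
        b_[j, h] <- milp_var(m, paste0("b[", j, ",", h, "]"))
        pe_[j, h] <- milp_var(m, paste0("pe[", j, ",", h, "]"))
      }
    }
  }
  ctx$u <- u; ctx$lam <- lam; ctx$w <- w; ctx$s <- s_; ctx$a <- a_; ctx$b <- b_
  ctx$pe <- pe_; ctx$d <- d_

  for (r in seq_len(n_roots)) ctx$sel[[paste0("R", r)]] <- const_expr(1)
  for (j in seq_len(nB)) ctx$sel[[paste0("B", j)]] <- var_expr(u[j])
  for (h in seq_len(t_star)) ctx$sel[[paste0("P", h)]] <- var_expr(w[h])

  # --- branch-tree structure ----------------------------------------------
  for (j in seq_len(nB)) {
    pj <- Bv[[j]]$par_glob
    if (pj > 0L) milp_con(m, c(u[j], u[pj]), c(1, -1), ub = 0)  # prefix
    kids <- Bv[[j]]$children
    # lambda definition
    milp_con(m, c(lam[j], u[j]), c(1, -1), ub = 0)
    if (length(kids)) {
      milp_con(m, c(lam[j], u[j], u[kids]), c(1, -1, rep(1, length(kids))), lb = 0)
      for (kk in kids) milp_con(m, c(lam[j], u[kk]), c(1, 1), ub = 1)
      # non-leaf selected vertices branch (>= 2 selected children)
      milp_con(m, c(u[kids], u[j], lam[j]), c(rep(1, length(kids)), -2, 2), lb = 0)
    } else {
      milp_con(m, c(lam[j], u[j]), c(1, -1), lb = 0, ub = 0)
    }
  }
  # sibling precedence (canonical subtree selection)
  for (sd in seq_along(sides)) {
    tb <- sides[[sd]]
    glob_of <- function(loc) which(vapply(Bv, function(b) b$side == sd && b$loc == loc, logical(1)))
    for (v in seq_len(tb$n)) {
      kids <- tb$children[[v]]
      if (length(kids) > 1) {
        for (q in seq_len(length(kids) - 1L)) {
          g1 <- glob_of(kids[q]); g2 <- glob_of(kids[q + 1L])
          milp_con(m, c(u[g2], u[g1]), c(1, -1), ub = 0)
        }
      }
    }
  }
  milp_con(m, lam, rep(1, nB), lb = spec$bl_star, ub = spec$bl_star)
  at_bh <- which(vapply(Bv, function(b) b$dep == spec$bh_star, logical(1)))
  milp_con(m, u[at_bh], rep(1, length(at_bh)), lb = 1)

  # --- link-path windows ---------------------------------------------------
  if (t_star > 0) {
    for (h in seq_len(t_star)) {
      milp_con(m, c(w[h], s_[, h]), c(1, rep(-1, nB)), lb = 0, ub = 0)
      if (h < t_star) milp_con(m, c(w[h], w[h + 1L]), c(1, -1), lb = 0)   # packed prefix
    }
    for (j in seq_len(nB)) {
      for (h in seq_len(t_star)) {
        if (h > 1) {
          milp_con(m, c(pe_[j, h - 1L], a_[j, h], s_[j, h]), c(1, 1, -1), lb = 0, ub = 0)
        } else {
          milp_con(m, c(a_[j, 1L], s_[j, 1L]), c(1, -1), lb = 0, ub = 0)
        }
        milp_con(m, c(pe_[j, h], b_[j, h], s_[j, h]), c(1, 1, -1), lb = 0, ub = 0)
      }
      # no continuation beyond the last position
      milp_con(m, pe_[j, t_star], 1, ub = 0)
    }
    # ordering of segments along the path (symmetry reduction):
    # the owning-edge index is non-decreasing over used positions
    if (t_star > 1) {
      for (h in seq_len(t_star - 1L)) {
        milp_con(m, c(s_[, h + 1L], s_[, h], w[h + 1L]),
                 c(seq_len(nB), -seq_len(nB), -nB), lb = -nB)
      }
    }
  }
  for (j in seq_len(nB)) {
    if (t_star > 0) {
      milp_con(m, c(a_[j, ], d_[j], u[j]), c(rep(1, t_star), 1, -1), lb = 0, ub = 0)
      milp_con(m, c(b_[j, ], d_[j], u[j]), c(rep(1, t_star), 1, -1), lb = 0, ub = 0)
    } else {
      milp_con(m, c(d_[j], u[j]), c(1, -1), lb = 0, ub = 0)
    }
  }

  # --- fringe skeletons ----------------------------------------------------
  f <- list(); fg <- list()
  for (sn in ctx$spine_slots) {
    C1 <- fringe_c(sn)
    if (C1 == 0) next
    fv <- integer(C1); gv <- matrix(0L, C1, max(fringe_g, 1L))
    for (cc in seq_len(C1)) {
      fv[cc] <- milp_var(m, paste0("f[", sn, ",", cc, "]"))
      cslot <- paste0(sn, ".c", cc)
      ctx$fringe_slots <- c(ctx$fringe_slots, cslot)
      ctx$sel[[cslot]] <- var_expr(fv[cc])
      if (fringe_g > 0) {
        for (gg in seq_len(fringe_g)) {
          gv[cc, gg] <- milp_var(m, paste0("fg[", sn, ",", cc, ",", gg, "]"))
          gslot <- paste0(sn, ".c", cc, ".g", gg)
          ctx$fringe_slots <- c(ctx$fringe_slots, gslot)
          ctx$sel[[gslot]] <- var_expr(gv[cc, gg])
          milp_con(m, c(gv[cc, gg], fv[cc]), c(1, -1), ub = 0)
          if (gg > 1) milp_con(m, c(gv[cc, gg], gv[cc, gg - 1L]), c(1, -1), ub = 0)
        }
      }
      if (cc > 1) {
        milp_con(m, c(fv[cc], fv[cc - 1L]), c(1, -1), ub = 0)
        if (fringe_g > 0) {
          milp_con(m, c(gv[cc - 1L, seq_len(fringe_g)], gv[cc, seq_len(fringe_g)]),
                   c(rep(1, fringe_g), rep(-1, fringe_g)), lb = 0)
        }
      }
    }
    sel_e <- ctx$sel[[sn]]
    # fringe roots only on selected spine slots
    for (cc in seq_len(C1)) {
      milp_con(m, c(fv[cc], sel_e$idx), c(1, -sel_e$coef), ub = sel_e$const)
    }
    # size rule n(F) <= 2 deg_F(r) + 2  <=>  #grandchildren <= #children + 1
    if (k_star == 2L && fringe_g > 0) {
      milp_con(m, c(as.integer(gv[, seq_len(fringe_g)]), fv, sel_e$idx),
               c(rep(1, C1 * fringe_g), rep(-1, C1), -sel_e$coef), ub = sel_e$const)
    }
    f[[sn]] <- fv; fg[[sn]] <- gv
  }
  ctx$f <- f; ctx$fg <- fg
  # leaf branches carry a fringe of height exactly k*; non-leaf selected
  # branch vertices carry none (their children must all reach height >= k*)
  for (j in seq_len(nB)) {
    sn <- paste0("B", j)
    fv <- f[[sn]]
    if (k_star == 2L) {
      milp_con(m, c(as.integer(fg[[sn]]), lam[j]), c(rep(1, length(fg[[sn]])), -1), lb = 0)
    } else {
      milp_con(m, c(fv, lam[j]), c(rep(1, length(fv)), -1), lb = 0)
    }
    for (cc in seq_along(fv)) milp_con(m, c(fv[cc], lam[j]), c(1, -1), ub = 0)
  }

  # --- labels --------------------------------------------------------------
  all_slots <- c(ctx$spine_slots, ctx$fringe_slots)
  for (sn in all_slots) {
    av <- vapply(el$label, function(aa) milp_var(m, paste0("al[", sn, ",", aa, "]")), integer(1))
    ctx$al[[sn]] <- av
    se <- ctx$sel[[sn]]
    milp_con(m, c(av, se$idx), c(rep(1, length(av)), -se$coef), lb = se$const, ub = se$const)
  }

  # --- edges ---------------------------------------------------------------
  add_edge <- function(uslot, vslot, sel_idx, sel_coef, internal, tag) {
    e <- length(ctx$edges) + 1L
    muv <- vapply(1:3, function(mm) milp_var(m, paste0("mu[", e, ",", mm, "]")), integer(1))
    milp_con(m, c(muv, sel_idx), c(rep(1, 3), -sel_coef), lb = 0, ub = 0)
    ctx$edges[[e]] <- list(u = uslot, v = vslot, sel_idx = sel_idx,
                           sel_coef = sel_coef, mu = muv, internal = internal,
                           tag = tag)
    for (sl in c(uslot, vslot)) {
      inc <- ctx$incid[[sl]]; if (is.null(inc)) inc <- expr_new()
      ctx$incid[[sl]] <- expr_add(inc, sel_idx, sel_coef)
      ml <- ctx$mult[[sl]]; if (is.null(ml)) ml <- expr_new()
      ctx$mult[[sl]] <- expr_add(ml, muv, 1:3)
    }
    e
  }
  ctx$add_edge <- add_edge

  if (pair_mode) {
    re <- milp_var(m, "rootedge", lb = 1, ub = 1)
    add_edge("R1", "R2", re, 1, TRUE, "rootedge")
  }
  par_slot_of <- vapply(seq_len(nB), function(j) {
    if (Bv[[j]]$par_glob == 0L) paste0("R", Bv[[j]]$side) else paste0("B", Bv[[j]]$par_glob)
  }, character(1))
  for (j in seq_len(nB)) {
    add_edge(par_slot_of[j], paste0("B", j), d_[j], 1, TRUE, paste0("direct", j))
  }
  if (t_star > 0) {
    # entry arcs merged per parent slot (at most one child's segment can own
    # a position, so the merged selection stays binary-valued)
    for (ps in unique(par_slot_of)) {
      js <- which(par_slot_of == ps)
      for (h in seq_len(t_star)) {
        add_edge(ps, paste0("P", h), a_[js, h], rep(1, length(js)), TRUE,
                 paste0("entry", ps, ".", h))
      }
    }
    for (j in seq_len(nB)) {
      for (h in seq_len(t_star)) {
        add_edge(paste0("P", h), paste0("B", j), b_[j, h], 1, TRUE, paste0("exit", j, ".", h))
      }
    }
    if (t_star > 1) {
      for (h in seq_len(t_star - 1L)) {
        add_edge(paste0("P", h), paste0("P", h + 1L), pe_[, h], rep(1, nB), TRUE,
                 paste0("pe", h))
      }
    }
  }
  for (sn in ctx$spine_slots) {
    fv <- f[[sn]]
    if (is.null(fv)) next
    for (cc in seq_along(fv)) {
      add_edge(sn, paste0(sn, ".c", cc), fv[cc], 1, FALSE, paste0("fc", sn, ".", cc))
      if (fringe_g > 0) {
        for (gg in seq_len(fringe_g)) {
          add_edge(paste0(sn, ".c", cc), paste0(sn, ".c", cc, ".g", gg),
                   fg[[sn]][cc, gg], 1, FALSE, paste0("fgx", sn, ".", cc, ".", gg))
        }
      }
    }
  }

  # --- degrees -------------------------------------------------------------
  for (sn in all_slots) {
    dv <- vapply(seq_len(d_max), function(dd) milp_var(m, paste0("dl[", sn, ",", dd, "]")), integer(1))
    ctx$dl[[sn]] <- dv
    se <- ctx$sel[[sn]]
    milp_con(m, c(dv, se$idx), c(rep(1, d_max), -se$coef), lb = se$const, ub = se$const)
    inc <- ctx$incid[[sn]]
    if (is.null(inc)) inc <- expr_new()
    milp_con(m, c(dv, inc$idx), c(seq_len(d_max), -inc$coef), lb = 0, ub = 0)
  }
  if (d_max == 4L) {
    d4 <- unlist(lapply(all_slots, function(sn) ctx$dl[[sn]][4]))
    milp_con(m, d4, rep(1, length(d4)), lb = 1)   # d_max = 4 means degree exactly 4 somewhere
  }

  # --- valence -------------------------------------------------------------
  for (sn in all_slots) {
    ml <- ctx$mult[[sn]]
    if (is.null(ml)) ml <- expr_new()
    av <- ctx$al[[sn]]
    milp_con(m, c(ml$idx, av), c(ml$coef, -el$valence), ub = 0)
  }

  # --- per-edge adjacency / bond configurations ---------------------------
  gam_keys <- gamma_key(gam$a, gam$b, gam$m)
  bc_keys <- bc_key(bc$d1, bc$d2, bc$m)
  for (e in seq_along(ctx$edges)) {
    ed <- ctx$edges[[e]]
    alu <- ctx$al[[ed$u]]; alv <- ctx$al[[ed$v]]
    dlu <- ctx$dl[[ed$u]]; dlv <- ctx$dl[[ed$v]]
    acv <- integer(nrow(gam))
    for (gi in seq_len(nrow(gam))) {
      acv[gi] <- milp_var(m, paste0("acv[", e, ",", gi, "]"))
      ia <- match(gam$a[gi], el$label); ib <- match(gam$b[gi], el$label)
      mm <- gam$m[gi]
      if (ia != ib) {
        milp_con(m, c(acv[gi], alu[ia], alv[ib], ed$mu[mm]), c(1, -1, -1, -1), lb = -2)
        milp_con(m, c(acv[gi], alu[ib], alv[ia], ed$mu[mm]), c(1, -1, -1, -1), lb = -2)
        milp_con(m, c(acv[gi], alu[ia], alu[ib]), c(1, -1, -1), ub = 0)
        milp_con(m, c(acv[gi], alv[ia], alv[ib]), c(1, -1, -1), ub = 0)
        milp_con(m, c(acv[gi], alu[ia], alv[ia]), c(1, -1, -1), ub = 0)
        milp_con(m, c(acv[gi], alu[ib], alv[ib]), c(1, -1, -1), ub = 0)
      } else {
        milp_con(m, c(acv[gi], alu[ia], alv[ia], ed$mu[mm]), c(1, -1, -1, -1), lb = -2)
        milp_con(m, c(acv[gi], alu[ia]), c(1, -1), ub = 0)
        milp_con(m, c(acv[gi], alv[ia]), c(1, -1), ub = 0)
      }
      milp_con(m, c(acv[gi], ed$mu[mm]), c(1, -1), ub = 0)
    }
    milp_con(m, c(acv, ed$sel_idx), c(rep(1, length(acv)), -ed$sel_coef), lb = 0, ub = 0)
    bcv <- integer(nrow(bc))
    for (bi in seq_len(nrow(bc))) {
      d1 <- bc$d1[bi]; d2 <- bc$d2[bi]; mm <- bc$m[bi]
      if (d1 > d_max || d2 > d_max) { bcv[bi] <- NA_integer_; next }
      bcv[bi] <- milp_var(m, paste0("bcv[", e, ",", bi, "]"))
      if (d1 != d2) {
        milp_con(m, c(bcv[bi], dlu[d1], dlv[d2], ed$mu[mm]), c(1, -1, -1, -1), lb = -2)
        milp_con(m, c(bcv[bi], dlu[d2], dlv[d1], ed$mu[mm]), c(1, -1, -1, -1), lb = -2)
        milp_con(m, c(bcv[bi], dlu[d1], dlu[d2]), c(1, -1, -1), ub = 0)
        milp_con(m, c(bcv[bi], dlv[d1], dlv[d2]), c(1, -1, -1), ub = 0)
        milp_con(m, c(bcv[bi], dlu[d1], dlv[d1]), c(1, -1, -1), ub = 0)
        milp_con(m, c(bcv[bi], dlu[d2], dlv[d2]), c(1, -1, -1), ub = 0)
      } else {
        milp_con(m, c(bcv[bi], dlu[d1], dlv[d1], ed$mu[mm]), c(1, -1, -1, -1), lb = -2)
        milp_con(m, c(bcv[bi], dlu[d1]), c(1, -1), ub = 0)
        milp_con(m, c(bcv[bi], dlv[d1]), c(1, -1), ub = 0)
      }
      milp_con(m, c(bcv[bi], ed$mu[mm]), c(1, -1), ub = 0)
    }
    ok <- !is.na(bcv)
    milp_con(m, c(bcv[ok], ed$sel_idx), c(rep(1, sum(ok)), -ed$sel_coef), lb = 0, ub = 0)
    ctx$edges[[e]]$acv <- acv
    ctx$edges[[e]]$bcv <- bcv
  }

  # --- total size ----------------------------------------------------------
  sel_all <- expr_new()
  for (sn in all_slots) {
    se <- ctx$sel[[sn]]
    sel_all <- expr_add(sel_all, se$idx, se$coef)
  }
  milp_con(m, sel_all$idx, sel_all$coef,
           lb = spec$n_star - n_roots, ub = spec$n_star - n_roots)

  # --- diameter and center -------------------------------------------------
  kst <- k_star
  R <- if (pair_mode) (spec$dia_star - 1L) %/% 2L else spec$dia_star %/% 2L
  bigM <- spec$bh_star * (t_star + 1L) + kst + R
  z <- integer(nB)
  for (j in seq_len(nB)) {
    z[j] <- milp_var(m, paste0("z[", j, "]"))
    milp_con(m, c(z[j], lam[j]), c(1, -1), ub = 0)
    anc <- j
    p <- Bv[[j]]$par_glob
    while (p > 0L) { anc <- c(anc, p); p <- Bv[[p]]$par_glob }
    # path length of the arm: sum over ancestors of (1 + #path vertices)
    idxs <- c(u[anc], if (t_star > 0) as.integer(s_[anc, , drop = FALSE]) else integer(0))
    cfs <- c(rep(1, length(anc)), if (t_star > 0) rep(1, length(anc) * t_star) else numeric(0))
    # arm depth <= R for every leaf branch
    milp_con(m, c(idxs, lam[j]), c(cfs, bigM), ub = R - kst + bigM)
    # attainment indicator
    milp_con(m, c(idxs, z[j]), c(cfs, -bigM), lb = R - kst - bigM)
  }
  ctx$z <- z
  if (pair_mode) {
    for (sd in 1:2) {
      side_j <- which(vapply(Bv, function(b) b$side == sd, logical(1)))
      milp_con(m, z[side_j], rep(1, length(side_j)), lb = 1)
    }
  } else {
    dirs <- attr(Bv, "dir1")
    tv <- integer(length(dirs))
    for (q in seq_along(dirs)) {
      tv[q] <- milp_var(m, paste0("tdir[", q, "]"))
      sub <- subtree_of(Bv, dirs[q])
      milp_con(m, c(tv[q], z[sub]), c(1, rep(-1, length(sub))), ub = 0)
    }
    milp_con(m, tv, rep(1, length(tv)), lb = 2)
  }
  ctx
}

#' @noRd
subtree_of <- function(Bv, root_j) {
  out <- root_j
  queue <- root_j
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    kids <- Bv[[v]]$children
    out <- c(out, kids); queue <- c(queue, kids)
  }
  out
}

# ---------------------------------------------------------------------------
# descriptor rows

#' @noRd
add_descriptor_rows <- function(m, ctx) {
  spec <- ctx$spec; dspec <- ctx$dspec
  el <- spec$elements; gam <- dspec$gamma; bc <- dspec$bc
  n_star <- spec$n_star
  xv <- new.env(parent = emptyenv())
  mkx <- function(name, lb, ub, type = "C") {
    xv[[name]] <- milp_var(m, paste0("x[", name, "]"), lb = lb, ub = ub, type = type)
    xv[[name]]
  }
  spine <- ctx$spine_slots; fringe <- ctx$fringe_slots
  mkx("n", n_star, n_star)
  mkx("dia_bar", spec$dia_star / n_star, spec$dia_star / n_star)
  mkx("ms_bar", 0, max(el$mass_star))
  mkx("n_H", 0, 4 * n_star)
  mkx("bl", spec$bl_star, spec$bl_star)
  mkx("bh", spec$bh_star, spec$bh_star)
  for (dd in 1:4) for (tt in c("in", "ex")) mkx(paste0("dg_", dd, "_", tt), 0, n_star)
  for (aa in el$label) for (tt in c("in", "ex")) mkx(paste0("ce_", aa, "_", tt), 0, n_star)
  for (mm in 2:3) for (tt in c("in", "ex")) mkx(paste0("bd_", mm, "_", tt), 0, n_star)
  for (gi in seq_len(nrow(gam))) {
    key <- gamma_key(gam$a[gi], gam$b[gi], gam$m[gi])
    for (tt in c("in", "ex")) mkx(paste0("ac_", key, "_", tt), 0, n_star)
  }
  for (bi in seq_len(nrow(bc))) {
    key <- bc_key(bc$d1[bi], bc$d2[bi], bc$m[bi])
    for (tt in c("in", "ex")) mkx(paste0("bc_", key, "_", tt), 0, n_star)
  }
  ctx$xv <- xv

  sum_over_slots <- function(slots, pick) {
    e <- expr_new()
    for (sn in slots) {
      ii <- pick(sn)
      if (length(ii)) e <- expr_add(e, ii, rep(1, length(ii)))
    }
    e
  }
  for (dd in seq_len(spec$d_max)) {
    for (tt in c("in", "ex")) {
      slots <- if (tt == "in") spine else fringe
      e <- sum_over_slots(slots, function(sn) ctx$dl[[sn]][dd])
      milp_con(m, c(e$idx, xv[[paste0("dg_", dd, "_", tt)]]), c(e$coef, -1), lb = 0, ub = 0)
    }
  }
  if (spec$d_max < 4L) {
    for (tt in c("in", "ex")) milp_con(m, xv[[paste0("dg_4_", tt)]], 1, lb = 0, ub = 0)
  }
  for (ai in seq_len(nrow(el))) {
    for (tt in c("in", "ex")) {
      slots <- if (tt == "in") spine else fringe
      e <- sum_over_slots(slots, function(sn) ctx$al[[sn]][ai])
      milp_con(m, c(e$idx, xv[[paste0("ce_", el$label[ai], "_", tt)]]), c(e$coef, -1), lb = 0, ub = 0)
    }
  }
  for (mm in 2:3) {
    for (tt in c("in", "ex")) {
      e <- expr_new()
      for (ed in ctx$edges) {
        if (ed$internal == (tt == "in")) e <- expr_add(e, ed$mu[mm], 1)
      }
      milp_con(m, c(e$idx, xv[[paste0("bd_", mm, "_", tt)]]), c(e$coef, -1), lb = 0, ub = 0)
    }
  }
  for (gi in seq_len(nrow(gam))) {
    key <- gamma_key(gam$a[gi], gam$b[gi], gam$m[gi])
    for (tt in c("in", "ex")) {
      e <- expr_new()
      for (ed in ctx$edges) {
        if (ed$internal == (tt == "in")) e <- expr_add(e, ed$acv[gi], 1)
      }
      milp_con(m, c(e$idx, xv[[paste0("ac_", key, "_", tt)]]), c(e$coef, -1), lb = 0, ub = 0)
    }
  }
  for (bi in seq_len(nrow(bc))) {
    key <- bc_key(bc$d1[bi], bc$d2[bi], bc$m[bi])
    for (tt in c("in", "ex")) {
      e <- expr_new()
      for (ed in ctx$edges) {
        if (!is.na(ed$bcv[bi]) && ed$internal == (tt == "in")) e <- expr_add(e, ed$bcv[bi], 1)
      }
      milp_con(m, c(e$idx, xv[[paste0("bc_", key, "_", tt)]]), c(e$coef, -1), lb = 0, ub = 0)
    }
  }
  # average mass*: sum mass* * labels = n* x_ms_bar
  e <- expr_new()
  for (sn in c(spine, fringe)) {
    e <- expr_add(e, ctx$al[[sn]], el$mass_star)
  }
  milp_con(m, c(e$idx, xv[["ms_bar"]]), c(e$coef, -n_star), lb = 0, ub = 0)
  # hydrogens: sum val * labels - 2 sum m mu = n_H
  e <- expr_new()
  for (sn in c(spine, fringe)) e <- expr_add(e, ctx$al[[sn]], el$valence)
  for (ed in ctx$edges) e <- expr_add(e, ed$mu, -2 * (1:3))
  milp_con(m, c(e$idx, xv[["n_H"]]), c(e$coef, -1), lb = 0, ub = 0)
}

#' @noRd
tighten_var_bounds <- function(m, xi, lo, hi) {
  lo2 <- max(m$lb[xi], lo); hi2 <- min(m$ub[xi], hi)
  if (lo2 > hi2) {
    # conflicting box: keep the model well-formed but infeasible
    milp_con(m, xi, 1, lb = lo2)
    milp_con(m, xi, 1, ub = hi2)
  } else {
    m$lb[xi] <- lo2; m$ub[xi] <- hi2
  }
}

#' @noRd
add_ad_rows <- function(m, ctx, ad) {
  n_star <- ctx$spec$n_star
  for (j in seq_len(nrow(ad))) {
    nm <- ad$descriptor[j]
    xi <- ctx$xv[[nm]]
    if (is.null(xi)) next
    scale <- if (ad$rule[j] == "divide_by_n") n_star else 1
    tighten_var_bounds(m, xi, ad$lo[j] * scale - 1e-9, ad$hi[j] * scale + 1e-9)
  }
}

#' @noRd
add_ac_bound_rows <- function(m, ctx, ac_bounds) {
  el <- ctx$spec$elements
  for (r in seq_len(nrow(ac_bounds))) {
    cfg <- normalize_adjacency(el, ac_bounds$a[r], ac_bounds$b[r], ac_bounds$m[r])
    key <- gamma_key(cfg$a, cfg$b, cfg$m)
    ii <- c(ctx$xv[[paste0("ac_", key, "_in")]], ctx$xv[[paste0("ac_", key, "_ex")]])
    milp_con(m, ii, c(1, 1), lb = ac_bounds$lo[r], ub = ac_bounds$hi[r])
  }
}

#' @noRd
fix_x_vars <- function(m, ctx, fix_x) {
  for (nm in names(fix_x)) {
    xi <- ctx$xv[[nm]]
    if (is.null(xi)) stop("unknown descriptor in fix_x: ", nm)
    tighten_var_bounds(m, xi, fix_x[[nm]] - 1e-6, fix_x[[nm]] + 1e-6)
  }
}

# ---------------------------------------------------------------------------
# C1: network inversion

#' @noRd
add_c1 <- function(m, ctx, predictor, y_star, eps, pi) {
  nm <- ctx$dspec$names
  xi <- vapply(nm, function(n_) ctx$xv[[n_]], integer(1))
  xlo <- m$lb[xi]; xhi <- m$ub[xi]
  W1 <- predictor$W1; b1 <- predictor$b1
  h <- nrow(W1)
  yv <- milp_var(m, paste0("y[", pi, "]"), lb = -Inf, ub = Inf, type = "C")
  zsum <- expr_new()
  for (k in seq_len(h)) {
    wk <- W1[k, ]
    s_lo <- sum(pmin(wk * xlo, wk * xhi)) + b1[k]
    s_hi <- sum(pmax(wk * xlo, wk * xhi)) + b1[k]
    zk <- milp_var(m, paste0("relu[", pi, ",", k, "]"), lb = 0, ub = max(s_hi, 0), type = "C")
    if (s_hi <= 0) {
      milp_con(m, zk, 1, lb = 0, ub = 0)
    } else if (s_lo >= 0) {
      milp_con(m, c(zk, xi), c(1, -wk), lb = b1[k], ub = b1[k])
    } else {
      sg <- milp_var(m, paste0("sig[", pi, ",", k, "]"))
      milp_con(m, c(zk, xi), c(1, -wk), lb = b1[k], ub = Inf)           # z >= s
      milp_con(m, c(zk, xi, sg), c(1, -wk, -s_lo), ub = b1[k] - s_lo)   # z <= s - s_lo (1 - sg)
      milp_con(m, c(zk, sg), c(1, -s_hi), ub = 0)                       # z <= s_hi sg
    }
    zsum <- expr_add(zsum, zk, predictor$W2[k])
  }
  milp_con(m, c(zsum$idx, yv), c(zsum$coef, -1),
           lb = -predictor$b2, ub = -predictor$b2)
  lo <- min((1 - eps) * y_star, (1 + eps) * y_star)
  hi <- max((1 - eps) * y_star, (1 + eps) * y_star)
  milp_con(m, yv, 1, lb = lo, ub = hi)
  paste0("y[", pi, "]")
}

# ---------------------------------------------------------------------------
# solve and decode

#' Solve an inverse-inference MILP
#'
#' Runs the engine and, on feasibility, decodes the graph-selection
#' variables into a chemical graph, re-validating every target feature with
#' the independent graph/decomposition/descriptor modules.
#'
#' @param model an [build_milp()] result.
#' @param engine engine name (see [milp_engines()]).
#' @param time_limit seconds.
#' @return object of class `inverse_solution`: list with `status`, `x`
#'   (inferred feature vector), `y` (per-predictor outputs), `graph`
#'   (decoded [chem_graph()] or `NULL`), `raw`.
#' @export
solve_inverse <- function(model, engine = "highs", time_limit = 600) {
  res <- milp_solve(model$milp, engine = engine, time_limit = time_limit)
  if (res$status != "feasible") {
    return(structure(list(status = res$status, x = NULL, y = NULL, graph = NULL,
                          raw = res$raw_status), class = "inverse_solution"))
  }
  g <- decode(res$x, model)
  xval <- stats::setNames(
    vapply(model$dspec$names, function(nm) res$x[[paste0("x[", nm, "]")]], numeric(1)),
    model$dspec$names)
  yv <- if (length(model$y_vars)) stats::setNames(res$x[model$y_vars], model$y_vars) else NULL
  structure(list(status = "feasible", x = xval, y = yv, graph = g, raw = res$raw_status),
            class = "inverse_solution")
}

#' @export
print.inverse_solution <- function(x, ...) {
  cat("<inverse_solution>", x$status, "\n")
  if (!is.null(x$y)) for (nm in names(x$y)) cat(" ", nm, "=", signif(x$y[[nm]], 5), "\n")
  if (!is.null(x$graph)) print(x$graph)
  invisible(x)
}

#' Decode a feasible selection into a chemical graph
#'
#' Reads the binary selection out of a solution vector, assembles the graph,
#' and verifies every contract of the target class (validity, vertex count,
#' diameter, branch height and leaf number, maximum degree, fringe size
#' rule, and descriptor-by-descriptor equality with the model's feature
#' variables). Any violation is reported with the offending feature named.
#'
#' @param sol named solution vector from the solver.
#' @param model an `inverse_milp`.
#' @return a [chem_graph()].
#' @export
decode <- function(sol, model) {
  ctx <- model$ctx; spec <- model$spec
  on <- function(i) !is.na(sol[i]) && sol[i] > 0.5
  verts <- list(); edges <- list()
  for (sn in c(ctx$spine_slots, ctx$fringe_slots)) {
    se <- ctx$sel[[sn]]
    val <- se$const + if (length(se$idx)) sum(sol[se$idx] * se$coef) else 0
    if (val > 0.5) {
      av <- ctx$al[[sn]]
      lab <- spec$elements$label[which.max(sol[av])]
      verts[[length(verts) + 1L]] <- tibble::tibble(id = sn, label = lab)
    }
  }
  for (ed in ctx$edges) {
    if (sum(sol[ed$sel_idx] * ed$sel_coef) > 0.5) {
      mm <- which.max(sol[ed$mu])
      edges[[length(edges) + 1L]] <- tibble::tibble(u = ed$u, v = ed$v, m = as.integer(mm))
    }
  }
  g <- chem_graph(dplyr::bind_rows(verts), dplyr::bind_rows(edges))
  v <- validate_chemical_graph(g, spec$elements, spec$gamma)
  if (!v$ok) stop("decoded graph invalid: ", paste(v$violations$rule, collapse = ", "))
  met <- tree_metrics(g)
  if (n_vertices(g) != spec$n_star) stop("decode: vertex count != n*")
  if (met$diameter != spec$dia_star) {
    stop("decode: diameter ", met$diameter, " != dia* = ", spec$dia_star)
  }
  if (max(met$degree) > spec$d_max) stop("decode: maximum degree exceeds d_max")
  if (spec$d_max == 4L && max(met$degree) != 4L) stop("decode: d_max = 4 demands a degree-4 vertex")
  rt <- root_at_center(g)
  dec <- decompose(rt, spec$k_star)
  if (dec$bl != spec$bl_star) stop("decode: bl_", spec$k_star, " = ", dec$bl, " != bl*")
  if (dec$bh != spec$bh_star) stop("decode: bh_", spec$k_star, " = ", dec$bh, " != bh*")
  if (spec$k_star == 2L && !all(vapply(dec$fringe_trees, fringe_size_ok, logical(1)))) {
    stop("decode: a 2-fringe-tree violates the size rule")
  }
  fv <- feature_vector(g, model$dspec)
  for (nm in model$dspec$names) {
    want <- sol[[paste0("x[", nm, "]")]]
    if (abs(fv[[nm]] - want) > 1e-6) {
      stop("decode: descriptor ", nm, " of the decoded graph (", fv[[nm]],
           ") differs from the model value (", want, ")")
    }
  }
  g
}
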