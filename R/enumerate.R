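#' Frequency-vector layout used by the dynamic program
#'
#' The enumeration stage never manipulates partial graphs directly; it adds
#' integer frequency vectors of chemical rooted trees. The layout is the
#' count sub-vector of the feature vector: element counts, adjacency
#' configurations, degrees and bond-configurations, each split by
#' internal/external attribution (spine vertices and spine edges are
#' 2-internal; fringe material is 2-external).
#'
#' @param dspec a [descriptor_spec()].
#' @return character vector of count-descriptor names.
#' @export
frequency_names <- function(dspec) {
  dspec$fq_names
}

#' @noRd
empty_counts <- function(dspec) {
  stats::setNames(integer(length(dspec$fq_names)), dspec$fq_names)
}

#' @noRd
x_counts <- function(x_star, dspec) {
  nm <- dspec$fq_names
  v <- vapply(nm, function(n_) as.integer(round(x_star[[n_]])), integer(1))
  stats::setNames(v, nm)
}

#' Increment a frequency entry by name; NULL signals a name outside the domain
#' @noRd
bump_at <- function(vec, dspec, name, by = 1L) {
  i <- dspec$fq_idx[[name]]
  if (is.null(i)) return(NULL)
  vec[i] <- vec[i] + by
  vec
}

#' @noRd
bump <- function(vec, name, by = 1L) {
  i <- match(name, names(vec))
  if (is.na(i)) stop("frequency entry outside the descriptor domain: ", name)
  vec[i] <- vec[i] + by
  vec
}

#' @noRd
ac_name <- function(dspec, la, lb, m, t) {
  ra <- match(la, dspec$elements$label)
  rb <- match(lb, dspec$elements$label)
  if (ra <= rb) paste0("ac_", la, "-", lb, "-", m, "_", t)
  else paste0("ac_", lb, "-", la, "-", m, "_", t)
}

#' @noRd
bc_name <- function(d1, d2, m, t) {
  paste0("bc_", bc_key(min(d1, d2), max(d1, d2), m), "_", t)
}

# ---------------------------------------------------------------------------
# FT: chemical rooted trees of height <= 2

#' Generate the fringe-tree pool FT with multiplicities
#'
#' All valence-valid chemical rooted trees of height at most 2 over the
#' spec's alphabet whose edges lie in Gamma and that satisfy the fringe
#' size rule `n(T) <= 2 deg(r) + 2`, pruned to those whose frequency vector
#' is dominated by `x_star`. Trees with the same frequency signature (the
#' vector contribution plus the root's label, fringe degree, used valence
#' and pending bond-configuration entries) are grouped; the group size is
#' the multiplicity W(FT) used for counting without materialising graphs.
#'
#' @param spec a [descriptor_spec()] (k* must be 2).
#' @param x_star a feature vector (the enumeration target).
#' @return list of entries; each has `vec`, `root_label`, `fdeg`, `used`,
#'   `pend` (per root-child `(m, child_deg)`), `height`, `count`, `trees`.
#' @export
generate_fringe_set <- function(spec, x_star) {
  stopifnot(spec$k_star == 2L)
  el <- spec$elements
  gam <- spec$gamma
  gk <- gamma_key(gam$a, gam$b, gam$m)
  xc <- x_counts(x_star, spec)
  n_star <- as.integer(round(x_star[["n"]]))

  rk <- stats::setNames(seq_len(nrow(el)), el$label)
  gamma_ok <- function(la, lb, m) {
    key <- if (rk[[la]] <= rk[[lb]]) paste0(la, "-", lb, "-", m) else paste0(lb, "-", la, "-", m)
    key %in% gk
  }

  # grandchild option lists per (child label b, incoming m): (m2, c)
  gchild_opts <- function(b) {
    out <- list()
    for (cl in el$label) {
      for (m2 in 1:3) {
        if (m2 > val_of(el, cl)) next
        if (!gamma_ok(b, cl, m2)) next
        out[[length(out) + 1L]] <- list(m = m2, lab = cl, code = paste0(m2, cl))
      }
    }
    out[order(vapply(out, function(o) o$code, character(1)), decreasing = TRUE)]
  }
  gopts <- stats::setNames(lapply(el$label, gchild_opts), el$label)

  # child subtrees per (root label a): (m, b, gset)
  child_subtrees <- function(a) {
    out <- list()
    for (b in el$label) {
      for (m in 1:3) {
        if (!gamma_ok(a, b, m)) next
        vb <- val_of(el, b)
        if (m > vb) next
        res <- vb - m
        opts <- gopts[[b]]
        rec <- function(first, mult_left, cnt, chosen) {
          # child degree = 1 + #grandchildren <= 4
          code <- paste0(m, b, "[", paste(vapply(chosen, function(o) o$code, character(1)), collapse = ","), "]")
          out[[length(out) + 1L]] <<- list(m = m, lab = b, gk = chosen, code = code)
          if (cnt >= 3L || first > length(opts)) return(invisible())
          for (k in first:length(opts)) {
            o <- opts[[k]]
            if (o$m > mult_left) next
            rec(k, mult_left - o$m, cnt + 1L, c(chosen, list(o)))
          }
        }
        rec(1L, res, 0L, list())
      }
    }
    out[order(vapply(out, function(o) o$code, character(1)), decreasing = TRUE)]
  }

  entries <- new.env(parent = emptyenv())
  add_tree <- function(a, children) {
    fdeg <- length(children)
    used <- sum(vapply(children, function(ch) ch$m, integer(1)))
    gtot <- sum(vapply(children, function(ch) length(ch$gk), integer(1)))
    if (1L + fdeg + gtot > 2L * fdeg + 2L) return(invisible())   # size rule
    vec <- empty_counts(spec)
    vec <- bump_at(vec, spec, paste0("ce_", a, "_in"))
    height <- 0L
    pend <- list()
    for (ch in children) {
      cd <- 1L + length(ch$gk)
      height <- max(height, 1L + (length(ch$gk) > 0L))
      vec <- bump_at(vec, spec, paste0("ce_", ch$lab, "_ex"))
      vec <- bump_at(vec, spec, paste0("dg_", cd, "_ex"))
      vec <- bump_at(vec, spec, ac_name(spec, a, ch$lab, ch$m, "ex"))
      if (is.null(vec)) return(invisible())
      pend[[length(pend) + 1L]] <- c(ch$m, cd)
      for (g in ch$gk) {
        vec <- bump_at(vec, spec, paste0("ce_", g$lab, "_ex"))
        vec <- bump_at(vec, spec, "dg_1_ex")
        vec <- bump_at(vec, spec, ac_name(spec, ch$lab, g$lab, g$m, "ex"))
        if (!is.null(vec)) vec <- bump_at(vec, spec, bc_name(cd, 1L, g$m, "ex"))
        if (is.null(vec)) return(invisible())
      }
    }
    if (any(vec > xc)) return(invisible())
    if (sum(vec[startsWith(names(vec), "ce_")]) > n_star) return(invisible())
    pend_key <- paste(vapply(pend, function(p) paste(p, collapse = ":"), character(1)), collapse = ";")
    pend_key <- paste(sort(strsplit(pend_key, ";")[[1]]), collapse = ";")
    key <- paste(a, fdeg, used, height, pend_key, paste(vec, collapse = ","), sep = "|")
    cur <- entries[[key]]
    tree <- list(root = a, children = children)
    if (is.null(cur)) {
      entries[[key]] <- list(vec = vec, root_label = a, fdeg = fdeg, used = used,
                             pend = pend, height = height, count = 1L,
                             trees = list(tree), key = key)
    } else {
      cur$count <- cur$count + 1L
      cur$trees <- c(cur$trees, list(tree))
      entries[[key]] <- cur
    }
    invisible()
  }

  for (a in el$label) {
    va <- val_of(el, a)
    subs <- child_subtrees(a)
    rec <- function(first, mult_left, cnt, chosen) {
      add_tree(a, chosen)
      if (cnt >= 3L || first > length(subs)) return(invisible())
      for (k in first:length(subs)) {
        o <- subs[[k]]
        if (o$m > mult_left) next
        rec(k, mult_left - o$m, cnt + 1L, c(chosen, list(o)))
      }
    }
    # at least one unit of valence is reserved for the spine bond
    rec(1L, va - 1L, 0L, list())
  }
  out <- lapply(ls(entries), function(k) entries[[k]])
  out
}

# ---------------------------------------------------------------------------
# chain states

#' @noRd
chain_start <- function(entry) {
  list(vec = entry$vec, end_label = entry$root_label, end_fdeg = entry$fdeg,
       end_used = entry$used, end_pend = entry$pend, pend_edge = NULL,
       p = 1L)
}

#' @noRd
state_key <- function(st) {
  paste(st$end_label, st$end_fdeg, st$end_used,
        paste(vapply(st$end_pend, function(p) paste(p, collapse = ":"), character(1)), collapse = ";"),
        if (is.null(st$pend_edge)) "-" else paste(st$pend_edge, collapse = ":"),
        paste(st$vec, collapse = ","), sep = "|")
}

#' Extend a chain by one fringe tree
#'
#' Joins the roots of the current chain end and a new fringe tree with a
#' spine edge of multiplicity `m`. The old end's degree becomes final, which
#' settles its pending bond-configuration entries and the previous spine
#' edge's bond-configuration; the new spine edge's bond-configuration stays
#' pending on the new end. Returns `NULL` when the join violates valence or
#' overruns the target counts (a rejected combination, not an error).
#'
#' @param st chain state.
#' @param entry fringe-set entry becoming the new end.
#' @param m spine bond multiplicity in \[1, 3\].
#' @param spec a [descriptor_spec()].
#' @param xc target counts (from the feature vector being inverted).
#' @return new state or `NULL`.
#' @export
chain_extend <- function(st, entry, m, spec, xc) {
  el <- spec$elements
  prev_m <- if (is.null(st$pend_edge)) 0L else st$pend_edge[1]
  if (st$end_used + prev_m + m > val_of(el, st$end_label)) return(NULL)
  D <- st$end_fdeg + (if (is.null(st$pend_edge)) 1L else 2L)
  if (D > 4L) return(NULL)
  vec <- st$vec + entry$vec
  vec <- bump_at(vec, spec, paste0("dg_", D, "_in"))
  for (p_ in st$end_pend) {
    if (is.null(vec)) return(NULL)
    vec <- bump_at(vec, spec, bc_name(D, p_[2], p_[1], "ex"))
  }
  if (is.null(vec)) return(NULL)
  if (!is.null(st$pend_edge)) {
    vec <- bump_at(vec, spec, bc_name(D, st$pend_edge[2], st$pend_edge[1], "in"))
    if (is.null(vec)) return(NULL)
  }
  vec <- bump_at(vec, spec, ac_name(spec, st$end_label, entry$root_label, m, "in"))
  if (is.null(vec)) return(NULL)
  if (any(vec > xc)) return(NULL)
  list(vec = vec, end_label = entry$root_label, end_fdeg = entry$fdeg,
       end_used = entry$used, end_pend = entry$pend,
       pend_edge = c(m, D), p = st$p + 1L)
}

#' Close a pair of chains with a middle bond
#'
#' Joins the exposed roots of two chains with an edge of multiplicity `m`,
#' finalising both end degrees, both pending spine edges and the middle
#' edge itself. Returns the completed frequency vector or `NULL` if the
#' join is invalid.
#'
#' @param st1,st2 chain states.
#' @param m middle bond multiplicity.
#' @param spec a [descriptor_spec()].
#' @param xc target counts.
#' @return completed counts vector or `NULL`.
#' @export
combine <- function(st1, st2, m, spec, xc) {
  el <- spec$elements
  fin <- function(st) {
    prev_m <- if (is.null(st$pend_edge)) 0L else st$pend_edge[1]
    if (st$end_used + prev_m + m > val_of(el, st$end_label)) return(NULL)
    D <- st$end_fdeg + (if (is.null(st$pend_edge)) 1L else 2L)
    if (D > 4L) return(NULL)
    D
  }
  D1 <- fin(st1); if (is.null(D1)) return(NULL)
  D2 <- fin(st2); if (is.null(D2)) return(NULL)
  vec <- st1$vec + st2$vec
  sts <- list(st1, st2); Ds <- c(D1, D2)
  for (si in 1:2) {
    st <- sts[[si]]; D <- Ds[si]
    vec <- bump_at(vec, spec, paste0("dg_", D, "_in"))
    for (p_ in st$end_pend) {
      if (is.null(vec)) return(NULL)
      vec <- bump_at(vec, spec, bc_name(D, p_[2], p_[1], "ex"))
    }
    if (is.null(vec)) return(NULL)
    if (!is.null(st$pend_edge)) {
      vec <- bump_at(vec, spec, bc_name(D, st$pend_edge[2], st$pend_edge[1], "in"))
      if (is.null(vec)) return(NULL)
    }
  }
  vec <- bump_at(vec, spec, ac_name(spec, st1$end_label, st2$end_label, m, "in"))
  if (is.null(vec)) return(NULL)
  vec <- bump_at(vec, spec, bc_name(D1, D2, m, "in"))
  if (is.null(vec)) return(NULL)
  if (any(vec > xc)) return(NULL)
  vec
}

# ---------------------------------------------------------------------------
# main enumeration

#' Enumerate chemical acyclic graphs matching a feature vector
#'
#' Stage-5 search: a two-sided (or, for `bl* = 3`, three-armed) dynamic
#' program over frequency vectors of chains of fringe trees. For
#' `bl* = 2` the target graph is a caterpillar whose spine (the 2-internal
#' path between the two leaf 2-branches) has `s = dia* - 3` vertices; chains
#' of `p` fringe trees (the first always of height exactly 2) are extended
#' one tree at a time, and chains of `floor(s/2)` and `ceil(s/2)` trees are
#' joined by the middle bond. For `bl* = 3` three arms meeting at a junction
#' are combined, with the junction's fringe and centrality deciding the
#' branch height. `#FP` counts feasible vector tuples; `G-LB` is a lower
#' bound on the number of target graphs computed from multiplicity products
#' without materialising graphs; up to `cap` graphs are reconstructed by
#' back-tracing.
#'
#' @param x_star feature vector to invert (integral counts).
#' @param spec a [descriptor_spec()] with `k* = 2`.
#' @param cap maximum number of graphs to reconstruct (default 100).
#' @param ub_schedule upper bounds on the running vector-set size, escalated
#'   on overflow (default `c(1e6, 1e7, 1e8)`).
#' @param time_limit seconds per stage (default 600).
#' @return object of class `enumeration_result`: `feasible_pairs` (#FP),
#'   `lower_bound` (G-LB), `graphs`, `status`, `diagnostic`.
#' @export
enumerate_graphs <- function(x_star, spec, cap = 100L,
                             ub_schedule = c(1e6, 1e7, 1e8), time_limit = 600) {
  chk <- check_x_consistency(x_star, spec)
  if (!chk$ok) {
    return(structure(list(feasible_pairs = 0L, lower_bound = 0L, graphs = list(),
                          status = "inconsistent", diagnostic = chk$why),
                     class = "enumeration_result"))
  }
  bl <- as.integer(round(x_star[["bl"]]))
  if (!(bl %in% c(2L, 3L))) {
    return(structure(list(feasible_pairs = 0L, lower_bound = 0L, graphs = list(),
                          status = "unsupported", diagnostic = paste0("bl = ", bl, " outside {2, 3}")),
                     class = "enumeration_result"))
  }
  for (ub in ub_schedule) {
    res <- tryCatch(
      enumerate_attempt(x_star, spec, bl, cap, ub, time_limit),
      overflowError = function(e) NULL
    )
    if (!is.null(res)) return(res)
  }
  structure(list(feasible_pairs = 0L, lower_bound = 0L, graphs = list(),
                 status = "memory-bound", diagnostic = "vector-set size exceeded every UB"),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat("<enumeration_result>", x$status, " #FP =", x$feasible_pairs,
      " G-LB =", format(x$lower_bound, big.mark = ","), " graphs =", length(x$graphs), "\n")
  invisible(x)
}

#' Glance at an enumeration result
#' @param x an `enumeration_result`.
#' @param ... unused.
#' @method glance enumeration_result
#' @export
glance.enumeration_result <- function(x, ...) {
  tibble::tibble(status = x$status, feasible_pairs = x$feasible_pairs,
                 lower_bound = x$lower_bound, n_graphs = length(x$graphs))
}

#' @noRd
check_x_consistency <- function(x_star, spec) {
  bad <- function(why) list(ok = FALSE, why = why)
  xc <- x_counts(x_star, spec)
  n <- round(x_star[["n"]])
  ce <- xc[startsWith(names(xc), "ce_")]
  ac <- xc[startsWith(names(xc), "ac_")]
  dg <- xc[startsWith(names(xc), "dg_")]
  if (sum(ce) != n) return(bad("element counts do not sum to n"))
  if (sum(ac) != n - 1) return(bad("adjacency-configuration counts do not sum to n - 1"))
  if (sum(dg) != n) return(bad("degree counts do not sum to n"))
  # hydrogen identity
  el <- spec$elements
  valsum <- 0
  for (a in el$label) {
    valsum <- valsum + val_of(el, a) *
      (xc[[paste0("ce_", a, "_in")]] + xc[[paste0("ce_", a, "_ex")]])
  }
  msum <- 0
  for (gi in seq_len(nrow(spec$gamma))) {
    key <- gamma_key(spec$gamma$a[gi], spec$gamma$b[gi], spec$gamma$m[gi])
    msum <- msum + spec$gamma$m[gi] *
      (xc[[paste0("ac_", key, "_in")]] + xc[[paste0("ac_", key, "_ex")]])
  }
  if (abs(valsum - 2 * msum - x_star[["n_H"]]) > 1e-6) {
    return(bad("n_H inconsistent with element/adjacency counts"))
  }
  # bd identity
  for (mm in 2:3) for (tt in c("in", "ex")) {
    tot <- 0
    for (gi in which(spec$gamma$m == mm)) {
      key <- gamma_key(spec$gamma$a[gi], spec$gamma$b[gi], spec$gamma$m[gi])
      tot <- tot + xc[[paste0("ac_", key, "_", tt)]]
    }
    if (tot != round(x_star[[paste0("bd_", mm, "_", tt)]])) {
      return(bad(paste0("bd_", mm, "_", tt, " inconsistent with ac counts")))
    }
  }
  dia <- round(x_star[["dia_bar"]] * n)
  if (dia < 1) return(bad("diameter from dia_bar is degenerate"))
  list(ok = TRUE, why = NULL)
}

#' @noRd
overflow <- function() {
  stop(structure(class = c("overflowError", "error", "condition"),
                 list(message = "UB exceeded", call = NULL)))
}

#' @noRd
enumerate_attempt <- function(x_star, spec, bl, cap, ub, time_limit) {
  t0 <- Sys.time()
  timed_out <- function() as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit
  xc <- x_counts(x_star, spec)
  n <- as.integer(round(x_star[["n"]]))
  dia <- as.integer(round(x_star[["dia_bar"]] * n))
  bh <- as.integer(round(x_star[["bh"]]))
  s_in <- sum(xc[startsWith(names(xc), "ce_") & endsWith(names(xc), "_in")])

  ft <- generate_fringe_set(spec, x_star)
  ft_by_key <- stats::setNames(ft, vapply(ft, function(e) e$key, character(1)))
  ends <- Filter(function(e) e$height == 2L, ft)

  if (bl == 2L) {
    s <- dia - 3L
    if (bh != 1L || s < 3L || s_in != s) {
      return(structure(list(feasible_pairs = 0L, lower_bound = 0L, graphs = list(),
                            status = "completed",
                            diagnostic = "no caterpillar spine consistent with x*"),
                       class = "enumeration_result"))
    }
    enumerate_bl2(x_star, spec, xc, s, ends, ft, ft_by_key, cap, ub, timed_out)
  } else {
    enumerate_bl3(x_star, spec, xc, n, dia, bh, s_in, ends, ft, ft_by_key, cap, ub, timed_out)
  }
}

#' @noRd
grow_levels <- function(p_max, ends, ft, spec, xc, ub, timed_out, s, reserve_min) {
  # W[[p]]: map key -> list(state, count, preds = list of (prev_key, entry_key, m))
  W <- vector("list", p_max)
  lvl <- new.env(parent = emptyenv())
  for (e in ends) {
    st <- chain_start(e)
    if (sum(st$vec[startsWith(names(st$vec), "ce_")]) + (s - 1L) > sum(xc[startsWith(names(xc), "ce_")])) next
    k <- state_key(st)
    lvl[[k]] <- list(state = st, count = e$count, preds = list(list(NULL, e$key, NA_integer_)))
  }
  W[[1]] <- lvl
  if (p_max >= 2) {
    for (p in 2:p_max) {
      if (timed_out()) stop(structure(class = c("timeoutError", "error", "condition"),
                                      list(message = "time limit", call = NULL)))
      nxt <- new.env(parent = emptyenv())
      cnt <- 0L
      for (k in ls(W[[p - 1]])) {
        rec <- W[[p - 1]][[k]]
        for (e in ft) {
          for (mm in 1:3) {
            st <- chain_extend(rec$state, e, mm, spec, xc)
            if (is.null(st)) next
            # room: each remaining spine vertex needs >= 1 vertex
            if (sum(st$vec[startsWith(names(st$vec), "ce_")]) + (s - p) >
                sum(xc[startsWith(names(xc), "ce_")])) next
            # the exposed end still needs reserve_min spine valence
            if (st$end_used + st$pend_edge[1] + (reserve_min - 1L) > val_of(spec$elements, st$end_label)) next
            kk <- state_key(st)
            cur <- nxt[[kk]]
            if (is.null(cur)) {
              cnt <- cnt + 1L
              if (cnt > ub) overflow()
              nxt[[kk]] <- list(state = st, count = rec$count * e$count,
                                preds = list(list(k, e$key, mm)))
            } else {
              cur$count <- cur$count + rec$count * e$count
              cur$preds <- c(cur$preds, list(list(k, e$key, mm)))
              nxt[[kk]] <- cur
            }
          }
        }
      }
      W[[p]] <- nxt
    }
  }
  W
}

#' @noRd
enumerate_bl2 <- function(x_star, spec, xc, s, ends, ft, ft_by_key, cap, ub, timed_out) {
  p1 <- s %/% 2L; p2 <- s - p1
  status <- "completed"
  W <- tryCatch(
    grow_levels(max(p1, p2), ends, ft, spec, xc, ub, timed_out, s, reserve_min = 1L),
    timeoutError = function(e) NULL
  )
  if (is.null(W)) {
    return(structure(list(feasible_pairs = 0L, lower_bound = 0L, graphs = list(),
                          status = "time-limit", diagnostic = "chain growth timed out"),
                     class = "enumeration_result"))
  }
  fp <- 0L
  ordered_assemblies <- 0
  pairs <- list()
  k1s <- ls(W[[p1]]); k2s <- ls(W[[p2]])
  seen_pair <- new.env(parent = emptyenv())
  for (k1 in k1s) {
    r1 <- W[[p1]][[k1]]
    for (k2 in k2s) {
      r2 <- W[[p2]][[k2]]
      for (mm in 1:3) {
        vec <- combine(r1$state, r2$state, mm, spec, xc)
        if (is.null(vec)) next
        if (!all(vec == xc)) next
        pkey <- if (p1 == p2) paste(min(k1, k2), max(k1, k2), mm) else paste(k1, k2, mm)
        if (!is.null(seen_pair[[pkey]])) next
        seen_pair[[pkey]] <- TRUE
        fp <- fp + 1L
        if (p1 == p2) {
          ordered_assemblies <- ordered_assemblies +
            if (k1 == k2) r1$count * (r1$count + 1) / 2 else r1$count * r2$count
        } else {
          ordered_assemblies <- ordered_assemblies + r1$count * r2$count
        }
        pairs[[length(pairs) + 1L]] <- list(k1 = k1, k2 = k2, m = mm)
      }
    }
  }
  glb <- if (p1 == p2) ordered_assemblies else ceiling(ordered_assemblies / 2)
  graphs <- reconstruct_bl2(pairs, W, p1, p2, ft_by_key, spec, cap)
  glb <- max(glb, length(graphs))
  structure(list(feasible_pairs = fp, lower_bound = as.numeric(glb), graphs = graphs,
                 status = status, diagnostic = NULL),
            class = "enumeration_result")
}

#' @noRd
unroll_chain <- function(key, p, W, ft_by_key, limit) {
  # returns list of chains; each chain = list of (entry_tree, m_to_previous)
  rec <- W[[p]][[key]]
  out <- list()
  for (pr in rec$preds) {
    prev_key <- pr[[1]]; ekey <- pr[[2]]; mm <- pr[[3]]
    entry <- ft_by_key[[ekey]]
    if (is.null(prev_key)) {
      for (tr in entry$trees) {
        out[[length(out) + 1L]] <- list(list(tree = tr, m = NA_integer_))
        if (length(out) >= limit) return(out)
      }
    } else {
      subs <- unroll_chain(prev_key, p - 1L, W, ft_by_key, limit)
      for (sb in subs) {
        for (tr in entry$trees) {
          out[[length(out) + 1L]] <- c(sb, list(list(tree = tr, m = mm)))
          if (length(out) >= limit) return(out)
        }
      }
    }
  }
  out
}

#' @noRd
tree_to_rows <- function(tree, base_id) {
  verts <- list(tibble::tibble(id = base_id, label = tree$root))
  edges <- list()
  ci <- 0L
  for (ch in tree$children) {
    ci <- ci + 1L
    cid <- paste0(base_id, ".", ci)
    verts[[length(verts) + 1L]] <- tibble::tibble(id = cid, label = ch$lab)
    edges[[length(edges) + 1L]] <- tibble::tibble(u = base_id, v = cid, m = as.integer(ch$m))
    gi <- 0L
    for (g in ch$gk) {
      gi <- gi + 1L
      gid <- paste0(cid, ".", gi)
      verts[[length(verts) + 1L]] <- tibble::tibble(id = gid, label = g$lab)
      edges[[length(edges) + 1L]] <- tibble::tibble(u = cid, v = gid, m = as.integer(g$m))
    }
  }
  list(vertices = dplyr::bind_rows(verts),
       edges = if (length(edges)) dplyr::bind_rows(edges) else NULL)
}

#' @noRd
assemble_spine <- function(chains_with_links) {
  # chains_with_links: list of (tree, m_link) in spine order; m_link joins to
  # the previous spine vertex
  verts <- list(); edges <- list()
  prev_id <- NULL
  for (i in seq_along(chains_with_links)) {
    it <- chains_with_links[[i]]
    bid <- paste0("s", i)
    rows <- tree_to_rows(it$tree, bid)
    verts[[length(verts) + 1L]] <- rows$vertices
    if (!is.null(rows$edges)) edges[[length(edges) + 1L]] <- rows$edges
    if (!is.null(prev_id)) {
      edges[[length(edges) + 1L]] <- tibble::tibble(u = prev_id, v = bid, m = as.integer(it$m))
    }
    prev_id <- bid
  }
  chem_graph(dplyr::bind_rows(verts), dplyr::bind_rows(edges))
}

#' @noRd
reconstruct_bl2 <- function(pairs, W, p1, p2, ft_by_key, spec, cap) {
  graphs <- list()
  seen <- new.env(parent = emptyenv())
  for (pr in pairs) {
    if (length(graphs) >= cap) break
    left <- unroll_chain(pr$k1, p1, W, ft_by_key, limit = cap * 4L)
    right <- unroll_chain(pr$k2, p2, W, ft_by_key, limit = cap * 4L)
    for (lc in left) {
      for (rc in right) {
        # spine order: left tip .. left inner end, middle bond, right inner
        # end .. right tip (chains are stored tip-first)
        items <- list()
        for (i in seq_along(lc)) {
          items[[length(items) + 1L]] <- list(tree = lc[[i]]$tree, m = lc[[i]]$m)
        }
        for (i in rev(seq_along(rc))) {
          items[[length(items) + 1L]] <- list(
            tree = rc[[i]]$tree,
            m = if (i == length(rc)) pr$m else rc[[i + 1L]]$m)
        }
        g <- assemble_spine(items)
        cf <- canonical_form(g)
        if (is.null(seen[[cf]])) {
          seen[[cf]] <- TRUE
          graphs[[length(graphs) + 1L]] <- g
          if (length(graphs) >= cap) break
        }
      }
      if (length(graphs) >= cap) break
    }
  }
  graphs
}

#' @noRd
enumerate_bl3 <- function(x_star, spec, xc, n, dia, bh, s_in, ends, ft, ft_by_key,
                          cap, ub, timed_out) {
  # three arms of c1 >= c2 >= c3 >= 1 spine vertices each meet a junction;
  # c1 + c2 = dia - 4 and 1 + c1 + c2 + c3 = #internal vertices fixes c3.
  c12 <- dia - 4L
  c3 <- s_in - 1L - c12
  empty <- function(why) structure(
    list(feasible_pairs = 0L, lower_bound = 0L, graphs = list(),
         status = "completed", diagnostic = why), class = "enumeration_result")
  if (c3 < 1L || c12 < 2L) return(empty("no three-arm split consistent with x*"))
  p_max <- max(c12 - c3, c3)
  if (c12 - c3 < ceiling(c12 / 2)) return(empty("arm ordering infeasible"))
  W <- tryCatch(
    grow_levels(p_max, ends, ft, spec, xc, ub, timed_out,
                s = s_in, reserve_min = 1L),
    timeoutError = function(e) NULL
  )
  if (is.null(W)) {
    return(structure(list(feasible_pairs = 0L, lower_bound = 0L, graphs = list(),
                          status = "time-limit", diagnostic = "chain growth timed out"),
                     class = "enumeration_result"))
  }
  el <- spec$elements
  fp <- 0L; glb <- 0
  tuples <- list()
  seen_t <- new.env(parent = emptyenv())
  for (c1 in seq.int(ceiling(c12 / 2), c12 - 1L)) {
    c2 <- c12 - c1
    if (c2 < c3) next
    j_central <- (c1 - c2) <= 1L
    for (jent in c(ft, list(NULL))) {
      # junction fringe: NULL = bare junction vertex (counts as an FT entry of
      # a single vertex? no: a bare junction is the single-vertex tree in FT)
      if (is.null(jent)) next
      jdeg <- 3L + jent$fdeg
      if (jdeg > 4L) next
      want_bh <- if (j_central || jent$fdeg > 0L) 1L else 2L
      if (want_bh != bh) next
      if (jent$used + 3L > val_of(el, jent$root_label)) next
      for (k1 in ls(W[[c1]])) {
        r1 <- W[[c1]][[k1]]
        for (k2 in ls(W[[c2]])) {
          r2 <- W[[c2]][[k2]]
          for (k3 in ls(W[[c3]])) {
            r3 <- W[[c3]][[k3]]
            for (m1 in 1:3) for (m2 in 1:3) for (m3 in 1:3) {
              vec <- join_three(jent, list(r1$state, r2$state, r3$state),
                                c(m1, m2, m3), jdeg, spec, xc)
              if (is.null(vec)) next
              if (!all(vec == xc)) next
              arms <- list(list(c1, k1, m1), list(c2, k2, m2), list(c3, k3, m3))
              okey <- vapply(arms, function(a_) paste(a_[[1]], a_[[2]], a_[[3]]), character(1))
              tkey <- paste(jent$key, paste(sort(okey), collapse = "||"))
              if (!is.null(seen_t[[tkey]])) next
              seen_t[[tkey]] <- TRUE
              fp <- fp + 1L
              counts <- c(r1$count, r2$count, r3$count)
              perms <- prod(factorial(table(okey)))
              glb <- glb + max(1, floor(jent$count * prod(counts) / perms))
              tuples[[length(tuples) + 1L]] <-
                list(j = jent$key, arms = list(c(c1, m1), c(c2, m2), c(c3, m3)),
                     keys = c(k1, k2, k3))
            }
          }
        }
      }
    }
  }
  graphs <- reconstruct_bl3(tuples, W, ft_by_key, cap)
  glb <- max(glb, length(graphs))
  structure(list(feasible_pairs = fp, lower_bound = as.numeric(glb), graphs = graphs,
                 status = "completed", diagnostic = NULL),
            class = "enumeration_result")
}

#' @noRd
join_three <- function(jent, states, ms, jdeg, spec, xc) {
  el <- spec$elements
  if (sum(ms) + jent$used > val_of(el, jent$root_label)) return(NULL)
  vec <- jent$vec + states[[1]]$vec + states[[2]]$vec + states[[3]]$vec
  vec <- bump_at(vec, spec, paste0("dg_", jdeg, "_in"))
  for (p_ in jent$pend) {
    if (is.null(vec)) return(NULL)
    vec <- bump_at(vec, spec, bc_name(jdeg, p_[2], p_[1], "ex"))
  }
  if (is.null(vec)) return(NULL)
  for (i in 1:3) {
    st <- states[[i]]; m <- ms[i]
    prev_m <- if (is.null(st$pend_edge)) 0L else st$pend_edge[1]
    if (st$end_used + prev_m + m > val_of(el, st$end_label)) return(NULL)
    D <- st$end_fdeg + (if (is.null(st$pend_edge)) 1L else 2L)
    if (D > 4L) return(NULL)
    vec <- bump_at(vec, spec, paste0("dg_", D, "_in"))
    for (p_ in st$end_pend) {
      if (is.null(vec)) return(NULL)
      vec <- bump_at(vec, spec, bc_name(D, p_[2], p_[1], "ex"))
    }
    if (is.null(vec)) return(NULL)
    if (!is.null(st$pend_edge)) {
      vec <- bump_at(vec, spec, bc_name(D, st$pend_edge[2], st$pend_edge[1], "in"))
      if (is.null(vec)) return(NULL)
    }
    vec <- bump_at(vec, spec, ac_name(spec, jent$root_label, st$end_label, m, "in"))
    if (is.null(vec)) return(NULL)
    vec <- bump_at(vec, spec, bc_name(jdeg, D, m, "in"))
    if (is.null(vec)) return(NULL)
    if (any(vec > xc)) return(NULL)
  }
  vec
}

#' @noRd
reconstruct_bl3 <- function(tuples, W, ft_by_key, cap) {
  graphs <- list()
  seen <- new.env(parent = emptyenv())
  for (tp in tuples) {
    if (length(graphs) >= cap) break
    jent <- ft_by_key[[tp$j]]
    armsets <- lapply(1:3, function(i) {
      unroll_chain(tp$keys[i], tp$arms[[i]][1], W, ft_by_key, limit = cap * 2L)
    })
    for (a1 in armsets[[1]]) for (a2 in armsets[[2]]) for (a3 in armsets[[3]]) {
      for (jt in jent$trees) {
        verts <- list(); edges <- list()
        jr <- tree_to_rows(jt, "J")
        verts[[1]] <- jr$vertices
        if (!is.null(jr$edges)) edges[[length(edges) + 1L]] <- jr$edges
        arms <- list(a1, a2, a3)
        for (ai in 1:3) {
          chain <- arms[[ai]]
          m_j <- tp$arms[[ai]][2]
          prev <- "J"
          # chain runs tip -> inward; attach inward-most first
          for (q in rev(seq_along(chain))) {
            bid <- paste0("a", ai, "v", q)
            rows <- tree_to_rows(chain[[q]]$tree, bid)
            verts[[length(verts) + 1L]] <- rows$vertices
            if (!is.null(rows$edges)) edges[[length(edges) + 1L]] <- rows$edges
            mlink <- if (q == length(chain)) m_j else chain[[q + 1L]]$m
            edges[[length(edges) + 1L]] <- tibble::tibble(u = prev, v = bid, m = as.integer(mlink))
            prev <- bid
          }
        }
        g <- chem_graph(dplyr::bind_rows(verts), dplyr::bind_rows(edges))
        cf <- canonical_form(g)
        if (is.null(seen[[cf]])) {
          seen[[cf]] <- TRUE
          graphs[[length(graphs) + 1L]] <- g
          if (length(graphs) >= cap) break
        }
      }
      if (length(graphs) >= cap) break
    }
  }
  graphs
}

#' Lower bound on the number of target graphs
#'
#' Extracted from an [enumerate_graphs()] result: the bound computed from
#' products of frequency-vector multiplicities (never smaller than the
#' number of distinct reconstructed graphs, never larger than the true
#' count).
#'
#' @param result an `enumeration_result`.
#' @return numeric scalar.
#' @export
lower_bound <- function(result) {
  stopifnot(inherits(result, "enumeration_result"))
  result$lower_bound
}
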