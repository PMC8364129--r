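#' @noRd
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generator configuration
#'
#' Settings for the synthetic-data generator that stands in for a curated
#' database in the training stage: element table, adjacency-configuration
#' set, size and class parameters, and the linear-plus-noise synthetic
#' property model.
#'
#' @param elements an [element_table()].
#' @param gamma a `gamma_set` (default: all valence-feasible configurations).
#' @param n vertex count or range `c(lo, hi)`.
#' @param d_max 3 or 4.
#' @param k_star branch-parameter (the generator targets `k* = 2` classes).
#' @param bl range of 2-branch-leaf numbers to draw from (subset of 2:3).
#' @param dia optional diameter or range; default chosen feasibly from `n`.
#' @param p_multi probability that an upgradable edge receives a higher
#'   multiplicity.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(elements = default_elements(), gamma = NULL,
                             n = c(10L, 16L), d_max = 3L, k_star = 2L,
                             bl = c(2L, 3L), dia = NULL, p_multi = 0.15) {
  if (is.null(gamma)) gamma <- all_adjacency_configs(elements)
  if (k_star != 2L) stop("the class generator supports k* = 2")
  structure(list(elements = elements, gamma = gamma, n = as.integer(n),
                 d_max = as.integer(d_max), k_star = 2L, bl = as.integer(bl),
                 dia = if (is.null(dia)) NULL else as.integer(dia),
                 p_multi = p_multi),
            class = "generator_config")
}

#' Random chemical acyclic graph in the bounded branch-height class
#'
#' Draws a valence-valid chemical tree with the requested vertex count,
#' maximum degree, exact 2-branch-leaf number `bl` in \{2, 3\} and exact
#' diameter. The graph is built constructively — a spine (or three-armed
#' star of spines) realising the diameter, leaf-2-branch fringe trees of
#' height exactly 2 at the arm tips, and random valence-feasible fringe
#' material elsewhere — so class membership holds by construction rather
#' than rejection. Deterministic per seed.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a [chem_graph()].
#' @export
random_graph <- function(config, seed) {
  with_local_seed(seed, random_graph_impl(config))
}

#' @noRd
random_graph_impl <- function(config) {
  el <- config$elements
  d_max <- config$d_max
  n <- if (length(config$n) == 2) sample(config$n[1]:config$n[2], 1) else config$n[1]
  bl_ok <- config$bl[config$bl == 2L | (config$bl == 3L & n >= 10L)]
  if (!length(bl_ok)) {
    stop("unsatisfiable generator request: n = ", n,
         " cannot host bl in {", paste(config$bl, collapse = ","), "}")
  }
  bl <- if (length(bl_ok) >= 2) sample(bl_ok, 1) else bl_ok[1]

  cap_end <- (d_max - 1L) + min(d_max - 1L + 1L, (d_max - 1L) * (d_max - 1L))  # c + g caps
  cap_end <- min(cap_end, 2L * d_max - 1L)
  cap_int <- if (d_max >= 3) (d_max - 2L) + min(d_max - 2L + 1L, (d_max - 2L) * (d_max - 1L)) else 0L

  if (bl == 2L) {
    # caterpillar: spine of s = dia - 3 vertices, height-2 fringes at both ends
    dia_rng <- if (!is.null(config$dia)) config$dia else c(6L, n - 1L)
    lo <- max(6L, dia_rng[1]); hi <- min(n - 1L, dia_rng[length(dia_rng)])
    feas <- integer(0)
    for (d in lo:hi) {
      s <- d - 3L
      if (s >= 3L && n >= s + 4L && n <= s + 2L * cap_end + (s - 2L) * cap_int) feas <- c(feas, d)
    }
    if (!length(feas)) stop("unsatisfiable generator request: n = ", n, ", bl = 2, dia in [",
                            lo, ",", hi, "] cannot host a caterpillar in the class")
    dia <- sample(rep(feas, 2), 1)
    s <- dia - 3L
    extras <- allocate_extras(n - s, n_slots = s,
                              lo = c(2L, rep(0L, s - 2L), 2L),
                              hi = c(cap_end, rep(cap_int, s - 2L), cap_end))
    build_caterpillar(el, config$gamma, extras, d_max, config$p_multi)
  } else {
    dia_rng <- if (!is.null(config$dia)) config$dia else c(6L, n - 1L)
    lo <- max(6L, dia_rng[1]); hi <- min(n - 1L, dia_rng[length(dia_rng)])
    pick <- NULL
    for (d in sample(lo:hi)) {
      tot12 <- d - 4L          # c1 + c2
      if (tot12 < 2L) next
      for (c1 in sample(seq.int(ceiling(tot12 / 2), tot12 - 1L))) {
        c2 <- tot12 - c1
        if (c2 < 1L) next
        for (c3 in sample(seq_len(c2))) {
          spine <- 1L + c1 + c2 + c3
          if (n < spine + 6L) next   # three height-2 tip fringes
          cap_total <- 3L * cap_end + (c1 + c2 + c3 - 3L) * cap_int +
            max(d_max - 3L, 0L) * 2L
          if (n > spine + cap_total) next
          pick <- c(d, c1, c2, c3); break
        }
        if (!is.null(pick)) break
      }
      if (!is.null(pick)) break
    }
    if (is.null(pick)) stop("unsatisfiable generator request: n = ", n,
                            ", bl = 3, dia in [", lo, ",", hi, "]")
    build_y_tree(el, config$gamma, n, pick[1], pick[2:4], d_max, config$p_multi)
  }
}

#' @noRd
allocate_extras <- function(total, n_slots, lo, hi) {
  extras <- lo
  rem <- total - sum(lo)
  if (rem < 0) stop("internal: allocation infeasible")
  open <- which(extras < hi)
  while (rem > 0 && length(open)) {
    k <- if (length(open) == 1) open else sample(open, 1)
    extras[k] <- extras[k] + 1L
    rem <- rem - 1L
    open <- which(extras < hi)
  }
  if (rem > 0) stop("internal: allocation infeasible (caps)")
  extras
}

#' @noRd
pick_label <- function(el, min_val) {
  ok <- el$label[el$valence >= min_val]
  if (!length(ok)) stop("no element with valence >= ", min_val)
  if (length(ok) == 1) ok else sample(ok, 1, prob = ifelse(ok == "C", 4, 1))
}

#' Build one fringe tree at a host; returns vertices/edges rows
#' @noRd
build_fringe <- function(el, host_id, extra, max_children, id0, exact_height2 = FALSE) {
  stopifnot(extra >= 0)
  verts <- list(); edges <- list()
  nid <- id0
  if (extra == 0) return(list(vertices = NULL, edges = NULL, next_id = nid, children = 0L))
  # split extra into c children and g grandchildren with g <= c + 1 (size rule)
  c_lo <- max(1L, ceiling((extra - 1L) / 2))
  c_hi <- min(max_children, extra)
  if (exact_height2) c_hi <- min(c_hi, extra - 1L)
  if (c_lo > c_hi) stop("internal: fringe split infeasible")
  cc <- if (c_lo == c_hi) c_lo else sample(c_lo:c_hi, 1)
  gg <- extra - cc
  if (gg > cc + 1L) stop("internal: fringe size rule violated")
  kids <- character(cc)
  for (i in seq_len(cc)) {
    kids[i] <- as.character(nid); nid <- nid + 1L
  }
  # distribute grandchildren over children (child k gets g_k)
  gdist <- integer(cc)
  rem <- gg
  while (rem > 0) {
    k <- if (cc == 1) 1L else sample(seq_len(cc), 1)
    gdist[k] <- gdist[k] + 1L
    rem <- rem - 1L
  }
  for (i in seq_len(cc)) {
    lab <- pick_label(el, min_val = 1L + gdist[i])
    verts[[length(verts) + 1L]] <- tibble::tibble(id = kids[i], label = lab)
    edges[[length(edges) + 1L]] <- tibble::tibble(u = host_id, v = kids[i], m = 1L)
    for (j in seq_len(gdist[i])) {
      gid <- as.character(nid); nid <- nid + 1L
      verts[[length(verts) + 1L]] <- tibble::tibble(id = gid, label = pick_label(el, 1L))
      edges[[length(edges) + 1L]] <- tibble::tibble(u = kids[i], v = gid, m = 1L)
    }
  }
  list(vertices = dplyr::bind_rows(verts), edges = dplyr::bind_rows(edges),
       next_id = nid, children = cc)
}

#' @noRd
build_caterpillar <- function(el, gamma, extras, d_max, p_multi) {
  s <- length(extras)
  spine_ids <- as.character(seq_len(s))
  verts <- list(); edges <- list()
  nid <- s + 1L
  fringe_children <- integer(s)
  for (i in seq_len(s)) {
    maxc <- if (i == 1L || i == s) d_max - 1L else d_max - 2L
    fr <- build_fringe(el, spine_ids[i], extras[i], maxc, nid,
                       exact_height2 = (i == 1L || i == s))
    nid <- fr$next_id
    fringe_children[i] <- fr$children
    if (!is.null(fr$vertices)) { verts[[length(verts) + 1L]] <- fr$vertices; edges[[length(edges) + 1L]] <- fr$edges }
  }
  spine_deg <- ifelse(seq_len(s) %in% c(1L, s), 1L, 2L) + fringe_children
  spine_labels <- vapply(seq_len(s), function(i) pick_label(el, spine_deg[i]), character(1))
  verts[[length(verts) + 1L]] <- tibble::tibble(id = spine_ids, label = spine_labels)
  for (i in seq_len(s - 1L)) edges[[length(edges) + 1L]] <- tibble::tibble(u = spine_ids[i], v = spine_ids[i + 1L], m = 1L)
  g <- chem_graph(dplyr::bind_rows(verts), dplyr::bind_rows(edges))
  upgrade_multiplicities(g, el, gamma, p_multi)
}

#' @noRd
build_y_tree <- function(el, gamma, n, dia, arms, d_max, p_multi) {
  c1 <- arms[1]; c2 <- arms[2]; c3 <- arms[3]
  j_central <- (c1 - c2) <= 1L
  # bh = 2 requires a fringe-free, non-central junction; bh = 1 otherwise.
  # Either outcome is in the generator's class; the junction fringe is only
  # allowed when d_max = 4 (degree 3 + fringe children).
  spine_n <- 1L + c1 + c2 + c3
  cap_end <- 2L * d_max - 1L
  cap_int <- if (d_max >= 3) (d_max - 2L) + min(d_max - 1L, (d_max - 2L) * (d_max - 1L)) else 0L
  cap_j <- if (d_max >= 4) 1L + min(2L, d_max - 1L) else 0L
  arm_ids <- list()
  nid <- 1L
  jid <- as.character(nid); nid <- nid + 1L
  for (k in 1:3) {
    ids <- as.character(seq.int(nid, nid + arms[k] - 1L)); nid <- nid + arms[k]
    arm_ids[[k]] <- ids  # ids[1] adjacent to J ... ids[c_k] = tip (leaf 2-branch)
  }
  slots_lo <- c(0L, unlist(lapply(1:3, function(k) c(rep(0L, arms[k] - 1L), 2L))))
  slots_hi <- c(cap_j, unlist(lapply(1:3, function(k) c(rep(cap_int, arms[k] - 1L), cap_end))))
  extras <- allocate_extras(n - spine_n, n_slots = spine_n, lo = slots_lo, hi = slots_hi)
  all_ids <- c(jid, unlist(arm_ids))
  verts <- list(); edges <- list()
  vid0 <- nid
  fringe_children <- integer(spine_n)
  is_tip <- c(FALSE, unlist(lapply(1:3, function(k) c(rep(FALSE, arms[k] - 1L), TRUE))))
  for (i in seq_along(all_ids)) {
    maxc <- if (i == 1L) max(d_max - 3L, 0L) else if (is_tip[i]) d_max - 1L else d_max - 2L
    fr <- build_fringe(el, all_ids[i], extras[i], maxc, vid0, exact_height2 = is_tip[i])
    vid0 <- fr$next_id
    fringe_children[i] <- fr$children
    if (!is.null(fr$vertices)) { verts[[length(verts) + 1L]] <- fr$vertices; edges[[length(edges) + 1L]] <- fr$edges }
  }
  spine_deg <- integer(spine_n)
  spine_deg[1] <- 3L + fringe_children[1]
  pos <- 2L
  for (k in 1:3) {
    for (q in seq_len(arms[k])) {
      spine_deg[pos] <- (if (q == arms[k]) 1L else 2L) + fringe_children[pos]
      pos <- pos + 1L
    }
  }
  labels <- vapply(seq_len(spine_n), function(i) pick_label(el, spine_deg[i]), character(1))
  verts[[length(verts) + 1L]] <- tibble::tibble(id = all_ids, label = labels)
  for (k in 1:3) {
    ids <- arm_ids[[k]]
    edges[[length(edges) + 1L]] <- tibble::tibble(u = jid, v = ids[1], m = 1L)
    if (arms[k] > 1) {
      for (q in seq_len(arms[k] - 1L)) {
        edges[[length(edges) + 1L]] <- tibble::tibble(u = ids[q], v = ids[q + 1L], m = 1L)
      }
    }
  }
  g <- chem_graph(dplyr::bind_rows(verts), dplyr::bind_rows(edges))
  upgrade_multiplicities(g, el, gamma, p_multi)
}

#' Randomly raise some bond multiplicities where valence headroom allows
#' @noRd
upgrade_multiplicities <- function(g, el, gamma, p_multi) {
  if (p_multi <= 0 || nrow(g$edges) == 0) return(g)
  lab <- stats::setNames(g$vertices$label, g$vertices$id)
  gk <- gamma_key(gamma$a, gamma$b, gamma$m)
  for (i in sample(seq_len(nrow(g$edges)))) {
    if (stats::runif(1) > p_multi) next
    bs <- beta_sums(g)
    u <- g$edges$u[i]; v <- g$edges$v[i]
    head_u <- val_of(el, lab[[u]]) - bs[[u]]
    head_v <- val_of(el, lab[[v]]) - bs[[v]]
    up <- min(head_u, head_v, 3L - g$edges$m[i])
    if (up <= 0) next
    add <- sample(seq_len(up), 1)
    cfg <- normalize_adjacency(el, lab[[u]], lab[[v]], g$edges$m[i] + add)
    if (gamma_key(cfg$a, cfg$b, cfg$m) %in% gk) g$edges$m[i] <- g$edges$m[i] + add
  }
  g
}

#' Random valence-valid chemical tree (no class targeting)
#'
#' Sequential attachment: useful for property tests that need arbitrary
#' valid graphs rather than members of the bounded branch-height class.
#'
#' @param n vertex count.
#' @param elements an [element_table()].
#' @param gamma a `gamma_set` or `NULL` for all configurations.
#' @param d_max maximum degree.
#' @param seed integer seed.
#' @param p_multi chance of upgrading an edge multiplicity.
#' @return a [chem_graph()].
#' @export
random_chem_tree <- function(n, elements = default_elements(), gamma = NULL,
                             d_max = 4L, seed = 1L, p_multi = 0.15) {
  if (is.null(gamma)) gamma <- all_adjacency_configs(elements)
  with_local_seed(seed, {
    ids <- as.character(seq_len(n))
    deg <- integer(n)
    verts <- tibble::tibble(id = ids, label = NA_character_)
    edges <- list()
    parent <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (i > 1) {
        cand <- which(deg[seq_len(i - 1L)] < d_max)
        p <- if (length(cand) == 1) cand else sample(cand, 1)
        parent[i] <- p
        deg[p] <- deg[p] + 1L
        deg[i] <- 1L
        edges[[length(edges) + 1L]] <- tibble::tibble(u = ids[p], v = ids[i], m = 1L)
      }
    }
    for (i in seq_len(n)) {
      kids <- sum(parent == i, na.rm = TRUE)
      need <- kids + as.integer(!is.na(parent[i]))
      verts$label[i] <- pick_label(elements, max(need, 1L))
    }
    g <- chem_graph(verts, if (length(edges)) dplyr::bind_rows(edges) else NULL)
    upgrade_multiplicities(g, elements, gamma, p_multi)
  })
}

#' Synthetic property value
#'
#' `w . f(G) + Gaussian(0, sigma)`: the linear-in-descriptors synthetic
#' property used in place of measured activities. Deterministic per seed.
#'
#' @param graph a [chem_graph()].
#' @param coefficients numeric vector of length `spec$K`.
#' @param sigma noise standard deviation.
#' @param seed integer seed.
#' @param spec a [descriptor_spec()].
#' @return numeric scalar.
#' @export
synthetic_property <- function(graph, coefficients, sigma, seed, spec) {
  stopifnot(length(coefficients) == spec$K)
  x <- as.numeric(feature_vector(graph, spec))
  base <- sum(coefficients * x)
  if (sigma == 0) return(base)
  base + with_local_seed(seed, stats::rnorm(1, 0, sigma))
}

#' Synthetic training set
#'
#' Draws `n_samples` class graphs and synthetic property values; the tabular
#' form consumed by the training stage.
#'
#' @param n_samples number of graphs.
#' @param config a [generator_config()].
#' @param spec a [descriptor_spec()].
#' @param coefficients property coefficient vector (length K).
#' @param sigma noise sd.
#' @param seed integer seed.
#' @return list with `graphs` (list) and `data` (tibble: id, descriptors, value).
#' @export
synthetic_dataset <- function(n_samples, config, spec, coefficients, sigma = 0, seed = 1L) {
  graphs <- lapply(seq_len(n_samples), function(i) random_graph(config, seed = seed + i))
  tab <- feature_table(graphs, spec)
  vals <- vapply(seq_len(n_samples), function(i) {
    synthetic_property(graphs[[i]], coefficients, sigma, seed = seed * 100003L %% 2147480000L + i, spec)
  }, numeric(1))
  tab$value <- vals
  list(graphs = graphs, data = tab)
}

# ---------------------------------------------------------------------------
# Exhaustive isomorph-free oracle

#' Exhaustive chemical acyclic graphs up to isomorphism
#'
#' Generates every chemical acyclic graph with `n` vertices over the given
#' alphabet and adjacency-configuration set, one representative per
#' isomorphism class: canonical rooted generation at the (unique) centroid
#' plus a bicentroid pass for even `n`. Desk-scale ground truth for the
#' feasibility and enumeration contracts; refuses `n > 11`.
#'
#' @param n vertex count (<= 11).
#' @param elements an [element_table()].
#' @param gamma a `gamma_set` or `NULL` for all configurations.
#' @return list of [chem_graph()]s.
#' @export
exhaustive_graphs <- function(n, elements = default_elements(), gamma = NULL) {
  if (n > 11) stop("exhaustive generation is desk-scale only (n <= 11); ",
                   "use random_graph() for larger sizes")
  if (is.null(gamma)) gamma <- all_adjacency_configs(elements)
  if (n == 1) {
    return(lapply(elements$label, function(a)
      chem_graph(tibble::tibble(id = "1", label = a))))
  }
  rooted <- rooted_trees_by_size(n, elements, gamma)
  out <- list()
  half <- floor((n - 1) / 2)
  for (tr in rooted[[n]]) {
    sizes <- vapply(tr$children, function(ch) ch$tree$size, integer(1))
    if (all(sizes <= half)) out[[length(out) + 1L]] <- rooted_to_graph(tr)
  }
  if (n %% 2 == 0) {
    hn <- n %/% 2
    halves <- rooted[[hn]]
    gk <- gamma_key(gamma$a, gamma$b, gamma$m)
    for (i in seq_along(halves)) {
      for (j in i:length(halves)) {
        t1 <- halves[[i]]; t2 <- halves[[j]]
        cfg <- normalize_adjacency(elements, t1$label, t2$label, 1L)
        for (m in 1:3) {
          if (t1$used + m > val_of(elements, t1$label)) next
          if (t2$used + m > val_of(elements, t2$label)) next
          if (!(gamma_key(cfg$a, cfg$b, m) %in% gk)) next
          out[[length(out) + 1L]] <- bicentroid_to_graph(t1, t2, m)
        }
      }
    }
  }
  out
}

#' All canonical rooted chemical trees of sizes 1..n
#' @noRd
rooted_trees_by_size <- function(n, elements, gamma) {
  gk <- gamma_key(gamma$a, gamma$b, gamma$m)
  store <- vector("list", n)
  store[[1]] <- lapply(elements$label, function(a)
    list(label = a, used = 0L, size = 1L, code = paste0("(", a, ")"), children = list()))
  if (n == 1) return(store)
  for (sz in 2:n) {
    acc <- list()
    for (a in elements$label) {
      va <- val_of(elements, a)
      # child options: (m, subtree) with Gamma-valid edge and child residual valence
      opts <- list()
      for (s in 1:(sz - 1)) {
        for (tr in store[[s]]) {
          for (m in 1:3) {
            if (tr$used + m > val_of(elements, tr$label)) next
            cfg <- normalize_adjacency(elements, a, tr$label, m)
            if (!(gamma_key(cfg$a, cfg$b, cfg$m) %in% gk)) next
            opts[[length(opts) + 1L]] <- list(m = m, tree = tr, size = s,
                                              ccode = paste0(m, tr$code))
          }
        }
      }
      if (!length(opts)) next
      ord <- order(vapply(opts, function(o) o$ccode, character(1)), decreasing = TRUE)
      opts <- opts[ord]
      # choose a non-increasing (by ccode) sequence of options totalling sz - 1
      build <- function(first_idx, remaining, mult_left, chosen) {
        if (remaining == 0) {
          acc[[length(acc) + 1L]] <<- list(
            label = a,
            used = sum(vapply(chosen, function(o) o$m, integer(1))),
            size = sz,
            code = paste0("(", a,
                          paste(vapply(chosen, function(o) o$ccode, character(1)), collapse = ""),
                          ")"),
            children = chosen)
          return(invisible())
        }
        if (first_idx > length(opts)) return(invisible())
        for (k in first_idx:length(opts)) {
          o <- opts[[k]]
          if (o$size > remaining) next
          if (o$m > mult_left) next
          build(k, remaining - o$size, mult_left - o$m, c(chosen, list(o)))
        }
      }
      build(1L, sz - 1L, va, list())
    }
    store[[sz]] <- acc
  }
  store
}

#' @noRd
rooted_to_graph <- function(tr) {
  verts <- list(); edges <- list()
  nid <- 0L
  emit <- function(node) {
    nid <<- nid + 1L
    my <- as.character(nid)
    verts[[length(verts) + 1L]] <<- tibble::tibble(id = my, label = node$label)
    for (ch in node$children) {
      cid <- emit(ch$tree)
      edges[[length(edges) + 1L]] <<- tibble::tibble(u = my, v = cid, m = as.integer(ch$m))
    }
    my
  }
  emit(tr)
  chem_graph(dplyr::bind_rows(verts),
             if (length(edges)) dplyr::bind_rows(edges) else NULL)
}

#' @noRd
bicentroid_to_graph <- function(t1, t2, m) {
  g1 <- rooted_to_graph(t1)
  n1 <- nrow(g1$vertices)
  g2 <- rooted_to_graph(t2)
  g2$vertices$id <- as.character(as.integer(g2$vertices$id) + n1)
  if (nrow(g2$edges)) {
    g2$edges$u <- as.character(as.integer(g2$edges$u) + n1)
    g2$edges$v <- as.character(as.integer(g2$edges$v) + n1)
  }
  chem_graph(
    dplyr::bind_rows(g1$vertices, g2$vertices),
    dplyr::bind_rows(g1$edges, g2$edges,
                     tibble::tibble(u = "1", v = as.character(n1 + 1L), m = as.integer(m)))
  )
}
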