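# Stage-5 dynamic program

test_that("the fringe-tree pool matches a brute-force rooted enumeration for C alone", {
  # all valence-valid C rooted trees of height <= 2 under the size rule, with
  # single bonds, at most n = 8 vertices, one unit of root valence reserved
  x_dummy <- stats::setNames(numeric(spec_cno$K), spec_cno$names)
  x_dummy["n"] <- 8
  for (nm in grep("^(ce|ac|dg|bc)_", spec_cno$names, value = TRUE)) x_dummy[nm] <- 8
  x_dummy[grep("^ce_(N|O)_", names(x_dummy))] <- 0      # prune non-carbon
  x_dummy[grepl("^ac_.*[NO]", names(x_dummy))] <- 0
  pool <- generate_fringe_set(spec_cno, x_dummy)
  trees_total <- sum(vapply(pool, function(e) e$count, integer(1)))
  # brute force: root degree c in 0..3, grandchildren per child g_i <= 3,
  # multiplicities in {1,2,3} pruned by valence 4 and sum(g) <= c + 1,
  # counted up to sibling reordering
  brute <- 0L
  for (cdeg in 0:3) {
    if (cdeg == 0L) { brute <- brute + 1L; next }
    # child shapes: (m, g, (m2 multiset)) canonicalised
    shapes <- list()
    for (m in 1:3) {
      for (g in 0:3) {
        if (m + g > 4) next  # child valence: m + sum m2 (>= g) <= 4
        m2sets <- if (g == 0) list(integer(0)) else {
          grid <- expand.grid(rep(list(1:3), g))
          sets <- unique(lapply(seq_len(nrow(grid)), function(r) sort(as.integer(grid[r, ]))))
          Filter(function(s) m + sum(s) <= 4, sets)
        }
        for (s in m2sets) shapes[[length(shapes) + 1L]] <- list(m = m, s = s)
      }
    }
    codes <- vapply(shapes, function(sh) paste(sh$m, paste(sh$s, collapse = "."), sep = "|"), character(1))
    # multisets of cdeg shapes with total root multiplicity <= 3 (one reserved)
    # and total grandchildren <= cdeg + 1
    idx <- seq_along(shapes)
    count_multisets <- function(first, left_m, left_g, depth) {
      if (depth == 0L) return(1L)
      tot <- 0L
      for (k in first:length(idx)) {
        sh <- shapes[[k]]
        if (sh$m > left_m) next
        if (length(sh$s) > left_g) next
        tot <- tot + count_multisets(k, left_m - sh$m, left_g - length(sh$s), depth - 1L)
      }
      tot
    }
    brute <- brute + count_multisets(1L, 3L, cdeg + 1L, cdeg)
  }
  expect_identical(trees_total, brute)
})

test_that("domination pruning removes trees containing absent elements", {
  g <- random_graph(generator_config(elements_cno, gamma_cno, n = 11L, d_max = 3L),
                    seed = 4)
  x_star <- unclass(feature_vector(g, spec_cno))
  pool <- generate_fringe_set(spec_cno, x_star)
  absent <- elements_cno$label[vapply(elements_cno$label, function(a) {
    x_star[[paste0("ce_", a, "_in")]] + x_star[[paste0("ce_", a, "_ex")]] == 0
  }, logical(1))]
  for (a in absent) {
    expect_false(any(vapply(pool, function(e) {
      any(grepl(a, vapply(e$trees, function(t) t$root, character(1)))) ||
        e$vec[[paste0("ce_", a, "_ex")]] > 0
    }, logical(1))))
  }
  # multiplicities never exceed the tree count
  expect_true(all(vapply(pool, function(e) e$count >= 1, logical(1))))
})

test_that("the smallest joins behave per the descriptor domain", {
  x_dummy <- stats::setNames(rep(99, spec_cno$K), spec_cno$names)
  pool <- generate_fringe_set(spec_cno, x_dummy)
  singleC <- Filter(function(e) e$root_label == "C" && e$fdeg == 0L, pool)[[1]]
  xc <- stats::setNames(rep(99L, length(frequency_names(spec_cno))), frequency_names(spec_cno))
  # two bare vertices joined: the (1,1,m) bond-configuration lies outside the
  # descriptor domain (targets have n >= 3), so the join is rejected
  expect_null(combine(chain_start(singleC), chain_start(singleC), 1L, spec_cno, xc))
  # three-vertex path: counts come out exactly
  mid <- chain_extend(chain_start(singleC), singleC, 1L, spec_cno, xc)
  vec <- combine(mid, chain_start(singleC), 1L, spec_cno, xc)
  expect_identical(vec[["ce_C_in"]], 3L)
  expect_identical(vec[["ac_C-C-1_in"]], 2L)
  expect_identical(vec[["dg_1_in"]], 2L)
  expect_identical(vec[["dg_2_in"]], 1L)
  expect_identical(vec[["bc_1-2-1_in"]], 2L)
})

test_that("chain growth is order independent on a three-vertex path", {
  x_dummy <- stats::setNames(rep(99, spec_cno$K), spec_cno$names)
  pool <- generate_fringe_set(spec_cno, x_dummy)
  singleC <- Filter(function(e) e$root_label == "C" && e$fdeg == 0L, pool)[[1]]
  singleO <- Filter(function(e) e$root_label == "O" && e$fdeg == 0L, pool)[[1]]
  xc <- stats::setNames(rep(99L, length(frequency_names(spec_cno))), frequency_names(spec_cno))
  # path C - O - C built as (C+O) + C and as (C) + (O+C)
  a <- chain_extend(chain_start(singleC), singleO, 1L, spec_cno, xc)
  v1 <- combine(a, chain_start(singleC), 1L, spec_cno, xc)
  b <- chain_extend(chain_start(singleC), singleO, 1L, spec_cno, xc)
  v2 <- combine(chain_start(singleC), b, 1L, spec_cno, xc)
  expect_identical(v1, v2)
})

test_that("joins that exceed the residual valence at a root are rejected", {
  x_dummy <- stats::setNames(rep(99, spec_cno$K), spec_cno$names)
  pool <- generate_fringe_set(spec_cno, x_dummy)
  singleO <- Filter(function(e) e$root_label == "O" && e$fdeg == 0L, pool)[[1]]
  xc <- stats::setNames(rep(99L, length(frequency_names(spec_cno))), frequency_names(spec_cno))
  expect_null(combine(chain_start(singleO), chain_start(singleO), 3L, spec_cno, xc))
})

test_that("enumeration equals the exhaustive oracle on n = 7 graphs over C,O", {
  cs <- co7_census()
  fvs <- cs$fvs; keys <- cs$keys; cfs <- cs$cfs
  set.seed(4242)
  test_idx <- sample(which(!duplicated(keys)), 40)
  for (i in test_idx) {
    res <- enumerate_graphs(fvs[[i]], spec_co, cap = 100L)
    expect_identical(res$status, "completed")
    oracle_cf <- sort(cfs[keys == keys[i]])
    enum_cf <- sort(vapply(res$graphs, canonical_form, character(1)))
    expect_identical(enum_cf, oracle_cf)
    expect_lte(res$lower_bound, length(oracle_cf))
    expect_gte(res$lower_bound, length(res$graphs))
    expect_gte(res$feasible_pairs, 1L)
    for (gg in res$graphs) {
      expect_equal(unclass(feature_vector(gg, spec_co)), fvs[[i]], tolerance = 1e-9)
    }
    expect_false(any(duplicated(enum_cf)))
  }
})

test_that("a bl = 3 target reproduces the oracle as well", {
  g <- random_graph(generator_config(elements_co, gamma_co, n = 11L, d_max = 3L,
                                     bl = 3L, p_multi = 0),
                    seed = 31)
  x_star <- unclass(feature_vector(g, spec_co))
  res <- enumerate_graphs(x_star, spec_co, cap = 100L)
  expect_gte(length(res$graphs), 1L)
  expect_true(canonical_form(g) %in% vapply(res$graphs, canonical_form, character(1)))
  for (gg in res$graphs) {
    expect_equal(unclass(feature_vector(gg, spec_co)), x_star, tolerance = 1e-9)
  }
})

test_that("an internally inconsistent x* yields an empty result with a diagnostic", {
  g <- random_graph(generator_config(elements_cno, gamma_cno, n = 11L, d_max = 3L),
                    seed = 9)
  x_star <- unclass(feature_vector(g, spec_cno))
  x_bad <- x_star
  x_bad[["n_H"]] <- x_bad[["n_H"]] + 2
  res <- enumerate_graphs(x_bad, spec_cno, cap = 10L)
  expect_identical(res$status, "inconsistent")
  expect_identical(res$feasible_pairs, 0L)
  expect_match(res$diagnostic, "n_H")
})

test_that("the cap limits reconstruction but not the counts", {
  g <- random_graph(generator_config(elements_cno, gamma_cno, n = 12L, d_max = 3L, bl = 2L),
                    seed = 17)
  x_star <- unclass(feature_vector(g, spec_cno))
  full <- enumerate_graphs(x_star, spec_cno, cap = 100L)
  one <- enumerate_graphs(x_star, spec_cno, cap = 1L)
  expect_identical(length(one$graphs), 1L)
  expect_identical(one$feasible_pairs, full$feasible_pairs)
  expect_equal(unclass(feature_vector(one$graphs[[1]], spec_cno)), x_star, tolerance = 1e-9)
})
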