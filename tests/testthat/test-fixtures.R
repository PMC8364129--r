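test_that("class generator output validates and hits the requested class exactly", {
  for (seed in 1:30) {
    cfg <- generator_config(elements_cno, gamma_cno,
                            n = c(10L, 16L), d_max = if (seed %% 2) 3L else 4L)
    g <- random_graph(cfg, seed = seed)
    expect_true(validate_chemical_graph(g, elements_cno, gamma_cno)$ok)
    dec <- decompose(root_at_center(g), 2L)
    expect_true(dec$bl %in% c(2L, 3L))
    expect_true(all(vapply(dec$fringe_trees, fringe_size_ok, logical(1))))
    expect_lte(max(tree_metrics(g)$degree), cfg$d_max)
  }
})

test_that("the generator is deterministic per seed and honours exact requests", {
  cfg <- generator_config(elements_cno, gamma_cno, n = 13L, d_max = 3L, bl = 2L,
                          dia = c(8L, 8L))
  g1 <- random_graph(cfg, seed = 5)
  g2 <- random_graph(cfg, seed = 5)
  expect_identical(canonical_form(g1), canonical_form(g2))
  expect_identical(nrow(g1$vertices), 13L)
  expect_identical(tree_metrics(g1)$diameter, 8L)
  expect_identical(decompose(root_at_center(g1), 2L)$bl, 2L)
})

test_that("unsatisfiable generator requests fail loudly with the conflict named", {
  cfg <- generator_config(elements_cno, gamma_cno, n = 8L, d_max = 3L, bl = 3L)
  expect_error(random_graph(cfg, seed = 1), "unsatisfiable")
  cfg2 <- generator_config(elements_cno, gamma_cno, n = 30L, d_max = 3L, bl = 2L,
                           dia = c(6L, 6L))
  expect_error(random_graph(cfg2, seed = 1), "unsatisfiable")
})

test_that("exhaustive generation matches an independent Pruefer-based count", {
  # single-bond carbon trees: isomorphism classes under the valence-4 cap
  for (n in 4:7) {
    mine <- exhaustive_graphs(n, elements_c, gamma_c1)
    indep <- pruefer_trees(n, d_max = 4L)
    expect_identical(length(mine), length(indep))
    expect_setequal(vapply(mine, canonical_form, character(1)),
                    vapply(indep, canonical_form, character(1)))
  }
  # n = 4 single-bond carbon: exactly the path and the star
  g4 <- exhaustive_graphs(4, elements_c, gamma_c1)
  expect_identical(length(g4), 2L)
})

test_that("exhaustive output is valid, isomorph-free, and refuses large n", {
  gs <- exhaustive_graphs(6, elements_co, gamma_co)
  cf <- vapply(gs, canonical_form, character(1))
  expect_false(any(duplicated(cf)))
  for (g in gs) expect_true(validate_chemical_graph(g, elements_co, gamma_co)$ok)
  expect_identical(length(exhaustive_graphs(1, elements_c, gamma_c1)), 1L)
  expect_error(exhaustive_graphs(12, elements_c, gamma_c1), "desk-scale")
})

test_that("synthetic properties are linear in descriptors with seeded noise", {
  g <- random_chem_tree(9, elements_cno, gamma_cno, seed = 2)
  w <- numeric(spec_cno$K)
  w[match("n", spec_cno$names)] <- 1
  expect_identical(synthetic_property(g, w, sigma = 0, seed = 1, spec = spec_cno), 9)
  w2 <- runif(spec_cno$K)
  expect_equal(synthetic_property(g, w2, sigma = 0, seed = 1, spec = spec_cno),
               sum(w2 * as.numeric(feature_vector(g, spec_cno))))
  a <- synthetic_property(g, w, sigma = 1, seed = 7, spec = spec_cno)
  b <- synthetic_property(g, w, sigma = 1, seed = 7, spec = spec_cno)
  expect_identical(a, b)
  expect_false(a == 9)
})
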