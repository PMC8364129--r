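test_that("element tables order labels by mass and validate fields", {
  el <- element_table(c("O", "C", "N"), c(2, 4, 3), c(16.00, 12.01, 14.01))
  expect_identical(el$label, c("C", "N", "O"))
  expect_identical(el$mass_star, c(120L, 140L, 160L))
  expect_error(element_table(c("C", "C"), c(4, 4), c(12, 13)), "duplicate")
  expect_error(element_table("X", 5, 10), "valences")
  expect_error(element_table("H", 1, 1.008), "hydrogen")
})

test_that("adjacency configurations normalise into the mass order and split classes", {
  g <- adjacency_configs(elements_cno, c("O", "C", "C"), c("C", "C", "N"), c(1, 2, 1))
  expect_identical(g$a, c("C", "C", "C"))
  expect_identical(g$b, c("C", "N", "O"))
  expect_identical(g$class, c("eq", "lt", "lt"))
  # reversal of (a,b,m) lands on the same normalised tuple
  n1 <- normalize_adjacency(elements_cno, "O", "C", 2)
  n2 <- normalize_adjacency(elements_cno, "C", "O", 2)
  expect_identical(n1, n2)
})

test_that("bond-configuration domain has 16 members after dropping (1,1,m)", {
  bc <- bond_config_domain()
  expect_identical(nrow(bc), 16L)
  expect_true(all(bc$d1 <= bc$d2))
  expect_true(all(pmax(bc$d1, bc$d2) + bc$m <= 5))
  expect_false(any(bc$d1 == 1 & bc$d2 == 1))
  expect_identical(nrow(bond_config_domain(drop_trivial = FALSE)), 19L)
})

test_that("validation accepts valid graphs and reports each violated rule", {
  g <- chem_graph(data.frame(id = "1", label = "C"))
  expect_true(validate_chemical_graph(g, elements_cno)$ok)

  # O with a triple bond: beta(O) = 3 > val(O) = 2
  g2 <- chem_graph(data.frame(id = c("1", "2"), label = c("O", "C")),
                   data.frame(u = "1", v = "2", m = 3))
  v2 <- validate_chemical_graph(g2, elements_cno)
  expect_false(v2$ok)
  expect_true("valence" %in% v2$violations$rule)

  # deleting an edge from a valid random tree breaks connectivity
  g3 <- random_chem_tree(9, elements_cno, gamma_cno, seed = 4)
  g3$edges <- g3$edges[-1, ]
  v3 <- validate_chemical_graph(g3, elements_cno)
  expect_false(v3$ok)
  expect_true("connectivity" %in% v3$violations$rule)

  expect_error(validate_chemical_graph(
    chem_graph(data.frame(id = "1", label = "Zz")), elements_cno), "unknown element")
})

test_that("tree metrics, diameter and degrees match a BFS oracle", {
  expect_identical(tree_metrics(path_graph(4))$diameter, 3L)
  expect_identical(tree_metrics(star_graph(3))$diameter, 2L)
  for (seed in 1:25) {
    g <- random_chem_tree(sample(2:14, 1), elements_cno, gamma_cno, seed = seed)
    m <- tree_metrics(g)
    dia_oracle <- max(vapply(g$vertices$id, function(s) max(oracle_bfs(g, s)), integer(1)))
    expect_identical(m$diameter, as.integer(dia_oracle))
    expect_identical(sum(m$degree), 2L * nrow(g$edges))
  }
})

test_that("the center is the eccentricity argmin and has the right size by parity", {
  expect_identical(find_center(path_graph(5)), "3")
  expect_identical(find_center(path_graph(6)), sort(c("3", "4")))
  for (seed in 1:25) {
    g <- random_chem_tree(sample(3:14, 1), elements_cno, gamma_cno, seed = seed + 100)
    ecc <- vapply(g$vertices$id, function(s) max(oracle_bfs(g, s)), integer(1))
    expect_setequal(find_center(g), g$vertices$id[ecc == min(ecc)])
    dia <- tree_metrics(g)$diameter
    expect_identical(length(find_center(g)), if (dia %% 2 == 0) 1L else 2L)
  }
})

test_that("edge configurations normalise and are invariant under vertex relabelling", {
  g <- chem_graph(data.frame(id = c("1", "2"), label = c("O", "C")),
                  data.frame(u = "1", v = "2", m = 2))
  cfg <- edge_configs(g, elements_cno)
  expect_identical(cfg$a, "C"); expect_identical(cfg$b, "O"); expect_identical(cfg$m, 2L)
  expect_identical(cfg$d1, 1L); expect_identical(cfg$d2, 1L)

  for (seed in 1:10) {
    g <- random_chem_tree(10, elements_cno, gamma_cno, seed = seed + 300)
    cfg1 <- edge_configs(g, elements_cno)
    perm <- sample(g$vertices$id)
    map <- stats::setNames(perm, g$vertices$id)
    g2 <- chem_graph(
      data.frame(id = map[g$vertices$id], label = g$vertices$label),
      data.frame(u = map[g$edges$u], v = map[g$edges$v], m = g$edges$m))
    cfg2 <- edge_configs(g2, elements_cno)
    k1 <- sort(paste(cfg1$a, cfg1$b, cfg1$m, cfg1$d1, cfg1$d2))
    k2 <- sort(paste(cfg2$a, cfg2$b, cfg2$m, cfg2$d1, cfg2$d2))
    expect_identical(k1, k2)
    expect_true(all(pmax(cfg1$d1, cfg1$d2) + cfg1$m <= 5))
  }
})

test_that("beta sums obey the handshake identity on valid graphs", {
  for (seed in 1:10) {
    g <- random_chem_tree(sample(2:12, 1), elements_cno, gamma_cno, seed = seed + 40)
    expect_identical(sum(beta_sums(g)), 2L * sum(g$edges$m))
  }
})

test_that("JSON round trip preserves the graph", {
  g <- random_chem_tree(11, elements_cno, gamma_cno, seed = 77)
  f <- tempfile(fileext = ".json")
  write_graph_json(g, f)
  g2 <- read_graph_json(f)
  expect_identical(canonical_form(g), canonical_form(g2))
})

test_that("canonical form separates non-isomorphic and merges relabelled trees", {
  g <- random_chem_tree(9, elements_cno, gamma_cno, seed = 8)
  perm <- rev(g$vertices$id)
  map <- stats::setNames(perm, g$vertices$id)
  g2 <- chem_graph(data.frame(id = map[g$vertices$id], label = g$vertices$label),
                   data.frame(u = map[g$edges$u], v = map[g$edges$v], m = g$edges$m))
  expect_identical(canonical_form(g), canonical_form(g2))
  expect_false(canonical_form(path_graph(4)) == canonical_form(star_graph(3)))
})
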