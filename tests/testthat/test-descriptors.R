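test_that("the descriptor count is 2|Lambda| + 2|Gamma| + 50 and names are stable", {
  expect_identical(spec_cno$K, 2L * 3L + 2L * nrow(gamma_cno) + 50L)
  expect_identical(length(spec_cno$names), spec_cno$K)
  g <- random_chem_tree(8, elements_cno, gamma_cno, seed = 3)
  fv <- feature_vector(g, spec_cno)
  expect_identical(length(fv), spec_cno$K)
  expect_identical(names(fv), spec_cno$names)
})

test_that("a two-vertex graph has the forced descriptor values", {
  g <- chem_graph(data.frame(id = c("1", "2"), label = "C"),
                  data.frame(u = "1", v = "2", m = 1))
  fv <- feature_vector(g, spec_cno)
  expect_identical(fv[["n"]], 2)
  expect_identical(fv[["dia_bar"]], 0.5)
  expect_identical(fv[["bl"]], 0)
  # both vertices are 2-external (no 2-branch exists)
  expect_identical(fv[["dg_1_ex"]], 2)
  expect_identical(fv[["dg_1_in"]], 0)
  expect_identical(fv[["n_H"]], 6)  # 2 * 4 - 2 * 1
})

test_that("feature vectors satisfy the count identities on random graphs", {
  for (seed in 1:40) {
    g <- random_chem_tree(sample(2:16, 1), elements_cno, gamma_cno, seed = seed + 3000)
    fv <- feature_vector(g, spec_cno)
    n <- fv[["n"]]
    dg <- fv[grep("^dg_", names(fv))]
    ce <- fv[grep("^ce_", names(fv))]
    ac <- fv[grep("^ac_", names(fv))]
    expect_identical(sum(dg), n)
    expect_identical(sum(ce), n)
    expect_identical(sum(ac), n - 1)
    # bd_i^t is determined by the adjacency-configuration counts
    for (mm in 2:3) for (tt in c("in", "ex")) {
      sel <- grepl(paste0("-", mm, "_", tt, "$"), names(fv)) & startsWith(names(fv), "ac_")
      expect_identical(fv[[paste0("bd_", mm, "_", tt)]], sum(fv[sel]))
    }
    expect_equal(fv[["ms_bar"]],
                 sum(elements_cno$mass_star[match(g$vertices$label, elements_cno$label)]) / n)
  }
})

test_that("the two hydrogen-count expressions agree on every valid graph", {
  for (seed in 1:40) {
    g <- random_chem_tree(sample(1:16, 1), elements_cno, gamma_cno, seed = seed + 4000)
    fv <- feature_vector(g, spec_cno)
    # first printed form: sum val(a) ce_a - sum 2 m ac_gamma
    ce_term <- sum(vapply(elements_cno$label, function(a) {
      val_of(elements_cno, a) * (fv[[paste0("ce_", a, "_in")]] + fv[[paste0("ce_", a, "_ex")]])
    }, numeric(1)))
    ac_term <- sum(vapply(seq_len(nrow(gamma_cno)), function(i) {
      key <- paste0(gamma_cno$a[i], "-", gamma_cno$b[i], "-", gamma_cno$m[i])
      2 * gamma_cno$m[i] * (fv[[paste0("ac_", key, "_in")]] + fv[[paste0("ac_", key, "_ex")]])
    }, numeric(1)))
    form1 <- ce_term - ac_term
    # second printed form: via n - 1 and the multiple-bond counts
    bd_term <- sum(vapply(2:3, function(mm) {
      (mm - 1) * (fv[[paste0("bd_", mm, "_in")]] + fv[[paste0("bd_", mm, "_ex")]])
    }, numeric(1)))
    form2 <- ce_term - 2 * (fv[["n"]] - 1 + bd_term)
    expect_identical(form1, form2)
    expect_identical(fv[["n_H"]], form1)
    expect_identical(hydrogen_count(g, spec_cno), as.integer(form1))
  }
  expect_identical(hydrogen_count(chem_graph(data.frame(id = "1", label = "C")), spec_cno), 4L)
})

test_that("feature vectors are isomorphism invariant", {
  for (seed in 1:10) {
    g <- random_chem_tree(12, elements_cno, gamma_cno, seed = seed + 5000)
    perm <- sample(g$vertices$id)
    map <- stats::setNames(perm, g$vertices$id)
    g2 <- chem_graph(data.frame(id = map[g$vertices$id], label = g$vertices$label),
                     data.frame(u = map[g$edges$u], v = map[g$edges$v], m = g$edges$m))
    expect_equal(feature_vector(g, spec_cno), feature_vector(g2, spec_cno))
  }
})

test_that("graphs with configurations outside Gamma are rejected", {
  narrow <- adjacency_configs(elements_cno, "C", "C", 1L)
  nspec <- descriptor_spec(elements_cno, narrow, 2L)
  g <- chem_graph(data.frame(id = c("1", "2"), label = c("C", "O")),
                  data.frame(u = "1", v = "2", m = 1))
  expect_error(feature_vector(g, nspec), "invalid graph")
})

test_that("feature tables keep canonical column order and round-trip through CSV", {
  expect_identical(nrow(feature_table(list(), spec_cno)), 0L)
  gs <- lapply(1:4, function(s) random_chem_tree(9, elements_cno, gamma_cno, seed = s))
  tab <- feature_table(gs, spec_cno)
  expect_identical(names(tab), c("id", spec_cno$names))
  expect_equal(unname(unlist(tab[2, -1])), unname(as.numeric(feature_vector(gs[[2]], spec_cno))))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  tab2 <- tibble::as_tibble(utils::read.csv(f, check.names = FALSE, colClasses = c(id = "character")))
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("tidiers return well-formed tibbles", {
  g <- random_chem_tree(7, elements_cno, gamma_cno, seed = 11)
  td <- tidy(g)
  expect_identical(nrow(td), 7L)
  fv <- feature_vector(g, spec_cno)
  tf <- tidy(fv)
  expect_identical(nrow(tf), spec_cno$K)
})
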