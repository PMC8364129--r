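# the solver layer and the inverse MILP at desk scale

test_that("the solver layer distinguishes feasible, infeasible and objective sense", {
  m <- milp_new()
  x <- milp_var(m, "x", 0, 10, "I")
  y <- milp_var(m, "y", 0, 10, "C")
  milp_con(m, c(x, y), c(1, 1), lb = 3.5, ub = 3.5)
  res <- milp_solve(m, objective = c(x = -1))
  expect_identical(res$status, "feasible")
  expect_equal(unname(res$x["x"]), 3)
  m2 <- milp_new()
  a <- milp_var(m2, "a")
  milp_con(m2, a, 1, lb = 2)
  expect_identical(milp_solve(m2)$status, "infeasible")
})

round_trip_case <- function(seed, n, d_max) {
  cfg <- generator_config(elements_cno, gamma_cno, n = n, d_max = d_max)
  g <- random_graph(cfg, seed = seed)
  met <- tree_metrics(g)
  dec <- decompose(root_at_center(g), 2L)
  fv <- feature_vector(g, spec_cno)
  ts <- target_spec(elements_cno, gamma_cno, n_star = nrow(g$vertices),
                    d_max = if (max(met$degree) == 4L) 4L else 3L,
                    dia_star = met$diameter, k_star = 2L,
                    bh_star = dec$bh, bl_star = dec$bl)
  mod <- build_milp(predictors = list(), spec = ts, fix_x = unclass(fv))
  sol <- solve_inverse(mod, time_limit = 240)
  list(g = g, fv = fv, sol = sol)
}

test_that("fixing x to f(G) of an in-class graph yields a feasible model whose decode matches", {
  for (case in list(c(11, 9, 3), c(12, 10, 3), c(13, 12, 4), c(14, 11, 3))) {
    rt <- round_trip_case(case[1], as.integer(case[2]), as.integer(case[3]))
    expect_identical(rt$sol$status, "feasible")
    expect_equal(unclass(feature_vector(rt$sol$graph, spec_cno)), unclass(rt$fv),
                 tolerance = 1e-9)
  }
})

test_that("decoded graphs re-validate and satisfy every target-class feature", {
  rt <- round_trip_case(21, 12L, 3L)
  g2 <- rt$sol$graph
  expect_true(validate_chemical_graph(g2, elements_cno, gamma_cno)$ok)
  dec <- decompose(root_at_center(g2), 2L)
  expect_true(all(vapply(dec$fringe_trees, fringe_size_ok, logical(1))))
})

test_that("dia* >= n* is reported infeasible", {
  ts <- target_spec(elements_cno, gamma_cno, n_star = 8L, d_max = 3L,
                    dia_star = 8L, k_star = 2L, bh_star = 1L, bl_star = 2L)
  mod <- build_milp(predictors = list(), spec = ts)
  expect_identical(solve_inverse(mod, time_limit = 60)$status, "infeasible")
})

test_that("a class with bl* = 3 but too few vertices is infeasible, matching brute force", {
  # three leaf 2-branches need >= 10 vertices (junction + three arms of >= 3)
  ts <- target_spec(elements_cno, gamma_cno, n_star = 9L, d_max = 3L,
                    dia_star = 7L, k_star = 2L, bh_star = 1L, bl_star = 3L)
  mod <- build_milp(predictors = list(), spec = ts)
  expect_identical(solve_inverse(mod, time_limit = 120)$status, "infeasible")
  # brute force: bl_2 depends only on the underlying tree, and no 9-vertex
  # degree-<=3 tree has three leaf 2-branches
  bl_vals <- vapply(exhaustive_graphs(9, elements_c, gamma_c1), function(g) {
    if (max(tree_metrics(g)$degree) > 3L) return(0L)
    decompose(root_at_center(g), 2L)$bl
  }, integer(1))
  expect_false(any(bl_vals >= 3))
})

test_that("small-scale completeness: exhaustive in-class graphs embed feasibly", {
  incl <- co7_census()$incl
  pick <- incl[round(seq(1, length(incl), length.out = 4))]
  for (g in pick) {
    met <- tree_metrics(g)
    dec <- decompose(root_at_center(g), 2L)
    fv <- feature_vector(g, spec_co)
    ts <- target_spec(elements_co, gamma_co, n_star = 7L,
                      d_max = if (max(met$degree) == 4L) 4L else 3L,
                      dia_star = met$diameter, k_star = 2L,
                      bh_star = dec$bh, bl_star = dec$bl)
    mod <- build_milp(predictors = list(), spec = ts, fix_x = unclass(fv))
    sol <- solve_inverse(mod, time_limit = 180)
    expect_identical(sol$status, "feasible")
  }
})

test_that("model size grows affinely in n* for fixed class parameters", {
  sizes <- vapply(c(10L, 14L, 18L, 22L), function(n) {
    ts <- target_spec(elements_cno, gamma_cno, n_star = n, d_max = 3L,
                      dia_star = 8L, k_star = 2L, bh_star = 1L, bl_star = 2L)
    mod <- build_milp(predictors = list(), spec = ts)
    length(mod$milp$var_names)
  }, numeric(1))
  expect_identical(diff(diff(sizes)), c(0, 0))
})

test_that("predictor blocks are additive in variable count", {
  cfg <- generator_config(elements_cno, gamma_cno, n = c(8L, 12L), d_max = 3L)
  coef <- numeric(spec_cno$K); coef[match("n", spec_cno$names)] <- 1
  ds <- synthetic_dataset(25, cfg, spec_cno, coef, sigma = 0, seed = 60)
  pd <- property_dataset(ds$data, spec_cno)
  mod <- train(pd, hidden = 4L, seed = 1L, maxit = 60L)
  ad <- ad_bounds(pd)
  ts <- target_spec(elements_cno, gamma_cno, n_star = 10L, d_max = 3L,
                    dia_star = 7L, k_star = 2L, bh_star = 1L, bl_star = 2L)
  m0 <- build_milp(list(), ts, ad = ad)
  m1 <- build_milp(list(mod), ts, ad = ad, targets = data.frame(y_star = 10, eps = 0.02))
  m3 <- build_milp(list(mod, mod, mod), ts, ad = ad,
                   targets = data.frame(y_star = c(10, 10, 10), eps = 0.02))
  d1 <- length(m1$milp$var_names) - length(m0$milp$var_names)
  d3 <- length(m3$milp$var_names) - length(m0$milp$var_names)
  expect_identical(d3, 3L * d1)
})

test_that("the C1 block alone reproduces the forward pass on random box points", {
  cfg <- generator_config(elements_cno, gamma_cno, n = c(8L, 12L), d_max = 3L)
  coef <- numeric(spec_cno$K); coef[match(c("n", "n_H"), spec_cno$names)] <- c(1, 0.3)
  ds <- synthetic_dataset(25, cfg, spec_cno, coef, sigma = 0, seed = 91)
  pd <- property_dataset(ds$data, spec_cno)
  mod <- train(pd, hidden = 6L, seed = 5L, maxit = 150L)
  ad <- ad_bounds(pd)
  lo <- ifelse(ad$rule == "divide_by_n", ad$lo * 10, ad$lo)
  hi <- ifelse(ad$rule == "divide_by_n", ad$hi * 10, ad$hi)
  set.seed(11)
  for (rep in 1:10) {
    x <- lo + runif(length(lo)) * (hi - lo)
    names(x) <- ad$descriptor
    psi <- predict(mod, x[spec_cno$names])
    m <- milp_new()
    ctx <- new.env()
    ctx$dspec <- spec_cno
    ctx$xv <- new.env()
    for (nm in spec_cno$names) {
      ctx$xv[[nm]] <- milp_var(m, paste0("x[", nm, "]"), lb = x[[nm]], ub = x[[nm]], type = "C")
    }
    treeqsar:::add_c1(m, ctx, mod, y_star = psi, eps = 1e-4 / max(abs(psi), 1), pi = 1L)
    res <- milp_solve(m, time_limit = 30)
    expect_identical(res$status, "feasible")
    expect_equal(unname(res$x[["y[1]"]]), psi, tolerance = 1e-6)
  }
})

test_that("the encoded network reproduces the forward pass on AD-box points", {
  cfg <- generator_config(elements_cno, gamma_cno, n = c(8L, 12L), d_max = 3L)
  coef <- numeric(spec_cno$K)
  coef[match(c("n", "n_H"), spec_cno$names)] <- c(1, 0.3)
  ds <- synthetic_dataset(30, cfg, spec_cno, coef, sigma = 0, seed = 90)
  pd <- property_dataset(ds$data, spec_cno)
  mod <- train(pd, hidden = 6L, seed = 2L, maxit = 150L)
  ad <- ad_bounds(pd)
  # fix x to training points inside the AD and check the y variable agrees
  for (i in c(3, 11, 26)) {
    x <- stats::setNames(as.numeric(ds$data[i, spec_cno$names]), spec_cno$names)
    g <- ds$graphs[[i]]
    met <- tree_metrics(g)
    dec <- decompose(root_at_center(g), 2L)
    ts <- target_spec(elements_cno, gamma_cno, n_star = as.integer(x[["n"]]),
                      d_max = if (max(met$degree) == 4L) 4L else 3L,
                      dia_star = met$diameter,
                      k_star = 2L, bh_star = dec$bh, bl_star = dec$bl)
    psi <- predict(mod, x)
    im <- build_milp(list(mod), ts, ad = ad,
                     targets = data.frame(y_star = psi, eps = 1e-7),
                     fix_x = x)
    sol <- solve_inverse(im, time_limit = 180)
    expect_identical(sol$status, "feasible")
    expect_equal(unname(sol$y[[1]]), psi, tolerance = 1e-5)
  }
})
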