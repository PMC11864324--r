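fake_selection <- function(label = "growth:base+N", params = c(n1 = 12),
                           status = "selected", endpoint = "growth") {
  specs <- enumerate_models(endpoint)
  labels <- vapply(specs, `[[`, character(1), "label")
  spec <- specs[[match(label, labels)]]
  structure(list(species = "SP", division = "21", endpoint = endpoint,
                 status = status,
                 selected_fit = list(spec = spec, params = params),
                 candidate_set = list(), ns_correlation = 0.1),
            class = "forestcl_selection")
}

test_that("N shapes follow the peak-versus-range rule", {
  expect_equal(classify_n_shape(fake_selection("growth:base", c(a = 1)),
                                c(5, 25)), "flat")
  expect_equal(classify_n_shape(fake_selection(params = c(n1 = 30)),
                                c(5, 25)), "increase")
  expect_equal(classify_n_shape(fake_selection(params = c(n1 = 12)),
                                c(5, 25)), "unimodal_sigmoid")
  expect_equal(classify_n_shape(fake_selection(params = c(n1 = 3)),
                                c(5, 25)), "decrease")
  # boundary equality goes to the monotone class
  expect_equal(classify_n_shape(fake_selection(params = c(n1 = 25)),
                                c(5, 25)), "increase")
  expect_equal(classify_n_shape(fake_selection(params = c(n1 = 5)),
                                c(5, 25)), "decrease")
  excl <- fake_selection(status = "excluded_ns_collinearity")
  expect_equal(classify_n_shape(excl, c(5, 25)), "not_applicable")
  expect_error(classify_n_shape(fake_selection(), c(5, 5)), "degenerate")
})

test_that("S shapes follow the fitted S form", {
  expect_equal(classify_s_shape(fake_selection("growth:base+N", c(n1 = 1))),
               "flat")
  expect_equal(classify_s_shape(fake_selection("growth:base+Slognormal",
                                               c(s1 = 2))), "decrease")
  expect_equal(classify_s_shape(fake_selection("growth:base+N+Ssigmoid",
                                               c(s1 = 5))),
               "unimodal_sigmoid")
  expect_equal(classify_s_shape(fake_selection(status = "insufficient_data")),
               "not_applicable")
})

test_that("the vulnerability scale is a fixed total order", {
  f <- shape_factor(c("increase", "flat", "unimodal_sigmoid", "decrease",
                      "not_applicable"))
  expect_true(is.ordered(f))
  expect_equal(levels(f),
               c("increase", "flat", "unimodal_sigmoid", "decrease"))
  expect_true(f[1] < f[2] && f[2] < f[3] && f[3] < f[4])
  expect_true(is.na(f[5]))
  # serialization round-trips losslessly
  expect_identical(shape_factor(as.character(f[1:4])), f[1:4])
})

test_that("direct critical loads are the fitted location parameters", {
  cl <- critical_load_direct(c(n1 = 8.7, n2 = 1), "N")
  expect_equal(cl$value, 8.7)
  expect_equal(cl$basis, "n1")
  cl_s <- critical_load_direct(c(s1 = 4.2, s2 = 1), "S", s_form = "lognormal")
  expect_equal(cl_s$value, 4.2)
  cl_none <- critical_load_direct(c(a = 1), "N")
  expect_true(is.na(cl_none$value))
  expect_match(cl_none$status, "undefined")
})

test_that("sigmoid inversion matches its anchors and a bisection oracle", {
  # f = 0.5 with no plateau returns exactly the 50%-decline point s1
  expect_equal(critical_load_sigmoid(10, 1, 0, 0.5)$value, 10.0)
  # bisection oracle for sulfur_sigmoid(S) = 0.95
  target <- function(S) sulfur_sigmoid(S, 10, 2, 0) - 0.95
  lo <- 1e-9; hi <- 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (target(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(critical_load_sigmoid(10, 2, 0, 0.05)$value, (lo + hi) / 2,
               tolerance = 1e-9)
  expect_equal(critical_load_sigmoid(10, 2, 0, 0.05)$value, 2.2941573,
               tolerance = 1e-6)
  # a plateau above 1 - f makes the CL undefined, not clipped
  und <- critical_load_sigmoid(10, 2, 0.2, 0.9)
  expect_true(is.na(und$value))
  expect_match(und$status, "plateau")
})

test_that("sigmoid CL round-trips through the sulfur term", {
  set.seed(33)
  for (i in 1:1000) {
    s1 <- runif(1, 0.1, 30); s2 <- runif(1, 0.1, 8); s3 <- runif(1, 0, 0.95)
    f <- runif(1, 0.005, 1 - s3 - 0.005)
    if (f <= 0) next
    cl <- critical_load_sigmoid(s1, s2, s3, f)
    expect_equal(sulfur_sigmoid(cl$value, s1, s2, s3), 1 - f,
                 tolerance = 1e-9)
  }
})

test_that("the CL grows with s1 and with the tolerated reduction f", {
  # a larger tolerated reduction sits further down the declining curve,
  # hence at higher deposition: CL is increasing in f (as in the
  # f = 0.5 -> s1 anchor versus f = 0.05 above)
  set.seed(34)
  for (i in 1:200) {
    s2 <- runif(1, 0.2, 6); s3 <- runif(1, 0, 0.8)
    s1a <- runif(1, 0.5, 10); s1b <- s1a + runif(1, 0.1, 10)
    f1 <- runif(1, 0.01, (1 - s3) / 2)
    f2 <- f1 + runif(1, 0.001, (1 - s3) / 2 - 0.001)
    expect_lt(critical_load_sigmoid(s1a, s2, s3, f1)$value,
              critical_load_sigmoid(s1b, s2, s3, f1)$value)
    expect_lt(critical_load_sigmoid(s1a, s2, s3, f1)$value,
              critical_load_sigmoid(s1a, s2, s3, f2)$value)
  }
})

test_that("unit critical loads dispatch on endpoint and S form", {
  sel <- fake_selection("growth:base+N+Ssigmoid",
                        c(n1 = 9, s1 = 8, s2 = 2, s3 = 0.1))
  cls <- unit_critical_loads(sel, f_growth = 0.05, f_survival = 0.01)
  expect_equal(cls$N$value, 9)
  expect_equal(cls$S$f, 0.05)
  expect_equal(sulfur_sigmoid(cls$S$value, 8, 2, 0.1), 0.95, tolerance = 1e-9)
  sel_s <- fake_selection("survival:base+N+Ssigmoid:B",
                          c(n1 = 9, s1 = 8, s2 = 2, s3 = 0.1),
                          endpoint = "survival")
  expect_equal(unit_critical_loads(sel_s)$S$f, 0.01)
})
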