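test_that("node throughflow sums inflows and scales homogeneously", {
  w1 <- toy_web_w1()
  expect_equal(node_throughflow(w1), c(A = 100, B = 50))

  single <- flow_network(
    data.frame(name = "X", living = TRUE, storage = 0, input = 7,
               export = 0, respiration = 7),
    matrix(0, 1, 1))
  expect_equal(node_throughflow(single), c(X = 7))

  w3 <- w1
  w3$F <- w1$F * 3
  w3$nodes$input <- w1$nodes$input * 3
  w3$nodes$export <- w1$nodes$export * 3
  w3$nodes$respiration <- w1$nodes$respiration * 3
  expect_equal(node_throughflow(w3), 3 * node_throughflow(w1))

  unbal <- w1
  unbal$nodes$export[2] <- 25
  expect_warning(node_throughflow(unbal), "out of balance")
})

test_that("flow partition matches the power-series oracle on W1", {
  fp <- flow_partition(toy_web_w1())
  expect_equal(fp$G[1, 2], 0.5)
  expect_equal(fp$Nout, power_series(fp$G, 50), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(fp$Nout, matrix(c(1, 0.5, 0, 1), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(fp$BFI, 100 / 150)
  expect_equal(fp$DFI, 50 / 150)
  expect_equal(fp$IFI, 0)
  expect_equal(fp$APL, 1.5)
})

test_that("a three-node chain yields the hand-inverted indirect fraction", {
  # A -> B -> C with half passed at each step: Nout row A = (1, .5, .25)
  fp <- flow_partition(toy_chain3())
  expect_equal(fp$Nout[1, ], c(1, 0.5, 0.25), ignore_attr = TRUE)
  expect_equal(fp$Nout, power_series(fp$G, 60), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(fp$TST, 175)
  expect_equal(fp$IFI, 25 / 175)
  expect_equal(fp$BFI + fp$DFI + fp$IFI, 1, tolerance = 1e-12)
})

test_that("homogenization reproduces the brute-force CV ratios on W1", {
  w1 <- toy_web_w1()
  cv <- function(M) stats::sd(as.vector(M)) / mean(M)
  fp <- flow_partition(w1)
  expect_equal(cv(fp$Gp), 2.0)
  expect_equal(cv(fp$Nin), 2 / 3)
  expect_equal(homogenization(w1, "input"), 3.0)
  expect_equal(homogenization(w1, "output"), cv(fp$G) / cv(fp$Nout))
  expect_equal(homogenization(w1, "output"), 2.6111648, tolerance = 1e-6)
})

test_that("ascendency matches the single-node hand computation and is base-invariant", {
  single <- flow_network(
    data.frame(name = "X", living = TRUE, storage = 0, input = 100,
               export = 50, respiration = 50),
    matrix(0, 1, 1))
  a <- ascendency_suite(single)
  expect_equal(a$A, 200)
  expect_equal(a$Cdev, 300)
  expect_equal(a$rel_ascendency, 2 / 3)

  an <- ascendency_suite(single, base = exp(1))
  expect_equal(an$rel_ascendency, a$rel_ascendency, tolerance = 1e-12)

  # duplicating the system in parallel shares one virtual import row and
  # one export/dissipation column, so A and C both grow but not in
  # proportion; hand computation gives A = 400, C = 1000
  twin <- flow_network(
    data.frame(name = c("X1", "X2"), living = TRUE, storage = 0, input = 100,
               export = 50, respiration = 50),
    matrix(0, 2, 2))
  at <- ascendency_suite(twin)
  expect_equal(at$A, 400)
  expect_equal(at$Cdev, 1000)

  # homogeneity: scaling every flow scales A and C linearly, ratio fixed
  k <- 2.5
  sk <- flow_network(
    data.frame(name = "X", living = TRUE, storage = 0, input = 100 * k,
               export = 50 * k, respiration = 50 * k),
    matrix(0, 1, 1))
  ak <- ascendency_suite(sk)
  expect_equal(ak$A, k * a$A, tolerance = 1e-12)
  expect_equal(ak$rel_ascendency, a$rel_ascendency, tolerance = 1e-12)

  expect_error(ascendency_suite(flow_network(
    data.frame(name = "X", living = TRUE, storage = 0, input = 0,
               export = 0, respiration = 0), matrix(0, 1, 1))), "zero total flow")
})

test_that("utility analysis matches the 2x2 hand inversion on W1", {
  u <- utility_suite(toy_web_w1())
  expect_equal(u$D, matrix(c(0, 0.5, -1, 0), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(u$rho, sqrt(0.5), tolerance = 1e-12)
  expect_true(u$convergent)
  expect_equal(u$U, matrix(c(2, 1, -2, 2) / 3, 2, 2, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-12)
  # oracle: U equals the truncated utility power series
  expect_equal(u$U, power_series(u$D, 200), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(u$Y, matrix(c(200, 100, -100, 100) / 3, 2, 2, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(u$synergism_F, 4.0)
  expect_equal(u$mutualism_F, 3.0)
  expect_equal(sign(u$U), matrix(c(1, 1, -1, 1), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("symmetric exchange gives identity utility and Inf mutualism", {
  sym <- flow_network(
    data.frame(name = c("A", "B"), living = TRUE, storage = 0,
               input = c(60, 60), export = c(30, 30),
               respiration = c(30, 30)),
    matrix(c(0, 20, 20, 0), 2, 2))
  u <- utility_suite(sym)
  expect_equal(u$D, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(u$U, diag(2), ignore_attr = TRUE)
  expect_true(all(u$Y >= 0))
  expect_identical(u$mutualism_F, Inf)
  expect_identical(u$synergism_F, Inf)
})

test_that("environ centrality normalizes to one and respects symmetry", {
  ec <- environ_centrality(toy_web_w1())
  expect_equal(ec$EC_out, c(A = 0.6, B = 0.4))
  expect_equal(ec$EC_in, c(A = 1 / 3, B = 2 / 3))
  expect_equal(ec$AEC, c(A = 7 / 15, B = 8 / 15))
  expect_equal(sum(ec$AEC), 1)

  twin <- flow_network(
    data.frame(name = c("X1", "X2"), living = TRUE, storage = 0, input = 10,
               export = 5, respiration = 5),
    matrix(0, 2, 2))
  expect_equal(unname(environ_centrality(twin)$AEC), c(0.5, 0.5))
})

test_that("metric summary composes sub-metrics and records failures", {
  s <- ena_summary(toy_web_w1())
  expect_equal(unname(s$metrics[c("TST", "Resp", "Exports", "TSS",
                                  "NetAgg", "IFI")]),
               c(150, 70, 30, 300, 1.5, 0))
  expect_equal(unname(s$metrics["HmgInput"]), 3.0)
  expect_equal(unname(s$metrics["SynFlow"]), 4.0)
  expect_length(s$errors, 0)
  expect_equal(sum(s$AEC), 1)
})

test_that("intensive metrics are scale-invariant, extensive ones linear", {
  w1 <- toy_web_w1()
  w2 <- w1
  k <- 3.7
  w2$F <- w1$F * k
  w2$nodes$input <- w1$nodes$input * k
  w2$nodes$export <- w1$nodes$export * k
  w2$nodes$respiration <- w1$nodes$respiration * k
  s1 <- ena_summary(w1)$metrics
  s2 <- ena_summary(w2)$metrics
  intensive <- c("NetAgg", "IFI", "HmgInput", "RelAsc", "MutFlow", "SynFlow")
  extensive <- c("TST", "Resp", "Exports")
  expect_equal(s2[intensive], s1[intensive], tolerance = 1e-10)
  expect_equal(s2[extensive], k * s1[extensive], tolerance = 1e-10)
})
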