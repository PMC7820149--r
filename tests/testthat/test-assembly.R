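test_that("consumption identity C = P + R + U closes", {
  d <- consumption_demand(PB = 6, RB = 3, AE = 0.75, biomass = 10)
  expect_equal(d$production, 60)
  expect_equal(d$respiration, 30)
  expect_equal(d$consumption, 120)
  expect_equal(d$unassimilated, 30)
  expect_equal(d$consumption,
               d$production + d$respiration + d$unassimilated)

  d1 <- consumption_demand(PB = 6, RB = 3, AE = 1, biomass = 10)
  expect_equal(d1$consumption, 90)
  expect_equal(d1$unassimilated, 0)

  # periphyton energetics: annual P/B 35, daily R/B 0.03 annualized
  dp <- consumption_demand(PB = 35, RB = annualize_daily_rate(0.03),
                           AE = NA, biomass = 10)
  expect_equal(dp$production, 350)
  expect_equal(dp$respiration, 109.5)
  expect_equal(dp$consumption, 0)

  expect_error(consumption_demand(6, 3, 0, 10), "AE")
})

test_that("diet shares are productivity-times-preference proportional", {
  expect_equal(unname(allocate_diet(c(300, 100), c(1, 1))), c(0.75, 0.25))
  expect_equal(unname(allocate_diet(c(300, 100), c(1, 0))), c(1, 0))
  expect_equal(unname(allocate_diet(c(100, 100, 100), c(2, 1, 1))),
               c(0.5, 0.25, 0.25))
  expect_error(allocate_diet(c(0, 0), c(1, 1), consumer = "Mayfly"),
               "Mayfly")
})

test_that("a minimal grazer web assembles balanced with the expected budget", {
  ms <- minimal_survey()
  out <- assemble_web(ms$survey, ms$diet)
  net <- out$network
  expect_true(attr(out$report, "converged"))
  expect_lte(max(abs(steady_state_residuals(net)$relative)), 1e-6)
  expect_true(all(net$F >= 0))
  # node order: basal, detritus pools, invertebrates
  expect_equal(net$nodes$name, c("Alga", "CPOM", "FPOM", "Grazer"))

  # hand-derived budget: B_grazer = 10 * 1e-3 * 22000 = 220 J/m2
  # P = 1100, R = 2200, C = (P+R)/0.5 = 6600, U = 3300
  B_alga <- 5000 * 2e-4 * 20000
  expect_equal(net$F["Alga", "Grazer"], 6600)
  expect_lt(6600, 35 * B_alga)  # demand below production: no drift needed
  expect_equal(net$nodes$input[net$nodes$name == "Grazer"], 0)
  # algal surplus exported
  expect_equal(net$nodes$export[net$nodes$name == "Alga"],
               35 * B_alga - 6600)
  # consumption identity per consumer (producers acquire energy at the
  # boundary, not by ingestion)
  bud <- out$budget[out$budget$consumption > 0, ]
  expect_equal(bud$consumption,
               bud$production + bud$respiration + bud$unassimilated,
               tolerance = 1e-9)
})

test_that("demand beyond local production enters as drift input", {
  ms <- minimal_survey(grazer_density = 1e5)  # demand >> algal production
  out <- assemble_web(ms$survey, ms$diet)
  net <- out$network
  B_alga <- 5000 * 2e-4 * 20000
  P_alga <- 35 * B_alga
  demand <- out$budget$consumption[out$budget$name == "Grazer"]
  expect_gt(demand, P_alga)
  i <- which(net$nodes$name == "Alga")
  # boundary input = own production + respiration + the shortfall
  expect_equal(net$nodes$input[i],
               P_alga + 10.95 * B_alga + (demand - P_alga))
  expect_true(attr(out$report, "converged"))
})

test_that("egestion and mortality routing keep the web balanced", {
  ms <- minimal_survey()
  out <- assemble_web(ms$survey, ms$diet, egestion_to = "FPOM",
                      mortality_to_cpom = 0.3)
  net <- out$network
  expect_true(attr(out$report, "converged"))
  expect_equal(net$F["Grazer", "FPOM"],
               out$budget$unassimilated[out$budget$name == "Grazer"])
  expect_gt(net$F["Alga", "CPOM"], 0)
  # detritus pools import exactly what is not supplied internally
  expect_lte(max(abs(steady_state_residuals(net)$relative)), 1e-6)
  expect_equal(net$nodes$respiration[!net$nodes$living], c(0, 0))
})

test_that("dangling diet references and missing AE are errors", {
  ms <- minimal_survey()
  bad <- ms$diet
  bad$resource <- "Ghost"
  expect_error(assemble_web(ms$survey, bad), "Ghost")
  badc <- rbind(ms$diet,
                data.frame(consumer = "Phantom", resource = "Alga",
                           preference = 1))
  expect_error(assemble_web(ms$survey, badc), "Phantom")
  noae <- ms$survey
  noae$AE[2] <- NA
  expect_error(assemble_web(noae, ms$diet), "AE")
})

test_that("doubling densities doubles throughflow (assembly homogeneity)", {
  ms <- minimal_survey()
  t1 <- sum(node_throughflow(assemble_web(ms$survey, ms$diet)$network))
  ms$survey$density <- ms$survey$density * 2
  t2 <- sum(node_throughflow(assemble_web(ms$survey, ms$diet)$network))
  expect_equal(t2, 2 * t1, tolerance = 1e-9)
})
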