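test_that("the bounded simplex solves hand-checkable LPs", {
  # max x1 + x2 st x1 + x2 <= 4 (as equality with slack via Ain), x <= 3
  sol <- solveLP(c(1, 1), Ain = matrix(c(1, 1), 1), bin = 4,
                 lb = c(0, 0), ub = c(3, 3))
  expect_equal(sol$objective, 4)
  # equality-constrained: x1 = 2 fixed by bounds conflict -> infeasible
  bad <- solveLP(c(1), Aeq = matrix(1, 1, 1), beq = 5, lb = 0, ub = 4)
  expect_equal(bad$status, "infeasible")
  # minimization with negative costs and free-ish ranges
  sol2 <- solveLP(c(2, -1), Aeq = matrix(c(1, 1), 1), beq = 1,
                  lb = c(-5, -5), ub = c(5, 5), maximize = FALSE)
  expect_equal(sol2$objective, 2 * (-4) - 5)  # x = (-4, 5)
})

test_that("packaged fixture loads, validates and shows", {
  m <- ptoyNitrogenModel()
  expect_s4_class(m, "MetabolicModel")
  expect_true(validObject(m))
  expect_true(all(c("EX_no3_e", "EX_urea_e", "EX_o2_e", "AOX_m", "NR_c",
                    "NiR_h", "GSII_h", "GOGAT_h", "URE_m", "GSIII_m",
                    "GOGAT_m", "AST_h", "AST_m", "ALT_h", "ALT_m",
                    "PYC_h", "NH4t_hc", "NH4t_mc", "GLUt_hc", "GLNt_hc",
                    "AGPR_h", "CPS_m", "OTC_m", "ASS_ASL_c", "bof_c") %in%
                    reactions(m)$id))
  expect_output(show(m), "MetabolicModel")
  expect_equal(objectiveReaction(m), "bof_c")
})

test_that("breaking glutamate's formula names every consuming reaction", {
  m <- ptoyNitrogenModel()
  met <- metabolites(m)
  met$nitrogen[met$id == "glu_h"] <- 0
  expect_error(
    new("MetabolicModel", metabolites = met, reactions = reactions(m),
        stoich = stoichiometry(m), objective = "bof_c"),
    "nitrogen imbalance.*GSII_h")
  err <- tryCatch(
    new("MetabolicModel", metabolites = met, reactions = reactions(m),
        stoich = stoichiometry(m), objective = "bof_c"),
    error = function(e) conditionMessage(e))
  for (rxn in c("GSII_h", "GOGAT_h", "AST_h", "ALT_h", "AGPR_h"))
    expect_match(err, rxn)
  # exchange reactions are exempt: unbalancing an external metabolite is fine
  met2 <- metabolites(m)
  met2$nitrogen[met2$id == "o2_e"] <- 5   # only touched by EX/transport
  expect_error(
    new("MetabolicModel", metabolites = met2, reactions = reactions(m),
        stoich = stoichiometry(m), objective = "bof_c"),
    "O2t_ce")   # internal transport now unbalanced, exchange not named
})

test_that("concentration changes convert to model units", {
  ser <- data.frame(metabolite = "pro_c", t0 = 0, t1 = 1000)
  expect_equal(unname(concentrationsToRates(ser)), 0.7)
  expect_equal(unname(concentrationsToRates(ser, 0.35)), 0.35)
  expect_equal(unname(concentrationsToRates(
    data.frame(metabolite = "x", t0 = 5, t1 = 5))), 0)
  expect_error(concentrationsToRates(data.frame(metabolite = "x", t0 = 1)),
               "timepoint")
})

test_that("constraints set the published bounds and scenario exchanges", {
  m <- ptoyNitrogenModel()
  con <- applyConstraints(m, scenario = "nitrate")
  r <- reactions(con)
  expect_equal(r$upper[r$id == "EX_o2_e"], 10)
  expect_equal(r$lower[r$id == "AOX_m"], 0.33)
  expect_equal(r$lower[r$id == "NH4t_hc"], -0.1)
  expect_equal(r$upper[r$id == "NH4t_mc"], 0.1)
  expect_equal(r$lower[r$id == "EX_urea_e"], 0)
  expect_equal(r$upper[r$id == "EX_urea_e"], 0)
  conu <- applyConstraints(m, scenario = "urea")
  ru <- reactions(conu)
  expect_equal(ru$lower[ru$id == "EX_no3_e"], 0)
  expect_lt(ru$lower[ru$id == "EX_urea_e"], 0)
  expect_error(applyConstraints(m, rates = c(nonexistent_met = 1),
                                scenario = "nitrate"), "absent")
})

test_that("a measured rate forces exactly that sink flux", {
  m <- ptoyNitrogenModel()
  con <- applyConstraints(m, rates = c(pro_c = 0.05), scenario = "nitrate")
  sol <- fbaOptimize(con)
  expect_equal(unname(fluxes(sol)[["SK_pro_c"]]), 0.05, tolerance = 1e-9)
})

test_that("fba solves bottleneck toys and reports degenerate cases", {
  tiny <- tinyChainModel()
  sol <- fbaOptimize(tiny)
  expect_equal(sol@objective, 5, tolerance = 1e-9)
  # all exchanges closed: nothing can flow
  closed <- tiny
  closed@reactions$lower[closed@reactions$id == "EX_a_e"] <- 0
  expect_equal(fbaOptimize(closed)@objective, 0, tolerance = 1e-12)
})

test_that("fixture optimum matches an independent LP implementation", {
  m <- ptoyNitrogenModel()
  con <- applyConstraints(m, scenario = "nitrate")
  r <- reactions(con)
  obj <- as.numeric(r$id == "bof_c")
  ours <- fbaOptimize(con)
  oracle <- scipyLP(obj, stoichiometry(con), numeric(nrow(stoichiometry(con))),
                    r$lower, r$upper)
  expect_equal(oracle$status, "optimal")
  expect_equal(ours@objective, oracle$objective, tolerance = 1e-6)
})

test_that("feasible models pass through relaxation untouched", {
  m <- ptoyNitrogenModel()
  con <- applyConstraints(m, rates = c(glu_c = 0.001), scenario = "nitrate")
  rel <- relaxToFeasible(con)
  expect_equal(nrow(rel$report), 0)
  expect_equal(reactions(rel$model)$lower[
    reactions(rel$model)$id == "SK_glu_c"], 0.001)
})

test_that("an oversized sink is scaled back to the line-search maximum", {
  m <- ptoyNitrogenModel()
  # proline beyond the synthesis capacity bound of 1
  con <- applyConstraints(m, rates = c(pro_c = 6.6), scenario = "urea")
  expect_error(fbaOptimize(con), "infeasible")
  rel <- relaxToFeasible(con)
  expect_equal(rel$report$sink, "SK_pro_c")
  expect_equal(rel$report$original, 6.6)
  # grid-search oracle for the maximal feasible value
  feasible_at <- function(v) {
    cc <- applyConstraints(m, rates = c(pro_c = v), scenario = "urea")
    tryCatch({ fbaOptimize(cc); TRUE }, error = function(e) FALSE)
  }
  grid <- seq(0.9, 1.1, by = 0.005)
  gmax <- max(grid[vapply(grid, feasible_at, logical(1))])
  expect_lt(abs(rel$report$relaxed - gmax), 1e-2)
  expect_equal(rel$report$relaxed, 1, tolerance = 1e-3)
})

test_that("loopless preserves objective/exchanges and removes planted cycles", {
  tiny <- tinyChainModel()
  # plant a 2-reaction futile cycle a_c <-> b_c
  met <- metabolites(tiny); rxn <- reactions(tiny); S <- stoichiometry(tiny)
  rxn <- rbind(rxn, data.frame(id = c("LOOP1", "LOOP2"),
                               lower = c(0, 0), upper = c(50, 50),
                               exchange = FALSE))
  S <- cbind(S, LOOP1 = c(0, -1, 1), LOOP2 = c(0, 1, -1))
  loopy <- new("MetabolicModel", metabolites = met, reactions = rxn,
               stoich = S, objective = "BIO")
  sol <- fbaOptimize(loopy)
  # force flux around the cycle on top of the optimum
  v <- fluxes(sol)
  v[["LOOP1"]] <- v[["LOOP1"]] + 20
  v[["LOOP2"]] <- v[["LOOP2"]] + 20
  forced <- new("FluxSolution", fluxes = v, objective = sol@objective,
                status = "optimal")
  ll <- looplessSolution(loopy, forced)
  expect_equal(ll@objective, sol@objective, tolerance = 1e-8)
  expect_equal(unname(fluxes(ll)[["LOOP1"]]), 0, tolerance = 1e-9)
  expect_equal(unname(fluxes(ll)[["LOOP2"]]), 0, tolerance = 1e-9)
  internal <- !reactions(loopy)$exchange
  expect_lte(sum(abs(fluxes(ll)[internal])),
             sum(abs(v[internal])) + 1e-9)
  # exchange fluxes fixed
  expect_equal(fluxes(ll)[["EX_a_e"]], v[["EX_a_e"]], tolerance = 1e-9)
  # loop-free input comes back with the same internal L1
  ll2 <- looplessSolution(loopy, ll)
  expect_equal(sum(abs(fluxes(ll2)[internal])),
               sum(abs(fluxes(ll)[internal])), tolerance = 1e-8)
  # independent L1 oracle for the same restricted problem
  r2 <- reactions(loopy)
  fixed <- r2$exchange | r2$id == "BIO"
  lb <- ifelse(fixed, v, r2$lower); ub <- ifelse(fixed, v, r2$upper)
  n <- nrow(r2); ni <- sum(!fixed)
  Aeq <- cbind(S, matrix(0, nrow(S), ni))
  Ain <- matrix(0, 2 * ni, n + ni)
  for (j in seq_len(ni)) {
    i <- which(!fixed)[j]
    Ain[2 * j - 1, i] <- 1; Ain[2 * j - 1, n + j] <- -1
    Ain[2 * j, i] <- -1; Ain[2 * j, n + j] <- -1
  }
  ora <- scipyLP(c(numeric(n), rep(1, ni)), Aeq, numeric(nrow(Aeq)),
                 lb = c(lb, numeric(ni)), ub = c(ub, rep(100, ni)),
                 Ain = Ain, bin = numeric(2 * ni), maximize = FALSE)
  expect_equal(ora$status, "optimal")
  expect_equal(sum(abs(fluxes(ll)[internal])), ora$objective,
               tolerance = 1e-7)
})

test_that("every solution is mass balanced and conserves nitrogen atoms", {
  m <- ptoyNitrogenModel()
  for (sc in c("nitrate", "urea")) {
    con <- applyConstraints(m, scenario = sc)
    sol <- looplessSolution(con, fbaOptimize(con))
    v <- fluxes(sol)
    S <- stoichiometry(con)
    expect_lt(max(abs(S %*% v)), 1e-6)
    natoms <- metabolites(con)$nitrogen
    exch <- reactions(con)$exchange
    nflux <- as.vector(t(S) %*% natoms) * v
    expect_lt(abs(sum(nflux[exch])), 1e-6)
  }
})

test_that("the nitrogen source switches the dominant amino shuttle", {
  m <- ptoyNitrogenModel()
  shut <- lapply(c(nitrate = "nitrate", urea = "urea"), function(sc) {
    con <- applyConstraints(m, scenario = sc)
    shuttleReport(looplessSolution(con, fbaOptimize(con)))
  })
  rn <- shut$nitrate$routes
  expect_gte(rn$dominance[rn$route == "aspartate"], 0.8)
  expect_lt(abs(rn$n_flux[rn$route == "alanine"]), 0.01)
  ru <- shut$urea$routes
  expect_gte(ru$dominance[ru$route == "alanine"], 0.8)
  # arginine synthesis runs whenever biomass demands arginine; arginase off
  for (s in shut) {
    expect_gt(s$arginine_synthesis, 0)
    expect_lt(abs(s$arginase_flux), 1e-9)
  }
  expect_equal(shut$nitrate$assimilation_organelle, "chloroplast")
  expect_equal(shut$urea$assimilation_organelle, "mitochondrion")
})

test_that("solutions display and expose fluxes", {
  con <- applyConstraints(ptoyNitrogenModel(), scenario = "nitrate")
  sol <- fbaOptimize(con)
  expect_output(show(sol), "FluxSolution")
  expect_equal(length(fluxes(sol)), nrow(reactions(con)))
})
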