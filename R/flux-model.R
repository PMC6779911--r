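#' Load a compartmentalized stoichiometric model from JSON
#'
#' Reads a constraint-based model document (compartments, metabolites with
#' carbon/nitrogen atom counts, reactions with sparse stoichiometry, bounds
#' and exchange flags, objective) and validates it: dimensions, bounds, and
#' exact C/N balance of every internal reaction (exchange reactions are
#' exempt by definition). The packaged toy fixture is available via
#' [ptoyNitrogenModel()].
#'
#' @param path JSON file path.
#' @return A [MetabolicModel-class].
#' @export
loadMetabolicModel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  met <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = m$id, compartment = m$compartment,
               carbon = as.numeric(m$carbon),
               nitrogen = as.numeric(m$nitrogen),
               stringsAsFactors = FALSE)))
  rxn <- do.call(rbind, lapply(doc$reactions, function(r)
    data.frame(id = r$id, lower = as.numeric(r$lower_bound),
               upper = as.numeric(r$upper_bound),
               exchange = isTRUE(r$exchange), stringsAsFactors = FALSE)))
  S <- matrix(0, nrow(met), nrow(rxn),
              dimnames = list(met$id, rxn$id))
  for (r in doc$reactions) {
    st <- unlist(r$stoichiometry)
    if (!all(names(st) %in% met$id))
      stop("reaction ", r$id, " references unknown metabolites")
    S[names(st), r$id] <- as.numeric(st)
  }
  new("MetabolicModel", metabolites = met, reactions = rxn, stoich = S,
      objective = doc$objective)
}

#' The packaged toy nitrogen-assimilation model
#'
#' A hand-built ~60-reaction model of compartmentalized diatom nitrogen
#' assimilation (external/cytosol/chloroplast/mitochondrion) with carbon
#' and nitrogen atom annotations: chloroplast nitrate assimilation
#' (NR, NiR, GSII/GOGAT), mitochondrial urea assimilation (urease,
#' GSIII/GOGAT), paired aspartate and alanine transaminase shuttles,
#' plastid pyruvate carboxylase, the split-organelle ornithine/urea-cycle
#' arginine synthesis route, and a cytosolic biomass objective. Capacities
#' (restricted direct glutamate/glutamine transport, irreversible
#' transaminase directions) are engineered so that nitrogen leaves the
#' assimilating organelle predominantly on an aspartate (nitrate) or
#' alanine (urea) carbon skeleton; the fixture file documents this.
#'
#' @return A validated [MetabolicModel-class].
#' @export
ptoyNitrogenModel <- function() {
  loadMetabolicModel(system.file("extdata", "ptoy_nitrogen.json",
                                 package = "nitrosense"))
}

#' Convert metabolite concentration changes to model-unit rates
#'
#' Concentrations measured in nmol per mg protein at 0 and 1 h are
#' converted to mmol per gDW per h using the biomass protein fraction:
#' `rate = (c1 - c0) * protein_fraction * 1e3 (mg/gDW) * 1e-6 (mmol/nmol)`,
#' i.e. `7e-4 * delta` at the default 70% protein fraction.
#'
#' @param series data.frame with `metabolite`, `t0`, `t1` (nmol/mg
#'   protein).
#' @param protein_fraction Protein fraction of biomass dry weight
#'   (default 0.70).
#' @return Named numeric vector of rates (mmol gDW^-1 h^-1).
#' @export
concentrationsToRates <- function(series, protein_fraction = 0.70) {
  if (!all(c("metabolite", "t0", "t1") %in% names(series)))
    stop("series needs columns metabolite, t0, t1 (missing timepoint?)")
  if (any(is.na(series$t0)) || any(is.na(series$t1)))
    stop("missing timepoint measurement")
  setNames((series$t1 - series$t0) * protein_fraction * 1e3 * 1e-6,
           series$metabolite)
}

.setBounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- match(id, model@reactions$id)
  if (is.na(i)) stop("named reaction absent from model: ", id)
  if (!is.null(lower)) model@reactions$lower[i] <- lower
  if (!is.null(upper)) model@reactions$upper[i] <- upper
  model
}

#' Apply the experimental constraints and a nitrogen-source scenario
#'
#' Sets the maximum O2 evolution rate (upper bound of `EX_o2_e`), the
#' maintenance requirement (lower bound of the mitochondrial alternative
#' oxidase `AOX_m`), caps the magnitude of chloroplast-cytosol and
#' mitochondrion-cytosol ammonium transport, opens exactly one nitrogen
#' exchange (`EX_no3_e` or `EX_urea_e`) while closing the other, and
#' integrates each measured metabolite rate as a sink reaction with both
#' bounds fixed at the rate, so any feasible flux distribution reproduces
#' the measured metabolite dynamics.
#'
#' @param model A [MetabolicModel-class].
#' @param rates Optional named rates from [concentrationsToRates()].
#' @param scenario `"nitrate"` or `"urea"`.
#' @param o2_max Max O2 evolution (mmol gDW^-1 h^-1, default 10).
#' @param maintenance Maintenance O2 demand (default 0.33).
#' @param nh4_transport_cap Ammonium transport cap (default 0.1; the
#'   source prints no time unit, read as mmol gDW^-1 h^-1).
#' @return The constrained [MetabolicModel-class].
#' @export
applyConstraints <- function(model, rates = NULL,
                             scenario = c("nitrate", "urea"),
                             o2_max = 10, maintenance = 0.33,
                             nh4_transport_cap = 0.1) {
  scenario <- match.arg(scenario)
  model <- .setBounds(model, "EX_o2_e", upper = o2_max)
  model <- .setBounds(model, "AOX_m", lower = maintenance)
  for (t in c("NH4t_hc", "NH4t_mc"))
    model <- .setBounds(model, t, lower = -nh4_transport_cap,
                        upper = nh4_transport_cap)
  closed <- if (scenario == "nitrate") "EX_urea_e" else "EX_no3_e"
  model <- .setBounds(model, closed, lower = 0, upper = 0)
  if (!is.null(rates)) {
    for (m in names(rates)) {
      if (!(m %in% model@metabolites$id))
        stop("sink metabolite absent from model: ", m)
      rid <- paste0("SK_", m)
      model@reactions <- rbind(model@reactions,
        data.frame(id = rid, lower = rates[[m]], upper = rates[[m]],
                   exchange = TRUE, stringsAsFactors = FALSE))
      col <- matrix(0, nrow(model@stoich), 1,
                    dimnames = list(rownames(model@stoich), rid))
      col[m, 1] <- -1
      model@stoich <- cbind(model@stoich, col)
    }
  }
  validObject(model)
  model
}

.feasible <- function(model) {
  sol <- .solveModel(model)
  sol$status != "infeasible"
}

.solveModel <- function(model, obj = NULL, maximize = TRUE) {
  rxn <- model@reactions
  if (is.null(obj)) {
    obj <- numeric(nrow(rxn))
    obj[rxn$id == model@objective] <- 1
  }
  solveLP(obj, Aeq = model@stoich, beq = numeric(nrow(model@stoich)),
          lb = rxn$lower, ub = rxn$upper, maximize = maximize)
}

#' Relax infeasible metabolite sink rates until the model is feasible
#'
#' Bisection-scales the largest-magnitude sink rate (then the next largest,
#' and so on) until a feasible model is obtained; every altered rate is
#' reported (original and relaxed value). A feasible model is returned
#' unchanged with an empty report. If the model stays infeasible with
#' every sink at zero a hard error is raised.
#'
#' @param model A constrained model from [applyConstraints()].
#' @param tol Bisection resolution on the scale factor.
#' @return List with `model` and `report` (data.frame: sink, original,
#'   relaxed).
#' @export
relaxToFeasible <- function(model, tol = 1e-4) {
  report <- data.frame(sink = character(), original = numeric(),
                       relaxed = numeric(), stringsAsFactors = FALSE)
  if (.feasible(model)) return(list(model = model, report = report))
  sinks <- grep("^SK_", model@reactions$id, value = TRUE)
  rates <- setNames(model@reactions$lower[match(sinks, model@reactions$id)],
                    sinks)
  for (s in names(sort(-abs(rates)))) {
    if (.feasible(model)) break
    orig <- rates[[s]]
    if (orig == 0) next
    # largest feasible scale in [0, 1] by bisection (monotone feasibility)
    lo <- 0; hi <- 1
    test <- function(t) .feasible(.setBounds(model, s, lower = t * orig,
                                             upper = t * orig))
    if (!test(0)) { model <- .setBounds(model, s, 0, 0); next }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (test(mid)) lo <- mid else hi <- mid
    }
    model <- .setBounds(model, s, lower = lo * orig, upper = lo * orig)
    report <- rbind(report, data.frame(sink = s, original = orig,
                                       relaxed = lo * orig))
  }
  if (!.feasible(model))
    stop("model infeasible even with all metabolite sinks at zero")
  list(model = model, report = report)
}

#' Flux balance analysis: maximize the biomass objective
#'
#' Solves `max c'v` subject to `S v = 0` (metabolite rates appear as sink
#' reactions with fixed bounds) and the reaction bounds.
#'
#' @param model A constrained [MetabolicModel-class].
#' @return A [FluxSolution-class].
#' @export
fbaOptimize <- function(model) {
  sol <- .solveModel(model)
  if (sol$status == "infeasible")
    stop("model is infeasible; consider relaxToFeasible()")
  if (sol$status == "unbounded")
    stop("model is unbounded; check exchange bounds")
  new("FluxSolution",
      fluxes = setNames(sol$x, model@reactions$id),
      objective = sol$objective, status = sol$status)
}

#' Cycle-free (loopless) reduction of a flux solution
#'
#' Fixes every exchange flux and the objective flux at their solved values
#' and minimizes the L1 norm of the internal fluxes (linear program via
#' flux splitting). The result carries the same objective value and
#' exchange fluxes with internal L1 norm no larger than the input,
#' removing thermodynamically infeasible internal cycles.
#'
#' @param model The constrained model the solution was obtained on.
#' @param solution A [FluxSolution-class] from [fbaOptimize()].
#' @return A [FluxSolution-class].
#' @export
looplessSolution <- function(model, solution) {
  rxn <- model@reactions
  v <- fluxes(solution)
  fixed <- rxn$exchange | rxn$id == model@objective
  n <- nrow(rxn)
  internal <- which(!fixed)
  ni <- length(internal)
  lb <- ifelse(fixed, v, rxn$lower)
  ub <- ifelse(fixed, v, rxn$upper)
  # variables: v (n) then t (ni) with t_i >= |v_i|
  big <- max(abs(c(rxn$lower, rxn$upper))) + 1
  obj <- c(numeric(n), rep(1, ni))
  Aeq <- cbind(model@stoich, matrix(0, nrow(model@stoich), ni))
  Ain <- matrix(0, 2 * ni, n + ni)
  for (j in seq_len(ni)) {
    i <- internal[j]
    Ain[2 * j - 1, i] <- 1;  Ain[2 * j - 1, n + j] <- -1
    Ain[2 * j,     i] <- -1; Ain[2 * j,     n + j] <- -1
  }
  sol <- solveLP(obj, Aeq = Aeq, beq = numeric(nrow(Aeq)),
                 Ain = Ain, bin = numeric(2 * ni),
                 lb = c(lb, numeric(ni)), ub = c(ub, rep(big, ni)),
                 maximize = FALSE)
  if (sol$status != "optimal")
    stop("loopless minimization failed: ", sol$status)
  vv <- setNames(sol$x[seq_len(n)], rxn$id)
  new("FluxSolution", fluxes = vv, objective = solution@objective,
      status = "optimal")
}

# carrier routes: (transporter giving chloroplast->cytosol flow, sign),
# (transporter giving cytosol->mitochondrion flow, sign), N atoms carried
.SHUTTLE_ROUTES <- list(
  aspartate = list(hc = c("ASPt_hc", 1), cm = c("ASPt_cm", 1), n = 1),
  alanine   = list(hc = c("ALAt_ch", -1), cm = c("ALAt_mc", -1), n = 1),
  glutamate = list(hc = c("GLUt_hc", 1), cm = c("GLUt_mc", -1), n = 1),
  glutamine = list(hc = c("GLNt_hc", 1), cm = c("GLNt_mc", -1), n = 2))

#' Inter-organelle nitrogen shuttle report
#'
#' Quantifies the net amino nitrogen transferred between chloroplast and
#' mitochondria by the aspartate, alanine, glutamate and glutamine carrier
#' routes. Transport is through the cytosol, so the chloroplast-to-
#' mitochondrion transfer of a carrier is the direction-consistent
#' common flow of its two legs (organelle-to-cytosol and
#' cytosol-to-organelle); positive values run chloroplast to
#' mitochondrion. Dominance is each route's share of the summed absolute
#' inter-organelle amino-N transfer. Also reports the urea-cycle arginine
#' synthesis flux, the arginase flux, and the organelle with the larger
#' net ammonium assimilation (glutamine synthetase flux).
#'
#' @param solution A [FluxSolution-class] on the packaged fixture (named
#'   transporters must be present).
#' @return List with `routes` (data.frame: route, n_flux, dominance),
#'   `arginine_synthesis`, `arginase_flux`, `assimilation_organelle`.
#' @export
shuttleReport <- function(solution) {
  v <- fluxes(solution)
  need <- c(unlist(lapply(.SHUTTLE_ROUTES, function(r)
    c(r$hc[1], r$cm[1]))), "ASS_ASL_c", "ARGASE_m", "GSII_h", "GSIII_m")
  if (!all(need %in% names(v)))
    stop("named transporter missing from solution: ",
         paste(setdiff(need, names(v)), collapse = ", "))
  n_flux <- vapply(.SHUTTLE_ROUTES, function(r) {
    leg_hc <- v[[r$hc[1]]] * as.numeric(r$hc[2])   # chloroplast -> cytosol
    leg_cm <- v[[r$cm[1]]] * as.numeric(r$cm[2])   # cytosol -> mitochondrion
    tr <- if (sign(leg_hc) == sign(leg_cm))
      sign(leg_hc) * min(abs(leg_hc), abs(leg_cm)) else 0
    tr * r$n
  }, numeric(1))
  tot <- sum(abs(n_flux))
  routes <- data.frame(route = names(.SHUTTLE_ROUTES), n_flux = n_flux,
                       dominance = if (tot > 0) abs(n_flux) / tot
                                   else rep(0, length(n_flux)),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(routes = routes,
       arginine_synthesis = v[["ASS_ASL_c"]],
       arginase_flux = v[["ARGASE_m"]],
       assimilation_organelle =
         if (v[["GSII_h"]] >= v[["GSIII_m"]]) "chloroplast"
         else "mitochondrion")
}
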