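#' Energetic demand of a taxon
#'
#' Closes the consumption identity C = P + R + U for a consumer with
#' biomass `B` (J/m^2): production `P = PB * B`, respiration `R = RB * B`,
#' consumption `C = (P + R) / AE` and unassimilated (egested) food
#' `U = (1 - AE) * C`, where `AE` is the assimilation efficiency
#' (assimilation / ingestion). Producers (no `AE`) have zero consumption.
#'
#' @param PB,RB annual production/biomass and respiration/biomass ratios.
#' @param AE assimilation efficiency in (0, 1]; `NA` for producers.
#' @param biomass standing stock in J/m^2.
#' @return list with `production`, `respiration`, `consumption`,
#'   `unassimilated`, all in J/m^2/yr.
#' @export
consumption_demand <- function(PB, RB, AE, biomass) {
  if (any(biomass < 0) || any(PB < 0) || any(RB < 0)) {
    stop("biomass, PB and RB must be nonnegative")
  }
  P <- PB * biomass
  R <- RB * biomass
  if (is.na(AE)) {
    C <- 0
    U <- 0
  } else {
    if (AE <= 0 || AE > 1) stop("AE must lie in (0, 1]; got ", AE)
    C <- (P + R) / AE
    U <- (1 - AE) * C
  }
  list(production = P, respiration = R, consumption = C, unassimilated = U)
}

#' Allocate a consumer's diet across resources
#'
#' Dietary shares are proportional to resource availability (production
#' for living resources) times preference weight, the standard
#' productivity-weighted diet assumption.
#'
#' @param availability named nonnegative vector of resource availabilities
#'   (J/m^2/yr).
#' @param preference nonnegative weights on the same names.
#' @param consumer consumer name, used in error messages.
#' @return named shares summing to one.
#' @export
allocate_diet <- function(availability, preference, consumer = "consumer") {
  if (length(availability) != length(preference)) {
    stop("availability and preference lengths differ for ", consumer)
  }
  w <- availability * preference
  if (any(w < 0)) stop("negative availability or preference for ", consumer)
  if (sum(w) == 0) {
    stop("consumer '", consumer,
         "' has no resource with positive availability x preference")
  }
  w / sum(w)
}

#' Assemble a balanced energy-flow web from a community survey
#'
#' Converts a survey table (taxon densities, masses, energetic rates,
#' diets) into a [flow_network] balanced at steady state:
#' \enumerate{
#'   \item biomass `B = density * individual_mass * energy_density`;
#'   \item per-taxon production, respiration, consumption and egestion
#'     from [consumption_demand];
#'   \item internal flows from [allocate_diet] shares times consumption;
#'   \item where consumption of a taxon exceeds its local production the
#'     shortfall enters as boundary input (drift from upstream); where
#'     production exceeds consumption the surplus leaves as export
#'     (drift out, death, downstream processing), optionally with a
#'     fraction routed to the CPOM pool as non-predation mortality;
#'   \item detritus imports are set to balance detritivore consumption;
#'   \item residual numerical imbalance is removed by [balance_avg2].
#' }
#' Producers receive their production plus respiration as boundary input
#' (photosynthesis crosses the system boundary). Egested food is exported
#' by default or routed to FPOM via `egestion_to`.
#'
#' @param survey data.frame with columns name, guild
#'   (periphyton/invertebrate/fish), density (ind/m^2), individual_mass
#'   (g dry weight), energy_density (J/g), PB, RB, AE.
#' @param diet data.frame with columns consumer, resource, preference;
#'   resources may be taxa or the detritus pools "CPOM"/"FPOM".
#' @param detritus_storage nominal storage of each detritus pool (J/m^2).
#' @param detritus_availability availability used when allocating diets
#'   that include detritus; defaults to the mean periphyton production.
#' @param egestion_to "export" (default) or "FPOM".
#' @param mortality_to_cpom fraction of each taxon's production surplus
#'   routed to CPOM as non-predation mortality (default 0, i.e. all
#'   surplus is exported).
#' @param tol balancing tolerance passed to [balance_avg2].
#' @return list with `network` (balanced [flow_network]), `report`
#'   (balance_report) and `budget` (per-taxon P, R, C, U table).
#' @export
assemble_web <- function(survey, diet,
                         detritus_storage = 100,
                         detritus_availability = NULL,
                         egestion_to = c("export", "FPOM"),
                         mortality_to_cpom = 0,
                         tol = 1e-6) {
  egestion_to <- match.arg(egestion_to)
  stopifnot(is.data.frame(survey), is.data.frame(diet))
  need <- setdiff(c("name", "guild", "density", "individual_mass",
                    "energy_density", "PB", "RB", "AE"), names(survey))
  if (length(need)) stop("survey missing column(s): ", paste(need, collapse = ", "))
  need <- setdiff(c("consumer", "resource", "preference"), names(diet))
  if (length(need)) stop("diet missing column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(survey$name)) stop("duplicate taxon names in survey")
  if (!all(survey$guild %in% c("periphyton", "invertebrate", "fish"))) {
    stop("guild must be periphyton, invertebrate or fish")
  }
  if (mortality_to_cpom < 0 || mortality_to_cpom > 1) {
    stop("mortality_to_cpom must be in [0, 1]")
  }
  detritus <- c("CPOM", "FPOM")
  if (any(survey$name %in% detritus)) {
    stop("taxon names CPOM/FPOM are reserved for the detritus pools")
  }
  unknown <- setdiff(unique(diet$resource), c(survey$name, detritus))
  if (length(unknown)) {
    stop("diet references absent resource(s): ", paste(unknown, collapse = ", "))
  }
  unknownc <- setdiff(unique(diet$consumer), survey$name)
  if (length(unknownc)) {
    stop("diet references absent consumer(s): ", paste(unknownc, collapse = ", "))
  }

  # deterministic node order: periphyton, detritus pools, invertebrates, fish
  ord <- order(match(survey$guild, c("periphyton", "invertebrate", "fish")),
               survey$name)
  survey <- survey[ord, , drop = FALSE]
  basal <- survey$name[survey$guild == "periphyton"]
  names_all <- c(basal, detritus,
                 survey$name[survey$guild == "invertebrate"],
                 survey$name[survey$guild == "fish"])
  n <- length(names_all)
  idx <- stats::setNames(seq_len(n), names_all)

  B <- stats::setNames(survey$density * survey$individual_mass *
                         survey$energy_density, survey$name)
  P <- R <- C <- U <- stats::setNames(numeric(n), names_all)
  for (k in seq_len(nrow(survey))) {
    tx <- survey$name[k]
    d <- consumption_demand(survey$PB[k], survey$RB[k], survey$AE[k], B[[tx]])
    if (survey$guild[k] != "periphyton" && d$consumption == 0 &&
        d$production + d$respiration > 0) {
      stop("consumer '", tx, "' has energetic demand but AE is missing")
    }
    P[tx] <- d$production; R[tx] <- d$respiration
    C[tx] <- d$consumption; U[tx] <- d$unassimilated
  }

  if (is.null(detritus_availability)) {
    detritus_availability <- if (length(basal)) mean(P[basal]) else 1
    if (detritus_availability <= 0) detritus_availability <- 1
  }
  avail <- stats::setNames(numeric(n), names_all)
  avail[survey$name] <- P[survey$name]
  avail[detritus] <- detritus_availability

  F <- matrix(0, n, n, dimnames = list(names_all, names_all))
  for (cons in unique(diet$consumer)) {
    if (C[[cons]] <= 0) next
    rows <- diet[diet$consumer == cons, , drop = FALSE]
    shares <- allocate_diet(avail[rows$resource], rows$preference, cons)
    F[cbind(idx[rows$resource], idx[cons])] <-
      F[cbind(idx[rows$resource], idx[cons])] + shares * C[[cons]]
  }
  consumers_with_demand <- names(which(C > 0))
  nofood <- setdiff(consumers_with_demand, unique(diet$consumer))
  if (length(nofood)) {
    stop("consumer(s) with energetic demand but no diet entries: ",
         paste(nofood, collapse = ", "))
  }

  consumed <- rowSums(F)              # energy taken from each node by others
  input <- export <- resp <- stats::setNames(numeric(n), names_all)
  living <- names_all %in% survey$name
  resp[survey$name] <- R[survey$name]

  # egestion routing
  if (egestion_to == "FPOM") {
    F[cbind(idx[survey$name], idx["FPOM"])] <-
      F[cbind(idx[survey$name], idx["FPOM"])] + U[survey$name]
  }
  for (tx in survey$name) {
    shortfall <- max(0, consumed[tx] - P[[tx]])
    surplus <- max(0, P[[tx]] - consumed[tx])
    mort <- mortality_to_cpom * surplus
    if (mort > 0) F[idx[tx], idx["CPOM"]] <- F[idx[tx], idx["CPOM"]] + mort
    export[tx] <- surplus - mort
    g <- survey$guild[match(tx, survey$name)]
    if (g == "periphyton") {
      input[tx] <- P[[tx]] + R[[tx]] + shortfall
    } else {
      input[tx] <- shortfall
    }
    if (egestion_to == "export") export[tx] <- export[tx] + U[[tx]]
  }
  consumed <- rowSums(F)              # refresh: egestion/mortality added rows
  for (dt in detritus) {
    supplied <- sum(F[, idx[dt]])
    demand <- consumed[dt]
    input[dt] <- max(0, demand - supplied)
    export[dt] <- max(0, supplied - demand)
  }

  nodes <- data.frame(
    name = names_all,
    living = living,
    storage = ifelse(living, B[match(names_all, names(B))], detritus_storage),
    input = input, export = export, respiration = resp,
    stringsAsFactors = FALSE
  )
  nodes$storage[is.na(nodes$storage)] <- detritus_storage
  net <- flow_network(nodes, F)
  bal <- balance_avg2(net, tol = tol)
  budget <- data.frame(name = names_all, production = P, respiration = R,
                       consumption = C, unassimilated = U,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(network = bal$network, report = bal$report, budget = budget)
}

#' Read a community survey and diet table from CSV
#'
#' @param survey_path CSV with the [assemble_web] survey columns.
#' @param diet_path CSV with columns consumer,resource,preference.
#' @return list with `survey` and `diet` data.frames.
#' @export
read_survey <- function(survey_path, diet_path) {
  list(survey = utils::read.csv(survey_path, stringsAsFactors = FALSE),
       diet = utils::read.csv(diet_path, stringsAsFactors = FALSE))
}
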