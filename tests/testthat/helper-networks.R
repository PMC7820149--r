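# Shared fixtures: small webs with hand-checkable flow structure.

# two-node web: A receives 100 boundary input, passes 50 to B;
# balanced by construction
toy_web_w1 <- function(storage = c(200, 100)) {
  flow_network(
    nodes = data.frame(
      name = c("A", "B"), living = TRUE, storage = storage,
      input = c(100, 0), export = c(20, 10), respiration = c(30, 40)
    ),
    flows = matrix(c(0, 50, 0, 0), 2, 2, byrow = TRUE)
  )
}

# three-node chain A -> B -> C, half the inflow passed at each step
toy_chain3 <- function() {
  F <- matrix(0, 3, 3)
  F[1, 2] <- 50
  F[2, 3] <- 25
  flow_network(
    nodes = data.frame(
      name = c("A", "B", "C"), living = TRUE, storage = 100,
      input = c(100, 0, 0), export = c(10, 5, 5),
      respiration = c(40, 20, 20)
    ),
    flows = F
  )
}

# minimal two-taxon survey: one periphyton, one grazer whose demand stays
# below periphyton production
minimal_survey <- function(grazer_density = 10) {
  list(
    survey = data.frame(
      name = c("Alga", "Grazer"),
      guild = c("periphyton", "invertebrate"),
      density = c(5000, grazer_density),
      individual_mass = c(2e-4, 1e-3),
      energy_density = c(20000, 22000),
      PB = c(35, 5), RB = c(10.95, 10), AE = c(NA, 0.5),
      stringsAsFactors = FALSE
    ),
    diet = data.frame(consumer = "Grazer", resource = "Alga",
                      preference = 1, stringsAsFactors = FALSE)
  )
}

# brute-force integral matrix by truncated power series
power_series <- function(G, K = 200) {
  acc <- diag(nrow(G))
  P <- diag(nrow(G))
  for (k in seq_len(K)) {
    P <- P %*% G
    acc <- acc + P
  }
  acc
}
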