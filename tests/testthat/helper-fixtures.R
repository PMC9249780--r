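# Small models built in code, shared across test files.

# linear chain: EX_in -> A -> B -> ... -> biomass sink, all bounds [0, 10]
chain_model <- function(n_internal = 2) {
  mets <- sprintf("M%d", seq_len(n_internal))
  rxns <- c("EX_in", sprintf("r%d", seq_len(n_internal - 1)), "biomass")
  S <- matrix(0, n_internal, length(rxns),
              dimnames = list(mets, rxns))
  S[1, "EX_in"] <- 1
  for (i in seq_len(n_internal - 1)) {
    S[i, i + 1] <- -1
    S[i + 1, i + 1] <- 1
  }
  S[n_internal, "biomass"] <- -1
  metabolic_model(mets, rxns, S,
                  lower_bound = rep(0, length(rxns)),
                  upper_bound = rep(10, length(rxns)),
                  objective_tags = c(biomass = "biomass"))
}

# three-objective toy: one carbon source feeding biomass, ATP (with oxygen)
# and PI4P branches; used by the design-stage tests
design_model <- function(atp_ub = 1000, pi4p_ub = 4) {
  mets <- c("C", "O2", "ATP", "PI4P")
  rxns <- c("EX_in", "EX_o2", "atp_syn", "atp_sink", "pi4p_syn",
            "pi4p_sink", "biomass")
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  S["C", "EX_in"] <- 1
  S["O2", "EX_o2"] <- 1
  S["C", "atp_syn"] <- -1; S["O2", "atp_syn"] <- -2
  S["ATP", "atp_syn"] <- 2
  S["ATP", "atp_sink"] <- -1
  S["C", "pi4p_syn"] <- -1; S["PI4P", "pi4p_syn"] <- 1
  S["PI4P", "pi4p_sink"] <- -1
  S["C", "biomass"] <- -1
  metabolic_model(mets, rxns, S,
                  lower_bound = rep(0, length(rxns)),
                  upper_bound = c(10, 1000, atp_ub, 1000, pi4p_ub,
                                  1000, 1000),
                  objective_tags = c(biomass = "biomass",
                                     atp = "atp_sink",
                                     pi4p = "pi4p_sink",
                                     oxygen_uptake = "EX_o2"))
}

# two parallel equal-capacity paths, each sufficient for the full optimum
parallel_model <- function() {
  mets <- c("A", "B")
  rxns <- c("EX_in", "p1", "p2", "biomass")
  S <- matrix(0, 2, 4, dimnames = list(mets, rxns))
  S["A", "EX_in"] <- 1
  S["A", "p1"] <- -1; S["B", "p1"] <- 1
  S["A", "p2"] <- -1; S["B", "p2"] <- 1
  S["B", "biomass"] <- -1
  metabolic_model(mets, rxns, S, rep(0, 4), c(10, 10, 10, 10),
                  objective_tags = c(biomass = "biomass"))
}

# an all-active reduced network straight from an oriented matrix
as_net <- function(S, label = "test") reduced_network(S, label = label)

# the five figure motifs as oriented networks (focal reaction "R");
# context rows give every motif an upstream feed and downstream drain so
# that boundary effects do not leak into the focal classification
motif_network <- function(type) {
  edges <- switch(type,
    none = list(
      ex = c(IN = 1),
      p1 = c(IN = -1, X = 1), p2 = c(IN = -1, X = 1),
      R = c(X = -1, OUT = 1), c2 = c(X = -1, OUT = 1),
      dm = c(OUT = -1)),
    single_consuming = list(
      ex = c(IN = 1),
      a1 = c(IN = -1, X = 1), a2 = c(IN = -1, X = 1),
      R = c(X = -1, OUT = 1), d = c(IN = -1, OUT = 1),
      dm = c(OUT = -1)),
    single_producing = list(
      ex = c(IN = 1),
      R = c(IN = -1, X = 1),
      c1 = c(X = -1, OUT = 1), c2 = c(X = -1, OUT = 1),
      d = c(IN = -1, OUT = 1),
      dm = c(OUT = -1)),
    double = list(
      ex = c(IN = 1),
      p = c(IN = -1, m1 = 1, m3 = 1),
      q = c(IN = -1, m3 = 1, OUT = 1),
      R = c(m1 = -1, m2 = 1),
      e = c(m3 = -1),
      f = c(m2 = -1, OUT = 1),
      dm = c(OUT = -1)),
    extended = list(
      ex = c(IN = 1),
      p = c(IN = -1, m1 = 1),
      R = c(m1 = -1, m2 = 1),
      f = c(m2 = -1, OUT = 1),
      d = c(IN = -1, OUT = 1),
      dm = c(OUT = -1)),
    stop("unknown motif type")
  )
  mets <- unique(unlist(lapply(edges, names)))
  S <- matrix(0, length(mets), length(edges),
              dimnames = list(mets, names(edges)))
  for (j in seq_along(edges)) S[names(edges[[j]]), j] <- edges[[j]]
  as_net(S, label = type)
}

# TRUE when two lists of vectors contain the same elements up to order
setequal_vectors <- function(xs, ys) {
  used <- rep(FALSE, length(ys))
  for (x in xs) {
    hit <- FALSE
    for (i in seq_along(ys)) {
      if (!used[i] && identical(x, ys[[i]])) { used[i] <- TRUE; hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  all(used)
}
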