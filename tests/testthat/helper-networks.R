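# Shared fixtures, built in code.

# the two-node chain A -> B used throughout as a worked example
chain_cpts <- function(p_a, p_b_given_at, p_b_given_af) {
  list(cpt("A", c("t", "f"), prob = c(p_a, 1 - p_a)),
       cpt("B", c("t", "f"), parents = "A", parent_states = list(A = c("t", "f")),
           prob = rbind(c(p_b_given_at, 1 - p_b_given_at),
                        c(p_b_given_af, 1 - p_b_given_af))))
}

chain_net <- function(p_a = 0.8, p_b_given_at = 0.9, p_b_given_af = 0.2) {
  discrete_bn(chain_cpts(p_a, p_b_given_at, p_b_given_af), name = "chain")
}

# the worked two-expert panel: expert 1 (0.8; 0.9, 0.2), expert 2 (0.2; 0.6, 0.3)
two_expert_panel <- function() {
  expert_panel(chain_net(),
               list(x1 = chain_cpts(0.8, 0.9, 0.2),
                    x2 = chain_cpts(0.2, 0.6, 0.3)))
}

# a homogeneous panel: n copies of one network's CPTs
homogeneous_panel <- function(net, n) {
  cps <- lapply(node_names_of(net), function(nd) net$cpts[[nd]])
  experts <- stats::setNames(rep(list(cps), n), sprintf("h%d", seq_len(n)))
  expert_panel(net, experts)
}

node_names_of <- function(net) names(net$nodes)

# a heterogeneous panel of Dirichlet perturbations around a random consensus
random_panel <- function(n_nodes, n_experts, seed, kappa = 8, max_parents = 2L) {
  consensus <- random_network(n_nodes, max_parents = max_parents, seed = seed)
  generate_panel(consensus,
                 panel_recipe(n_experts, kappa, seed = seed + 1000L))
}

# random evidence of a given size avoiding some nodes
random_evidence <- function(net, size, avoid = character()) {
  pool <- setdiff(names(net$nodes), avoid)
  size <- min(size, length(pool))
  if (size == 0L) return(character())
  nds <- sample(pool, size)
  stats::setNames(vapply(nds, function(nd) sample(net$nodes[[nd]], 1L), ""), nds)
}

# oracle conditional marginal via the enumerated joint
oracle_marginal <- function(net, target, evidence = character()) {
  joint <- enumerate_joint(net)
  keep <- rep(TRUE, nrow(joint))
  for (nd in names(evidence)) keep <- keep & joint[[nd]] == evidence[[nd]]
  sub <- joint[keep, , drop = FALSE]
  z <- sum(sub$prob)
  stopifnot(z > 0)
  agg <- tapply(sub$prob, factor(sub[[target]], levels = net$nodes[[target]]), sum)
  as.numeric(agg) / z
}
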