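# Shared fixtures, all built in code.

# unit-height 5-taxon binary tree
fix_tree5 <- function() {
  scale_to_unit_height(read_tree(
    "((A:0.4,B:0.4):0.6,((C:0.3,D:0.3):0.4,E:0.7):0.3);"))
}

# painting with one shift: the (A,B) clade is "NF", everything else "F".
# ape node numbering for fix_tree5: tips A=1..E=5, root=6, (A,B)=7,
# (C,D,E)=8, (C,D)=9.
fix_painting5 <- function(tr = fix_tree5()) {
  paint_from_node_states(tr, c("NF", "NF", "F", "F", "F",
                               "F", "NF", "F", "F"))
}

# brute-force Mk likelihood by summation over all internal-state assignments
brute_mk_loglik <- function(tr, tip_states, Q, root_prior) {
  states <- rownames(Q)
  ntip <- ape::Ntip(tr); nint <- tr$Nnode
  P <- lapply(seq_len(nrow(tr$edge)),
              function(e) ape::matexpo(Q * tr$edge.length[e]))
  tips_idx <- match(tip_states[tr$tip.label], states)
  total <- 0
  combos <- expand.grid(rep(list(seq_along(states)), nint))
  for (r in seq_len(nrow(combos))) {
    assign <- c(tips_idx, as.integer(combos[r, ]))
    lik <- root_prior[assign[ntip + 1L]]
    for (e in seq_len(nrow(tr$edge)))
      lik <- lik * P[[e]][assign[tr$edge[e, 1]], assign[tr$edge[e, 2]]]
    total <- total + lik
  }
  unname(log(total))
}

# brute-force marginal posterior of one node by enumeration
brute_mk_marginal <- function(tr, tip_states, Q, root_prior, node) {
  states <- rownames(Q)
  ntip <- ape::Ntip(tr); nint <- tr$Nnode
  P <- lapply(seq_len(nrow(tr$edge)),
              function(e) ape::matexpo(Q * tr$edge.length[e]))
  tips_idx <- match(tip_states[tr$tip.label], states)
  post <- numeric(length(states))
  combos <- expand.grid(rep(list(seq_along(states)), nint))
  for (r in seq_len(nrow(combos))) {
    assign <- c(tips_idx, as.integer(combos[r, ]))
    lik <- root_prior[assign[ntip + 1L]]
    for (e in seq_len(nrow(tr$edge)))
      lik <- lik * P[[e]][assign[tr$edge[e, 1]], assign[tr$edge[e, 2]]]
    post[assign[node]] <- post[assign[node]] + lik
  }
  post / sum(post)
}

# manual lineage history constructor for oracle tests
make_history <- function(regimes, breaks) {
  stopifnot(length(breaks) == length(regimes) + 1)
  h <- data.frame(regime = regimes, start = breaks[-length(breaks)],
                  end = breaks[-1], stringsAsFactors = FALSE)
  attr(h, "T") <- breaks[length(breaks)]
  class(h) <- c("lineage_history", "data.frame")
  h
}
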