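# Independent oracles used to cross-check the package's implementations.
# These deliberately avoid the package's own code paths.

# closed-form noise-free normalized recovery curve
oracle_recovery_curve <- function(t_rel, mobile, tau) {
  mobile * (1 - 2^(-t_rel / tau))
}

# ancestor-or-self check by walking the parent map (independent of the
# precomputed closure matrix inside lineage_tree)
oracle_is_anc_or_self <- function(parent, a, b) {
  cur <- b
  while (!is.na(cur)) {
    if (cur == a) return(TRUE)
    cur <- parent[[cur]]
  }
  FALSE
}

# recursive antichain enumerator over an ordered node list
oracle_antichains <- function(parent, nodes, max_k) {
  recurse <- function(idx, chosen) {
    out <- list(chosen)
    if (length(chosen) >= max_k || idx > length(nodes)) return(out)
    for (i in idx:length(nodes)) {
      nd <- nodes[i]
      compat <- !any(vapply(chosen, function(c) {
        oracle_is_anc_or_self(parent, c, nd) || oracle_is_anc_or_self(parent, nd, c)
      }, TRUE))
      if (compat) out <- c(out, recurse(i + 1L, c(chosen, nd)))
    }
    out
  }
  recurse(1L, character(0))
}

# naive hypothesis cost: per-tissue fraction via parent walking
oracle_cost <- function(loss_set, obs, parent, tissue_map,
                        alpha = 1, pgrade = 0.5) {
  ranks <- c("-" = 0, "-/+" = 1, "+/-" = 2, "+" = 3)
  pen <- 0
  for (tn in names(obs)) {
    td <- tissue_map[[tn]]
    w <- td$contributions
    lost <- vapply(names(w), function(cn) {
      any(vapply(loss_set, function(v) oracle_is_anc_or_self(parent, v, cn), TRUE))
    }, TRUE)
    if (length(loss_set) == 0L) lost[] <- FALSE
    frac <- sum(w[!lost]) / sum(w)
    pred <- if (frac >= 1) 3 else if (frac <= 0) 0 else if (frac >= 0.5) 2 else 1
    mult <- if (isTRUE(td$soft)) 0.5 else 1
    pen <- pen + mult * pgrade * abs(pred - ranks[[obs[[tn]]]])
  }
  alpha * length(loss_set) + pen
}

# per-node "omission penalty": the cost of explaining a single loss at `node`
# by the empty hypothesis instead. Events are identifiable by parsimony only
# when this exceeds alpha (see the methods vignette).
omission_penalty <- function(node, tree, tissue_map, alpha = 1, pgrade = 0.5) {
  obs <- predict_calls(node, tissue_map, tree)
  oracle_cost(character(0), obs, tree$parent, tissue_map,
              alpha = alpha, pgrade = pgrade)
}

identifiable_nodes <- function(tree = default_tree(),
                               tissue_map = default_tissue_map(), alpha = 1) {
  cand <- tree$nodes[vapply(tree$nodes, function(v) {
    any(predict_calls(v, tissue_map, tree) != "+")
  }, TRUE)]
  cand[vapply(cand, function(v) {
    omission_penalty(v, tree, tissue_map) > alpha + 1e-9
  }, TRUE)]
}
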