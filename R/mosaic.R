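#' Construct a lineage tree
#'
#' A rooted tree of named cells, given as a parent map. Used to represent the
#' early embryonic founder-cell lineage on which extrachromosomal array loss
#' is modelled as a Dollo character (lost at a division, never regained).
#'
#' @param parent Named character vector: `parent[child] = parent name`, with
#'   `NA` for the single root.
#' @return An object of class `lineage_tree` with elements `parent`, `nodes`
#'   and `anc` (logical matrix; `anc[a, b]` is `TRUE` when `a` is an
#'   ancestor of `b` or `a == b`).
#' @export
lineage_tree <- function(parent) {
  nodes <- names(parent)
  if (is.null(nodes) || any(nodes == "")) stop("all nodes must be named")
  if (anyDuplicated(nodes)) stop("duplicate node names")
  root <- nodes[is.na(parent)]
  if (length(root) != 1L) stop("tree must have exactly one root")
  if (!all(parent[!is.na(parent)] %in% nodes)) stop("parent refers to unknown node")
  # ancestor-or-self closure by walking each node up to the root
  anc <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (nd in nodes) {
    cur <- nd
    steps <- 0L
    while (!is.na(cur)) {
      anc[cur, nd] <- TRUE
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > length(nodes)) stop("cycle in parent map")
    }
  }
  structure(list(parent = parent, nodes = nodes, root = root, anc = anc),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage tree: %d nodes, root %s\n", length(x$nodes), x$root))
  invisible(x)
}

#' The default early-embryo lineage tree
#'
#' P0 divides into AB and P1; AB into ABa and ABp (with the ABar/ABara/ABaraa
#' and ABpl/ABplp/ABplpa sublineage chains needed to place the scored
#' pharyngeal and excretory cells); P1 into EMS and P2; EMS into MS (with the
#' spermatheca/gonad-sheath sublineages MSpppapp and MSappaap) and E; P2 into
#' C and P3; P3 into D and P4.
#'
#' @return A [lineage_tree()].
#' @export
default_tree <- function() {
  lineage_tree(c(
    P0 = NA, AB = "P0", P1 = "P0",
    ABa = "AB", ABp = "AB",
    ABar = "ABa", ABara = "ABar", ABaraa = "ABara",
    ABpl = "ABp", ABplp = "ABpl", ABplpa = "ABplp",
    EMS = "P1", P2 = "P1",
    MS = "EMS", E = "EMS",
    MSpppapp = "MS", MSappaap = "MS",
    C = "P2", P3 = "P2",
    D = "P3", P4 = "P3"
  ))
}

#' Define a scored tissue
#'
#' @param name Tissue name.
#' @param contributions Named numeric vector of lineage contributions
#'   (relative cell counts), e.g. `c(ABa = 4, MS = 2)` for the procorpus.
#' @param soft Logical; `TRUE` for tissues scored only approximately (the
#'   "mostly ABp" neuronal rows), whose mismatch penalties are halved.
#' @return An object of class `tissue_def`.
#' @export
tissue_def <- function(name, contributions, soft = FALSE) {
  if (length(contributions) < 1L || is.null(names(contributions))) {
    stop("contributions must be a named vector with at least one entry")
  }
  if (any(contributions <= 0)) stop("contribution weights must be positive")
  structure(list(name = name, contributions = contributions, soft = soft),
            class = "tissue_def")
}

#' The default scored-tissue map
#'
#' The 19 tissues of the packaged mosaic scoring table with their lineage
#' contributions. Multi-lineage pharyngeal tissues carry the recorded relative
#' cell counts (procorpus 4 ABa / 2 MS, metacorpus 5 MS / 1 ABar, isthmus
#' 4 MS / 2 ABaraa). The two neuronal rows annotated only as "mostly ABp" use
#' a declared 3:1 ABp:ABa convention and are flagged as soft evidence.
#'
#' @return Named list of [tissue_def()] objects.
#' @export
default_tissue_map <- function() {
  defs <- list(
    tissue_def("Intestine", c(E = 1)),
    tissue_def("Spermatheca A", c(MSpppapp = 1)),
    tissue_def("Spermatheca P", c(MSappaap = 1)),
    tissue_def("Gonad sheath A", c(MSpppapp = 1)),
    tissue_def("Gonad sheath P", c(MSappaap = 1)),
    tissue_def("Lateral hypodermis", c(ABa = 1, ABp = 1, C = 1)),
    tissue_def("Ventral hypodermal ridge", c(ABp = 1)),
    tissue_def("Excretory canal", c(ABplpa = 1)),
    tissue_def("Procorpus", c(ABa = 4, MS = 2)),
    tissue_def("Metacorpus", c(MS = 5, ABar = 1)),
    tissue_def("Isthmus", c(MS = 4, ABaraa = 2)),
    tissue_def("Posterior bulb", c(MS = 1)),
    tissue_def("Hyp 10", c(AB = 1)),
    tissue_def("Body wall muscles Head", c(MS = 1)),
    tissue_def("Body wall muscles Mid", c(D = 1)),
    tissue_def("Body wall muscles Posterior", c(C = 1)),
    tissue_def("VC2-6 neurons", c(ABp = 1)),
    tissue_def("Head ganglion neurons", c(ABp = 3, ABa = 1), soft = TRUE),
    tissue_def("Ventral nerve cord neurons", c(ABp = 3, ABa = 1), soft = TRUE)
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

check_antichain <- function(loss_events, tree) {
  loss_events <- unique(as.character(loss_events))
  if (!all(loss_events %in% tree$nodes)) {
    stop("unknown loss node(s): ",
         paste(setdiff(loss_events, tree$nodes), collapse = ", "))
  }
  if (length(loss_events) > 1L) {
    sub <- tree$anc[loss_events, loss_events, drop = FALSE]
    diag(sub) <- FALSE
    if (any(sub)) stop("loss events must form an antichain (no node may be an ancestor of another)")
  }
  loss_events
}

#' Fraction of a tissue positive for the array
#'
#' Given a set of loss events (an antichain of tree nodes), the positive
#' fraction of a tissue is the weight of its lineage contributions that do
#' not descend from any loss event, divided by the total weight.
#'
#' @param tissue A [tissue_def()].
#' @param loss_events Character vector of node names (antichain).
#' @param tree A [lineage_tree()].
#' @return Fraction in \[0, 1\].
#' @export
positive_fraction <- function(tissue, loss_events, tree = default_tree()) {
  stopifnot(inherits(tissue, "tissue_def"))
  loss_events <- check_antichain(loss_events, tree)
  w <- tissue$contributions
  if (length(loss_events) == 0L) return(1)
  covered <- colSums(tree$anc[loss_events, names(w), drop = FALSE]) > 0
  sum(w[!covered]) / sum(w)
}

rank_to_call <- function(rank) mosaic_calls()[rank + 1L]

fraction_to_rank <- function(frac) {
  ifelse(frac >= 1, 3L, ifelse(frac <= 0, 0L, ifelse(frac >= 0.5, 2L, 1L)))
}

#' Predict tissue calls under a loss hypothesis
#'
#' A tissue with positive fraction 1 is scored `+`, 0 is `-`, at least half
#' `+/-` (majority positive), and below half `-/+` (minority positive).
#'
#' @param loss_events Antichain of node names.
#' @param tissue_map Named list of [tissue_def()]s.
#' @param tree A [lineage_tree()].
#' @return Named character vector of predicted calls per tissue.
#' @export
predict_calls <- function(loss_events, tissue_map = default_tissue_map(),
                          tree = default_tree()) {
  fr <- vapply(tissue_map, positive_fraction, 0, loss_events = loss_events,
               tree = tree)
  stats::setNames(rank_to_call(fraction_to_rank(fr)), names(tissue_map))
}

#' Enumerate antichains of a lineage tree
#'
#' All duplicate-free sets of at most `max_events` nodes in which no node is
#' an ancestor of another. For the default 21-node tree at `max_events = 4`
#' this is a complete, exhaustively feasible enumeration.
#'
#' @param tree A [lineage_tree()].
#' @param max_events Maximum antichain size (>= 0).
#' @param nodes Candidate node set; defaults to all tree nodes.
#' @return List of character vectors (including the empty antichain).
#' @export
enumerate_antichains <- function(tree, max_events, nodes = tree$nodes) {
  stopifnot(max_events >= 0)
  nodes <- unique(nodes)
  stopifnot(all(nodes %in% tree$nodes))
  anc <- tree$anc[nodes, nodes, drop = FALSE]
  diag(anc) <- FALSE
  comparable <- anc | t(anc)
  out <- list(character(0))
  if (max_events == 0 || length(nodes) == 0) return(out)
  for (k in seq_len(min(max_events, length(nodes)))) {
    sets <- utils::combn(nodes, k, simplify = FALSE)
    keep <- vapply(sets, function(s) {
      k == 1L || !any(comparable[s, s])
    }, TRUE)
    out <- c(out, sets[keep])
  }
  out
}

candidate_nodes <- function(tree, tissue_map) {
  contrib <- unique(unlist(lapply(tissue_map, function(td) names(td$contributions))))
  covers <- rowSums(tree$anc[, contrib, drop = FALSE]) > 0
  tree$nodes[covers]
}

#' Infer array-loss events from one worm's tissue calls
#'
#' Exhaustive Dollo-parsimony search: every antichain of candidate loss nodes
#' of size at most `max_events` is scored as
#' \deqn{cost(H) = \alpha |H| + \sum_{tissues} w_t \cdot p \cdot
#'   |rank(predicted) - rank(observed)|}
#' where ranks order the call alphabet `-` < `-/+` < `+/-` < `+`, `p` is the
#' per-grade penalty, and `w_t = 0.5` for soft tissues, 1 otherwise. By
#' default candidate nodes are restricted to those affecting at least one
#' scored tissue (losses elsewhere are unidentifiable). All hypotheses are
#' returned ranked by cost; cost ties at the minimum are reported together.
#'
#' @param obs Named character vector: tissue name -> observed call.
#' @param tree A [lineage_tree()].
#' @param tissue_map Named list of [tissue_def()]s.
#' @param alpha Cost per loss event (default 1).
#' @param penalty_per_grade Penalty per ordinal grade of mismatch (default 0.5).
#' @param max_events Enumeration bound (default 4).
#' @param candidates Candidate loss nodes; default as described above.
#' @return Object of class `mosaic_inference`: `hypotheses` (data frame with
#'   `events`, `n_events`, `penalty`, `cost`, sorted by cost), `loss_sets`
#'   (list of node sets in the same order), `best` (indices of minimal-cost
#'   ties), `top_events`, `predicted` and `mismatches` for the top hypothesis.
#' @export
infer_losses <- function(obs, tree = default_tree(),
                         tissue_map = default_tissue_map(),
                         alpha = 1.0, penalty_per_grade = 0.5, max_events = 4,
                         candidates = NULL) {
  obs <- obs[!is.na(obs)]
  if (length(obs) == 0L) stop("empty observation")
  unknown <- setdiff(names(obs), names(tissue_map))
  if (length(unknown) > 0) {
    stop("observation uses unknown tissue(s): ", paste(unknown, collapse = ", "))
  }
  tmap <- tissue_map[names(obs)]
  obs_rank <- call_rank(obs)
  if (is.null(candidates)) candidates <- candidate_nodes(tree, tmap)
  sets <- enumerate_antichains(tree, max_events, nodes = candidates)
  # per-node lost weight per tissue (antichain nodes cover disjoint subtrees)
  totw <- vapply(tmap, function(td) sum(td$contributions), 0)
  lostw <- matrix(0, nrow = length(candidates), ncol = length(tmap),
                  dimnames = list(candidates, names(tmap)))
  for (v in candidates) {
    lostw[v, ] <- vapply(tmap, function(td) {
      covered <- tree$anc[v, names(td$contributions)]
      sum(td$contributions[covered])
    }, 0)
  }
  soft_mult <- ifelse(vapply(tmap, `[[`, TRUE, "soft"), 0.5, 1)
  score_set <- function(s) {
    lost <- if (length(s) == 0L) rep(0, length(tmap))
            else colSums(lostw[s, , drop = FALSE])
    frac <- 1 - lost / totw
    pred <- fraction_to_rank(frac)
    sum(soft_mult * penalty_per_grade * abs(pred - obs_rank))
  }
  penalty <- vapply(sets, score_set, 0)
  n_events <- lengths(sets)
  cost <- alpha * n_events + penalty
  ord <- order(cost, n_events)
  sets <- sets[ord]
  hypotheses <- data.frame(
    events = vapply(sets, function(s) paste(sort(s), collapse = "+"), ""),
    n_events = n_events[ord],
    penalty = penalty[ord],
    cost = cost[ord],
    stringsAsFactors = FALSE
  )
  best <- which(hypotheses$cost <= hypotheses$cost[1] + 1e-12)
  top <- sets[[1]]
  predicted <- predict_calls(top, tmap, tree)
  mism <- names(obs)[predicted != obs]
  structure(
    list(hypotheses = hypotheses, loss_sets = sets, best = best,
         top_events = top, predicted = predicted,
         observed = obs, mismatches = mism,
         alpha = alpha, penalty_per_grade = penalty_per_grade,
         max_events = max_events, candidates = candidates),
    class = "mosaic_inference"
  )
}

#' @export
print.mosaic_inference <- function(x, ...) {
  cat(sprintf("Dollo loss inference: %d hypotheses scored (max %d events)\n",
              nrow(x$hypotheses), x$max_events))
  ties <- x$hypotheses[x$best, , drop = FALSE]
  cat("minimal-cost hypothesis(es):\n")
  for (i in seq_len(nrow(ties))) {
    ev <- ties$events[i]
    cat(sprintf("  {%s}  cost %.2f (penalty %.2f)\n",
                if (nzchar(ev)) ev else "none", ties$cost[i], ties$penalty[i]))
  }
  if (length(x$mismatches)) {
    cat("tissues inconsistent with the top hypothesis: ",
        paste(x$mismatches, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize loss events in founder vocabulary
#'
#' Maps loss nodes onto the founder-cell vocabulary used in mosaic scoring
#' summaries ({ABa, ABp, MS, E, C, D} plus the early P-lineage cells). A node
#' lying strictly below a founder reports that founder with a `(partial)`
#' qualifier (e.g. a loss at MSpppapp reports `MS (partial)`).
#'
#' @param loss_events Character vector of node names.
#' @param tree A [lineage_tree()].
#' @return Character vector of founder labels.
#' @export
founder_summary <- function(loss_events, tree = default_tree()) {
  founders <- c("ABa", "ABp", "MS", "E", "C", "D")
  loss_events <- check_antichain(loss_events, tree)
  vapply(loss_events, function(nd) {
    if (nd %in% founders) return(nd)
    below <- founders[tree$anc[founders, nd] & founders != nd]
    if (length(below) > 0) paste0(below[1], " (partial)") else nd
  }, "")
}

parse_founder_call <- function(s) {
  s <- gsub("\\?", "", s)
  parts <- trimws(strsplit(s, ",")[[1]])
  parts <- parts[nzchar(parts)]
  vapply(parts, function(p) {
    if (grepl("^most ", p)) paste0(sub("^most ", "", p), " (partial)") else p
  }, "", USE.NAMES = FALSE)
}

#' Compare inferred loss events with recorded per-worm summaries
#'
#' Runs [infer_losses()] on every worm of a scoring table and compares the
#' founder summary of each cost-minimal hypothesis with the table's recorded
#' "Likely missing from" call. Worms whose recorded call is flagged uncertain
#' are reported but excluded from the aggregate concordance count.
#'
#' @param table A `mosaic_table` with summary rows (see
#'   [load_mosaic_fixture()]).
#' @param ... Passed to [infer_losses()].
#' @return Object of class `mosaic_concordance`: per-worm data frame `worms`
#'   (recorded call, top inferred founders, cost, concordance, mismatching
#'   tissues) and counts `n_concordant` / `n_evaluated` over non-uncertain
#'   worms.
#' @export
concordance_report <- function(table, ...) {
  stopifnot(inherits(table, "mosaic_table"))
  if (is.null(table$likely_missing)) stop("table has no 'Likely missing from' row")
  rows <- lapply(seq_along(table$worm_ids), function(j) {
    obs <- table$calls[, j]
    inf <- infer_losses(obs, ...)
    recorded <- sort(parse_founder_call(table$likely_missing[j]))
    tie_summaries <- lapply(inf$best, function(i) {
      sort(unname(founder_summary(inf$loss_sets[[i]])))
    })
    concordant <- any(vapply(tie_summaries, identical, TRUE, y = recorded))
    data.frame(
      worm_id = table$worm_ids[j],
      recorded = paste(recorded, collapse = ", "),
      inferred = paste(sort(unname(founder_summary(inf$top_events))),
                       collapse = ", "),
      cost = inf$hypotheses$cost[1],
      n_ties = length(inf$best),
      concordant = concordant,
      uncertain = table$uncertain[j],
      mismatches = paste(inf$mismatches, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  worms <- do.call(rbind, rows)
  eval_idx <- !worms$uncertain
  structure(
    list(worms = worms,
         n_concordant = sum(worms$concordant[eval_idx]),
         n_evaluated = sum(eval_idx)),
    class = "mosaic_concordance"
  )
}

#' @export
print.mosaic_concordance <- function(x, ...) {
  cat(sprintf("mosaic concordance: %d/%d worms (uncertain worms excluded)\n",
              x$n_concordant, x$n_evaluated))
  print(x$worms[, c("worm_id", "recorded", "inferred", "cost", "concordant",
                    "uncertain")], row.names = FALSE)
  invisible(x)
}
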