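# Ancestral-state reconstruction of mating systems on a rooted species tree
# by parsimony: Fitch candidate sets with policy-based top-down resolution
# under uniform costs, Sankoff dynamic programming with a cost matrix,
# exhaustive enumeration of most-parsimonious reconstructions (MPRs), and
# transition counting.

STATE_PRIORITY <- c("HET", "PHC", "PHN", "FF1", "FF2", "3LOC", "NOMAT")

#' Parse a rooted tree from Newick text
#'
#' Branch lengths are parsed but ignored by all downstream parsimony
#' operations; quoted labels are supported. The tree is used rooted exactly
#' as supplied.
#'
#' @param text Newick string (terminating semicolon required).
#' @return an `ape` `phylo` object.
#' @export
parse_newick <- function(text) {
  if (!grepl(";", text, fixed = TRUE)) stop("Newick must end with ';'")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick: ", substr(text, 1, 60))
  if (ape::Ntip(tree) < 2L) stop("tree needs at least 2 tips")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip names")
  tree
}

check_states <- function(tree, states, missing = c("strict", "uninformative")) {
  missing <- match.arg(missing)
  bad <- setdiff(unique(unname(states)), MAT_SYSTEMS)
  if (length(bad)) stop("unknown state symbol(s): ", paste(bad, collapse = ", "))
  absent <- setdiff(tree$tip.label, names(states))
  if (length(absent) && missing == "strict")
    stop("tips without states: ", paste(absent, collapse = ", "))
  states
}

uniform_cost <- function() {
  S <- length(MAT_SYSTEMS)
  m <- matrix(1, S, S, dimnames = list(MAT_SYSTEMS, MAT_SYSTEMS))
  diag(m) <- 0
  m
}

# Bottom-up Sankoff pass. Returns the (n_nodes x n_states) cost matrix.
sankoff_up <- function(tree, states, cost, missing = "strict") {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  S <- length(MAT_SYSTEMS)
  C <- matrix(0, n_all, S, dimnames = list(NULL, MAT_SYSTEMS))
  for (i in seq_len(n_tip)) {
    st <- states[tree$tip.label[i]]
    if (is.na(st)) next                       # uninformative tip: all zero
    C[i, ] <- ifelse(MAT_SYSTEMS == st, 0, Inf)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    contrib <- vapply(seq_len(S), function(s)
      min(C[ch, ] + cost[s, ]), 0)
    C[p, ] <- C[p, ] + contrib
  }
  C
}

root_node <- function(tree) ape::Ntip(tree) + 1L

#' Reconstruct ancestral mating systems by parsimony
#'
#' Bottom-up pass: Fitch state sets under uniform costs (equivalently, the
#' states minimizing the Sankoff subtree cost), or Sankoff dynamic
#' programming when a cost matrix is given. Top-down pass: each node takes
#' its parent's resolved state when that attains the conditional minimum,
#' otherwise the tie-break policy decides.
#'
#' Policies:
#' * `"default"` — parent-state preference, remaining ties broken by the
#'   fixed priority HET > PHC > PHN > FF1 > FF2 > 3LOC > NOMAT, which
#'   encodes the expectation that derived homothallic systems arise from
#'   heterothallic ancestors while staying within the set of
#'   most-parsimonious reconstructions.
#' * `"prefer_gains"` — enumerate all MPRs ([enumerate_mprs()]) and select
#'   the one maximizing gain events (HET to non-HET), breaking remaining
#'   ties by fewest loss events, then lexicographic node order. The choice
#'   is recorded in the returned object, never silent.
#'
#' @param tree rooted `phylo`.
#' @param states named character vector, species -> category.
#' @param policy `"default"` or `"prefer_gains"`.
#' @param costs optional state-by-state cost matrix (rows/cols in
#'   `MAT_SYSTEMS` order); `NULL` means uniform unit costs.
#' @param missing `"strict"` (error on unmapped tips) or `"uninformative"`.
#' @param mpr_max_tips passed to [enumerate_mprs()] for `prefer_gains`.
#' @return a `mat_reconstruction`: list with `tree`, `candidates` (per-node
#'   state sets before resolution), `resolved` (per-node states, tips
#'   first), `min_changes`, `policy`.
#' @export
reconstruct_states <- function(tree, states, policy = c("default", "prefer_gains"),
                               costs = NULL, missing = c("strict", "uninformative"),
                               mpr_max_tips = 16L) {
  policy <- match.arg(policy)
  missing <- match.arg(missing)
  states <- check_states(tree, states, missing)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  cost <- costs %||% uniform_cost()
  stopifnot(identical(dim(cost), c(7L, 7L)))
  C <- sankoff_up(tree, states, cost, missing)
  root <- root_node(tree)
  min_changes <- min(C[root, ])
  candidates <- lapply(seq_len(n_all), function(i)
    MAT_SYSTEMS[C[i, ] == min(C[i, ])])
  resolved <- character(n_all)
  if (policy == "prefer_gains") {
    mprs <- enumerate_mprs(tree, states, costs = costs,
                           mpr_max_tips = mpr_max_tips, missing = missing)
    resolved <- select_prefer_gains(tree, mprs)
  } else {
    pick <- function(set) STATE_PRIORITY[STATE_PRIORITY %in% set][1]
    resolved[root] <- pick(candidates[[root]])
    pre <- ape::reorder.phylo(tree, "postorder")
    edges <- pre$edge[rev(seq_len(nrow(pre$edge))), , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; ch <- edges[e, 2]
      ps <- resolved[p]
      if (is.null(costs)) {
        set <- candidates[[ch]]
        resolved[ch] <- if (ps %in% set) ps else pick(set)
      } else {
        cond <- C[ch, ] + cost[ps, ]
        set <- MAT_SYSTEMS[cond == min(cond)]
        resolved[ch] <- if (ps %in% set) ps else pick(set)
      }
    }
  }
  names(resolved) <- c(tree$tip.label, rep("", tree$Nnode))
  structure(list(tree = tree, candidates = candidates, resolved = resolved,
                 min_changes = min_changes, policy = policy,
                 states = states),
            class = "mat_reconstruction")
}

select_prefer_gains <- function(tree, mprs) {
  score <- vapply(mprs$labelings, function(lab) {
    ev <- edge_events(tree, lab)
    gains <- sum(ev$from == "HET" & ev$to != "HET")
    losses <- sum(ev$from != "HET" & ev$to == "HET")
    gains * 1000 - losses
  }, 0)
  best <- which(score == max(score))
  if (length(best) > 1L) {
    keys <- vapply(mprs$labelings[best], paste, "", collapse = "|")
    best <- best[order(keys)][1]
  } else best <- best[1]
  mprs$labelings[[best]]
}

edge_events <- function(tree, resolved) {
  e <- tree$edge
  data.frame(parent = e[, 1], child = e[, 2],
             from = unname(resolved[e[, 1]]), to = unname(resolved[e[, 2]]))
}

#' Number of state changes implied by a resolved reconstruction
#' @param rec a `mat_reconstruction`.
#' @export
implied_changes <- function(rec) {
  ev <- edge_events(rec$tree, rec$resolved)
  sum(ev$from != ev$to)
}

#' Enumerate all most-parsimonious reconstructions
#'
#' Exhaustive enumeration of every ancestral labeling attaining the
#' parsimony minimum, by backtracking over the Sankoff dynamic program.
#' Intended for the desk-scale questions where competing equally
#' parsimonious hypotheses must be listed explicitly (e.g. several
#' independent gains of a switching system versus one ancestral gain plus
#' losses).
#'
#' @inheritParams reconstruct_states
#' @param mpr_max_tips guard on tree size; above this the enumeration
#'   errors and directs to policy-based resolution.
#' @param max_mprs hard cap on the number of labelings returned.
#' @return a `mat_mpr_set`: list with `tree`, `labelings` (each a character
#'   vector over all nodes), `min_changes`.
#' @export
enumerate_mprs <- function(tree, states, costs = NULL, mpr_max_tips = 16L,
                           max_mprs = 50000L,
                           missing = c("strict", "uninformative")) {
  missing <- match.arg(missing)
  if (ape::Ntip(tree) > mpr_max_tips)
    stop("tree has ", ape::Ntip(tree), " tips > mpr_max_tips = ",
         mpr_max_tips, "; use policy-based resolution (reconstruct_states) ",
         "or raise mpr_max_tips")
  states <- check_states(tree, states, missing)
  cost <- costs %||% uniform_cost()
  C <- sankoff_up(tree, states, cost, missing)
  root <- root_node(tree)
  n_tip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  enum_node <- function(node, s) {
    # all subtree labelings with `node` assigned state `s`
    if (node <= n_tip) {
      lab <- stats::setNames(s, NULL)
      out <- list(stats::setNames(lab, node))
      return(out)
    }
    per_child <- lapply(kids[[as.character(node)]], function(ch) {
      cond <- C[ch, ] + cost[s, ]
      allowed <- MAT_SYSTEMS[cond == min(cond)]
      unlist(lapply(allowed, function(t) enum_node(ch, t)),
             recursive = FALSE)
    })
    combos <- Reduce(function(acc, nxt) {
      out <- list()
      for (a in acc) for (b in nxt) {
        out[[length(out) + 1L]] <- c(a, b)
        if (length(out) + counter$n > max_mprs)
          stop("more than ", max_mprs, " MPRs; aborting enumeration")
      }
      out
    }, per_child, accumulate = FALSE)
    lapply(combos, function(x) c(x, stats::setNames(s, node)))
  }
  root_states <- MAT_SYSTEMS[C[root, ] == min(C[root, ])]
  labs <- unlist(lapply(root_states, function(s) enum_node(root, s)),
                 recursive = FALSE)
  n_all <- n_tip + tree$Nnode
  labelings <- lapply(labs, function(x) {
    v <- character(n_all)
    v[as.integer(names(x))] <- unname(x)
    names(v) <- c(tree$tip.label, rep("", tree$Nnode))
    v
  })
  structure(list(tree = tree, labelings = labelings,
                 min_changes = min(C[root, ])),
            class = "mat_mpr_set")
}

#' Count evolutionary transitions implied by a reconstruction
#'
#' One event per branch whose endpoint states differ. Aggregates: counts by
#' (from, to) pair, transitions from heterothallism into any homothallic
#' system and the reverse, and independent origins of mating-type switching
#' (events entering \{FF1, FF2, 3LOC\} from outside that set).
#'
#' @param rec a `mat_reconstruction`, or a labeling vector with a `tree`
#'   attribute.
#' @param tree tree to use when `rec` is a bare labeling vector.
#' @return a `transition_summary` list: `events`, `counts`,
#'   `to_homothallism`, `to_heterothallism`, `switching_origins`.
#' @export
count_transitions <- function(rec, tree = NULL) {
  if (inherits(rec, "mat_reconstruction")) {
    tree <- rec$tree; resolved <- rec$resolved
  } else {
    stopifnot(!is.null(tree)); resolved <- rec
  }
  ev <- edge_events(tree, resolved)
  ev <- ev[ev$from != ev$to, , drop = FALSE]
  n_tip <- ape::Ntip(tree)
  ev$child_label <- ifelse(ev$child <= n_tip, tree$tip.label[ev$child], "")
  counts <- if (nrow(ev)) {
    ag <- stats::aggregate(list(n = rep(1L, nrow(ev))),
                           by = list(from = ev$from, to = ev$to), FUN = sum)
    ag[order(ag$from, ag$to), , drop = FALSE]
  } else data.frame(from = character(), to = character(), n = integer())
  rownames(counts) <- NULL
  structure(list(
    events = ev,
    counts = counts,
    to_homothallism = sum(ev$from == "HET" & ev$to %in% HOMOTHALLIC_SYSTEMS),
    to_heterothallism = sum(ev$from %in% HOMOTHALLIC_SYSTEMS & ev$to == "HET"),
    switching_origins = sum(!(ev$from %in% SWITCHING_SYSTEMS) &
                              ev$to %in% SWITCHING_SYSTEMS)),
    class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("<transition_summary> ", nrow(x$events), " event(s); ",
      "to homothallism: ", x$to_homothallism,
      ", to heterothallism: ", x$to_heterothallism,
      ", switching origins: ", x$switching_origins, "\n", sep = "")
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}

#' Independent origins of mating-type switching in a summary
#'
#' Events whose parent state is outside \{FF1, FF2, 3LOC\} and whose child
#' state is inside it.
#'
#' @param summary a `transition_summary`.
#' @return integer count.
#' @export
count_switching_origins <- function(summary) {
  summary$switching_origins
}

#' Tree with resolved internal states as node labels
#' @param rec a `mat_reconstruction`.
#' @return `phylo` with `node.label` set.
#' @export
state_labelled_tree <- function(rec) {
  tr <- rec$tree
  n_tip <- ape::Ntip(tr)
  tr$node.label <- unname(rec$resolved[(n_tip + 1L):length(rec$resolved)])
  tr
}

#' Size of the largest uniform-state clade containing a tip
#'
#' Walks rootward from `tip` while the clade remains monophyletic for
#' `state`, and returns the number of tips of the largest such clade (used
#' e.g. to measure the extent of one switching clade around a reference
#' species).
#'
#' @param tree `phylo`.
#' @param states named character vector of tip states.
#' @param tip tip label.
#' @param state state the clade must be uniform for.
#' @return integer tip count (0 if the tip itself is not in `state`).
#' @export
largest_state_clade <- function(tree, states, tip, state) {
  stopifnot(tip %in% tree$tip.label)
  if (states[[tip]] != state) return(0L)
  node <- which(tree$tip.label == tip)
  best <- 1L
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (!length(parent)) break
    tips <- tip_labels_of_clade(tree, parent)
    if (!all(states[tips] == state)) break
    best <- length(tips)
    node <- parent
  }
  best
}

tip_labels_of_clade <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(tree$tip.label[node])
  todo <- node; tips <- integer()
  while (length(todo)) {
    nd <- todo[1]; todo <- todo[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- c(tips, ch[ch <= n_tip])
    todo <- c(todo, ch[ch > n_tip])
  }
  tree$tip.label[tips]
}
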