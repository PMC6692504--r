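test_that("Newick parsing preserves topology and rejects malformed input", {
  tr <- parse_newick("((A,B),C);")
  expect_equal(ape::Ntip(tr), 3L)
  root <- ape::Ntip(tr) + 1L
  expect_length(tr$edge[tr$edge[, 1] == root, 2], 2L)
  tr2 <- parse_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(ape::Ntip(tr2), 3L)
  expect_error(parse_newick("((A,B,C);"), "malformed|Newick")
  expect_error(parse_newick("((A,B),C)"), ";")
  expect_error(parse_newick("((A,A),C);"), "duplicate")
})

test_that("uniform tip states reconstruct with zero changes", {
  tr <- parse_newick("((A,B),(C,(D,E)));")
  st <- stats::setNames(rep("HET", 5), LETTERS[1:5])
  rec <- reconstruct_states(tr, st)
  expect_true(all(rec$resolved == "HET"))
  expect_equal(rec$min_changes, 0)
  expect_equal(nrow(count_transitions(rec)$events), 0L)
  mprs <- enumerate_mprs(tr, st)
  expect_length(mprs$labelings, 1L)
})

test_that("parsimony minimum matches exhaustive enumeration on random trees", {
  for (i in 1:50) {
    inst <- random_instance(n_tips = sample(4:7, 1), n_states = sample(2:4, 1),
                            seed = 1000 + i)
    rec <- reconstruct_states(inst$tree, inst$states)
    oracle <- brute_force_min_changes(inst$tree, inst$states)
    expect_equal(rec$min_changes, oracle, label = paste("instance", i))
    # the resolved labeling itself attains the minimum (policy containment)
    expect_equal(implied_changes(rec), oracle, label = paste("resolved", i))
    # resolved state is always within the candidate set
    for (nd in seq_along(rec$candidates)) {
      expect_true(rec$resolved[nd] %in% rec$candidates[[nd]])
    }
  }
})

test_that("parsimony minimum agrees with an independent phangorn run", {
  skip_if_not_installed("phangorn")
  for (i in 1:10) {
    inst <- random_instance(n_tips = 7, n_states = 3, seed = 2000 + i)
    dat <- phangorn::phyDat(matrix(inst$states[inst$tree$tip.label],
                                   ncol = 1,
                                   dimnames = list(inst$tree$tip.label, NULL)),
                            type = "USER", levels = MAT_SYSTEMS)
    expect_equal(reconstruct_states(inst$tree, inst$states)$min_changes,
                 phangorn::parsimony(inst$tree, dat, method = "fitch"))
  }
})

test_that("every enumerated MPR attains the minimum; prefer_gains dominates", {
  for (i in 1:12) {
    inst <- random_instance(n_tips = 6, n_states = 3, seed = 3000 + i)
    mprs <- enumerate_mprs(inst$tree, inst$states)
    counts <- vapply(mprs$labelings, function(lab) {
      ev <- matsys:::edge_events(inst$tree, lab)
      sum(ev$from != ev$to)
    }, 0)
    expect_true(all(counts == mprs$min_changes))
    gains <- vapply(mprs$labelings, function(lab) {
      ev <- matsys:::edge_events(inst$tree, lab)
      sum(ev$from == "HET" & ev$to != "HET")
    }, 0)
    rec <- reconstruct_states(inst$tree, inst$states, policy = "prefer_gains")
    ev <- matsys:::edge_events(inst$tree, rec$resolved)
    expect_equal(sum(ev$from == "HET" & ev$to != "HET"), max(gains))
    expect_equal(implied_changes(rec), mprs$min_changes)
  }
})

test_that("reconstruction is invariant to tip ordering", {
  st <- c(A = "HET", B = "PHC", C = "PHC", D = "FF1", E = "HET")
  t1 <- parse_newick("((A,B),(C,(D,E)));")
  t2 <- parse_newick("(((E,D),C),(B,A));")
  s1 <- count_transitions(reconstruct_states(t1, st))
  s2 <- count_transitions(reconstruct_states(t2, st))
  expect_equal(s1$counts, s2$counts)
  expect_equal(s1$switching_origins, s2$switching_origins)
})

test_that("transition counting aggregates events and origins correctly", {
  # two switching clades each nested among heterothallic tips, so both
  # gains are unambiguous
  tr <- parse_newick("((A,(C,D)),(B,(E,F)));")
  st <- c(A = "HET", B = "HET", C = "FF1", D = "FF1", E = "3LOC",
          F = "3LOC")
  s <- count_transitions(reconstruct_states(tr, st))
  expect_equal(s$to_homothallism, 2L)
  expect_equal(s$to_heterothallism, 0L)
  expect_equal(count_switching_origins(s), 2L)
  expect_equal(sum(s$counts$n), nrow(s$events))

  # reversal counting
  tr2 <- parse_newick("((A,B),((C,D),(E,F)));")
  st2 <- c(A = "PHC", B = "PHC", C = "PHC", D = "HET", E = "PHC",
           F = "PHC")
  s2 <- count_transitions(reconstruct_states(tr2, st2))
  expect_equal(s2$to_heterothallism, 1L)
  expect_equal(count_switching_origins(s2), 0L)
})

test_that("strict missing-tip policy errors; uninformative policy proceeds", {
  tr <- parse_newick("((A,B),C);")
  st <- c(A = "HET", B = "PHC")
  expect_error(reconstruct_states(tr, st), "without states")
  rec <- reconstruct_states(tr, st, missing = "uninformative")
  expect_equal(implied_changes(rec), rec$min_changes)
  expect_error(reconstruct_states(tr, c(A = "HET", B = "XX", C = "HET")),
               "unknown state")
})

test_that("enumerate_mprs enforces its tree-size guard", {
  tr <- ape::rtree(20)
  st <- stats::setNames(rep("HET", 20), tr$tip.label)
  expect_error(enumerate_mprs(tr, st), "mpr_max_tips")
  expect_length(enumerate_mprs(tr, st, mpr_max_tips = 32)$labelings, 1L)
})

test_that("simulated histories propagate and are recovered exactly", {
  tr <- parse_newick("((A,(B,C)),((D,E),(F,(G,H))));")
  # zero events: all tips carry the root state
  h0 <- simulate_history(tr, "HET", events = data.frame(child = character(),
                                                        to = character()))
  expect_true(all(h0$tip_states == "HET"))

  # two planted gains on disjoint subtrees
  bc <- ape::getMRCA(tr, c("B", "C"))
  de <- ape::getMRCA(tr, c("D", "E"))
  h <- simulate_history(tr, "HET",
                        events = data.frame(child = c(bc, de),
                                            to = c("PHN", "PHN")))
  expect_equal(unname(h$tip_states[c("B", "C", "D", "E")]), rep("PHN", 4))
  expect_equal(unname(h$tip_states[c("A", "F", "G", "H")]), rep("HET", 4))
  rec <- reconstruct_states(tr, h$tip_states)
  s <- count_transitions(rec)
  expect_equal(s$counts$n[s$counts$from == "HET" & s$counts$to == "PHN"], 2L)

  # events on nonexistent branches are rejected
  expect_error(simulate_history(tr, "HET",
                                events = data.frame(child = "nope",
                                                    to = "PHN")),
               "nonexistent")
  # parsimony-inconsistent plants are rejected when consistency is
  # required: two sister-tip gains are one ancestral gain to parsimony
  expect_error(simulate_history(tr, "HET",
                                events = data.frame(
                                  child = c("B", "C"),
                                  to = c("PHN", "PHN"))),
               "consistent")
})

test_that("random consistent histories match their transition counts", {
  tr <- ape::rtree(12)
  for (seed in 1:8) {
    h <- simulate_history(tr, "HET", p_change = 0.12, seed = seed)
    rec <- reconstruct_states(tr, h$tip_states)
    expect_equal(implied_changes(rec), nrow(h$events))
  }
})

test_that("largest uniform-state clade is measured correctly", {
  tr <- parse_newick("((A,(B,C)),(D,(E,F)));")
  st <- c(A = "HET", B = "FF1", C = "FF1", D = "FF1", E = "FF1", F = "HET")
  expect_equal(largest_state_clade(tr, st, "B", "FF1"), 2L)
  expect_equal(largest_state_clade(tr, st, "D", "FF1"), 1L)
  expect_equal(largest_state_clade(tr, st, "A", "FF1"), 0L)
})

test_that("a cost matrix steers Sankoff reconstruction away from priority", {
  tr <- parse_newick("((A,B),C);")
  st <- c(A = "FF1", B = "FF1", C = "HET")
  # uniform costs: tie at the root resolves to HET by the fixed priority
  expect_equal(unname(reconstruct_states(tr, st)$resolved[4]), "HET")
  # make gaining FF1 five times costlier than losing it: the root must be
  # FF1 (one cheap loss on the C branch) despite HET priority
  cost <- matrix(1, 7, 7, dimnames = list(MAT_SYSTEMS, MAT_SYSTEMS))
  diag(cost) <- 0
  cost["HET", "FF1"] <- 5
  rec <- reconstruct_states(tr, st, costs = cost)
  expect_equal(unname(rec$resolved[4]), "FF1")
  expect_equal(rec$min_changes, 1)
  # a uniform matrix passed explicitly matches the implicit one
  u <- matrix(1, 7, 7, dimnames = list(MAT_SYSTEMS, MAT_SYSTEMS)); diag(u) <- 0
  inst <- random_instance(6, 3, seed = 909)
  expect_equal(reconstruct_states(inst$tree, inst$states, costs = u)$min_changes,
               reconstruct_states(inst$tree, inst$states)$min_changes)
})
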