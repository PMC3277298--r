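toy_matrix_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("read_character_matrix parses TSV, infers alphabets, rejects dups", {
  f <- toy_matrix_file(c("taxon\tc1\tc2",
                         "A\t0\tx",
                         "B\t1\t?",
                         "C\t0\ty"))
  cm <- read_character_matrix(f)
  expect_equal(cm$taxa, c("A", "B", "C"))
  expect_equal(cm$characters, c("c1", "c2"))
  expect_equal(cm$alphabets$c1, c("0", "1"))
  expect_equal(cm$alphabets$c2, c("x", "y"))   # '?' excluded
  f2 <- toy_matrix_file(c("taxon\tc1", "A\t0", "A\t1"))
  expect_error(read_character_matrix(f2), "duplicate")
})

test_that("fitch_length matches hand cases and tolerates missing tips", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_length(tr, c(A = "1", B = "0", C = "1", D = "0")), 2L)
  expect_equal(fitch_length(tr, c(A = "1", B = "1", C = "1", D = "1")), 0L)
  expect_equal(fitch_length(tr, c(A = "1", B = "?", C = "0", D = "0")), 1L)
  expect_error(fitch_length(tr, c(A = "1", B = "0", C = "1")), "absent")
})

test_that("fitch_length equals the brute-force minimum on random instances", {
  set.seed(20)
  for (i in 1:200) {
    tr <- random_tree(sample(3:8, 1), lengths = FALSE)
    st <- random_states(tr, sample(2:3, 1), missing_prob = 0.1)
    if (!length(unique(st[st != "?"]))) next
    costs <- unit_cost_matrix(sort(unique(st[st != "?"])))
    expect_equal(fitch_length(tr, st), brute_force_parsimony(tr, st, costs),
                 info = paste("case", i))
  }
})

test_that("fitch_length agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(77)
  for (i in 1:25) {
    tr <- random_tree(sample(4:12, 1), lengths = FALSE)
    st <- random_states(tr, 2)
    dat <- phangorn::phyDat(as.matrix(st)[tr$tip.label, , drop = FALSE],
                            type = "USER", levels = c("0", "1"))
    expect_equal(fitch_length(tr, st),
                 as.integer(phangorn::parsimony(tr, dat, method = "fitch")))
  }
})

test_that("fitch_length is invariant to child order and state relabeling", {
  set.seed(30)
  for (i in 1:25) {
    tr <- random_tree(sample(4:10, 1), lengths = FALSE)
    st <- random_states(tr, 2)
    rot <- ape::reorder.phylo(ape::rotateConstr(tr, rev(tr$tip.label)),
                              "cladewise")
    expect_equal(fitch_length(tr, st), fitch_length(rot, st))
    flip <- stats::setNames(ifelse(st == "0", "1",
                                   ifelse(st == "1", "0", "?")), names(st))
    expect_equal(fitch_length(tr, st), fitch_length(tr, flip))
  }
})

test_that("adding a '?' tip never increases the Fitch length", {
  set.seed(40)
  for (i in 1:30) {
    tr <- random_tree(sample(4:9, 1), lengths = FALSE)
    st <- random_states(tr, 2)
    drop <- sample(tr$tip.label, 1)
    st_q <- st
    st_q[drop] <- "?"
    smaller <- ape::reorder.phylo(ape::drop.tip(tr, drop), "cladewise")
    expect_lte(fitch_length(tr, st_q), fitch_length(smaller, st[smaller$tip.label]))
  }
})

test_that("sankoff handles weighted DNA costs and equals fitch at unit cost", {
  costs <- dna_cost_matrix()
  tr <- parse_newick("(A,B);")
  expect_equal(sankoff(tr, c(A = "A", B = "G"), costs)$cost, 1)
  expect_equal(sankoff(tr, c(A = "A", B = "T"), costs)$cost, 2)
  set.seed(50)
  for (i in 1:500) {
    tr <- random_tree(sample(3:8, 1), lengths = FALSE)
    st <- random_states(tr, sample(2:4, 1), missing_prob = 0.05)
    alpha <- sort(unique(st[st != "?"]))
    if (length(alpha) < 2) next
    res <- sankoff(tr, st, unit_cost_matrix(alpha))
    expect_equal(res$cost, fitch_length(tr, st))
    expect_equal(res$reconstruction$total_steps, res$cost)
  }
})

test_that("sankoff cost is monotone in any single cost entry", {
  set.seed(60)
  for (i in 1:20) {
    tr <- random_tree(6, lengths = FALSE)
    st <- random_states(tr, 3)
    alpha <- sort(unique(st[st != "?"]))
    if (length(alpha) < 2) next
    costs <- unit_cost_matrix(alpha)
    base <- sankoff(tr, st, costs)$cost
    i1 <- sample(length(alpha), 1)
    j1 <- sample(setdiff(seq_along(alpha), i1), 1)
    costs[i1, j1] <- costs[i1, j1] + 1.5
    expect_gte(sankoff(tr, st, costs)$cost, base)
  }
})

test_that("acctran attains the Fitch length and lies in the MP set", {
  set.seed(70)
  for (i in 1:60) {
    tr <- random_tree(sample(4:8, 1), lengths = FALSE)
    st <- random_states(tr, 2, missing_prob = 0.1)
    alpha <- sort(unique(st[st != "?"]))
    if (length(alpha) < 2) next
    rec <- acctran(tr, st)
    fl <- fitch_length(tr, st)
    expect_equal(rec$total_steps, fl)
    expect_equal(nrow(rec$changes), rec$total_steps)
    costs <- unit_cost_matrix(alpha)
    mp <- enumerate_mp_labelings(tr, st, costs)
    expect_equal(mp$cost, fl)
    n_tip <- length(tr$tip.label)
    internal <- setdiff(seq_len(max(tr$edge)), seq_len(n_tip))
    chosen <- match(rec$node_states[internal], alpha)
    in_set <- any(vapply(mp$labelings, function(lab)
      all(lab[internal] == chosen), logical(1)))
    expect_true(in_set, info = paste("case", i))
  }
})

test_that("acctran places changes as early as the MP set allows", {
  # walking the tree in preorder: whenever some most-parsimonious labeling
  # that agrees with the acctran assignment on all earlier nodes puts a
  # change on the current branch, acctran must put one there too
  set.seed(80)
  for (i in 1:40) {
    tr <- random_tree(sample(4:8, 1), lengths = FALSE)
    st <- random_states(tr, 2)
    alpha <- sort(unique(st))
    if (length(alpha) < 2) next
    rec <- acctran(tr, st)
    costs <- unit_cost_matrix(alpha)
    mp <- enumerate_mp_labelings(tr, st, costs)
    n_tip <- length(tr$tip.label)
    pre <- node_preorder(tr)
    internal <- pre[pre > n_tip]
    chosen <- match(rec$node_states, alpha)
    parent <- integer(max(tr$edge))
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    for (v in internal[-1]) {
      upper <- internal[seq_len(match(v, internal) - 1L)]
      agreeing <- Filter(function(lab) all(lab[upper] == chosen[upper]),
                         mp$labelings)
      any_change <- any(vapply(agreeing, function(lab)
        lab[v] != lab[parent[v]], logical(1)))
      if (any_change) {
        expect_true(chosen[v] != chosen[parent[v]],
                    info = paste("case", i, "node", v))
      }
    }
  }
})

test_that("count_events and root constraints behave on toy characters", {
  tr <- parse_newick("((A,B),(C,D));")
  uni <- c(A = "x", B = "x", C = "x", D = "x")
  expect_equal(nrow(acctran(tr, uni)$changes), 0L)
  rec0 <- root_constrained_reconstruction(tr, uni, "x")
  expect_equal(rec0$total_steps, 0)
  rec1 <- root_constrained_reconstruction(tr, uni, "y",
                                          alphabet = c("x", "y"))
  expect_equal(rec1$total_steps, 1)
  expect_equal(rec1$changes$node, caenophylo:::root_node(tr))
  expect_equal(count_events(rec1, "y", "x"), 1L)
})

test_that("constrained single-origin counting matches hand cases", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(constrained_single_origin_steps(
    tr, c(A = "1", B = "0", C = "0", D = "0"), "1"), 1L)
  expect_equal(constrained_single_origin_steps(
    tr, c(A = "1", B = "1", C = "0", D = "0"), "1"), 1L)
  # derived tips on both sides of the root: gain above their MRCA (the root
  # is reachable only through the virtual stem), reversals below
  expect_equal(constrained_single_origin_steps(
    tr, c(A = "1", B = "0", C = "1", D = "0"), "1"), 3L)
  expect_error(constrained_single_origin_steps(
    tr, c(A = "1", B = "0", C = "0", D = "0"), "2"), "derived")
})

test_that("constrained single-origin never beats unconstrained parsimony", {
  set.seed(90)
  for (i in 1:50) {
    tr <- random_tree(sample(4:9, 1), lengths = FALSE)
    st <- random_states(tr, 2)
    if (length(unique(st)) < 2) next
    expect_gte(constrained_single_origin_steps(tr, st, "1"),
               fitch_length(tr, st))
  }
})

test_that("the fixture reproduces every published character-evolution count", {
  tr <- load_fixture_tree("caenorhabditis26+outgroup")
  cm <- load_fixture_characters()
  rm <- character_states(cm, "reproductive_mode")
  expect_equal(fitch_length(tr, rm), 3L)
  rec <- acctran(tr, rm)
  herm_tips <- tr$tip.label[rec$changes$node[rec$changes$node <=
                                               length(tr$tip.label)]]
  expect_setequal(herm_tips, c("C_elegans", "C_briggsae", "C_sp11"))
  expect_true(all(rec$changes$to == "hermaphroditic"))
  expect_equal(constrained_single_origin_steps(tr, rm, "hermaphroditic"), 6L)
  expect_equal(fitch_length(tr, character_states(cm, "mid_dorsal_ray")), 2L)
  expect_equal(fitch_length(tr, character_states(cm, "short_ray4")), 3L)
  rn <- root_constrained_reconstruction(
    tr, character_states(cm, "rnai_response"), "competent")
  expect_equal(rn$total_steps, 4)
  expect_equal(count_events(rn, "competent", "incompetent"), 4L)
  stp <- acctran(tr, character_states(cm, "spicule_tip"))
  expect_equal(count_events(stp, "simple", "complex"), 2L)
})

test_that("map_all_characters summarises steps, homoplasy and polarity", {
  tr <- load_fixture_tree("caenorhabditis26+outgroup")
  cm <- load_fixture_characters()
  res <- map_all_characters(tr, cm)
  row <- res$table[res$table$character == "reproductive_mode", ]
  expect_equal(row$steps, 3L)
  expect_equal(row$min_steps, 1L)
  expect_true(row$homoplasy)
  expect_equal(row$n_gains, 3L)
  # apomorphies of the Elegans super-group map without homoplasy
  row2 <- res$table[res$table$character == "ray23_space", ]
  expect_equal(row2$steps, 1L)
  expect_false(row2$homoplasy)
})
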