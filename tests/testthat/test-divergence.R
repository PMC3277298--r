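test_that("gtr_params validates its inputs", {
  expect_error(gtr_params(freq = c(A = 0.5, C = 0.5, G = 0.2, T = 0.2)),
               "sum to 1")
  expect_error(gtr_params(p_inv = 1), "p_inv")
  expect_error(gtr_params(alpha = -1, n_categories = 4), "alpha")
  p <- gtr_params(n_categories = 25, alpha = 0.44081, p_inv = 0.1)
  expect_equal(p$n_categories, 25L)
})

test_that("rate matrix is normalized and P(t) is a reversible stochastic matrix", {
  p <- gtr_params(freq = c(A = 0.264, C = 0.217, G = 0.26, T = 0.259),
                  rates = c(AC = 1.39, AG = 3.12, AT = 1.182, CG = 1.115,
                            CT = 5.79, GT = 1))
  q <- gtr_rate_matrix(p)
  expect_equal(rowSums(q), rep(0, 4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(-sum(p$freq * diag(q)), 1, tolerance = 1e-12)
  for (t in c(0, 0.01, 0.3, 2)) {
    pt <- transition_prob(p, t)
    expect_equal(rowSums(pt), rep(1, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # detailed balance
    expect_equal(p$freq * pt, t(p$freq * pt), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(transition_prob(p, 0), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("discrete gamma category rates average one and increase", {
  for (alpha in c(0.2, 0.44081, 1, 5)) {
    for (m in c(2, 4, 25)) {
      r <- gamma_category_rates(alpha, m)
      expect_equal(mean(r), 1, tolerance = 1e-9)
      expect_true(all(diff(r) > 0))
    }
  }
  expect_equal(gamma_category_rates(0.5, 1), 1)
})

test_that("zero-length two-tip likelihood is the stationary log-probability", {
  p <- gtr_params(freq = c(A = 0.4, C = 0.1, G = 0.2, T = 0.3),
                  rates = c(AC = 2, AG = 3, AT = 1, CG = 1, CT = 4, GT = 1))
  aln <- as_alignment(c(a = "ACGTAC", b = "ACGTAC"))
  tr <- parse_newick("(a:0,b:0);")
  expect_equal(gtr_gamma_inv_loglik(tr, aln, p),
               sum(log(p$freq[c("A", "C", "G", "T", "A", "C")])),
               tolerance = 1e-10)
})

test_that("pruning matches the Jukes-Cantor closed form", {
  p <- jc_params()
  set.seed(140)
  for (d in c(0.05, 0.2, 0.7)) {
    tr <- parse_newick(sprintf("(a:%f,b:%f);", d / 3, 2 * d / 3))
    aln <- random_alignment(c("a", "b"), 500, gap_prob = 0)
    pd <- 0.75 * (1 - exp(-4 * d / 3))
    m <- unclass(aln)
    nd <- sum(m[1, ] != m[2, ])
    ns <- ncol(m) - nd
    closed <- ns * log(0.25 * (1 - pd)) + nd * log(0.25 * pd / 3)
    expect_equal(gtr_gamma_inv_loglik(tr, aln, p), closed, tolerance = 1e-10)
  }
})

test_that("pruning equals the enumeration oracle on small random instances", {
  set.seed(150)
  for (i in 1:12) {
    n <- sample(3:5, 1)
    tr <- random_tree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.6)
    p <- gtr_params(freq = local({
      f <- runif(4, 0.5, 1.5)
      stats::setNames(f / sum(f), c("A", "C", "G", "T"))
    }),
    rates = stats::setNames(c(runif(5, 0.5, 4), 1),
                            c("AC", "AG", "AT", "CG", "CT", "GT")),
    alpha = runif(1, 0.3, 2),
    p_inv = sample(c(0, 0.2), 1),
    n_categories = sample(1:3, 1))
    aln <- random_alignment(tr$tip.label, 12, gap_prob = 0.1)
    expect_equal(gtr_gamma_inv_loglik(tr, aln, p), enum_loglik(tr, aln, p),
                 tolerance = 1e-8)
  }
})

test_that("likelihood agrees with an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  set.seed(160)
  tr <- random_tree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  p <- gtr_params(freq = c(A = 0.3, C = 0.2, G = 0.25, T = 0.25),
                  rates = c(AC = 1.4, AG = 3.1, AT = 1.2, CG = 1.1,
                            CT = 5.8, GT = 1))
  aln <- random_alignment(tr$tip.label, 300, gap_prob = 0)
  dat <- phangorn::phyDat(unclass(aln))
  # phangorn parameterises GTR by Q = c(AC, AG, AT, CG, CT, GT)
  fitp <- phangorn::pml(tr, dat, bf = p$freq, Q = unname(p$rates), k = 1)
  expect_equal(gtr_gamma_inv_loglik(tr, aln, p), as.numeric(fitp$logLik),
               tolerance = 1e-6)
})

test_that("likelihood is invariant to site order and pattern compression", {
  set.seed(170)
  tr <- random_tree(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  p <- gtr_params(alpha = 0.5, n_categories = 4, p_inv = 0.1)
  aln <- random_alignment(tr$tip.label, 60, gap_prob = 0.05)
  perm <- sample(ncol(aln))
  aln2 <- as_alignment(unclass(aln)[, perm])
  expect_equal(gtr_gamma_inv_loglik(tr, aln, p),
               gtr_gamma_inv_loglik(tr, aln2, p), tolerance = 1e-9)
  expect_equal(gtr_gamma_inv_loglik(tr, site_patterns(aln), p),
               gtr_gamma_inv_loglik(tr, aln, p), tolerance = 1e-9)
  # p_inv = 0, one category reduces exactly to plain GTR
  p1 <- gtr_params(alpha = 123, n_categories = 1, p_inv = 0)
  p2 <- gtr_params(n_categories = 1)
  expect_equal(gtr_gamma_inv_loglik(tr, aln, p1),
               gtr_gamma_inv_loglik(tr, aln, p2), tolerance = 1e-12)
})

test_that("two-tip JC branch-length MLE equals the closed-form distance", {
  p <- jc_params()
  set.seed(180)
  for (i in 1:5) {
    tr <- parse_newick("(a:0.1,b:0.1);")
    rec <- simulate_alignment(tr, p, 4000, seed = 200 + i)
    m <- unclass(rec$alignment)
    prop <- mean(m[1, ] != m[2, ])
    fit <- optimize_branch_lengths(tr, rec$alignment, p, tol = 1e-9)
    expect_equal(sum(fit$edge.length), -0.75 * log(1 - 4 * prop / 3),
                 tolerance = 1e-6)
  }
})

test_that("identical sequences drive all branch lengths to the lower bound", {
  p <- jc_params()
  aln <- as_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                        c = "ACGTACGTAC"))
  tr <- parse_newick("((a:0.1,b:0.1):0.1,c:0.1);")
  fit <- optimize_branch_lengths(tr, aln, p)
  expect_true(all(fit$edge.length <= 1e-6))
})

test_that("non-convergence raises an error carrying the best tree so far", {
  p <- jc_params()
  set.seed(190)
  tr <- random_tree(4)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.3)
  rec <- simulate_alignment(tr, p, 500, seed = 3)
  err <- tryCatch(
    optimize_branch_lengths(tr, rec$alignment, p, max_sweeps = 0L),
    optim_nonconvergence = function(e) e)
  expect_s3_class(err, "optim_nonconvergence")
  expect_s3_class(err$tree, "phylo")
})

test_that("branch lengths are recovered on simulated data", {
  set.seed(200)
  tr <- random_tree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.03, 0.25)
  p <- gtr_params(freq = c(A = 0.264, C = 0.217, G = 0.26, T = 0.259),
                  rates = c(AC = 1.39, AG = 3.12, AT = 1.182, CG = 1.115,
                            CT = 5.79, GT = 1),
                  alpha = 0.8, n_categories = 4)
  rec <- simulate_alignment(tr, p, 20000, seed = 17)
  fit <- optimize_branch_lengths(tr, rec$alignment, p, tol = 1e-4)
  utr <- ape::unroot(tr)
  m <- match(paste(fit$edge[, 1], fit$edge[, 2]),
             paste(utr$edge[, 1], utr$edge[, 2]))
  rel <- abs(fit$edge.length - utr$edge.length[m]) / utr$edge.length[m]
  expect_lt(stats::median(rel), 0.1)
  expect_lt(max(rel), 0.25)
})

test_that("estimate_params improves the likelihood from wrong start values", {
  set.seed(210)
  tr <- random_tree(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  truth <- gtr_params(freq = c(A = 0.3, C = 0.2, G = 0.25, T = 0.25),
                      rates = c(AC = 1, AG = 4, AT = 1, CG = 1, CT = 4,
                                GT = 1))
  rec <- simulate_alignment(tr, truth, 3000, seed = 9)
  start <- gtr_params()   # JC start
  fit0 <- optimize_branch_lengths(tr, rec$alignment, start, tol = 1e-4)
  fit1 <- optimize_branch_lengths(tr, rec$alignment, start,
                                  estimate_params = TRUE, tol = 1e-4)
  expect_gt(attr(fit1, "loglik"), attr(fit0, "loglik"))
  est <- attr(fit1, "params")
  # transition-heavy exchangeabilities should be recovered as dominant
  expect_gt(est$rates[["AG"]], est$rates[["AC"]])
  expect_gt(est$rates[["CT"]], est$rates[["CG"]])
})

test_that("divergence_table lists sorted patristic distances", {
  tr <- parse_newick("(a:0.03,b:0.027);")
  tab <- divergence_table(tr)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$distance, 0.057)
  star <- parse_newick("(a:0.1,b:0.1,c:0.1,d:0.1);")
  tab2 <- divergence_table(star)
  expect_equal(nrow(tab2), 6L)
  expect_true(all(abs(tab2$distance - 0.2) < 1e-12))
  set.seed(220)
  tr3 <- random_tree(7)
  tab3 <- divergence_table(tr3)
  expect_false(is.unsorted(tab3$distance))
  expect_equal(tab3$distance[1],
               min(vapply(seq_len(nrow(tab3)), function(i)
                 patristic_distance(tr3, tab3$tip_a[i], tab3$tip_b[i]),
                 numeric(1))))
})
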