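test_that("CDS extraction concatenates exons and honors strand", {
  rec <- structure(list(
    seq = "AAACCCGGGTTTAAACCCGGG", locus_start = 0L, locus_length = 21L,
    exons = data.frame(start = c(3L, 12L), end = c(6L, 15L)),
    strand = "+", tokens = data.frame()), class = "locus_record")
  expect_equal(extract_cds(rec), "CCCAAA")
  rec$strand <- "-"
  expect_equal(extract_cds(rec), revcomp("CCCAAA"))
  rec$exons <- data.frame(start = 3L, end = 500L)
  rec$strand <- "+"
  expect_error(extract_cds(rec), "bounds")
  rec$exons <- data.frame(start = integer(), end = integer())
  expect_error(extract_cds(rec), "gene model")
})

test_that("five-exon CDS length is the sum of exon lengths", {
  fam <- simulate_family(small_config(seed = 30))
  rec <- fam$records$NOTCH2
  expect_equal(nchar(extract_cds(rec)),
               sum(rec$exons$end - rec$exons$start))
})

test_that("best transcript match finds the closest panel entry with margin", {
  set.seed(31)
  base <- rand_dna(900)
  panel <- c(A = base,
             B = with_subs(base, sample(900, 12)),
             C = with_subs(base, sample(900, 30)))
  exact <- best_transcript_match(panel[["A"]], panel)
  expect_equal(exact$best_label, "A")
  expect_equal(exact$mismatches, 0)
  q3 <- with_subs(panel[["A"]], c(10, 20, 30))
  m <- best_transcript_match(q3, panel)
  expect_equal(m$best_label, "A")
  expect_equal(m$mismatches, 3)
  expect_gte(m$margin, 7)
  expect_error(best_transcript_match("", panel), "empty")
})

test_that("a half-and-half recombinant CDS ties as ambiguous", {
  set.seed(32)
  a <- rand_dna(1000)
  diff_pos <- sort(sample(1000, 20))
  b <- with_subs(a, diff_pos)
  # chimera carrying the A allele at the first 10 diffs, B at the last 10
  chim <- with_subs(a, diff_pos[11:20])
  for (p in diff_pos[11:20]) {
    substr(chim, p, p) <- substr(b, p, p)
  }
  m <- best_transcript_match(chim, c(A = a, B = b))
  expect_equal(m$best_label, "ambiguous")
  expect_equal(sort(m$tied), c("A", "B"))
  expect_equal(m$margin, 0)
})

test_that("p-distance and JC69 follow their closed forms", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(jc69_distance(0), 0)
  expect_equal(jc69_distance(0.03), -0.75 * log(1 - 0.04), tolerance = 1e-12)
  expect_equal(jc69_distance(0.03), 0.030617, tolerance = 1e-4)
  expect_error(p_distance("NNNN", "NNNN"), "comparable")
  expect_error(jc69_distance(0.8), "satur")
  # sites with N excluded from both numerator and denominator
  expect_equal(p_distance("ACGTN", "ACCTA"), 0.25)
})

test_that("JC69 distance is monotone in p", {
  p <- seq(0, 0.74, by = 0.01)
  d <- vapply(p, jc69_distance, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("three-taxon NJ branch lengths solve the three-point formulas", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tr <- nj_tree(D)
  pat <- ape::cophenetic.phylo(tr)
  expect_equal(pat["a", "b"], 3)
  expect_equal(pat["a", "c"], 4)
  expect_equal(pat["b", "c"], 5)
  # x = (d_ab + d_ac - d_bc)/2 etc.
  len <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                  tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(unname(len["a"]), 1)
  expect_equal(unname(len["b"]), 2)
  expect_equal(unname(len["c"]), 3)
})

test_that("NJ input validation rejects malformed matrices", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), "3 taxa")
  D3 <- matrix(c(0, 1, 2, 1.1, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3), "asymmetric")
})

test_that("NJ recovers every additive 4- and 5-taxon matrix (exhaustive topology oracle)", {
  set.seed(33)
  ls_best_topology <- function(D, labels) {
    # enumerate all unrooted topologies; the generating one fits with zero
    # least-squares residual
    all_t <- phangorn::allTrees(length(labels), rooted = FALSE,
                                tip.label = labels)
    resid <- vapply(all_t, function(tr) {
      tr$edge.length <- rep(1, nrow(tr$edge))
      # design matrix: which edges lie on each tip-pair path
      n <- length(labels)
      pairs <- t(combn(n, 2))
      X <- matrix(0, nrow(pairs), nrow(tr$edge))
      for (r in seq_len(nrow(pairs))) {
        p <- ape::nodepath(tr, pairs[r, 1], pairs[r, 2])
        for (e in seq_len(nrow(tr$edge))) {
          i1 <- match(tr$edge[e, 1], p); i2 <- match(tr$edge[e, 2], p)
          if (!is.na(i1) && !is.na(i2) && abs(i1 - i2) == 1) X[r, e] <- 1
        }
      }
      y <- D[cbind(labels[pairs[, 1]], labels[pairs[, 2]])]
      fit <- lm.fit(X, y)
      sum(fit$residuals^2)
    }, numeric(1))
    all_t[[which.min(resid)]]
  }
  for (n in c(4, 5)) {
    for (rep in 1:8) {
      labels <- letters[1:n]
      tr0 <- ape::rtree(n, rooted = FALSE, tip.label = labels,
                        br = function(k) runif(k, 0.2, 1))
      D <- ape::cophenetic.phylo(tr0)[labels, labels]
      nj <- nj_tree(D)
      oracle <- ls_best_topology(D, labels)
      expect_equal(as.integer(phangorn::RF.dist(ape::unroot(nj),
                                                ape::unroot(oracle))), 0L)
      expect_equal(as.integer(phangorn::RF.dist(ape::unroot(nj),
                                                ape::unroot(tr0))), 0L)
    }
  }
})

test_that("clade assignment: distance zero, ties and monophyly", {
  tr <- ape::read.tree(text = "((query:0,A:0):1,(B:1,C:5):1);")
  cl <- assign_clade(tr, "query", c("A", "B", "C"))
  expect_equal(cl$clade_label, "A")
  expect_true(cl$monophyletic)
  # query equidistant to A and B: ambiguous with zero margin
  tr2 <- ape::read.tree(text = "(query:1,A:2,B:2,C:9);")
  cl2 <- assign_clade(tr2, "query", c("A", "B", "C"))
  expect_equal(cl2$clade_label, "ambiguous")
  expect_equal(cl2$patristic_margin, 0)
  # a reference nested inside the query's clade breaks monophyly
  tr3 <- ape::read.tree(text = "(((query:1,A:1):1,B:1):1,C:5);")
  cl3 <- assign_clade(tr3, "query", c("A", "B", "C"))
  expect_equal(cl3$clade_label, "A")
  expect_true(cl3$monophyletic)
  expect_error(assign_clade(tr, "nope", c("A", "B")), "absent")
})

test_that("a simulated B-to-A converted intron lands in clade A", {
  cfg <- sim_config(seed = 34, mu = 2e-3)
  fam <- simulate_family(cfg)
  conv <- apply_igc(fam$records$NOTCH2NLB, fam$records$NOTCH2NLA,
                    c(0L, cfg$locus_length))
  panel <- reference_panel(fam)
  ev <- locus_evidence(conv, panel)
  expect_equal(ev$clade$clade_label, "NOTCH2NLA")
  expect_equal(ev$location$label, "NOTCH2NLB")
})

test_that("strict-clock identities: zero distance and calibration point", {
  expect_equal(clock_time(0, 0.03), 0)
  expect_equal(clock_time(0.03, 0.03), 15.2)
  expect_error(clock_time(0.01, 0), "positive")
  # scale invariance
  expect_equal(clock_time(0.004, 0.02), clock_time(0.4, 2))
})

test_that("dating errors on a zero-distance outgroup and dates an identical pair at 0", {
  set.seed(35)
  s <- rand_dna(5000)
  o <- with_subs(s, sample(5000, 150))
  est <- date_divergence(c(s, s), o, n_bootstrap = 50)
  expect_equal(est$time, 0)
  expect_error(date_divergence(c(s, s), s), "outgroup distance")
})

test_that("dating recovers a simulated 4.5 MYA split", {
  cfg <- sim_config(seed = 36, mu = 1e-3,
                    paralog_tree = data.frame(label = c("A", "B"),
                                              time = c(4.5, 4.5)))
  fam <- simulate_family(cfg)
  est <- date_divergence(c(sdparalog:::locus_seq(fam$records$A),
                           sdparalog:::locus_seq(fam$records$B)),
                         sdparalog:::locus_seq(fam$outgroup),
                         n_bootstrap = 200)
  expect_lt(abs(est$time - 4.5), 1.5)
  expect_lte(est$ci_low, est$time)
  expect_gte(est$ci_high, est$time)
})
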