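test_that("anchors: identical sequences give one spanning anchor", {
  s <- rand_dna(1000, seed = 1)
  a <- find_anchors(s, s, 21)
  expect_equal(nrow(a), 1)
  expect_equal(a$qstart, 0)
  expect_equal(a$qend, 1000)
  expect_equal(a$strand, "+")
})

test_that("anchors: reverse-complement target yields minus-strand anchors only", {
  s <- rand_dna(1000, seed = 2)
  a <- find_anchors(s, revcomp(s), 21)
  expect_true(nrow(a) >= 1)
  expect_true(all(a$strand == "-"))
})

test_that("anchors: a substitution splits the anchor in two", {
  q <- rand_dna(2000, seed = 3)
  t <- with_subs(q, 1000)
  a <- find_anchors(q, t, 21)
  expect_equal(nrow(a), 2)
  expect_equal(a$qend[1], 999)   # 0-based: position 1000 (1-based) differs
  expect_equal(a$qstart[2], 1000)
})

test_that("anchors: k below 8 is rejected", {
  expect_error(find_anchors("ACGTACGTACGT", "ACGTACGTACGT", 7), "k must be")
})

test_that("chaining bridges small gaps and splits at large ones", {
  set.seed(4)
  left <- rand_dna(3000)
  right <- rand_dna(3000)
  spacer_q <- rand_dna(100)
  spacer_t <- rand_dna(100)
  q <- paste0(left, spacer_q, right)
  t <- paste0(left, spacer_t, right)
  blocks <- synteny_blocks(q, t, min_chain = 1000)
  expect_equal(length(blocks), 1) # 100 bp gap < max_gap: one chain
  big_q <- paste0(left, rand_dna(50000), right)
  big_t <- paste0(left, rand_dna(50000), right)
  blocks2 <- synteny_blocks(big_q, big_t, max_gap = 10000, min_chain = 1000)
  expect_equal(length(blocks2), 2) # 50 kbp gap > max_gap: two blocks
})

test_that("block identity matches hand-computed column counts", {
  q <- rand_dna(2000, seed = 5)
  t10 <- with_subs(q, seq(150, 1950, length.out = 10))
  b <- synteny_blocks(q, t10, min_chain = 500)[[1]]
  expect_equal(b$identity, 99.50)
  # one 20 bp deletion, no substitutions: identity = 100 * 1980/2000
  t_del <- paste0(substr(q, 1, 990), substr(q, 1011, 2000))
  b2 <- synteny_blocks(q, t_del, min_chain = 500)[[1]]
  expect_equal(b2$identity, 100 * 1980 / 2000)
  expect_equal(b2$insertions, 20)
})

test_that("anchored block identity equals the full-DP identity oracle", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(600:2000, 1)
    q <- rand_dna(n)
    t <- with_subs(q, sample(n, sample(1:25, 1)))
    if (i %% 3 == 0) { # add an indel
      cut <- sample(200:(n - 200), 1)
      t <- paste0(substr(t, 1, cut), substr(t, cut + sample(5:30, 1), n))
    }
    b <- synteny_blocks(q, t, min_chain = 200)
    expect_true(length(b) >= 1)
    bb <- b[[which.max(vapply(b, function(x) x$qend - x$qstart, numeric(1)))]]
    oracle <- nw_align(substr(q, bb$qstart + 1, bb$qend),
                       substr(t, bb$tstart + 1, bb$tend))
    expect_equal(bb$identity, alignment_identity_oracle(oracle))
  }
})

test_that("longest syntenic block: self gives full length at 100", {
  s <- rand_dna(3000, seed = 7)
  r <- longest_syntenic_block(s, s)
  expect_equal(r$length, 3000)
  expect_equal(r$identity, 100)
})

test_that("longest syntenic block: unrelated sequences give none", {
  r <- longest_syntenic_block(rand_dna(2000, seed = 8), rand_dna(2000, seed = 9))
  expect_equal(r$length, 0)
  expect_true(is.na(r$identity))
})

test_that("longest syntenic block recovers an embedded shared segment", {
  set.seed(10)
  shared <- rand_dna(8000)
  shared_div <- with_subs(shared, sample(8000, 24)) # 99.7 percent identity
  q <- paste0(rand_dna(3000), shared, rand_dna(3000))
  t <- paste0(rand_dna(2000), shared_div, rand_dna(4000))
  r <- longest_syntenic_block(q, t)
  expect_lt(abs(r$length - 8000) / 8000, 0.01)
  expect_lt(abs(r$identity - 99.7), 0.05)
})

test_that("identity matrix is symmetric with 100 on the diagonal", {
  set.seed(11)
  base <- rand_dna(4000)
  regions <- c(A = base,
               B = with_subs(base, sample(4000, 12)),
               C = with_subs(base, sample(4000, 40)))
  im <- identity_matrix(regions, min_chain = 500)
  expect_identical(im$identity, t(im$identity))
  expect_identical(im$length, t(im$length))
  expect_equal(unname(diag(im$identity)), rep(100, 3))
  expect_error(identity_matrix(setNames(regions, c("A", "A", "C"))),
               "unique")
})

test_that("published homology table fixture: mean length ~287 kbp, max identity 99.7", {
  im <- read_identity_matrix(system.file("extdata", "chm13_region_identity.tsv",
                                         package = "sdparalog"))
  s <- identity_matrix_stats(im)
  expect_equal(s$mean_length, 286958.7, tolerance = 1e-6)
  expect_equal(s$max_identity, 99.7)
  expect_equal(im$length["NOTCH2NLA", "NOTCH2NLB"], 416088)
  expect_equal(im$identity["NOTCH2NLA", "NOTCH2NLB"], 99.7)
})

test_that("windowed identity detects a copied prefix at the 99.9 threshold", {
  set.seed(12)
  donorA <- rand_dna(20000)
  backbone <- with_subs(donorA, sample(20000, 400)) # 2 percent diverged
  chimera <- paste0(substr(donorA, 1, 5000), substr(backbone, 5001, 20000))
  wp <- window_identity(chimera, c(A = donorA), window_size = 1000)
  expect_equal(wp$assigned[1:5], rep("A", 5))
  expect_true(all(is.na(wp$assigned[6:20])))
  # weighted mean of window identities equals the global block identity
  m <- attr(wp, "matches"); cl <- attr(wp, "columns")
  global <- synteny_blocks(chimera, donorA)[[1]]
  expect_equal(100 * sum(m[, "A"]) / sum(cl[, "A"]), global$identity,
               tolerance = 0.1)
})

test_that("windows tile the acceptor and a too-large window collapses to one", {
  s <- rand_dna(2500, seed = 13)
  wp <- window_identity(s, c(self = s), window_size = 1000)
  expect_equal(wp$window_start, c(0, 1000, 2000))
  expect_equal(wp$window_end, c(1000, 2000, 2500))
  expect_true(all(wp$self == 100))
  expect_true(all(wp$assigned == "self"))
  wp1 <- window_identity(s, c(self = s), window_size = 10000)
  expect_equal(nrow(wp1), 1)
})

test_that("identity never increases when substitutions are added", {
  set.seed(14)
  q <- rand_dna(2000)
  t <- q
  last <- 100
  for (k in c(2, 6, 12, 24, 48)) {
    t <- with_subs(q, sample(2000, k))
    b <- synteny_blocks(q, t, min_chain = 200)
    idy <- max(vapply(b, `[[`, numeric(1), "identity"))
    expect_lte(idy, last + 1e-9)
    last <- idy
  }
})

test_that("indel extraction reports only indels at or above the cutoff", {
  q <- rand_dna(4000, seed = 15)
  # 100 bp insertion in the query at position 2000
  qi <- paste0(substr(q, 1, 2000), rand_dna(100), substr(q, 2001, 4000))
  b <- synteny_blocks(qi, q, min_chain = 500)[[1]]
  ind <- extract_indels(b, min_len = 50)
  expect_equal(nrow(ind), 1)
  expect_equal(ind$type, "INS")
  expect_equal(ind$length, 100)
  expect_lt(abs(ind$position - 2000), 25) # placement within repeat slack
  expect_equal(nrow(extract_indels(b, min_len = 150)), 0)
  # identical sequences: nothing
  b0 <- synteny_blocks(q, q)[[1]]
  expect_equal(nrow(extract_indels(b0, min_len = 50)), 0)
  # 40 bp insertion below the default cutoff
  q40 <- paste0(substr(q, 1, 2000), rand_dna(40), substr(q, 2001, 4000))
  b40 <- synteny_blocks(q40, q, min_chain = 500)[[1]]
  expect_equal(nrow(extract_indels(b40, min_len = 50)), 0)
})

test_that("synteny blocks round-trip through the PAF-like TSV", {
  q <- rand_dna(3000, seed = 16)
  t <- with_subs(q, c(500, 1500))
  blocks <- synteny_blocks(q, t, min_chain = 500)
  f <- tempfile(fileext = ".tsv")
  write_synteny_tsv(blocks, f)
  back <- read_synteny_tsv(f)
  expect_equal(length(back), length(blocks))
  for (i in seq_along(blocks)) {
    for (fld in c("qstart", "qend", "tstart", "tend", "strand", "matches",
                  "columns", "identity", "cigar")) {
      expect_equal(back[[i]][[fld]], blocks[[i]][[fld]])
    }
  }
})
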