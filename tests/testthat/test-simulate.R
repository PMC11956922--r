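test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(config_frequencies = c(H1 = 0.6, H2 = 0.5)),
               "sum to 1")
  expect_error(sim_config(mu = -1), "mu")
  expect_error(sim_config(paralog_tree = data.frame(
    label = c("A", "B"), time = c(20, 20))), "outgroup_time")
  expect_error(sim_config(exon_layout = data.frame(start = 100, end = 30000)),
               "exon outside locus")
  expect_error(sim_config(exon_layout = data.frame(start = c(100, 150),
                                                   end = c(200, 250))),
               "non-overlapping")
})

test_that("degenerate sizes give an empty record", {
  cfg <- sim_config(locus_length = 0, flank_length = 0,
                    exon_layout = data.frame(start = integer(),
                                             end = integer()))
  rec <- simulate_ancestor(cfg)
  expect_equal(nchar(rec$seq), 0)
  expect_equal(nrow(rec$exons), 0)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 99)
  expect_identical(simulate_ancestor(cfg), simulate_ancestor(cfg))
  expect_identical(simulate_family(cfg), simulate_family(cfg))
  co1 <- simulate_cohort(small_config(seed = 3, n_haplotypes = 3))
  co2 <- simulate_cohort(small_config(seed = 3, n_haplotypes = 3))
  expect_identical(co1$haplotypes, co2$haplotypes)
  expect_identical(co1$truth, co2$truth)
})

test_that("ancestor geometry follows the configuration", {
  cfg <- sim_config(seed = 2)
  rec <- simulate_ancestor(cfg)
  expect_equal(nchar(rec$seq), 20000 + 2 * 5000)
  expect_equal(nrow(rec$exons), 5)
  expect_equal(rec$locus_start, 5000)
  expect_true(all(rec$tokens$end <= nchar(rec$seq)))
})

test_that("zero rate leaves all paralogs identical to the ancestor", {
  cfg <- small_config(seed = 5, mu = 0)
  fam <- simulate_family(cfg)
  anc <- sdparalog:::locus_seq(fam$ancestor)
  for (rec in fam$records) {
    expect_identical(sdparalog:::locus_seq(rec), anc)
  }
})

test_that("saturation is rejected", {
  expect_error(simulate_family(small_config(mu = 0.05)), "saturation")
})

test_that("pairwise divergence matches the 2*mu*T expectation (binomial oracle)", {
  cfg <- sim_config(seed = 17, mu = 1e-3,
                    paralog_tree = data.frame(label = c("A", "B"),
                                              time = c(4.5, 4.5)))
  fam <- simulate_family(cfg)
  p <- p_distance(sdparalog:::locus_seq(fam$records$A),
                  sdparalog:::locus_seq(fam$records$B))
  expected <- 2 * 1e-3 * 4.5
  tol <- 3 * sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(p - expected), tol)
})

test_that("neighbor joining on simulated sequences recovers the input ladder", {
  cfg <- sim_config(seed = 21, mu = 2e-3)
  fam <- simulate_family(cfg)
  seqs <- vapply(fam$records, sdparalog:::locus_seq, character(1))
  seqs <- c(seqs, setNames(sdparalog:::locus_seq(fam$outgroup), "outgroup"))
  tr <- nj_tree(jc69_matrix(seqs))
  truth <- ape::read.tree(text = paste0(
    "(outgroup,(NOTCH2,(NOTCH2NLR,(NOTCH2NLC,(NOTCH2NLA,NOTCH2NLB)))));"))
  expect_equal(as.integer(phangorn::RF.dist(ape::unroot(tr),
                                            ape::unroot(truth))), 0L)
})

test_that("gene conversion copies the donor inside the tract only", {
  cfg <- small_config(seed = 8, mu = 5e-3)
  fam <- simulate_family(cfg)
  a <- fam$records$NOTCH2NLA
  b <- fam$records$NOTCH2NLB
  conv <- apply_igc(b, a, c(500, 1500))
  sa <- sdparalog:::locus_seq(a); sb <- sdparalog:::locus_seq(b)
  sc <- sdparalog:::locus_seq(conv)
  expect_identical(substr(sc, 501, 1500), substr(sa, 501, 1500))
  expect_identical(substr(sc, 1, 500), substr(sb, 1, 500))
  expect_identical(substr(sc, 1501, 2000), substr(sb, 1501, 2000))
  # zero-length tract: unchanged; full-locus tract: full copy
  expect_identical(sdparalog:::locus_seq(apply_igc(b, a, c(700, 700))), sb)
  expect_identical(sdparalog:::locus_seq(apply_igc(b, a, c(0, 2000))), sa)
  expect_error(apply_igc(b, a, c(-5, 100)), "bounds")
  expect_error(apply_igc(b, a, c(100, 99999)), "bounds")
})

test_that("window identity confirms a conversion tract at full identity", {
  cfg <- sim_config(seed = 9, mu = 2e-3)
  fam <- simulate_family(cfg)
  conv <- apply_igc(fam$records$NOTCH2NLB, fam$records$NOTCH2NLA,
                    c(5000, 10000))
  wp <- window_identity(sdparalog:::locus_seq(conv),
                        c(A = sdparalog:::locus_seq(fam$records$NOTCH2NLA)),
                        window_size = 1000)
  inside <- wp$A[wp$window_start >= 5000 & wp$window_end <= 10000]
  outside <- wp$A[wp$window_end <= 5000 | wp$window_start >= 10000]
  expect_true(all(inside == 100))
  expect_true(all(outside < 100))
})

test_that("empirical configuration frequencies obey the multinomial bound", {
  freqs <- c(H1 = 0.43, H5 = 0.20, H3 = 0.10, H2 = 0.27)
  cfg <- small_config(seed = 31, n_haplotypes = 1000,
                      config_frequencies = freqs)
  co <- simulate_cohort(cfg)
  emp <- table(factor(co$truth$haplotypes$config_label, levels = names(freqs)))
  for (l in names(freqs)) {
    p <- freqs[[l]]
    expect_lt(abs(emp[[l]] / 1000 - p), 3 * sqrt(p * (1 - p) / 1000))
  }
})

test_that("unknown configuration labels are rejected", {
  expect_error(simulate_cohort(small_config(
    config_frequencies = c(H1 = 0.5, HX = 0.5))), "unknown configuration")
})

test_that("truth conversion tracts verify at 100 percent donor identity", {
  cfg <- small_config(seed = 12, n_haplotypes = 8, mu = 5e-3,
                      config_frequencies = c(H3 = 0.4, H5 = 0.4, H10 = 0.2))
  co <- simulate_cohort(cfg)
  ev <- co$truth$igc_events
  expect_gt(nrow(ev), 0)
  for (i in seq_len(nrow(ev))) {
    rec <- co$haplotypes[[ev$haplotype[i]]][[ev$acceptor[i]]]
    donor <- co$family$records[[ev$donor[i]]]
    if (ev$end[i] == ev$start[i]) next
    acc_tract <- substr(sdparalog:::locus_seq(rec), ev$start[i] + 1, ev$end[i])
    don_tract <- substr(sdparalog:::locus_seq(donor), ev$start[i] + 1, ev$end[i])
    # later events at the same locus may overwrite earlier ones (the hybrid
    # construction); verify the final event and the non-overlapped part of
    # earlier ones
    later <- ev[ev$haplotype == ev$haplotype[i] &
                  ev$acceptor == ev$acceptor[i], , drop = FALSE]
    if (i == max(as.integer(rownames(later)))) {
      expect_identical(acc_tract, don_tract)
    }
  }
  # deleted loci carry no conversion events
  deleted <- co$truth$loci[co$truth$loci$deleted, ]
  for (j in seq_len(nrow(deleted))) {
    expect_false(any(ev$haplotype == deleted$haplotype[j] &
                       ev$acceptor == deleted$position[j]))
  }
})

test_that("a cohort round-trips through the on-disk formats", {
  cfg <- small_config(seed = 13, n_haplotypes = 4)
  co <- simulate_cohort(cfg)
  dir <- tempfile()
  write_cohort(co, dir)
  expect_equal(length(list.files(dir, pattern = "\\.fa$")), 4)
  back <- read_cohort(dir)
  expect_identical(names(back$haplotypes), names(co$haplotypes))
  expect_identical(back$truth$haplotypes, co$truth$haplotypes)
  expect_identical(back$truth$igc_events$donor, co$truth$igc_events$donor)
  for (h in names(co$haplotypes)) {
    for (p in names(co$haplotypes[[h]])) {
      a <- co$haplotypes[[h]][[p]]; b <- back$haplotypes[[h]][[p]]
      expect_identical(b$seq, a$seq)
      expect_equal(b$exons$start, a$exons$start)
      expect_equal(b$exons$end, a$exons$end)
      expect_equal(b$tokens$token_id, a$tokens$token_id)
      expect_equal(b$tokens$strand, a$tokens$strand)
      expect_equal(b$locus_start, a$locus_start)
    }
  }
  # writing what was read reproduces identical files
  dir2 <- tempfile()
  write_cohort(back, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir2, f)), readLines(file.path(dir, f)))
  }
})

test_that("an empty cohort writes valid empty files", {
  cfg <- small_config(seed = 14, n_haplotypes = 0)
  co <- simulate_cohort(cfg)
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$haplotypes), 0)
  expect_equal(nrow(back$truth$igc_events), 0)
})
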