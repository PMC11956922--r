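# minimal evidence triplet builder for rule-level tests
triplet <- function(t_label, c_label, l_label, tied = character(),
                    l_margin = 2) {
  list(locus = "x", haplotype = "hap",
       transcript = structure(list(best_label = t_label, mismatches = 0,
                                   margin = if (t_label == "ambiguous") 0 else 5,
                                   tied = tied),
                              class = "transcript_match"),
       clade = structure(list(clade_label = c_label, patristic_margin = 0.01,
                              monophyletic = TRUE),
                         class = "clade_assignment"),
       location = list(label = l_label, margin = l_margin))
}

test_that("call rules: agreement, conversion, NOTCH2tv and hybrid", {
  clean <- call_paralog(triplet("NOTCH2NLA", "NOTCH2NLA", "NOTCH2NLA"))
  expect_equal(clean$status, "clean")
  expect_equal(clean$consensus_label, "NOTCH2NLA")
  igc <- call_paralog(triplet("NOTCH2NLA", "NOTCH2NLA", "NOTCH2NLB"))
  expect_equal(igc$status, "igc")
  expect_equal(igc$donor_label, "NOTCH2NLA")
  expect_equal(igc$acceptor_label, "NOTCH2NLB")
  tv <- call_paralog(triplet("NOTCH2", "NOTCH2", "NOTCH2NLR"))
  expect_equal(tv$consensus_label, "NOTCH2tv")
  hyb <- call_paralog(triplet("ambiguous", "NOTCH2NLA", "NOTCH2NLC",
                              tied = c("NOTCH2NLA", "NOTCH2NLB")))
  expect_equal(hyb$consensus_label, "hybrid")
  amb <- call_paralog(triplet("NOTCH2NLA", "NOTCH2NLB", "NOTCH2NLA"))
  expect_equal(amb$status, "ambiguous")
  amb2 <- call_paralog(triplet("NOTCH2NLA", "NOTCH2NLA", "ambiguous",
                               l_margin = 0))
  expect_equal(amb2$status, "ambiguous")
  del <- call_paralog(list(locus = "x", position = "NOTCH2NLR",
                           deleted = TRUE))
  expect_equal(del$status, "deleted")
})

test_that("tract delineation requires a long enough donor-favoring run", {
  wp <- structure(data.frame(
    window_start = seq(0, 9000, 1000), window_end = seq(1000, 10000, 1000),
    donor = c(99, 99, 100, 100, 100, 100, 99, 100, 100, 99),
    ref = c(100, 100, 99.8, 99.8, 99.8, 99.8, 100, 99.8, 99.8, 100),
    assigned = NA_character_), class = c("window_profile", "data.frame"),
    window_size = 1000, threshold = 99.9)
  expect_equal(delineate_tract(wp, "donor", "ref"), c(2000, 6000))
  expect_null(delineate_tract(wp, "donor", "ref", min_run = 5))
  # no donor-favoring window at all
  wp$donor <- rep(99, 10)
  expect_null(delineate_tract(wp, "donor", "ref"))
})

test_that("the catalog encodes the published constraints and is distinct", {
  cat <- config_catalog()
  expect_equal(nrow(cat), 10)
  expect_true(all(cat$NOTCH2 == "NOTCH2"))
  expect_true(all(cat$NOTCH2NLA == "NOTCH2NLA"))
  expect_equal(cat$config_label[cat$deletion_class], c("H2", "H4", "H8", "H9"))
  expect_equal(cat$config_label[cat$NOTCH2NLR == "NOTCH2tv"], c("H3", "H6"))
  expect_true(all(c("H4", "H5", "H6") %in%
                    cat$config_label[cat$NOTCH2NLB == "NOTCH2NLA"]))
  expect_true(all(c("H7", "H8") %in%
                    cat$config_label[cat$NOTCH2NLC == "absent"]))
  expect_equal(cat$config_label[cat$NOTCH2NLC == "hybrid"], "H10")
  keys <- apply(cat[, sdparalog:::CANONICAL_POSITIONS], 1, paste,
                collapse = "|")
  expect_false(anyDuplicated(keys) > 0)
  f <- tempfile(fileext = ".tsv")
  write_catalog(cat, f)
  expect_identical(read_catalog(f), cat)
})

call_for <- function(position, status, consensus = position) {
  structure(list(locus = position, position = position, status = status,
                 consensus_label = consensus,
                 igc = status == "igc",
                 donor_label = NA_character_, acceptor_label = NA_character_,
                 tract = NULL, haplotype = "hap"), class = "paralog_call")
}

hap_calls <- function(states) {
  lapply(names(states), function(p) {
    st <- states[[p]]
    if (st == "absent") {
      call_for(p, "deleted", "absent")
    } else if (st == p) {
      call_for(p, "clean", st)
    } else {
      call_for(p, "igc", st)
    }
  })
}

config_of <- function(label, catalog = config_catalog()) {
  states <- setNames(unlist(catalog[catalog$config_label == label,
                                    sdparalog:::CANONICAL_POSITIONS]),
                     sdparalog:::CANONICAL_POSITIONS)
  classify_haplotype(hap_calls(as.list(states)), catalog)
}

test_that("classification maps state vectors to catalog labels", {
  expect_equal(config_of("H1")$config_label, "H1")
  expect_equal(config_of("H2")$config_label, "H2")
  expect_equal(config_of("H6")$config_label, "H6")
  expect_equal(config_of("H10")$config_label, "H10")
  # an unknown vector is novel
  states <- as.list(setNames(
    c("NOTCH2", "NOTCH2NLR", "NOTCH2NLA", "NOTCH2NLB", "ambiguous"),
    sdparalog:::CANONICAL_POSITIONS))
  calls <- hap_calls(states[1:4])
  calls[[5]] <- call_for("NOTCH2NLC", "ambiguous", NA_character_)
  calls[[5]]$status <- "ambiguous"
  expect_equal(classify_haplotype(calls)$config_label, "novel")
  # duplicate positions error
  expect_error(classify_haplotype(c(hap_calls(as.list(setNames(
    config_catalog()[1, sdparalog:::CANONICAL_POSITIONS],
    sdparalog:::CANONICAL_POSITIONS))),
    list(call_for("NOTCH2", "clean")))), "two calls")
})

test_that("the published 69-haplotype composition reproduces the printed percentages", {
  counts <- c(H1 = 30, H2 = 13, H3 = 5, H4 = 2, H5 = 8, H6 = 2, H7 = 1,
              H8 = 4, H9 = 2, H10 = 2)
  configs <- unlist(lapply(names(counts), function(l) {
    replicate(counts[[l]], config_of(l), simplify = FALSE)
  }), recursive = FALSE)
  s <- cohort_summary(configs)
  expect_equal(s$n, 69)
  expect_equal(s$igc_union_percent, 28)  # 19/69
  expect_equal(s$igc_union_count, 19)
  expect_equal(s$lacking_nlr_percent, 43) # 30/69
  expect_equal(s$lacking_nlr_count, 30)
  expect_equal(s$deletion_percent, 30)   # 21/69
  expect_equal(s$b_to_a_percent, 20)     # 14/69
  expect_equal(s$b_to_a_count, 14)
  expect_equal(s$notch2tv_percent, 10)   # 7/69
  expect_equal(s$both_igc_count, 2)
  expect_equal(unname(s$config_percent["H1"]), 43)
  expect_equal(length(s$ab_sum_violations), 0)
})

test_that("cohort summary is permutation invariant and internally consistent", {
  counts <- c(H1 = 5, H2 = 3, H5 = 4, H7 = 2)
  configs <- unlist(lapply(names(counts), function(l) {
    replicate(counts[[l]], config_of(l), simplify = FALSE)
  }), recursive = FALSE)
  s1 <- cohort_summary(configs)
  set.seed(40)
  s2 <- cohort_summary(sample(configs))
  expect_identical(s1$config_counts, s2$config_counts)
  expect_identical(s1$igc_union_percent, s2$igc_union_percent)
  # deletion-class plus non-deletion is the whole cohort
  expect_equal(s1$deletion_count + (s1$n - s1$deletion_count), s1$n)
  # an all-canonical cohort has no conversion and no flags
  s3 <- cohort_summary(replicate(5, config_of("H1"), simplify = FALSE))
  expect_equal(s3$igc_union_count, 0)
  expect_equal(length(s3$ab_sum_violations), 0)
  expect_error(cohort_summary(list()), "empty")
})

test_that("Fisher's exact test matches brute-force hypergeometric enumeration", {
  tabs <- list(matrix(c(0, 10, 10, 0), 2, 2),
               matrix(c(5, 5, 5, 5), 2, 2),
               matrix(c(7, 30, 0, 32), 2, 2),
               matrix(c(3, 1, 2, 9), 2, 2))
  for (tab in tabs) {
    r <- enrichment_test(tab)
    expect_equal(r$p_value, fisher_p_oracle(tab), tolerance = 1e-9)
  }
  expect_equal(enrichment_test(matrix(c(0, 10, 10, 0), 2, 2))$odds_ratio, 0)
  expect_equal(enrichment_test(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  expect_equal(enrichment_test(matrix(c(5, 5, 5, 5), 2, 2))$odds_ratio, 1,
               tolerance = 1e-6)
  expect_error(enrichment_test(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "margin")
  expect_error(enrichment_test(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
})
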