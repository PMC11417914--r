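test_that("label_site applies the strict 1% increment rule", {
  # first increment 1.3 > 1.0 -> active
  s <- list(covered = TRUE, pct_t0 = 0.2, pct_1wk = 1.5, pct_2wk = 2.0,
            pct_4wk = 4, pct_8wk = 9)
  expect_equal(label_site(s)$label, "active")
  # increments exactly at 0.9 / 0.9: strictly below threshold -> inactive
  expect_equal(label_site(list(covered = TRUE, pct_t0 = 0, pct_1wk = 0.9,
                               pct_2wk = 1.8))$label, "inactive")
  # increments exactly equal to the threshold do not fire
  expect_equal(label_site(list(covered = TRUE, pct_t0 = 0, pct_1wk = 1.0,
                               pct_2wk = 2.0))$label, "inactive")
  # second-step trigger
  expect_equal(label_site(list(covered = TRUE, pct_t0 = 0, pct_1wk = 0.2,
                               pct_2wk = 1.4))$label, "active")
  # uncovered site with no extents -> inactive
  expect_equal(label_site(list(covered = FALSE))$label, "inactive")
  # regression targets copied through
  expect_equal(label_site(s)$regression_targets,
               c(pct_2wk = 2.0, pct_4wk = 4, pct_8wk = 9))
})

test_that("labeling is monotone in the early extents", {
  set.seed(11)
  for (i in 1:200) {
    ext <- sort(runif(5, 0, 20))
    tc <- data.frame(molecule_id = "m", chain_id = "c", position = 1L,
                     residue = "N", pct_t0 = ext[1], pct_1wk = ext[2],
                     pct_2wk = ext[3], pct_4wk = ext[4], pct_8wk = ext[5],
                     covered = TRUE)
    base <- label_sites(tc)$label
    bumped <- tc
    col <- sample(c("pct_1wk", "pct_2wk"), 1)
    bumped[[col]] <- min(100, bumped[[col]] + runif(1, 0, 10))
    after <- label_sites(bumped)$label
    if (base == "active" && col == "pct_1wk") next  # bump can't be assessed
    expect_false(base == "active" && after == "inactive")
  }
})

test_that("enumerate_candidate_sites scans N and Q positions", {
  expect_equal(enumerate_candidate_sites("ANGQS"),
               data.frame(position = c(2L, 4L), residue = c("N", "Q"),
                          stringsAsFactors = FALSE))
  expect_equal(nrow(enumerate_candidate_sites("AAAA")), 0)
  # brute-force character-count oracle on random chains
  set.seed(5)
  for (i in 1:20) {
    s <- random_aa_string(sample(50:400, 1))
    chars <- strsplit(s, "")[[1]]
    expect_equal(nrow(enumerate_candidate_sites(s)),
                 sum(chars == "N") + sum(chars == "Q"))
  }
})

test_that("summarize_dataset counts classes", {
  s <- summarize_dataset(data.frame(label = c(rep("active", 276),
                                              rep("inactive", 2009))))
  expect_equal(s$n_total, 2285)
  expect_equal(s$active_fraction, 276 / 2285, tolerance = 1e-12)
  expect_equal(summarize_dataset(data.frame(label = character()))$active_fraction, 0)
  expect_equal(summarize_dataset(data.frame(label = rep("active", 5)))$active_fraction, 1)
})

test_that("build_dataset joins chains with time courses", {
  chains <- toy_chains()
  labeled <- build_dataset(chains, toy_timecourse())
  n_sites <- sum(vapply(chains$sequence, function(s)
    nrow(enumerate_candidate_sites(s)), 0L))
  expect_equal(nrow(labeled), n_sites)
  expect_equal(sum(labeled$label == "active"), 1)   # only the N3 site fires
  # sites absent from the table are uncovered and inactive
  absent <- labeled[labeled$molecule_id == "mAbY", ]
  expect_true(all(!absent$covered) && all(absent$label == "inactive"))
  # empty time course -> everything inactive
  all_inactive <- build_dataset(chains, NULL)
  expect_true(all(all_inactive$label == "inactive"))
  # unresolvable rows are reported
  bad <- toy_timecourse(); bad$position[1] <- 4L  # residue there is G
  expect_error(build_dataset(chains, bad), "unresolvable",
               class = "deamid_validation_error")
})
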