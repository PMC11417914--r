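test_that("motif_classify implements the NG/NS/NN rule", {
  expect_equal(motif_classify("AANGS", 3), "active")
  expect_equal(motif_classify("AANAS", 3), "inactive")
  expect_equal(motif_classify("AANSA", 3), "active")
  expect_equal(motif_classify("AANNA", 3), "active")
  # glutamine sites are never flagged
  expect_equal(motif_classify("AAQGS", 3), "inactive")
  # chain-terminal N has no successor
  expect_equal(motif_classify("AAN", 3), "inactive")
  expect_error(motif_classify("AAAGS", 3), class = "deamid_validation_error")
  expect_error(motif_rule(c("GG")), class = "deamid_validation_error")
})

test_that("motif rule has perfect recall on a motif-defined dataset", {
  set.seed(13)
  chains <- data.frame(molecule_id = sprintf("m%d", 1:5), chain_id = "HC",
                       sequence = vapply(1:5, function(i)
                         random_aa_string(120), ""))
  labeled <- build_dataset(chains, NULL)
  labeled <- motif_classify_sites(chains, labeled)
  # define truth as exactly the motif sites, then the rule must recall all
  labeled$label <- labeled$predicted_label
  if (sum(labeled$label == "active") > 0) {
    cm <- confusion_matrix(truth = labeled$label,
                           predicted = labeled$predicted_label)
    expect_equal(compute_metrics(cm)$recall, 1)
    expect_equal(compute_metrics(cm)$precision, 1)
  }
})

test_that("probe_motifs scores all 20 amino acids per direction", {
  sim <- small_world(5)
  lab <- label_sites(sim$timecourse)
  m <- fit_deamid(sim$chains, lab, "local_only", "classification",
                  fast_config(max_epochs = 10L, pos_weight = 4))
  for (dir in c("x_plus_1", "x_minus_1")) {
    tab <- probe_motifs(m, dir)
    expect_equal(nrow(tab), 20)
    expect_true(all(tab$score >= 0 & tab$score <= 1))
    expect_true(all(diff(tab$score) <= 0))  # sorted descending
    expect_identical(tab, probe_motifs(m, dir))  # deterministic
  }
  expect_true(all(startsWith(probe_motifs(m, "x_plus_1")$motif, "N")))
  expect_true(all(endsWith(probe_motifs(m, "x_minus_1")$motif, "N")))
  # untrained or wrong-variant models are rejected
  untrained <- build_model("local_only", "classification", fast_config())
  expect_error(probe_motifs(untrained), class = "deamid_validation_error")
  g <- fit_deamid(sim$chains, lab, "global_only", "classification",
                  fast_config(max_epochs = 3L))
  expect_error(probe_motifs(g), class = "deamid_validation_error")
})
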