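test_that("Cd categories partition [0, Inf) with left-closed bounds", {
  expect_identical(assign_cd_category(c(0.5, 1.0, 3.0)),
                   c("low", "medium", "high"))
  expect_identical(assign_cd_category(0), "low")
  expect_identical(assign_cd_category(2), "high")
  expect_identical(assign_cd_category(1e6), "high")
  expect_error(assign_cd_category(-0.1), ">= 0")
  # total and single-valued over a fine sweep
  sweep_vals <- seq(0, 5, by = 0.01)
  cats <- assign_cd_category(sweep_vals)
  expect_true(all(cats %in% c("low", "medium", "high")))
  expect_identical(length(cats), length(sweep_vals))
})

test_that("activity set logic equals the exhaustive truth table", {
  # all four membership combinations for one taxon
  for (in_spiked in c(TRUE, FALSE)) {
    for (in_control in c(TRUE, FALSE)) {
      spiked <- if (in_spiked) c(tx = 1) else numeric()
      ctrl <- if (in_control) "tx" else character()
      calls <- classify_activity_responders(spiked, ctrl)
      expect_identical("tx" %in% calls$taxon_id, in_spiked && !in_control)
    }
  }
  # worked set example and the empty case
  expect_identical(classify_activity_responders(c(A = 1, B = 1), "B")$taxon_id,
                   "A")
  expect_identical(nrow(classify_activity_responders(numeric(), c("A"))), 0L)
  # signs carry through from the spiked arm
  calls <- classify_activity_responders(c(A = 1, B = -1), character())
  expect_identical(calls$direction, c("positive", "negative"))
})

test_that("response summaries reproduce the worked accounting fractions", {
  # 16 up + 11 down of 100 -> 27% responsive, 73% stable
  calls <- data.frame(
    taxon_id = paste0("t", 1:27),
    direction = rep(c("positive", "negative"), c(16, 11))
  )
  s <- summarize_response(calls, paste0("t", 1:100))
  expect_equal(s$fraction_responsive, 0.27)
  expect_equal(s$fraction_stable, 0.73)
  expect_equal(s$fraction_positive + s$fraction_negative,
               s$fraction_responsive)

  s0 <- summarize_response(calls[0, ], paste0("t", 1:100))
  expect_equal(s0$fraction_responsive, 0)
  expect_equal(s0$fraction_stable, 1)

  set.seed(4)
  for (i in 1:5) {
    k <- sample(0:50, 1)
    cl <- data.frame(taxon_id = paste0("t", seq_len(k)),
                     direction = sample(c("positive", "negative"), k,
                                        replace = TRUE))
    ss <- summarize_response(cl, paste0("t", 1:50))
    expect_lt(abs(ss$fraction_responsive + ss$fraction_stable - 1), 1e-12)
  }
  expect_error(summarize_response(calls, character()), "empty")
})

test_that("composition classification turns 6+7 significant phyla into 13 calls", {
  n_phyla <- 46
  da <- data.frame(
    taxon_id = paste0("p__", seq_len(n_phyla)),
    lfc = c(rep(1.2, 6), rep(-0.9, 7), rep(0.05, n_phyla - 13)),
    se = 0.1, W = 0, p = c(rep(1e-4, 13), rep(0.6, n_phyla - 13)),
    q = c(rep(1e-3, 13), rep(0.8, n_phyla - 13)),
    structural_zero = FALSE, zero_group = "", direction = "none",
    stringsAsFactors = FALSE
  )
  cls <- classify_composition_responders(da, alpha = 0.05, rank = "phylum")
  expect_identical(nrow(cls$calls), 13L)
  expect_identical(sum(cls$calls$direction == "positive"), 6L)
  expect_identical(sum(cls$calls$direction == "negative"), 7L)
  expect_equal(cls$summary$n_responsive, 13)
  expect_error(classify_composition_responders(da[0, ]), "empty")
})

test_that("timepoint enrichment isolates spiked-only responders", {
  p <- community_sim_params(n_taxa = 80, seed = 15, responder_lfc = log(6),
                            overdispersion = 0.25)
  sim <- simulate_timepoint_counts(
    p, enriched_taxa = c(ASV0001 = 1),
    non_response_taxa = "ASV0002", n_replicates = 10
  )
  enr <- timepoint_enrichment(sim$table, sim$metadata)
  expect_true("ASV0001" %in% names(enr$spiked))
  expect_false("ASV0001" %in% names(enr$control))
  # the both-arm grower is enriched in both arms ...
  expect_true("ASV0002" %in% names(enr$spiked))
  expect_true("ASV0002" %in% names(enr$control))
  # ... so the set logic must NOT call it responsive
  calls <- classify_activity_responders(enr$spiked, names(enr$control))
  expect_true("ASV0001" %in% calls$taxon_id)
  expect_false("ASV0002" %in% calls$taxon_id)

  # missing-timepoint contract
  keep <- sim$metadata$timepoint != "S" | sim$metadata$treatment != "spiked"
  ct2 <- count_table(sim$table$counts[, keep], sim$table$taxon_ids,
                     sim$table$samples[keep])
  expect_error(timepoint_enrichment(ct2, sim$metadata[keep, ]),
               "spiked.*timepoint S")
})

test_that("intersection enrichment rule is contained in the union rule", {
  p <- community_sim_params(n_taxa = 60, seed = 25, responder_lfc = log(5),
                            overdispersion = 0.3)
  sim <- simulate_timepoint_counts(p, enriched_taxa = c(ASV0003 = 1),
                                   n_replicates = 8)
  e_union <- timepoint_enrichment(sim$table, sim$metadata,
                                  pipeline_config(enrichment_rule = "union"))
  e_inter <- timepoint_enrichment(
    sim$table, sim$metadata, pipeline_config(enrichment_rule = "intersection")
  )
  for (arm in c("control", "spiked")) {
    expect_true(all(names(e_inter[[arm]]) %in% names(e_union[[arm]])))
  }
})

test_that("null timepoint runs rarely flag anything", {
  hits <- sapply(1:10, function(s) {
    p <- community_sim_params(n_taxa = 50, seed = 100 + s)
    sim <- simulate_timepoint_counts(p, n_replicates = 6)
    enr <- timepoint_enrichment(sim$table, sim$metadata)
    length(enr$control) + length(enr$spiked)
  })
  expect_gte(mean(hits == 0), 0.9)
})

test_that("core-taxa Venn partition matches hand enumeration", {
  # 5 taxa, 2 groups of 2 samples, abundances placed around the thresholds
  cfg <- pipeline_config(detection_threshold = 0.1,
                         prevalence_threshold = 0.5)
  m <- rbind(
    both = c(50, 50, 50, 50), # detected everywhere
    g1_only = c(30, 30, 1, 1), # above 10% only in group 1
    g2_only = c(1, 1, 30, 30),
    nowhere = c(1, 1, 1, 1), # never reaches 10%
    barely = c(20, 1, 20, 1) # 1 of 2 samples per group = prevalence 0.5
  )
  colnames(m) <- paste0("s", 1:4)
  ct <- make_ct(m)
  res <- core_taxa(ct, c("g1", "g1", "g2", "g2"), cfg)
  expect_identical(res$regions[["g1+g2"]], 2L) # both, barely
  expect_identical(res$regions[["g1"]], 1L)
  expect_identical(res$regions[["g2"]], 1L)
  expect_identical(res$n_occurring, 4L)
  expect_identical(res$shared_all, 2L)
  # partition property: region counts sum to occurring taxa
  expect_identical(sum(res$regions), res$n_occurring)

  # one group only: everything occurring is unique to it
  res1 <- core_taxa(make_ct(m[, 1:2]), c("g1", "g1"), cfg)
  expect_identical(names(res1$regions), "g1")

  expect_error(core_taxa(ct, c("g1", "g1", "g1", "g1"))$regions, NA)
})

test_that("Venn partitions stay disjoint on simulated three-category data", {
  sim <- simulate_field_experiment(community_sim_params(n_taxa = 120,
                                                        seed = 9))
  cats <- assign_cd_category(sim$metadata$cd_soil)
  res <- core_taxa(sim$table, cats, pipeline_config())
  expect_identical(sum(res$regions), res$n_occurring)
  expect_lte(res$shared_all, res$n_occurring)
})
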