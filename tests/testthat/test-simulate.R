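test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 9, n_tus = 25)
  a <- generate_genome_and_tus(cfg)
  b <- generate_genome_and_tus(cfg)
  expect_identical(a, b)
  expect_identical(generate_junction_reads(cfg), generate_junction_reads(cfg))
  expect_identical(generate_toeprint_table(cfg), generate_toeprint_table(cfg))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(c(a, generate_junction_reads(cfg)), d1)
  write_simulation(c(b, generate_junction_reads(cfg)), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("null model yields zero SD signals", {
  cfg <- sim_config(seed = 2, n_tus = 30, sd_positive_rate = list(),
                    decoy_rate = 0)
  sim <- generate_genome_and_tus(cfg)
  calls <- scan_sd_signals(sim$genome, sim$genes)
  expect_false(any(calls$passes_rule))
  expect_identical(nrow(calls), 0L)   # windows are motif-free by rejection
})

test_that("scan flags exactly the planted positives despite decoys", {
  cfg <- sim_config(seed = 13, n_tus = 60,
                    leader_class_counts = c(leaderless = 20, short_leader = 10,
                                            leadered = 30),
                    n_distal = 40,
                    sd_positive_counts = list(proximal = c(GGAGG = 5, TGAGG = 3),
                                              distal = c(GGAGG = 6, TGAGG = 4)),
                    sd_decoy_counts = list(proximal = c(GGAGG = 8, TGAGG = 6),
                                           distal = c(GGAGG = 10, TGAGG = 8)))
  sim <- generate_genome_and_tus(cfg)
  calls <- scan_sd_signals(sim$genome, sim$genes)
  flags <- gene_sd_flags(calls, gene_ids = sim$genes$gene_id)
  truth_pos <- sim$truth$planted == "positive"
  for (m in c("GGAGG", "TGAGG")) {
    want <- sort(sim$truth$gene_id[truth_pos & sim$truth$planted_motif == m])
    got <- sort(flags$gene_id[flags$motif == m & flags$has_signal])
    expect_identical(got, want)
  }
  # stratified summary equals the planted counts
  ann <- annotate_leaders(sim$tus, sim$genes)
  s <- summarize_sd(calls, ann)
  expect_identical(s$n_with_signal, c(5L, 3L, 6L, 4L))
})

test_that("positional decoys fool a naive substring counter but not the rule", {
  cfg <- sim_config(seed = 31, n_tus = 40,
                    leader_class_counts = c(leaderless = 0, short_leader = 0,
                                            leadered = 40),
                    n_distal = 0,
                    sd_positive_counts = list(proximal = c(GGAGG = 4)),
                    sd_decoy_counts = list(proximal = c(GGAGG = 12)),
                    motifs = "GGAGG")
  sim <- generate_genome_and_tus(cfg)
  windows <- extract_upstream_windows(sim$genome, sim$genes)
  naive <- sum(vapply(seq_len(nrow(windows)), function(i) {
    nrow(find_motif_occurrences(windows[i, ], "GGAGG")) > 0
  }, logical(1)))
  calls <- scan_sd_signals(sim$genome, sim$genes, motifs = "GGAGG")
  flags <- gene_sd_flags(calls, gene_ids = sim$genes$gene_id, motifs = "GGAGG")
  expect_identical(sum(flags$has_signal), 4L)     # rule recovers the truth
  expect_identical(naive, 16L)                    # substring count overcounts
  expect_gt(naive, sum(flags$has_signal))
})

test_that("planted positives land in the rule window, decoys outside it", {
  cfg <- sim_config(seed = 77, n_tus = 30,
                    leader_class_counts = c(leaderless = 0, short_leader = 0,
                                            leadered = 30),
                    n_distal = 0,
                    sd_positive_counts = list(proximal = c(GGAGG = 6)),
                    sd_decoy_counts = list(proximal = c(GGAGG = 6)))
  sim <- generate_genome_and_tus(cfg)
  pos <- sim$truth$planted_offset[sim$truth$planted == "positive"]
  dec <- sim$truth$planted_offset[sim$truth$planted == "decoy"]
  expect_true(all(pos >= -18 & pos <= -9))
  expect_true(all(dec < -18 | dec > -9))
})

test_that("infeasible planting requests fail loudly", {
  cfg <- sim_config(seed = 1, n_tus = 5,
                    leader_class_counts = c(leaderless = 0, short_leader = 0,
                                            leadered = 5),
                    n_distal = 0,
                    sd_positive_counts = list(proximal = c(GGAGG = 4)),
                    sd_decoy_counts = list(proximal = c(GGAGG = 4)))
  expect_error(generate_genome_and_tus(cfg), "infeasible")
})

test_that("junction generator realizes exact mixtures in shuffled order", {
  cfg <- sim_config(seed = 23)
  jx <- generate_junction_reads(cfg)
  expect_identical(length(jx$reads), 32L)
  calls <- classify_junction_reads(jx$reads,
                                   reference_5prime = cfg$junction$reference_5prime)
  t <- tally_variants(calls)
  expect_identical(t$n, c(27L, 1L, 3L, 1L, 0L))
  # per-read calls equal the planted truth
  m <- merge(calls, jx$truth, by = "read_id")
  expect_identical(m$variant, m$true_variant)
  # reads are not emitted grouped by variant
  expect_false(identical(jx$truth$true_variant, sort(jx$truth$true_variant)))

  cfg2 <- sim_config(seed = 4, junction = list(
    n_reads = 10L, variant_counts = c(CCUCC = 10L)))
  jx2 <- generate_junction_reads(cfg2)
  calls2 <- classify_junction_reads(jx2$reads,
                                    reference_5prime = cfg2$junction$reference_5prime)
  expect_true(all(calls2$variant == "CCUCC"))
})

test_that("toeprint generator reproduces condition means at zero noise", {
  cfg <- sim_config(seed = 6, toeprint = list(
    condition_means = list(monophosphate = c(T = 30, RT = 10)),
    n_per_condition = 4L, mrnas = "m1", noise_sd = 0))
  tp <- generate_toeprint_table(cfg)
  expect_identical(nrow(tp$lanes), 4L)
  expect_true(all(toeprint_percent(tp$lanes$T, tp$lanes$RT) == 75))
  expect_identical(tp$truth$true_percent, 75)

  cfg2 <- sim_config(seed = 6)
  tp2 <- generate_toeprint_table(cfg2)
  expect_identical(nrow(tp2$lanes), 2L * 3L * 3L)
  expect_true(all(tp2$lanes$T >= 0 & tp2$lanes$RT >= 0))
})
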