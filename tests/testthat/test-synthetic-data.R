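test_that("transcriptome generation respects structure and empty/forced cases", {
  expect_error(sim_config(orf_length_range = c(90, 30)), "orf_length_range")
  expect_error(sim_config(conversion_rate = 1.5), "conversion_rate")
  expect_error(sim_config(site_positional_bias = -1), "bias")

  empty <- generate_transcriptome(sim_config(n_transcripts = 0))
  expect_length(empty$sequences, 0)
  expect_equal(nrow(empty$annotation), 0)

  cfg <- sim_config(n_transcripts = 10, orf_length_range = c(30, 30), seed = 3)
  tx <- generate_transcriptome(cfg)
  orf_len <- tx$annotation$orf_end - tx$annotation$orf_start
  expect_true(all(orf_len == 30))
  for (i in 1:10) {
    s <- tx$sequences[[i]]
    os <- tx$annotation$orf_start[i]; oe <- tx$annotation$orf_end[i]
    expect_equal(substr(s, os + 1, os + 3), "ATG")
    expect_true(substr(s, oe - 2, oe) %in% c("TAA", "TAG", "TGA"))
    expect_equal(nchar(s), tx$annotation$total_len[i])
  }
})

test_that("identical configuration reproduces identical outputs", {
  cfg <- sim_config(seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  expect_identical(a$clip_reads, b$clip_reads)
  expect_identical(a$footprints, b$footprints)
  expect_identical(a$rna_counts, b$rna_counts)
})

test_that("planted site positions follow the positional-bias density", {
  # bias 0: uniform over the ORF (chi-square on 10 centile bins)
  cfg0 <- sim_config(n_transcripts = 100, sites_per_transcript = 20,
                     site_positional_bias = 0, motif_insertion_frame = NA,
                     seed = 11)
  tx <- generate_transcriptome(cfg0)
  tr <- plant_sites(tx, cfg0)$truth
  ai <- match(tr$transcript_id, tx$annotation$transcript_id)
  cent <- (tr$crosslink_pos - tx$annotation$orf_start[ai]) /
    (tx$annotation$orf_end[ai] - tx$annotation$orf_start[ai])
  counts <- table(cut(cent, seq(0, 1, 0.1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # bias 3: mean relative position ~ 4/5, well above 0.6
  cfg3 <- sim_config(n_transcripts = 100, sites_per_transcript = 20,
                     site_positional_bias = 3, motif_insertion_frame = NA,
                     seed = 12)
  tr3 <- plant_sites(tx, cfg3)$truth
  ai <- match(tr3$transcript_id, tx$annotation$transcript_id)
  cent3 <- (tr3$crosslink_pos - tx$annotation$orf_start[ai]) /
    (tx$annotation$orf_end[ai] - tx$annotation$orf_start[ai])
  expect_gt(mean(cent3) * 100, 60)
  expect_lt(abs(mean(cent3) - 0.8), 0.03)
})

test_that("planted motifs sit at the requested reading frame", {
  for (fr in 0:2) {
    cfg <- sim_config(n_transcripts = 30, motif_insertion_frame = fr, seed = 20 + fr)
    tx <- generate_transcriptome(cfg)
    pl <- plant_sites(tx, cfg)
    ai <- match(pl$truth$transcript_id, tx$annotation$transcript_id)
    g <- pl$truth$crosslink_pos - 2L  # consensus G two nt before the U
    expect_true(all((g - tx$annotation$orf_start[ai]) %% 3 == fr))
    base_g <- substr(pl$sequences[ai], g + 1, g + 1)
    base_u <- substr(pl$sequences[ai], pl$truth$crosslink_pos + 1,
                     pl$truth$crosslink_pos + 1)
    expect_true(all(base_g == "G"))
    expect_true(all(base_u == "T"))
  }
})

test_that("CLIP read simulation honours depth, coverage and conversion rate", {
  cfg0 <- sim_config(depth_per_site = 0, background_frac = 0, seed = 5)
  tx <- generate_transcriptome(cfg0)
  pl <- plant_sites(tx, cfg0)
  expect_equal(nrow(simulate_parclip_reads(pl$truth, tx$annotation, cfg0)), 0)

  cfg1 <- sim_config(conversion_rate = 1, background_frac = 0, seed = 5)
  reads <- simulate_parclip_reads(pl$truth, tx$annotation, cfg1)
  pos <- setNames(pl$truth$crosslink_pos, pl$truth$transcript_id)
  cp <- conversion_positions(reads)
  covers <- reads$start <= pos[reads$chrom] & pos[reads$chrom] < reads$end
  expect_true(all(covers))
  expect_true(all(mapply(function(p, tid) p == pos[[tid]], cp, reads$chrom)))

  # Poisson oracle: 20 sites x depth 50 -> total within 3 sigma of 1000
  cfg <- sim_config(depth_per_site = 50, background_frac = 0, seed = 6)
  n <- nrow(simulate_parclip_reads(pl$truth, tx$annotation, cfg))
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
})

test_that("converted-read fraction is nondecreasing in conversion rate", {
  fracs <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(r) {
    cfg <- sim_config(depth_per_site = 500, background_frac = 0,
                      conversion_rate = r, seed = 30)
    tx <- generate_transcriptome(cfg)
    pl <- plant_sites(tx, cfg)
    reads <- simulate_parclip_reads(pl$truth, tx$annotation, cfg)
    mean(lengths(reads$conversions) > 0)
  })
  expect_true(all(diff(fracs) >= 0))
  expect_equal(fracs[1], 0)
  expect_equal(fracs[5], 1)
})

test_that("footprint classes have the stated lengths and placement", {
  cfg <- sim_config(seed = 8, footprint_jitter = 0)
  tx <- generate_transcriptome(cfg)
  pl <- plant_sites(tx, cfg)
  expect_error(simulate_footprints(pl$truth, tx$annotation, cfg, "nonsense"),
               "unknown footprint class")
  std <- simulate_footprints(pl$truth, tx$annotation, cfg, "standard",
                             n_background = 0)
  expect_true(all((std$end - std$start) %in% 28:30))
  # offset 0, jitter 0: read midpoints sit on the crosslink
  cfg0 <- cfg; cfg0$footprint_offsets["disome"] <- 0
  di <- simulate_footprints(pl$truth, tx$annotation, cfg0, "disome",
                            n_background = 0)
  expect_true(all((di$end - di$start) %in% 57:63))
  pos <- setNames(pl$truth$crosslink_pos, pl$truth$transcript_id)
  expect_true(all((di$start + di$end) %/% 2 == pos[di$chrom]))
})

test_that("RNA-seq, structure-track and measurement simulators are parameter-faithful", {
  cfg <- sim_config(seed = 9)
  tx <- generate_transcriptome(cfg)
  pl <- plant_sites(tx, cfg)
  expect_error(simulate_rnaseq(tx$annotation, -1, seed = 1), ">= 0")
  cnt <- simulate_rnaseq(tx$annotation, 100, dispersion = 0, seed = 1)
  expect_equal(nrow(cnt), nrow(tx$annotation))
  expect_true(all(cnt$count >= 0))

  flat <- simulate_pars_track(tx$annotation, pl$truth, baseline = 0.4,
                              site_boost = 0, noise_sd = 0, seed = 2)
  expect_true(all(flat$score == 0.4))

  # zero-noise reporters invert exactly through the quantification ops
  dlr <- simulate_reporter_table(c(UGA = 2), noise_cv = 0, seed = 1)
  rt <- readthrough_percent(dlr, "UGA")
  expect_equal(rt$mean_pct, 2)

  cq <- simulate_qpcr_table(c(1, 1, 2), noise_sd = 0, seed = 1)
  by_fr <- cq[cq$replicate == 1, ]
  expect_equal(by_fr$cq[3] - by_fr$cq[1], -1)  # 2x amount = exactly 1 cycle earlier
  expect_equal(by_fr$cq[2], by_fr$cq[1])
})
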