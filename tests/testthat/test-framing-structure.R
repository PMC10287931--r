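test_that("degenerate motif scanning enumerates all matches", {
  expect_equal(scan_motif("TGGT")$match_start, 0L)
  expect_equal(scan_motif("TGGT")$g_position, 1L)
  expect_equal(nrow(scan_motif("AGGT")), 0)          # A not in Y
  expect_equal(scan_motif("CGCTCGCT")$match_start, c(0L, 4L))
  expect_error(scan_motif("TGGT", pattern = "YGXU"), "non-IUPAC")

  h <- scan_motif("AATGGTAA", interval = c(2L, 8L))
  expect_equal(h$match_start, 2L)
  expect_equal(nrow(scan_motif("AATGGTAA", interval = c(0L, 5L))), 0)  # must fit inside
})

test_that("motif scanning matches a position-by-position oracle", {
  set.seed(51)
  for (k in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    pat <- sample(c("YGSU", "GGU", "RNYT", "TGA"), 1)
    expect_identical(scan_motif(s, pat)$match_start, oracle_scan_motif(s, pat))
  }
})

ann <- data.frame(transcript_id = "t1", utr5_len = 30L, orf_start = 30L,
                  orf_end = 330L, total_len = 400L, stringsAsFactors = FALSE)

test_that("frame attribution is mod-3 and shift-invariant", {
  h <- data.frame(transcript_id = "t1", g_position = 35L)  # (35-30) %% 3 = 2
  fd <- frame_distribution(h, ann)
  expect_equal(unname(fd$proportions), c(0, 0, 1))
  expect_equal(sum(fd$proportions), 1)

  shifted <- ann; shifted$orf_start <- 33L; shifted$utr5_len <- 33L
  h2 <- data.frame(transcript_id = "t1", g_position = 38L)
  expect_equal(frame_distribution(h2, shifted)$proportions, fd$proportions)

  out <- data.frame(transcript_id = "t1", g_position = c(35L, 350L))
  expect_equal(frame_distribution(out, ann)$n_skipped, 1)
})

test_that("planted motif frames dominate site hits over an even ORFome baseline", {
  cfg <- sim_config(n_transcripts = 40, motif_insertion_frame = 0, seed = 52)
  tx <- generate_transcriptome(cfg)
  pl <- plant_sites(tx, cfg)
  reads <- simulate_parclip_reads(pl$truth, tx$annotation, cfg)
  sites <- call_sites(reads, sequences = pl$sequences)
  hits <- site_motif_hits(sites, pl$sequences)
  # per-site statistic: each site votes through its mode-proximal hit
  fd <- frame_distribution(hits, tx$annotation, per_site_top = TRUE)
  expect_gt(fd$proportions["0"], 0.8)
  # per-hit tally still favours the planted frame over the other two
  fh <- frame_distribution(hits, tx$annotation)
  expect_gt(fh$proportions["0"], max(fh$proportions[c("1", "2")]))
  base <- orfome_frame_baseline(pl$sequences, tx$annotation)
  expect_lt(max(base$proportions), 0.5)
  expect_equal(sum(base$proportions), 1)
})

test_that("site edge frames follow the coordinates", {
  s <- data.frame(chrom = "t1", start = 30L, end = 41L, name = "s1",
                  strand = "+", read_count = 5L, conversion_count = 2L,
                  conversion_read_count = 2L, mode_location = 35L,
                  stringsAsFactors = FALSE)
  ef <- edge_frames(s, ann)
  expect_equal(unname(ef$leading), c(1, 0, 0))        # frame 0
  expect_equal(unname(ef$trailing), c(0, 1, 0))       # (40-30) %% 3 = 1

  # sites planted at codon boundaries give all-leading-frame-0
  starts <- ann$orf_start + 3L * (0:49)
  sc <- data.frame(chrom = "t1", start = starts, end = starts + 12L,
                   name = sprintf("s%02d", 1:50), strand = "+",
                   read_count = 5L, conversion_count = 2L,
                   conversion_read_count = 2L, mode_location = starts + 5L,
                   stringsAsFactors = FALSE)
  sc <- sc[sc$end <= ann$orf_end, ]
  expect_equal(unname(edge_frames(sc, ann)$leading["0"]), 1)

  set.seed(53)
  ru <- data.frame(chrom = "t1", start = ann$orf_start + sample(0:270, 300, TRUE),
                   strand = "+", stringsAsFactors = FALSE)
  ru$end <- ru$start + 12L
  ru$name <- sprintf("r%03d", 1:300)
  ru$read_count <- 5L; ru$conversion_count <- 2L
  ru$conversion_read_count <- 2L; ru$mode_location <- ru$start + 5L
  ru <- ru[ru$end <= ann$orf_end, ]
  lead <- edge_frames(ru, ann)$leading
  expect_true(all(abs(lead - 1 / 3) < 0.1))
})

test_that("structure window sums are exact", {
  track <- data.frame(transcript_id = "t1", pos = 0:199, score = 0.5)
  expect_equal(pars30(track, "t1", 10L), 15)
  expect_equal(pars_mean(track, "t1", 0L, 200L), 0.5)
  expect_true(is.na(pars30(track, "t1", 180L)))  # runs off the track

  set.seed(54)
  for (k in 1:10) {
    sc <- rnorm(200)
    tr <- data.frame(transcript_id = "t1", pos = 0:199, score = sc)
    ws <- sample(0:170, 1)
    expect_equal(pars30(tr, "t1", ws), sum(sc[(ws + 1):(ws + 30)]))
  }

  w <- pars30_around_mode(track, "t1", 60L)
  expect_equal(unname(w), c(15, 15, 15))
  # windows tile [-45, +45) without gap or overlap
  expect_equal(sum(w), pars_mean(track, "t1", 15L, 105L) * 90)
})

test_that("planted structure boost elevates the central window", {
  cfg <- sim_config(n_transcripts = 100, sites_per_transcript = 2, seed = 55)
  tx <- generate_transcriptome(cfg)
  pl <- plant_sites(tx, cfg)
  track <- simulate_pars_track(tx$annotation, pl$truth, baseline = 0.2,
                               site_boost = 1, noise_sd = 0.5, seed = 56)
  ws <- t(mapply(function(tid, pos) pars30_around_mode(track, tid, pos),
                 pl$truth$transcript_id, pl$truth$crosslink_pos))
  ok <- stats::complete.cases(ws)
  expect_gt(sum(ok), 150)
  expect_lt(rank_compare(ws[ok, "site"], ws[ok, "upstream"])$p.value, 0.01)
  expect_lt(rank_compare(ws[ok, "site"], ws[ok, "downstream"])$p.value, 0.01)
  expect_gt(median(ws[ok, "site"]), median(ws[ok, "upstream"]))
})
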