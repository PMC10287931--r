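test_that("read length filter keeps reads of at least min_len", {
  reads <- make_reads("t1", c(0, 0, 0), c(12, 13, 14))
  out <- filter_reads(reads, 13)
  expect_equal(out$end, c(13L, 14L))
  expect_equal(attr(out, "n_discarded"), 1L)
  expect_equal(nrow(filter_reads(make_reads("t1", integer(0), integer(0)))), 0)
  expect_equal(nrow(filter_reads(reads, 1)), 3)
})

test_that("read grouping is transitive, strand-separated and thresholded", {
  four <- make_reads("t1", c(0, 5, 10, 15), c(20, 25, 30, 35))
  expect_length(group_reads(four, 5), 0)

  five_plus_one <- make_reads("t1", c(0, 5, 10, 15, 18, 100),
                              c(20, 25, 30, 35, 38, 120))
  g <- group_reads(five_plus_one, 5)
  expect_length(g, 1)
  expect_equal(nrow(g[[1]]), 5)
  expect_equal(attr(g[[1]], "start"), 0L)
  expect_equal(attr(g[[1]], "end"), 38L)

  both <- make_reads("t1", rep(c(0, 5, 10, 15, 18), 2), rep(c(20, 25, 30, 35, 38), 2),
                     strand = rep(c("+", "-"), each = 5))
  g2 <- group_reads(both, 5)
  expect_length(g2, 2)
  expect_setequal(vapply(g2, function(x) attr(x, "strand"), character(1)),
                  c("+", "-"))
})

test_that("density estimation matches brute-force kernel sums", {
  set.seed(1)
  for (k in 1:10) {
    inst <- random_read_instance(n_reads = 12, with_seq = k %% 2 == 0)
    g <- group_reads(filter_reads(inst$reads), 1)  # keep all groups
    for (grp in g) {
      seqc <- if (is.null(inst$sequences)) NULL else inst$sequences$t1
      prof <- estimate_densities(grp, bandwidth = 3, min_depth = 1, seqc)
      chars <- if (is.null(seqc)) NULL else strsplit(seqc, "")[[1]]
      conv <- unlist(conversion_positions(grp))
      bg <- unlist(lapply(seq_len(nrow(grp)), function(i) {
        cov <- grp$start[i]:(grp$end[i] - 1)
        if (!is.null(chars)) cov <- cov[chars[cov + 1] == "T"]
        setdiff(cov, conversion_positions(grp)[[i]])
      }))
      for (p in sample(prof$positions, min(6, length(prof$positions)))) {
        i <- match(p, prof$positions)
        s_exp <- if (length(conv)) sum(dnorm(p - conv, sd = 3)) / length(conv) else 0
        b_exp <- if (length(bg)) sum(dnorm(p - bg, sd = 3)) / length(bg) else 0
        expect_equal(prof$signal[i], s_exp, tolerance = 1e-9)
        expect_equal(prof$background[i], b_exp, tolerance = 1e-9)
      }
    }
  }
})

test_that("density edge cases: no conversions, single conversion peak", {
  g <- group_reads(make_stack(n = 6, n_conv = 0), 5)[[1]]
  prof <- estimate_densities(g)
  expect_true(all(prof$signal == 0))
  expect_true(all(prof$ratio[prof$defined] == 0))

  g1 <- group_reads(make_stack(n = 6, n_conv = 1, conv_pos = 110), 5)[[1]]
  prof1 <- estimate_densities(g1, bandwidth = 0.5, min_depth = 1)
  expect_equal(prof1$positions[which.max(prof1$ratio)], 110)
  expect_error(estimate_densities(g1, bandwidth = 0), "bandwidth")
})

test_that("mode location is the leftmost argmax of the signal ratio", {
  prof <- structure(list(positions = 10:13, ratio = c(0.2, 0.9, 0.9, 0.5),
                         defined = rep(TRUE, 4), capable = rep(TRUE, 4)),
                    class = "density_profile")
  expect_equal(mode_location(prof), 11)
  prof$ratio <- rep(0.4, 4)
  expect_equal(mode_location(prof), 10)
  prof$defined <- c(FALSE, FALSE, TRUE, FALSE)
  expect_equal(mode_location(prof), 12)
  prof$defined <- rep(FALSE, 4)
  expect_error(mode_location(prof), "no defined ratio")
})

test_that("cluster thresholds accept and reject as the parameterization states", {
  # a clean 20-nt stack with 3 converted reads is one accepted site
  reads <- make_stack(n = 8, n_conv = 3, conv_pos = 110)
  s <- call_sites(reads)
  expect_equal(nrow(s), 1)
  expect_equal(s$mode_location, 110)
  expect_equal(s$conversion_count, 3)
  expect_gte(s$end - s$start, 11)

  # only 1 conversion: rejected
  expect_equal(nrow(call_sites(make_stack(n = 8, n_conv = 1))), 0)

  # 4 overlapping reads: below the group threshold
  expect_equal(nrow(call_sites(make_stack(n = 4, n_conv = 3))), 0)

  # reads shorter than 13 nt are dropped before grouping
  expect_equal(nrow(call_sites(make_stack(len = 12, n = 8, n_conv = 3,
                                          conv_pos = 105))), 0)

  # depth>=5 span of 150 nt: cluster too large, filtered out
  wide <- make_reads("t1", rep(seq(0, 130, by = 10), each = 6),
                     rep(seq(0, 130, by = 10), each = 6) + 20,
                     conversions = rep(list(10L), 84))
  sw <- call_sites(wide)
  expect_equal(nrow(sw), 0)

  # same construction trimmed to 60 nt passes the width filter
  narrow <- make_reads("t1", rep(seq(0, 40, by = 10), each = 6),
                       rep(seq(0, 40, by = 10), each = 6) + 20,
                       conversions = rep(list(10L), 30))
  expect_equal(nrow(call_sites(narrow)), 1)
})

test_that("caller output matches the brute-force oracle on random instances", {
  set.seed(99)
  for (k in 1:40) {
    inst <- random_read_instance(n_reads = sample(5:50, 1),
                                 with_seq = k %% 2 == 0)
    got <- sort_sites(call_sites(inst$reads, sequences = inst$sequences))
    want <- oracle_call_sites(inst$reads, sequences = inst$sequences)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("accepted sites always satisfy the record invariants", {
  set.seed(7)
  for (k in 1:20) {
    inst <- random_read_instance(n_reads = 40)
    s <- call_sites(inst$reads)
    if (nrow(s) == 0) next
    w <- s$end - s$start
    expect_true(all(w >= 11 & w <= 100))
    expect_true(all(s$conversion_count >= 2))
    expect_true(all(s$conversion_read_count >= 2))
    expect_true(all(s$mode_location >= s$start & s$mode_location < s$end))
    expect_true(all(s$read_count >= 5))
  }
})

test_that("adding a conversion-bearing read preserves existing site modes as candidates", {
  set.seed(17)
  candidate_positions <- function(reads) {
    unlist(lapply(group_reads(filter_reads(reads), 5), function(g) {
      prof <- estimate_densities(g)
      prof$positions[prof$defined & prof$signal > prof$background]
    }))
  }
  for (k in 1:15) {
    inst <- random_read_instance(n_reads = 30)
    s <- call_sites(inst$reads)
    if (nrow(s) == 0) next
    extra <- make_reads("t1", s$mode_location[1] - 8L, s$mode_location[1] + 8L,
                        conversions = list(8L))
    extra$name <- "extra"
    aug <- rbind(inst$reads, extra)
    expect_true(all(s$mode_location %in% candidate_positions(aug)))
  }
})
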