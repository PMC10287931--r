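#' Simulation configuration
#'
#' Holds every parameter of the synthetic dataset generator. Defaults are the
#' regime the pipeline is validated in: a small yeast-like transcriptome, one
#' crosslink site per transcript with a 3'-ORF positional bias, PAR-CLIP
#' reads of 13-40 nt converting at the crosslink in half of the overlapping
#' reads, 10% conversion-free background reads, and footprint classes
#' centered on the site mode (disomes offset +30 nt, roughly one ribosome
#' downstream).
#'
#' @param n_transcripts number of transcripts.
#' @param utr5_length_range,orf_length_range,utr3_length_range integer pairs
#'   (min, max) in nt; ORF lengths are rounded down to multiples of 3 and
#'   include the start and stop codons.
#' @param site_positional_bias exponent `b >= 0`; crosslink positions are
#'   sampled within the ORF with density proportional to
#'   `((pos - orf_start)/orf_len)^b`, so `b = 0` is uniform and larger `b`
#'   skews sites toward the ORF 3' end.
#' @param motif_insertion_frame `0`, `1`, `2`, or `NA`. When not `NA`, a YGSU
#'   motif instance is written into the sequence at each planted site with
#'   the consensus G at this codon frame; the crosslink falls on the motif U.
#'   When `NA`, no motif is planted and the crosslink base is forced to T.
#' @param conversion_rate probability that a read overlapping the crosslink
#'   carries a T-to-C conversion there.
#' @param read_length_range CLIP read lengths, drawn uniformly (nt).
#' @param depth_per_site expected (Poisson) read count per planted site.
#' @param background_frac background reads as a fraction of expected site
#'   reads; background reads are uniform along transcripts and carry no
#'   conversions.
#' @param footprint_offsets named numeric: offset of each footprint class
#'   center from the crosslink position (nt).
#' @param footprint_jitter SD (nt) of the Gaussian jitter on footprint
#'   centers.
#' @param rna_abundance_dispersion negative-binomial dispersion of simulated
#'   RNA-seq counts; `0` gives Poisson counts.
#' @param sites_per_transcript planted crosslink sites per transcript.
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_transcripts = 20,
                       utr5_length_range = c(30L, 80L),
                       orf_length_range = c(300L, 900L),
                       utr3_length_range = c(50L, 150L),
                       site_positional_bias = 3,
                       motif_insertion_frame = 0L,
                       conversion_rate = 0.5,
                       read_length_range = c(13L, 40L),
                       depth_per_site = 50,
                       background_frac = 0.1,
                       footprint_offsets = c(standard = 0, short = 0, disome = 30),
                       footprint_jitter = 2,
                       rna_abundance_dispersion = 0.1,
                       sites_per_transcript = 1L,
                       seed = 1L) {
  chk_range <- function(r, nm, lo = 1L) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < lo)
      stop("invalid ", nm, ": must be a (min, max) pair with min <= max", call. = FALSE)
    as.integer(r)
  }
  if (n_transcripts < 0) stop("n_transcripts must be >= 0", call. = FALSE)
  if (site_positional_bias < 0) stop("site_positional_bias must be >= 0", call. = FALSE)
  if (conversion_rate < 0 || conversion_rate > 1)
    stop("conversion_rate must be in [0, 1]", call. = FALSE)
  if (!is.na(motif_insertion_frame) && !motif_insertion_frame %in% 0:2)
    stop("motif_insertion_frame must be 0, 1, 2 or NA", call. = FALSE)
  if (depth_per_site < 0 || background_frac < 0)
    stop("depth_per_site and background_frac must be >= 0", call. = FALSE)
  if (rna_abundance_dispersion < 0)
    stop("rna_abundance_dispersion must be >= 0", call. = FALSE)
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    utr5_length_range = chk_range(utr5_length_range, "utr5_length_range", 0L),
    orf_length_range = chk_range(orf_length_range, "orf_length_range", 9L),
    utr3_length_range = chk_range(utr3_length_range, "utr3_length_range", 0L),
    site_positional_bias = site_positional_bias,
    motif_insertion_frame = if (is.na(motif_insertion_frame)) NA_integer_ else as.integer(motif_insertion_frame),
    conversion_rate = conversion_rate,
    read_length_range = chk_range(read_length_range, "read_length_range"),
    depth_per_site = depth_per_site,
    background_frac = background_frac,
    footprint_offsets = footprint_offsets,
    footprint_jitter = footprint_jitter,
    rna_abundance_dispersion = rna_abundance_dispersion,
    sites_per_transcript = as.integer(sites_per_transcript),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_transcripts, "transcripts,",
      x$sites_per_transcript, "site(s)/transcript, bias",
      x$site_positional_bias, "\n")
  cat("  conversion_rate", x$conversion_rate,
      "| depth/site", x$depth_per_site,
      "| background", x$background_frac,
      "| seed", x$seed, "\n")
  invisible(x)
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                    b3 = c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

sample_range <- function(r, n) {
  if (r[1] == r[2]) rep(r[1], n) else sample(seq.int(r[1], r[2]), n, replace = TRUE)
}

#' Generate a toy transcriptome
#'
#' Builds `n_transcripts` plus-strand transcript sequences, each a 5'UTR, an
#' ORF (ATG start, sense codons, one stop codon, length divisible by 3) and a
#' 3'UTR, together with the 0-based half-open annotation table.
#'
#' @param cfg a [sim_config()].
#' @return a list with `sequences` (named character vector) and `annotation`
#'   (data.frame: transcript_id, utr5_len, orf_start, orf_end, total_len).
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  if (n == 0L) {
    return(list(sequences = setNames(character(0), character(0)),
                annotation = data.frame(transcript_id = character(0),
                                        utr5_len = integer(0),
                                        orf_start = integer(0),
                                        orf_end = integer(0),
                                        total_len = integer(0))))
  }
  u5 <- sample_range(cfg$utr5_length_range, n)
  orf <- (sample_range(cfg$orf_length_range, n) %/% 3L) * 3L
  u3 <- sample_range(cfg$utr3_length_range, n)
  ids <- sprintf("t%03d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i) {
    n_codons <- orf[i] %/% 3L
    paste0(
      paste(sample(c("A", "C", "G", "T"), u5[i], replace = TRUE), collapse = ""),
      "ATG",
      paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), collapse = ""),
      sample(STOP_CODONS, 1L),
      paste(sample(c("A", "C", "G", "T"), u3[i], replace = TRUE), collapse = ""))
  }, character(1))
  names(seqs) <- ids
  ann <- data.frame(transcript_id = ids, utr5_len = u5, orf_start = u5,
                    orf_end = u5 + orf, total_len = u5 + orf + u3,
                    stringsAsFactors = FALSE)
  list(sequences = seqs, annotation = ann)
}

#' Plant crosslink sites with known truth
#'
#' Samples crosslink positions within each ORF with density proportional to
#' `x^bias` (x = relative ORF position), optionally writes a YGSU motif
#' instance into the sequence with its consensus G at a fixed codon frame
#' (the crosslink then sits on the motif U), and returns the ground-truth
#' table alongside the (possibly edited) sequences.
#'
#' @param transcriptome result of [generate_transcriptome()].
#' @param cfg a [sim_config()].
#' @return list with `truth` (data.frame: transcript_id, crosslink_pos,
#'   motif_present, motif_frame) and `sequences` (edited copy).
#' @export
plant_sites <- function(transcriptome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- transcriptome$annotation
  if (nrow(ann) == 0L) stop("annotation is empty", call. = FALSE)
  if (cfg$site_positional_bias < 0) stop("bias must be >= 0", call. = FALSE)
  set.seed(cfg$seed + 101L)
  seqs <- transcriptome$sequences
  bias <- cfg$site_positional_bias
  frame <- cfg$motif_insertion_frame
  rows <- vector("list", nrow(ann) * cfg$sites_per_transcript)
  k <- 0L
  for (i in seq_len(nrow(ann))) {
    orf_start <- ann$orf_start[i]
    orf_len <- ann$orf_end[i] - orf_start
    for (s in seq_len(cfg$sites_per_transcript)) {
      # inverse-CDF sample from density x^bias on (0,1)
      x <- runif(1)^(1 / (bias + 1))
      pos <- orf_start + floor(x * orf_len)
      pos <- min(max(pos, orf_start + 5L), ann$orf_end[i] - 2L)
      if (!is.na(frame)) {
        # motif occupies [pos-3, pos+1); G at pos-2 must be at `frame`
        shift <- (pos - 2L - orf_start - frame) %% 3L
        pos <- pos - shift
        if (pos - 3L < orf_start) pos <- pos + 3L
        motif <- paste0(sample(c("C", "T"), 1L), "G", sample(c("G", "C"), 1L), "T")
        substr(seqs[i], pos - 2L, pos + 1L) <- motif  # 1-based substr of [pos-3, pos+1)
      } else {
        substr(seqs[i], pos + 1L, pos + 1L) <- "T"
      }
      k <- k + 1L
      rows[[k]] <- data.frame(transcript_id = ann$transcript_id[i],
                              crosslink_pos = as.integer(pos),
                              motif_present = !is.na(frame),
                              motif_frame = if (is.na(frame)) NA_integer_ else frame,
                              stringsAsFactors = FALSE)
    }
  }
  list(truth = do.call(rbind, rows), sequences = seqs)
}

empty_reads <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), score = integer(0), strand = character(0),
             conversions = I(list()), stringsAsFactors = FALSE)
}

#' Simulate PAR-CLIP reads with T-to-C conversions
#'
#' For each planted site, `Poisson(depth_per_site)` reads of uniform length
#' are placed so that each covers the crosslink position; each such read
#' carries a conversion at the crosslink with probability `conversion_rate`.
#' Background reads (uniform along transcripts, never converted) are added at
#' `background_frac` times the expected site-read total.
#'
#' @param truth truth table from [plant_sites()].
#' @param annotation transcriptome annotation.
#' @param cfg a [sim_config()].
#' @return a conversion-read table (chrom, start, end, name, score, strand,
#'   conversions list-column of 0-based offsets from read start).
#' @export
simulate_parclip_reads <- function(truth, annotation, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 202L)
  total_len <- setNames(annotation$total_len, annotation$transcript_id)
  out <- list()
  ridx <- 0L
  if (nrow(truth) > 0L && cfg$depth_per_site > 0) {
    for (i in seq_len(nrow(truth))) {
      tid <- truth$transcript_id[i]
      pos <- truth$crosslink_pos[i]
      tlen <- total_len[[tid]]
      n <- rpois(1L, cfg$depth_per_site)
      if (n == 0L) next
      len <- sample_range(cfg$read_length_range, n)
      lo <- pmax(0L, pos - len + 1L)
      hi <- pmin(pos, tlen - len)
      start <- lo + floor(runif(n) * (hi - lo + 1L))
      conv <- runif(n) < cfg$conversion_rate
      offs <- ifelse(conv, pos - start, NA_integer_)
      df <- data.frame(chrom = tid, start = as.integer(start),
                       end = as.integer(start + len),
                       name = sprintf("s%04d_%03d", i, seq_len(n)),
                       score = 0L, strand = "+", stringsAsFactors = FALSE)
      df$conversions <- I(lapply(seq_len(n), function(j)
        if (conv[j]) as.integer(offs[j]) else integer(0)))
      ridx <- ridx + 1L
      out[[ridx]] <- df
    }
  }
  exp_site <- nrow(truth) * cfg$depth_per_site
  n_bg <- if (cfg$background_frac > 0 && exp_site > 0)
    rpois(1L, cfg$background_frac * exp_site) else 0L
  if (n_bg > 0L) {
    tid <- sample(annotation$transcript_id, n_bg, replace = TRUE,
                  prob = annotation$total_len)
    len <- sample_range(cfg$read_length_range, n_bg)
    tlen <- total_len[tid]
    start <- floor(runif(n_bg) * pmax(1L, tlen - len + 1L))
    df <- data.frame(chrom = tid, start = as.integer(start),
                     end = as.integer(start + len),
                     name = sprintf("bg%05d", seq_len(n_bg)),
                     score = 0L, strand = "+", stringsAsFactors = FALSE)
    df$conversions <- I(replicate(n_bg, integer(0), simplify = FALSE))
    ridx <- ridx + 1L
    out[[ridx]] <- df
  }
  if (ridx == 0L) return(empty_reads())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Footprint class length ranges (nt)
#'
#' Standard monosome footprints are 28-30 nt (A-site occupied), short
#' footprints 20-22 nt (rotated ribosome, empty A site), disome footprints
#' 57-63 nt (two collided ribosomes).
#' @export
FOOTPRINT_CLASSES <- list(standard = 28:30, short = 20:22, disome = 57:63)

#' Simulate ribosome footprint reads of one length class
#'
#' Site reads have lengths drawn uniformly from the class range and centers
#' at `crosslink_pos + offset` plus Gaussian jitter; background reads are
#' uniform along ORFs.
#'
#' @param truth truth table from [plant_sites()].
#' @param annotation transcriptome annotation.
#' @param cfg a [sim_config()].
#' @param class one of `"standard"`, `"short"`, `"disome"`.
#' @param depth expected site reads per site (default `cfg$depth_per_site`).
#' @param n_background exact background read count; default draws
#'   `Poisson(background_frac * depth * n_sites)`.
#' @param jitter center jitter SD in nt (default `cfg$footprint_jitter`).
#' @return a read table (BED6 columns plus empty conversions).
#' @export
simulate_footprints <- function(truth, annotation, cfg, class,
                                depth = cfg$depth_per_site,
                                n_background = NULL,
                                jitter = cfg$footprint_jitter) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!class %in% names(FOOTPRINT_CLASSES))
    stop("unknown footprint class: ", class, call. = FALSE)
  lens <- FOOTPRINT_CLASSES[[class]]
  offset <- cfg$footprint_offsets[[class]]
  set.seed(cfg$seed + 303L + match(class, names(FOOTPRINT_CLASSES)))
  total_len <- setNames(annotation$total_len, annotation$transcript_id)
  out <- list(); ridx <- 0L
  if (nrow(truth) > 0L && depth > 0) {
    for (i in seq_len(nrow(truth))) {
      tid <- truth$transcript_id[i]
      tlen <- total_len[[tid]]
      n <- rpois(1L, depth)
      if (n == 0L) next
      len <- sample(lens, n, replace = TRUE)
      center <- truth$crosslink_pos[i] + offset +
        if (jitter > 0) round(rnorm(n, 0, jitter)) else 0
      start <- pmin(pmax(as.integer(center - len %/% 2L), 0L), tlen - len)
      df <- data.frame(chrom = tid, start = start, end = start + len,
                       name = sprintf("%s%04d_%03d", substr(class, 1, 2), i, seq_len(n)),
                       score = 0L, strand = "+", stringsAsFactors = FALSE)
      df$conversions <- I(replicate(n, integer(0), simplify = FALSE))
      ridx <- ridx + 1L; out[[ridx]] <- df
    }
  }
  if (is.null(n_background)) {
    exp_site <- nrow(truth) * depth
    n_background <- if (cfg$background_frac > 0 && exp_site > 0)
      rpois(1L, cfg$background_frac * exp_site) else 0L
  }
  if (n_background > 0L) {
    orf_len <- annotation$orf_end - annotation$orf_start
    tid <- sample(annotation$transcript_id, n_background, replace = TRUE, prob = orf_len)
    ai <- match(tid, annotation$transcript_id)
    len <- sample(lens, n_background, replace = TRUE)
    center <- annotation$orf_start[ai] +
      floor(runif(n_background) * (annotation$orf_end[ai] - annotation$orf_start[ai]))
    start <- pmin(pmax(as.integer(center - len %/% 2L), 0L), annotation$total_len[ai] - len)
    df <- data.frame(chrom = tid, start = start, end = start + len,
                     name = sprintf("fbg%05d", seq_len(n_background)),
                     score = 0L, strand = "+", stringsAsFactors = FALSE)
    df$conversions <- I(replicate(n_background, integer(0), simplify = FALSE))
    ridx <- ridx + 1L; out[[ridx]] <- df
  }
  if (ridx == 0L) return(empty_reads())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate total RNA-seq counts
#'
#' @param annotation transcriptome annotation.
#' @param abundances expected count per transcript (recycled if scalar).
#' @param dispersion NB dispersion; 0 gives Poisson.
#' @param seed integer seed.
#' @return data.frame transcript_id, count.
#' @export
simulate_rnaseq <- function(annotation, abundances, dispersion = 0, seed = 1L) {
  if (any(abundances < 0)) stop("abundances must be >= 0", call. = FALSE)
  set.seed(seed)
  mu <- rep_len(abundances, nrow(annotation))
  count <- if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
           else rpois(length(mu), mu)
  data.frame(transcript_id = annotation$transcript_id, count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Simulate a per-nucleotide structure-score (PARS-like) track
#'
#' Baseline score with optional Gaussian noise, elevated by `site_boost`
#' within +/-15 nt of each planted crosslink (one footprint width).
#'
#' @param annotation transcriptome annotation.
#' @param truth truth table (may have zero rows).
#' @param baseline baseline score.
#' @param site_boost additive boost at planted sites.
#' @param noise_sd Gaussian noise SD (0 = exact baseline).
#' @param seed integer seed.
#' @return data.frame transcript_id, pos, score.
#' @export
simulate_pars_track <- function(annotation, truth, baseline = 0.2,
                                site_boost = 1, noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    tlen <- annotation$total_len[i]
    score <- rep(baseline, tlen)
    if (noise_sd > 0) score <- score + rnorm(tlen, 0, noise_sd)
    th <- truth[truth$transcript_id == annotation$transcript_id[i], , drop = FALSE]
    for (p in th$crosslink_pos) {
      w <- intersect(seq.int(p - 15L, p + 14L), seq.int(0L, tlen - 1L))
      score[w + 1L] <- score[w + 1L] + site_boost
    }
    data.frame(transcript_id = annotation$transcript_id[i],
               pos = seq.int(0L, tlen - 1L), score = score,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a dual-luciferase measurement table
#'
#' Control reporters (CAA for readthrough, frame0 for frameshift) are given a
#' fixed Fluc/Rluc ratio; each test reporter's ratio is `rate/100` times its
#' control's. Multiplicative lognormal noise of coefficient of variation
#' `noise_cv` is applied to Fluc. With `noise_cv = 0` the quantification
#' operations recover the planted rates exactly.
#'
#' @param true_rates named percentages, e.g.
#'   `c(UAA = 0.5, UAG = 1, UGA = 2, fs_minus1 = 5, fs_plus1 = 8)`.
#' @param noise_cv coefficient of variation of the Fluc noise.
#' @param seed integer seed.
#' @param n_replicates replicates per reporter.
#' @param strain,condition labels copied into the table.
#' @return data.frame strain, condition, reporter, replicate, fluc, rluc.
#' @export
simulate_reporter_table <- function(true_rates, noise_cv = 0, seed = 1L,
                                    n_replicates = 3L, strain = "WT",
                                    condition = "UT") {
  if (any(true_rates < 0)) stop("true_rates must be >= 0", call. = FALSE)
  set.seed(seed)
  control_ratio <- 0.5
  rluc <- 1e6
  reporters <- c(names(true_rates), "CAA", "frame0")
  ratios <- c(true_rates / 100 * control_ratio,
              CAA = control_ratio, frame0 = control_ratio)
  rows <- lapply(seq_along(reporters), function(i) {
    fl <- ratios[[i]] * rluc
    if (noise_cv > 0) fl <- fl * exp(rnorm(n_replicates, 0, noise_cv))
    else fl <- rep(fl, n_replicates)
    data.frame(strain = strain, condition = condition,
               reporter = reporters[i], replicate = seq_len(n_replicates),
               fluc = fl, rluc = rluc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Simulate a qPCR Cq table over gradient fractions
#'
#' Cq values follow `Cq = cq0 - log(amount)/log(E)` for the target and a
#' constant spike-in Cq per fraction (equal spike amount in every fraction),
#' so with zero noise the efficiency-corrected quantification recovers the
#' planted fraction distribution exactly.
#'
#' @param true_fractions relative target amount per fraction (length =
#'   number of fractions).
#' @param efficiencies named amplification factors `c(target = 2, spike = 2)`.
#' @param noise_sd Gaussian noise SD on Cq cycles.
#' @param seed integer seed.
#' @param n_replicates replicates per fraction.
#' @param target target gene label.
#' @return data.frame target, fraction, replicate, cq, spike_cq.
#' @export
simulate_qpcr_table <- function(true_fractions, efficiencies = c(target = 2, spike = 2),
                                noise_sd = 0, seed = 1L, n_replicates = 3L,
                                target = "GENE1") {
  if (any(true_fractions < 0)) stop("true_fractions must be >= 0", call. = FALSE)
  if (any(efficiencies <= 1)) stop("efficiencies must be > 1", call. = FALSE)
  set.seed(seed)
  cq0 <- 30; spike_cq0 <- 20
  rows <- lapply(seq_along(true_fractions), function(f) {
    a <- true_fractions[f]
    cq <- cq0 - log(a) / log(efficiencies[["target"]])
    cq <- rep(cq, n_replicates)
    scq <- rep(spike_cq0, n_replicates)
    if (noise_sd > 0) {
      cq <- cq + rnorm(n_replicates, 0, noise_sd)
      scq <- scq + rnorm(n_replicates, 0, noise_sd)
    }
    data.frame(target = target, fraction = f, replicate = seq_len(n_replicates),
               cq = cq, spike_cq = scq, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: transcriptome, planted truth, CLIP reads, the three
#' footprint classes, RNA-seq counts and a structure track, all from one
#' seeded configuration.
#'
#' @param cfg a [sim_config()].
#' @return named list: sequences, annotation, truth, clip_reads,
#'   footprints (list by class), rna_counts, pars_track.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  tx <- generate_transcriptome(cfg)
  pl <- plant_sites(tx, cfg)
  tx$sequences <- pl$sequences
  clip <- simulate_parclip_reads(pl$truth, tx$annotation, cfg)
  fps <- lapply(setNames(nm = names(FOOTPRINT_CLASSES)), function(cl)
    simulate_footprints(pl$truth, tx$annotation, cfg, cl))
  rna <- simulate_rnaseq(tx$annotation,
                         abundances = tx$annotation$total_len / 10,
                         dispersion = cfg$rna_abundance_dispersion,
                         seed = cfg$seed + 404L)
  pars <- simulate_pars_track(tx$annotation, pl$truth, seed = cfg$seed + 505L)
  list(sequences = tx$sequences, annotation = tx$annotation, truth = pl$truth,
       clip_reads = clip, footprints = fps, rna_counts = rna, pars_track = pars)
}
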