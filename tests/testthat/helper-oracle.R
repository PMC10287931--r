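# Independent brute-force re-implementations used as oracles.
# Everything here is computed with naive loops and no shared code with the
# package internals.

oracle_empty_sites <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), read_count = integer(0),
             conversion_count = integer(0), conversion_read_count = integer(0),
             mode_location = integer(0), stringsAsFactors = FALSE)
}

# naive site caller: union-find grouping, per-position kernel sums,
# exhaustive run scanning and cluster extension by walking outward
oracle_call_sites <- function(reads, params = larpmap::site_params(),
                              sequences = NULL) {
  keep <- (reads$end - reads$start) >= params$min_read_len
  reads <- reads[keep, , drop = FALSE]
  n <- nrow(reads)
  if (n == 0L) return(oracle_empty_sites())
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          reads$chrom[i] == reads$chrom[j] &&
          reads$strand[i] == reads$strand[j] &&
          reads$start[i] < reads$end[j] && reads$start[j] < reads$end[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- oracle_empty_sites()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) < params$min_group_reads) next
    g <- reads[idx, , drop = FALSE]
    gstart <- min(g$start); gend <- max(g$end)
    pos <- gstart:(gend - 1L)
    seqc <- if (is.null(sequences)) NULL
            else strsplit(sequences[[g$chrom[1]]], "")[[1]]
    want <- if (g$strand[1] == "+") "T" else "A"
    conv_pos <- integer(0); conv_read <- integer(0); bg_pos <- integer(0)
    for (i in seq_len(nrow(g))) {
      offs <- g$conversions[[i]]
      cp <- if (g$strand[i] == "+") g$start[i] + offs else g$end[i] - 1L - offs
      conv_pos <- c(conv_pos, cp)
      conv_read <- c(conv_read, rep(i, length(cp)))
      cov <- g$start[i]:(g$end[i] - 1L)
      if (!is.null(seqc)) cov <- cov[seqc[cov + 1L] == want]
      bg_pos <- c(bg_pos, setdiff(cov, cp))
    }
    depth <- sapply(pos, function(p) sum(g$start <= p & p < g$end))
    sig <- sapply(pos, function(p)
      if (length(conv_pos) == 0L) 0
      else sum(dnorm(p - conv_pos, sd = params$bandwidth)) / length(conv_pos))
    bg <- sapply(pos, function(p)
      if (length(bg_pos) == 0L) 0
      else sum(dnorm(p - bg_pos, sd = params$bandwidth)) / length(bg_pos))
    defined <- depth >= params$min_depth & (sig + bg) > 0
    capable <- if (is.null(seqc)) rep(TRUE, length(pos))
               else seqc[pos + 1L] == want
    in_run <- defined & sig > bg
    # exhaustive scan for maximal runs, then extend to depth block
    clusters <- list()
    i <- 1L
    while (i <= length(pos)) {
      if (in_run[i]) {
        j <- i
        while (j < length(pos) && in_run[j + 1L]) j <- j + 1L
        a <- i; b <- j
        while (a > 1L && depth[a - 1L] >= params$min_depth) a <- a - 1L
        while (b < length(pos) && depth[b + 1L] >= params$min_depth) b <- b + 1L
        key <- paste(a, b)
        clusters[[key]] <- c(a, b)
        i <- j + 1L
      } else i <- i + 1L
    }
    for (cl in clusters) {
      a <- pos[cl[1]]; b <- pos[cl[2]]
      width <- b - a + 1L
      inside <- conv_pos >= a & conv_pos <= b
      if (sum(inside) < params$min_conversions) next
      if (length(unique(conv_read[inside])) < params$min_conversion_reads) next
      if (width < params$min_width || width > params$max_width) next
      seg <- cl[1]:cl[2]
      ok <- defined[seg]
      if (any(ok & capable[seg])) ok <- ok & capable[seg]
      ratio <- ifelse(defined[seg], sig[seg] / (sig[seg] + bg[seg]), -Inf)
      ratio[!ok] <- -Inf
      mode <- pos[seg][which.max(ratio)]
      out <- rbind(out, data.frame(
        chrom = g$chrom[1], start = a, end = b + 1L, strand = g$strand[1],
        read_count = sum(g$start < b + 1L & g$end > a),
        conversion_count = sum(inside),
        conversion_read_count = length(unique(conv_read[inside])),
        mode_location = mode, stringsAsFactors = FALSE))
    }
  }
  out[order(out$chrom, out$strand, out$start), , drop = FALSE]
}

sort_sites <- function(sites) {
  s <- sites[order(sites$chrom, sites$strand, sites$start),
             c("chrom", "start", "end", "strand", "read_count",
               "conversion_count", "conversion_read_count", "mode_location"),
             drop = FALSE]
  rownames(s) <- NULL
  s
}

# position-by-position degenerate matcher (no regex, no Biostrings)
oracle_scan_motif <- function(sequence, pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                N = c("A", "C", "G", "T"))
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(sequence), "")[[1]]
  hits <- integer(0)
  if (length(s) >= length(p)) {
    for (i in 1:(length(s) - length(p) + 1L)) {
      ok <- TRUE
      for (k in seq_along(p)) {
        if (!s[i + k - 1L] %in% iupac[[p[k]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i - 1L)
    }
  }
  hits
}

# exhaustive Mann-Whitney: U by pair counting, p by enumerating every
# assignment of pooled values to group A
oracle_rank_compare <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  pair_u <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u <- pair_u(a, b)
  mid <- na * nb / 2
  sets <- combn(na + nb, na)
  extreme <- 0L
  for (k in seq_len(ncol(sets))) {
    ua <- pair_u(pooled[sets[, k]], pooled[-sets[, k]])
    if (abs(ua - mid) >= abs(u - mid) - 1e-9) extreme <- extreme + 1L
  }
  list(U = u, p.value = extreme / ncol(sets))
}
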