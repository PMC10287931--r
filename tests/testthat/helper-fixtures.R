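# read-table builders used across tests

make_reads <- function(chrom, start, end, strand = "+", conversions = NULL) {
  n <- length(start)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), name = sprintf("r%03d", seq_len(n)),
                   score = integer(n), strand = strand, stringsAsFactors = FALSE)
  if (is.null(conversions)) conversions <- replicate(n, integer(0), simplify = FALSE)
  df$conversions <- I(lapply(conversions, as.integer))
  df
}

# a tight stack of `n` reads covering [start, start+len) with a conversion at
# `conv_pos` (transcript coordinate) in the first `n_conv` reads
make_stack <- function(chrom = "t1", start = 100L, len = 20L, n = 6L,
                       conv_pos = 110L, n_conv = 3L) {
  conv <- lapply(seq_len(n), function(i)
    if (i <= n_conv) conv_pos - start else integer(0))
  make_reads(chrom, rep(start, n), rep(start + len, n), conversions = conv)
}

random_read_instance <- function(n_reads = 30L, span = 200L, with_seq = FALSE) {
  len <- sample(10:40, n_reads, replace = TRUE)   # some below the 13-nt filter
  start <- sample.int(span, n_reads, replace = TRUE) - 1L
  conv <- lapply(seq_len(n_reads), function(i) {
    if (runif(1) < 0.5) sort(sample.int(len[i], sample(1:2, 1)) - 1L)
    else integer(0)
  })
  reads <- make_reads("t1", start, start + len, conversions = conv)
  seqs <- NULL
  if (with_seq) {
    seqs <- list(t1 = paste(sample(c("A", "C", "G", "T"), span + 60,
                                   replace = TRUE), collapse = ""))
  }
  list(reads = reads, sequences = seqs)
}
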