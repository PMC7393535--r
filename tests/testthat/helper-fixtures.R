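# Shared helpers: tiny hand-built references/reads and brute-force
# oracles kept independent of the implementation paths they check.

# a 30 bp reference with one A(10) homopolymer at 0-based position 10
tiny_ref_seq <- function() {
  paste0("TGCATGCATG", strrep("A", 10), "CTGCTGCGTA")
}

tiny_ref <- function() {
  Biostrings::DNAStringSet(c(c1 = tiny_ref_seq()))
}

tiny_site <- function() {
  data.frame(chrom = "c1", start = 10L, motif = "A", n = 10L,
             left_flank = "GCATG", right_flank = "CTGCT",
             site_id = "c1:10:A", stringsAsFactors = FALSE)
}

# write SAM records against tiny_ref() and return an indexed BAM path
tiny_bam <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "t.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:c1\tLN:30",
               records), sam)
  Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                   indexDestination = TRUE)
}

sam_record <- function(qname, pos, cigar, seq, flag = 0L, mapq = 60L,
                       chrom = "c1") {
  paste(qname, flag, chrom, pos, mapq, cigar, "*", 0L, 0L, seq, "*",
        sep = "\t")
}

# pair-enumeration AUC oracle (ties count one half)
auc_by_enumeration <- function(pos, neg) {
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# expectation of max(n - y, 0) / n by exhaustive pmf enumeration
expected_del_fraction <- function(n, p, q) {
  y <- 0:(2 * n)
  pr <- repeat_length_pmf(y, n, p, q)
  pr <- pr / sum(pr)
  sum(pr * pmax(n - y, 0)) / n
}

small_spec <- function(...) {
  cohort_spec(n_sites = 30L, n_normals = 6L, n_msi = 4L, n_mss = 4L, ...)
}
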