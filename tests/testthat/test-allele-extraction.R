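ref30 <- tiny_ref_seq()

test_that("reads matching the reference contribute y = n", {
  bam <- tiny_bam(sam_record("r1", 1, "30M", ref30))
  d <- extract_site_distribution(bam, tiny_site())
  expect_equal(d, c("10" = 1L))
})

test_that("a 2-base deletion in the homopolymer yields y = 8 on both paths", {
  # hand CIGAR walk: 18M covers the 10 bp flank plus 8 As, 2D removes
  # two repeat bases, 10M covers the right flank -> 8 motif copies
  seq <- paste0(substr(ref30, 1, 10), strrep("A", 8), substr(ref30, 21, 30))
  bam <- tiny_bam(sam_record("r1", 1, "18M2D10M", seq))
  expect_equal(extract_site_distribution(bam, tiny_site()), c("8" = 1L))
  expect_equal(extract_site_distribution(bam, tiny_site(), method = "cigar"),
               c("8" = 1L))
})

test_that("an inserted motif copy yields y = n + 1 on both paths", {
  seq <- paste0(substr(ref30, 1, 10), strrep("A", 11), substr(ref30, 21, 30))
  bam <- tiny_bam(sam_record("r1", 1, "20M1I10M", seq))
  expect_equal(extract_site_distribution(bam, tiny_site()), c("11" = 1L))
  expect_equal(extract_site_distribution(bam, tiny_site(), method = "cigar"),
               c("11" = 1L))
})

test_that("non-spanning, low-MAPQ, duplicate and unanchored reads are excluded", {
  recs <- c(
    # alignment ends 1 bp inside the repeat tract
    sam_record("r_in", 1, "11M", substr(ref30, 1, 11)),
    # spans the tract but not the right anchor
    sam_record("r_short", 4, "19M", substr(ref30, 4, 22)),
    # full span, MAPQ below the floor
    sam_record("r_mapq", 1, "30M", ref30, mapq = 5L),
    # full span, duplicate flag
    sam_record("r_dup", 1, "30M", ref30, flag = 1024L),
    # one good read
    sam_record("r_ok", 1, "30M", ref30))
  bam <- tiny_bam(recs)
  expect_equal(extract_site_distribution(bam, tiny_site()), c("10" = 1L))
})

test_that("reads whose flank anchor is absent are discarded on the flank path", {
  seq <- paste0(substr(ref30, 1, 9), "T", strrep("A", 10),
                substr(ref30, 21, 30))  # left anchor broken (GCATG -> GCATT)
  bam <- tiny_bam(c(sam_record("r_bad", 1, "30M", seq),
                    sam_record("r_ok", 1, "30M", ref30)))
  expect_equal(extract_site_distribution(bam, tiny_site()), c("10" = 1L))
})

test_that("empty alignments still emit one row per site with m = 0", {
  bam <- tiny_bam(character(0))
  sites <- rbind(tiny_site(), tiny_site(), tiny_site())
  sites$start <- c(10L, 10L, 10L)
  d <- extract_all(bam, sites)
  expect_equal(nrow(d), 3L)
  expect_equal(d$m, c(0L, 0L, 0L))
  expect_equal(d$dist, c(".", ".", "."))
})

test_that("sites on chromosomes missing from the BAM header are skipped", {
  bam <- tiny_bam(sam_record("r1", 1, "30M", ref30))
  sites <- rbind(tiny_site(), tiny_site())
  sites$chrom <- c("c1", "cZ")
  sites$site_id <- paste(sites$chrom, sites$start, sites$motif, sep = ":")
  expect_warning(d <- extract_all(bam, sites), "absent")
  expect_equal(d$m, c(1L, 0L))
})

test_that("extraction equals the planted truth and ignores read order", {
  spec <- small_spec(coverage = 25)
  gen <- generate_reference(spec, seed = 21)
  dir <- withr::local_tempdir()
  sb <- generate_sample_bam(gen$sites, gen$ref, spec,
                            file.path(dir, "s1"), role = "normal", seed = 8)
  d <- extract_all(sb$bam, gen$sites)
  planted <- split(sb$read_truth$y, sb$read_truth$site_id)
  for (i in seq_len(nrow(d))) {
    want <- planted[[d$site_id[i]]]
    expect_equal(sort(d$lengths[[i]]),
                 sort(if (is.null(want)) integer(0) else want))
  }
  # m never exceeds reads overlapping the site
  expect_true(all(d$m <= vapply(planted, length, integer(1))[d$site_id]))
  # CIGAR arithmetic agrees with flank re-anchoring on error-free reads
  d2 <- extract_all(sb$bam, gen$sites, method = "cigar")
  expect_equal(lapply(d$lengths, sort), lapply(d2$lengths, sort))
})

test_that("distribution TSV round-trips including empty sites", {
  spec <- small_spec(coverage = 8)
  gen <- generate_reference(spec, seed = 3)
  d <- generate_sample_dists(gen$sites, spec, "normal", seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distributions(d, path)
  back <- read_distributions(path)
  expect_equal(back$m, d$m)
  expect_equal(lapply(back$lengths, sort), lapply(d$lengths, sort))
  expect_equal(attr(back, "site_hash"), attr(d, "site_hash"))
})
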