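test_that("read_bed parses BED conventions and flags malformed input", {
  p <- write_bed_lines(c("chr1\t100\t200", "chr2\t0\t50\tpeakA\t0\t+"))
  ps <- read_bed(p)
  expect_s3_class(ps, "peak_set")
  expect_equal(ps$intervals$start, c(100, 0))
  expect_equal(ps$intervals$end, c(200, 50))
  expect_false(ps$normalized)

  empty <- write_bed_lines(character())
  expect_equal(nrow(read_bed(empty)$intervals), 0)

  bad <- write_bed_lines(c("chr1\t100\t200", "chr1\t200\t100"))
  expect_error(read_bed(bad), "line 2")
  short <- write_bed_lines(c("chr1\t100"))
  expect_error(read_bed(short), "malformed")
})

test_that("promoter windows are strand-aware, half-open, and clamped at 0", {
  g <- function(strand, tss) data.frame(gene_id = "g", chrom = "chr1",
                                        strand = strand, tss = tss)
  w <- promoter_window(g("+", 10000), 3000, 3000)
  expect_equal(c(w$start, w$end), c(7000, 13000))
  w <- promoter_window(g("+", 1000), 3000, 3000)
  expect_equal(c(w$start, w$end), c(0, 4000))
  w <- promoter_window(g("-", 10000), 2000, 500)
  expect_equal(c(w$start, w$end), c(9500, 12000))
})

test_that("sites map to overlapping promoters, nearest TSS wins conflicts", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = "+", tss = c(10000, 15800))
  sites <- tibble::tibble(tf = "TF1", chrom = "chr1",
                          start = c(7100, 20000, 12800),
                          end = c(7200, 20100, 12900))
  cat <- assign_sites_to_promoters(sites, genes)
  # site 1 only in gA's window; site 2 overlaps nothing; site 3 overlaps
  # both windows, midpoint 12850 is 2850 from gA's TSS and 2950 from gB's
  expect_equal(nrow(cat), 2)
  expect_equal(cat$gene_id[cat$start == 7100], "gA")
  expect_equal(cat$gene_id[cat$start == 12800], "gA")
  expect_error(assign_sites_to_promoters(sites, genes[0, ]), "empty")
})

test_that("overlap fractions match bp arithmetic and demand merged peaks", {
  peaks <- normalize_peaks(peak_set(data.frame(chrom = "chr1", start = 150, end = 250)))
  site <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(site_overlap_fraction(site, peaks), 0.5)
  far <- data.frame(chrom = "chr1", start = 500, end = 600)
  expect_equal(site_overlap_fraction(far, peaks), 0)
  big <- normalize_peaks(peak_set(data.frame(chrom = "chr1", start = 0, end = 1000)))
  expect_equal(site_overlap_fraction(site, big), 1)

  raw <- peak_set(data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 250)))
  expect_error(site_overlap_fraction(site, raw), "normalized")
})

test_that("overlap fractions equal the per-basepair oracle on random genomes", {
  set.seed(101)
  for (i in 1:40) {
    peaks_tbl <- rand_intervals(sample(1:15, 1))
    sites_tbl <- rand_intervals(sample(1:10, 1))
    ps <- normalize_peaks(peak_set(peaks_tbl))
    frac <- site_overlap_fraction(sites_tbl, ps)
    oracle <- vapply(seq_len(nrow(sites_tbl)), function(j) {
      coverage_oracle(sites_tbl$start[j], sites_tbl$end[j], peaks_tbl)
    }, numeric(1))
    expect_equal(frac, oracle)
  }
})

test_that("merging is idempotent and leaves overlap fractions unchanged", {
  set.seed(7)
  tbl <- rand_intervals(30)
  m1 <- normalize_peaks(peak_set(tbl))
  m2 <- normalize_peaks(peak_set(m1$intervals))
  expect_equal(m1$intervals, m2$intervals)
  sites <- rand_intervals(8)
  expect_equal(site_overlap_fraction(sites, m1), site_overlap_fraction(sites, m2))
})

test_that("mirroring all coordinates leaves overlap fractions unchanged", {
  set.seed(8)
  M <- 20000
  peaks_tbl <- rand_intervals(12)
  sites_tbl <- rand_intervals(6)
  mirror <- function(tbl) {
    tibble::tibble(chrom = tbl$chrom, start = M - tbl$end, end = M - tbl$start)
  }
  f1 <- site_overlap_fraction(sites_tbl, normalize_peaks(peak_set(peaks_tbl)))
  f2 <- site_overlap_fraction(mirror(sites_tbl), normalize_peaks(peak_set(mirror(peaks_tbl))))
  expect_equal(f1, f2)
})
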