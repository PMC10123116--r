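#' Peak sets: collections of genomic intervals
#'
#' A `peak_set` holds genomic intervals in BED convention (0-based,
#' half-open) as a tibble with columns `chrom`, `start`, `end`, `strand`,
#' `name`, together with a `normalized` flag (TRUE once intervals have been
#' sorted and merged per chromosome, so they are mutually non-overlapping)
#' and an optional per-cell ownership map for jointly profiled
#' accessibility/expression data, where each peak is traced back to the
#' cells whose reads produced it.
#'
#' @param intervals Data frame with at least `chrom`, `start`, `end`;
#'   optional `strand` (one of `+`, `-`, `.`) and `name`.
#' @param cell_assignment Optional named list, cell id -> integer vector of
#'   row indices of `intervals` owned by that cell.
#' @param normalized Logical; assert that intervals are already sorted and
#'   merged per chromosome.
#' @return A `peak_set` object.
#' @export
#' @examples
#' peak_set(data.frame(chrom = "chr1", start = 100, end = 200))
peak_set <- function(intervals, cell_assignment = NULL, normalized = FALSE) {
  intervals <- as_tibble(intervals)
  if (!all(c("chrom", "start", "end") %in% names(intervals))) {
    abort_velonet("intervals must have columns chrom, start, end")
  }
  if (!"strand" %in% names(intervals)) intervals$strand <- "."
  if (!"name" %in% names(intervals)) intervals$name <- NA_character_
  intervals <- intervals[, c("chrom", "start", "end", "strand", "name")]
  intervals$start <- as.double(intervals$start)
  intervals$end <- as.double(intervals$end)
  validate_intervals(intervals)
  if (!is.null(cell_assignment)) {
    if (is.null(names(cell_assignment)) || any(!nzchar(names(cell_assignment)))) {
      abort_velonet("cell_assignment must be a named list (cell id -> peak indices)")
    }
    idx <- unlist(cell_assignment, use.names = FALSE)
    if (length(idx) && (any(idx < 1) || any(idx > nrow(intervals)))) {
      abort_velonet("cell_assignment references unknown peak index")
    }
  }
  structure(
    list(
      intervals = intervals,
      cell_assignment = cell_assignment,
      normalized = isTRUE(normalized)
    ),
    class = "peak_set"
  )
}

validate_intervals <- function(x, file = NULL) {
  bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$start >= x$end |
                 x$start < 0 | !nzchar(x$chrom) | is.na(x$chrom))
  if (length(bad)) {
    abort_velonet(sprintf(
      "invalid interval at %s %d: start must satisfy 0 <= start < end (got start=%s end=%s)",
      if (is.null(file)) "row" else paste0(file, " line"),
      bad[1], format(x$start[bad[1]]), format(x$end[bad[1]])
    ), class = "velonet_validation_error")
  }
  ok <- x$strand %in% c("+", "-", ".")
  if (!all(ok)) {
    abort_velonet(sprintf("invalid strand '%s' at row %d", x$strand[which(!ok)[1]], which(!ok)[1]),
                  class = "velonet_validation_error")
  }
  invisible(x)
}

#' @exportS3Method base::print
print.peak_set <- function(x, ...) {
  cat(sprintf(
    "<peak_set> %d intervals on %d chromosome(s); normalized: %s%s\n",
    nrow(x$intervals), length(unique(x$intervals$chrom)), x$normalized,
    if (!is.null(x$cell_assignment)) sprintf("; %d cells", length(x$cell_assignment)) else ""
  ))
  print(head(x$intervals, 5), ...)
  invisible(x)
}

#' Read a BED file into a peak set
#'
#' Parses BED3/BED6 (tab-separated, 0-based half-open). Lines starting with
#' `#`, `track` or `browser` are skipped. Sorting/merging is *not* applied
#' unless `normalize = TRUE`.
#'
#' @param path Path to a BED file.
#' @param dialect `"auto"` (default), `"bed3"` or `"bed6"`.
#' @param normalize Sort and merge intervals per chromosome after reading.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, dialect = c("auto", "bed3", "bed6"), normalize = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_velonet(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  kept_lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(peak_set(tibble(chrom = character(), start = double(), end = double())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (dialect == "bed6") 6L else 3L
  if (any(nf < need)) {
    i <- which(nf < need)[1]
    abort_velonet(sprintf("malformed BED line %d in %s: %d field(s), need >= %d",
                          kept_lineno[i], path, nf[i], need),
                  class = "velonet_parse_error")
  }
  get <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, character(1))
  start <- suppressWarnings(as.double(get(2)))
  end <- suppressWarnings(as.double(get(3)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    abort_velonet(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                          kept_lineno[i], path), class = "velonet_parse_error")
  }
  tbl <- tibble(
    chrom = get(1), start = start, end = end,
    strand = if (dialect != "bed3" && all(nf >= 6)) get(6) else ".",
    name = if (dialect != "bed3" && all(nf >= 4)) get(4) else NA_character_
  )
  bad <- which(!is.finite(tbl$start) | !is.finite(tbl$end) |
                 tbl$start >= tbl$end | tbl$start < 0)
  if (length(bad)) {
    abort_velonet(sprintf(
      "invalid interval at %s line %d: need 0 <= start < end (got start=%s end=%s)",
      path, kept_lineno[bad[1]], format(tbl$start[bad[1]]), format(tbl$end[bad[1]])),
      class = "velonet_parse_error")
  }
  ps <- peak_set(tbl)
  if (normalize) ps <- normalize_peaks(ps)
  ps
}

intervals_to_iranges <- function(tbl) {
  # BED half-open [start, end) -> IRanges closed [start+1, end]
  IRanges::IRanges(start = tbl$start + 1, end = tbl$end)
}

#' Sort and merge the intervals of a peak set
#'
#' Overlapping or bookended intervals on the same chromosome are merged so
#' the result is mutually non-overlapping; this guarantees overlap fractions
#' never double-count a base pair.
#'
#' @param ps A [peak_set()].
#' @return A normalized `peak_set`.
#' @export
normalize_peaks <- function(ps) {
  stopifnot(inherits(ps, "peak_set"))
  if (!is.null(ps$cell_assignment)) {
    abort_velonet("cannot normalize a peak_set carrying a cell_assignment; per-cell activity merges each cell's peaks internally")
  }
  if (ps$normalized) return(ps)
  tbl <- ps$intervals
  if (!nrow(tbl)) return(peak_set(tbl, normalized = TRUE))
  merged <- dplyr::bind_rows(lapply(split(tbl, tbl$chrom), function(chunk) {
    red <- IRanges::reduce(intervals_to_iranges(chunk))
    tibble(chrom = chunk$chrom[1], start = IRanges::start(red) - 1, end = IRanges::end(red))
  }))
  merged <- merged[order(merged$chrom, merged$start), ]
  peak_set(merged, normalized = TRUE)
}

#' Strand-aware promoter windows around transcription start sites
#'
#' For a `+` strand gene the window is `[tss - upstream, tss + downstream)`;
#' for a `-` strand gene `[tss - downstream, tss + upstream)`; both
#' half-open and clamped at coordinate 0. Defaults follow the common
#' promoter definition of 3000 bp on either side of the TSS.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tss` (0-based).
#' @param upstream,downstream Window extents in bp (non-negative).
#' @return A tibble `gene_id, chrom, strand, start, end` (BED half-open).
#' @export
#' @examples
#' promoter_window(data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 10000))
promoter_window <- function(genes, upstream = 3000, downstream = 3000) {
  stopifnot(upstream >= 0, downstream >= 0)
  genes <- as_tibble(genes)
  req <- c("gene_id", "chrom", "strand", "tss")
  if (!all(req %in% names(genes))) {
    abort_velonet(sprintf("genes must have columns %s", paste(req, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) abort_velonet("gene strand must be '+' or '-'")
  if (any(genes$tss < 0)) abort_velonet("tss must be non-negative")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = as.double(genes$tss),
    start = pmax(0, as.double(start)), end = as.double(end)
  )
}

#' Assign TF binding sites to gene promoter windows
#'
#' A site is credited to a gene iff it overlaps the gene's promoter window
#' by at least 1 bp. A site overlapping several windows is assigned only to
#' the gene whose TSS is nearest to the site midpoint (ties broken by
#' lexicographic `gene_id`); sites overlapping no window are dropped.
#'
#' @param sites Either a tibble with columns `tf`, `chrom`, `start`, `end`
#'   (one row per binding site) or a named list of [peak_set()] objects,
#'   one per TF.
#' @param genes Gene annotation (`gene_id`, `chrom`, `strand`, `tss`).
#' @param upstream,downstream Promoter extents in bp.
#' @return A tibble with class `site_catalog`: columns `tf`, `gene_id`,
#'   `chrom`, `start`, `end`, sorted by (tf, gene_id, start).
#' @export
assign_sites_to_promoters <- function(sites, genes, upstream = 3000, downstream = 3000) {
  if (!nrow(as_tibble(genes))) abort_velonet("gene list is empty")
  if (inherits(sites, "peak_set")) abort_velonet("sites must be keyed by TF: pass a tibble with a 'tf' column or a named list of peak_set")
  if (is.list(sites) && !is.data.frame(sites)) {
    if (is.null(names(sites))) abort_velonet("list of site tracks must be named by TF id")
    sites <- dplyr::bind_rows(lapply(names(sites), function(tf) {
      tbl <- if (inherits(sites[[tf]], "peak_set")) sites[[tf]]$intervals else as_tibble(sites[[tf]])
      dplyr::mutate(tbl, tf = tf)
    }))
  }
  sites <- as_tibble(sites)
  if (!all(c("tf", "chrom", "start", "end") %in% names(sites))) {
    abort_velonet("sites must have columns tf, chrom, start, end")
  }
  proms <- promoter_window(genes, upstream, downstream)

  out <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(si) {
    pi <- which(proms$chrom == sites$chrom[si[1]])
    if (!length(pi)) return(NULL)
    sr <- intervals_to_iranges(sites[si, ])
    pr <- intervals_to_iranges(proms[pi, ])
    ov <- IRanges::findOverlaps(sr, pr, minoverlap = 1L)
    if (!length(ov)) return(NULL)
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    mid <- (sites$start[si[q]] + sites$end[si[q]]) / 2
    cand <- tibble(
      site_row = si[q],
      gene_id = proms$gene_id[pi[s]],
      dist = abs(mid - proms$tss[pi[s]])
    )
    cand <- cand[order(cand$site_row, cand$dist, cand$gene_id), ]
    cand[!duplicated(cand$site_row), c("site_row", "gene_id")]
  })
  picked <- dplyr::bind_rows(out)
  if (is.null(picked) || !nrow(picked)) {
    cat_empty <- tibble(tf = character(), gene_id = character(),
                        chrom = character(), start = double(), end = double())
    return(structure(cat_empty, class = c("site_catalog", class(cat_empty))))
  }
  cat_tbl <- tibble(
    tf = sites$tf[picked$site_row],
    gene_id = picked$gene_id,
    chrom = sites$chrom[picked$site_row],
    start = sites$start[picked$site_row],
    end = sites$end[picked$site_row]
  )
  cat_tbl <- cat_tbl[order(cat_tbl$tf, cat_tbl$gene_id, cat_tbl$start), ]
  structure(cat_tbl, class = c("site_catalog", class(cat_tbl)))
}

#' Fraction of each site covered by merged open-chromatin peaks
#'
#' For each binding site, returns (bp of the site covered by the merged
#' peaks) / (site length), a value in `[0, 1]`. The peak set must be
#' normalized (merged) so coverage cannot be double-counted.
#'
#' @param sites Data frame with `chrom`, `start`, `end` (BED half-open).
#' @param peaks A normalized [peak_set()].
#' @return Numeric vector of overlap fractions, one per row of `sites`.
#' @export
site_overlap_fraction <- function(sites, peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!peaks$normalized) {
    abort_velonet("peaks must be normalized (sorted+merged) before computing overlap fractions; call normalize_peaks()")
  }
  sites <- as_tibble(sites)
  n <- nrow(sites)
  frac <- numeric(n)
  if (!n) return(frac)
  ptbl <- peaks$intervals
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    pi <- which(ptbl$chrom == ch)
    if (!length(pi)) next
    sr <- intervals_to_iranges(sites[si, ])
    pr <- intervals_to_iranges(ptbl[pi, ])
    ov <- IRanges::findOverlaps(sr, pr, minoverlap = 1L)
    if (!length(ov)) next
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(sr[q], pr[s]))
    cov <- tapply(w, q, sum)
    idx <- as.integer(names(cov))
    frac[si[idx]] <- as.double(cov) / (sites$end[si[idx]] - sites$start[si[idx]])
  }
  frac
}
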