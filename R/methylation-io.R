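utils::globalVariables(c(
  "i.name", "i.score", "i.strand", "len", "percent", "sample_id", "family",
  "status", "path", "site_pos", "n_meth_plus", "n_unmeth_plus"
))

#' Construct a sample methylome
#'
#' Holds one sample's CpG methylation calls as a `data.table` with columns
#' `chrom`, `pos` (1-based position of the cytosine), `strand` (`+`/`-`;
#' dropped after destranding), `n_meth`, `n_unmeth`, together with the
#' sample metadata needed for differential analysis.
#'
#' @param calls data.frame of calls (chrom, pos, strand, n_meth, n_unmeth;
#'   `strand` optional, defaults to "+").
#' @param sample_id sample identifier.
#' @param family family label ("A", "C", or "none").
#' @param status "patient" or "control".
#' @param destranded logical; TRUE once opposite-strand calls are merged.
#' @return an object of class `sample_methylome`.
#' @export
sample_methylome <- function(calls, sample_id, family = "none",
                             status = c("control", "patient"),
                             destranded = FALSE) {
  status <- match.arg(status)
  dt <- as.data.table(calls)
  if (!"strand" %in% names(dt)) dt[, strand := "+"]
  req <- c("chrom", "pos", "strand", "n_meth", "n_unmeth")
  if (!all(req %in% names(dt)))
    stop("calls need columns chrom, pos, strand, n_meth, n_unmeth")
  dt <- dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
               strand = as.character(strand),
               n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  if (nrow(dt)) {
    if (any(dt$n_meth < 0L | dt$n_unmeth < 0L))
      stop("negative methylation counts in sample ", sample_id)
    if (any(dt$n_meth + dt$n_unmeth < 1L))
      stop("zero-coverage call in sample ", sample_id)
    if (any(!dt$strand %in% c("+", "-")))
      stop("strand must be + or - in sample ", sample_id)
    if (any(dt$pos < 1L)) stop("positions are 1-based; pos < 1 found")
    if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
      stop("duplicate (chrom, pos, strand) records in sample ", sample_id)
  }
  setorder(dt, chrom, pos)
  structure(list(sample_id = sample_id, family = family, status = status,
                 destranded = destranded, calls = dt),
            class = "sample_methylome")
}

#' @export
print.sample_methylome <- function(x, ...) {
  cat(sprintf(
    "sample_methylome '%s' (family %s, %s): %d calls%s\n",
    x$sample_id, x$family, x$status, nrow(x$calls),
    if (x$destranded) ", destranded" else ""))
  invisible(x)
}

#' Percent methylation of calls
#' @param calls data.table with n_meth, n_unmeth.
#' @return numeric vector, 100 * n_meth / coverage.
#' @export
percent_methylation <- function(calls) {
  100 * calls$n_meth / (calls$n_meth + calls$n_unmeth)
}

#' Read per-sample CpG methylation calls
#'
#' Accepts two tab-separated dialects of the Bismark coverage format, with
#' or without a header line:
#' * 6 columns `chrom, start, end, percent, n_meth, n_unmeth` (1-based
#'   start; no strand -- calls are taken as `+`-anchored CpG sites, i.e.
#'   already destranded or strand-unresolved);
#' * 7 columns with an explicit `strand` column appended.
#'
#' Malformed lines (wrong field count, non-numeric counts, negative counts,
#' zero coverage, bad strand) raise an error naming the first offending
#' line number.
#'
#' @param path file path.
#' @param sample_id sample identifier (default: file base name).
#' @param family,status sample metadata (see [sample_methylome()]).
#' @return a `sample_methylome`.
#' @export
read_methylation_calls <- function(path, sample_id = NULL,
                                   family = "none",
                                   status = c("control", "patient")) {
  status <- match.arg(status)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(cov|tsv|txt)(\\.gz)?$", "", basename(path))
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl("^#", lines)
  header <- length(lines) && grepl("^chrom\t", lines[1L])
  if (header) keep[1L] <- FALSE
  lines <- lines[keep]; lineno <- lineno[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (length(nf) && !all(nf %in% c(6L, 7L)))
    stop(sprintf("line %d of %s: expected 6 or 7 tab-separated fields, got %d",
                 lineno[which(!nf %in% c(6L, 7L))[1L]], path,
                 nf[which(!nf %in% c(6L, 7L))[1L]]))
  get <- function(i) vapply(parts, function(p) p[i], "")
  n <- length(parts)
  dt <- data.table(
    chrom = if (n) get(1L) else character(),
    pos = suppressWarnings(as.integer(if (n) get(2L) else character())),
    n_meth = suppressWarnings(as.integer(if (n) get(5L) else character())),
    n_unmeth = suppressWarnings(as.integer(if (n) get(6L) else character())),
    strand = if (n && all(nf == 7L)) get(7L) else rep("+", n))
  bad <- which(is.na(dt$pos) | is.na(dt$n_meth) | is.na(dt$n_unmeth))
  if (length(bad))
    stop(sprintf("line %d of %s: non-numeric coordinate or counts",
                 lineno[bad[1L]], path))
  bad <- which(dt$n_meth < 0L | dt$n_unmeth < 0L)
  if (length(bad))
    stop(sprintf("line %d of %s: negative count", lineno[bad[1L]], path))
  bad <- which(dt$n_meth + dt$n_unmeth < 1L)
  if (length(bad))
    stop(sprintf("line %d of %s: zero coverage", lineno[bad[1L]], path))
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("line %d of %s: strand must be + or -",
                 lineno[bad[1L]], path))
  sample_methylome(dt, sample_id = sample_id, family = family,
                   status = status,
                   destranded = !(n && all(nf == 7L)))
}

#' Write CpG methylation calls
#'
#' Writes the Bismark-coverage-style dialect read by
#' [read_methylation_calls()]: 7 columns while calls still carry strand,
#' 6 columns once destranded. A header line is included.
#'
#' @param m a `sample_methylome`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_methylation_calls <- function(m, path) {
  stopifnot(inherits(m, "sample_methylome"))
  dt <- copy(m$calls)
  out <- data.table(chrom = dt$chrom, start = dt$pos, end = dt$pos,
                    percent = round(100 * dt$n_meth /
                                      (dt$n_meth + dt$n_unmeth), 6),
                    n_meth = dt$n_meth, n_unmeth = dt$n_unmeth)
  if (!m$destranded) out[, strand := dt$strand]
  fwrite(out, path, sep = "\t", col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header `sample_id, family, status, path`; relative
#' paths are resolved against the sheet's directory.
#'
#' @param path sheet path.
#' @return data.table with the four columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  req <- c("sample_id", "family", "status", "path")
  if (!all(req %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample ids in sheet")
  if (any(!sheet$status %in% c("patient", "control")))
    stop("status must be patient or control")
  base <- dirname(normalizePath(path))
  sheet[, path := ifelse(grepl("^/", path), path, file.path(base, path))]
  sheet[]
}

#' Load all samples of a sheet
#' @param sheet data.table from [read_sample_sheet()].
#' @return named list of `sample_methylome` objects.
#' @export
load_samples <- function(sheet) {
  out <- lapply(seq_len(nrow(sheet)), function(i)
    read_methylation_calls(sheet$path[i], sample_id = sheet$sample_id[i],
                           family = sheet$family[i],
                           status = sheet$status[i]))
  stats::setNames(out, sheet$sample_id)
}

#' Merge opposite-strand CpG calls
#'
#' A CpG dinucleotide produces a `+` strand cytosine at position p and a
#' `-` strand cytosine at p+1. Destranding sums the counts of a `-` call
#' at p+1 into the `+` call at p; orphan `-` calls are repositioned to
#' their `+`-strand coordinate p. Total methylated and unmethylated read
#' counts are conserved. The result carries one record per CpG site and no
#' strand.
#'
#' @param m a `sample_methylome` (not yet destranded).
#' @return a destranded `sample_methylome`.
#' @export
destrand <- function(m) {
  stopifnot(inherits(m, "sample_methylome"))
  if (m$destranded) return(m)
  dt <- copy(m$calls)
  dt[, site_pos := fifelse(strand == "-", pos - 1L, pos)]
  if (any(dt$site_pos < 1L))
    stop("minus-strand call at position 1 cannot be repositioned")
  agg <- dt[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth),
                n_strands = .N),
            by = .(chrom, pos = site_pos)]
  if (any(agg$n_strands > 2L))
    stop("more than two calls collapse onto one CpG site; non-CpG input?")
  both <- dt[, .N, by = .(chrom, site_pos, strand)]
  if (any(both$N > 1L))
    stop("duplicate same-strand calls at one position")
  sample_methylome(agg[, .(chrom, pos, strand = "+", n_meth, n_unmeth)],
                   sample_id = m$sample_id, family = m$family,
                   status = m$status, destranded = TRUE)
}

#' Coverage-filter a methylome
#'
#' Keeps only CpG sites with read coverage (methylated + unmethylated)
#' of at least `min_cov` (default 5, i.e. the >= 5x rule).
#'
#' @param m a destranded `sample_methylome`.
#' @param min_cov minimum coverage, >= 1.
#' @return filtered `sample_methylome`.
#' @export
filter_coverage <- function(m, min_cov = 5L) {
  stopifnot(inherits(m, "sample_methylome"))
  if (min_cov < 1L) stop("min_cov must be >= 1")
  calls <- m$calls[n_meth + n_unmeth >= min_cov]
  sample_methylome(calls, sample_id = m$sample_id, family = m$family,
                   status = m$status, destranded = m$destranded)
}

#' Unite samples into a shared-position matrix
#'
#' Complete-case union of samples: only CpG positions covered (at
#' >= `min_cov`) in EVERY input sample are retained; counts are carried
#' through unchanged. Inputs are destranded and coverage-filtered first if
#' they are not already.
#'
#' @param methylomes list of `sample_methylome` objects (>= 2, unique ids).
#' @param min_cov minimum per-sample coverage (default 5).
#' @return a `united_matrix`: list with `sites` (data.table chrom/pos),
#'   `meth` and `cov` integer matrices (sites x samples), and `samples`
#'   metadata data.table.
#' @export
unite_methylomes <- function(methylomes, min_cov = 5L) {
  if (length(methylomes) < 2L) stop("unite needs at least 2 samples")
  ids <- unname(vapply(methylomes, function(m) m$sample_id, ""))
  if (anyDuplicated(ids)) stop("duplicated sample ids")
  prep <- lapply(methylomes, function(m)
    filter_coverage(destrand(m), min_cov = min_cov))
  tabs <- lapply(prep, function(m) m$calls[, .(chrom, pos)])
  common <- Reduce(function(x, y) {
    setkey(x, chrom, pos); setkey(y, chrom, pos); x[y, nomatch = NULL]
  }, tabs)
  setkey(common, chrom, pos)
  n <- nrow(common)
  meth <- matrix(0L, n, length(prep), dimnames = list(NULL, ids))
  cov <- matrix(0L, n, length(prep), dimnames = list(NULL, ids))
  for (j in seq_along(prep)) {
    cc <- prep[[j]]$calls
    setkey(cc, chrom, pos)
    hit <- cc[common]
    meth[, j] <- hit$n_meth
    cov[, j] <- hit$n_meth + hit$n_unmeth
  }
  samples <- data.table(
    sample_id = ids,
    family = vapply(prep, function(m) m$family, ""),
    status = vapply(prep, function(m) m$status, ""))
  structure(list(sites = common[, .(chrom, pos)], meth = meth, cov = cov,
                 samples = samples, min_cov = as.integer(min_cov)),
            class = "united_matrix")
}

#' @export
print.united_matrix <- function(x, ...) {
  cat(sprintf("united_matrix: %d CpG sites x %d samples (min_cov %d)\n",
              nrow(x$sites), nrow(x$samples), x$min_cov))
  invisible(x)
}

#' Percent-methylation matrix of a united matrix
#' @param um a `united_matrix`.
#' @return numeric matrix (sites x samples) of percent methylation.
#' @export
united_percent <- function(um) 100 * um$meth / um$cov
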