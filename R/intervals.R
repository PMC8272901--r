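#' @importFrom data.table data.table as.data.table setkey setkeyv setorder
#'   setorderv foverlaps rbindlist setnames fread fwrite setattr copy :=
#'   .N .SD fifelse shift
NULL

# data.table NSE column names
utils::globalVariables(c(
  ".", "chrom", "start", "end", "name", "score", "strand", "i.start", "i.end",
  "xid", "yid", "pos", "n_meth", "n_unmeth", "coverage", "grp", "cummax_end",
  "newgrp", "width", "distance"
))

#' Construct a genomic interval track
#'
#' An `interval_track` is the package's universal currency for genomic
#' regions (DMR tiles, LADs, ChIP peaks, ChromHMM segments, promoters,
#' regulatory domains). It is a `data.table` with columns `chrom`, `start`,
#' `end` (0-based half-open, BED convention), and optional `name`, `score`,
#' `strand`, kept sorted by (chrom, start, end). Overlap among its own
#' intervals is allowed and never implicitly merged.
#'
#' @param x data.frame with at least `chrom`, `start`, `end`; `name`,
#'   `score`, `strand` optional.
#' @param track_name label attached to the track (attribute `track_name`).
#' @param genome optional named integer vector of chromosome lengths.
#' @return an object of class `interval_track` (also a `data.table`).
#' @export
interval_track <- function(x, track_name = "track", genome = NULL) {
  dt <- as.data.table(x)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(dt)))
    stop("interval_track needs columns chrom, start, end")
  if (!"name" %in% names(dt)) dt[, name := "."]
  if (!"score" %in% names(dt)) dt[, score := NA_real_]
  if (!"strand" %in% names(dt)) dt[, strand := "."]
  dt <- dt[, .(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), name = as.character(name),
               score = as.numeric(score), strand = as.character(strand))]
  if (nrow(dt)) {
    if (any(is.na(dt$start) | is.na(dt$end)))
      stop("interval_track: NA coordinates")
    if (any(dt$start < 0L)) stop("interval_track: negative start")
    if (any(dt$start >= dt$end))
      stop("interval_track: zero- or negative-length interval (start >= end)")
    if (any(!nzchar(dt$chrom)) || any(is.na(dt$chrom)))
      stop("interval_track: empty chromosome name")
    if (any(!dt$strand %in% c("+", "-", ".")))
      stop("interval_track: strand must be one of +, -, .")
  }
  setorder(dt, chrom, start, end)
  setattr(dt, "class", c("interval_track", class(dt)))
  setattr(dt, "track_name", track_name)
  setattr(dt, "genome", genome)
  dt[]
}

#' @export
print.interval_track <- function(x, ...) {
  cat(sprintf("interval_track '%s': %d intervals on %d chromosome(s)\n",
              attr(x, "track_name"), nrow(x),
              length(unique(x$chrom))))
  NextMethod()
}

track_name <- function(x) attr(x, "track_name")

is_interval_track <- function(x) inherits(x, "interval_track")

assert_track <- function(x, arg = deparse(substitute(x))) {
  if (!is_interval_track(x)) stop(arg, " is not an interval_track")
  invisible(x)
}

#' Total bases covered by a track
#'
#' Bases are counted once even where intervals of the track overlap.
#'
#' @param a an `interval_track`.
#' @return total covered bases (numeric, to avoid integer overflow).
#' @export
interval_bases <- function(a) {
  assert_track(a)
  if (!nrow(a)) return(0)
  m <- interval_merge(a, gap = 0L)
  sum(as.numeric(m$end - m$start))
}

#' Intersect two interval tracks
#'
#' BEDTools `intersect`-style: reports, for every pair of overlapping
#' intervals (one from `a`, one from `b`), the piece of the `a` interval
#' truncated to the overlap, carrying the `a` interval's name/score/strand.
#' The number of distinct `a` intervals that contributed at least one piece
#' is available as attribute `n_a_hit` (the `-u`-style count).
#'
#' @param a,b `interval_track` objects. Strand is ignored.
#' @return an `interval_track` of overlap pieces (attribute `n_a_hit`).
#' @export
interval_intersect <- function(a, b) {
  assert_track(a); assert_track(b)
  if (!nrow(a) || !nrow(b)) {
    out <- interval_track(a[0L], track_name = track_name(a))
    setattr(out, "n_a_hit", 0L)
    return(out)
  }
  x <- copy(as.data.table(a))[, xid := .I]
  y <- copy(as.data.table(b))[, yid := .I]
  setkey(y, chrom, start, end)
  ov <- foverlaps(x, y, by.x = c("chrom", "start", "end"),
                  type = "any", nomatch = NULL)
  # foverlaps treats ranges as closed; drop bookended (zero-bp) "overlaps"
  ov <- ov[pmin(i.end, end) - pmax(i.start, start) > 0L]
  if (!nrow(ov)) {
    out <- interval_track(a[0L], track_name = track_name(a))
    setattr(out, "n_a_hit", 0L)
    return(out)
  }
  res <- ov[, .(chrom,
                start = pmax(i.start, start),
                end = pmin(i.end, end),
                name = i.name, score = i.score, strand = i.strand)]
  setnames(res, c("chrom", "start", "end", "name", "score", "strand"))
  out <- interval_track(res, track_name = track_name(a))
  setattr(out, "n_a_hit", length(unique(ov$xid)))
  out
}

#' Count a-intervals overlapping a track
#'
#' Convenience wrapper returning the number of distinct intervals of `a`
#' that overlap >= 1 bp of `b` (BEDTools `intersect -u | wc -l`).
#'
#' @inheritParams interval_intersect
#' @return integer count.
#' @export
interval_count_overlapping <- function(a, b) {
  attr(interval_intersect(a, b), "n_a_hit")
}

#' Subtract one track from another
#'
#' BEDTools `subtract` semantics: the portions of each `a` interval not
#' covered by any interval of `b`.
#'
#' @inheritParams interval_intersect
#' @return an `interval_track`; `a` rows untouched by `b` pass through.
#' @export
interval_subtract <- function(a, b) {
  assert_track(a); assert_track(b)
  if (!nrow(a) || !nrow(b))
    return(interval_track(copy(as.data.table(a)), track_name = track_name(a)))
  bu <- interval_merge(b, gap = 0L)   # disjoint union of b
  x <- copy(as.data.table(a))[, xid := .I]
  y <- as.data.table(bu)[, .(chrom, start, end)]
  setkey(y, chrom, start, end)
  ov <- foverlaps(x, y, by.x = c("chrom", "start", "end"),
                  type = "any", nomatch = NULL)
  ov <- ov[pmin(i.end, end) - pmax(i.start, start) > 0L]
  untouched <- x[!xid %in% ov$xid,
                 .(chrom, start, end, name, score, strand)]
  pieces <- list(untouched)
  if (nrow(ov)) {
    setorder(ov, xid, start)
    # per a-interval, emit the gaps between consecutive covering b-pieces
    # y (merged b) carries only chrom/start/end, so the a columns keep
    # their names except start/end (prefixed i. by foverlaps)
    gaps <- ov[, {
      s <- i.start[1L]; e <- i.end[1L]
      cs <- sort(pmax(start, s)); ce <- sort(pmin(end, e))
      outs <- c(s, ce); oute <- c(cs, e)
      keep <- outs < oute
      .(start = outs[keep], end = oute[keep],
        name = rep(name[1L], sum(keep)), score = rep(score[1L], sum(keep)),
        strand = rep(strand[1L], sum(keep)))
    }, by = .(xid, chrom)]
    if (nrow(gaps))
      pieces <- c(pieces,
                  list(gaps[, .(chrom, start, end, name, score, strand)]))
  }
  res <- rbindlist(pieces, use.names = TRUE)
  interval_track(res, track_name = track_name(a))
}

#' Closest interval in another track
#'
#' For every interval of `a`, the nearest interval of `b` and their gap in
#' bp (0 when overlapping or bookended; BEDTools `closest -d` convention:
#' gap = later start - earlier end). Ties are broken deterministically in
#' favor of the `b` interval with the smaller start. `a` intervals on
#' chromosomes absent from `b` get `distance = NA` (unreachable).
#'
#' @inheritParams interval_intersect
#' @return data.table: a_chrom/a_start/a_end/a_name, b_start/b_end/b_name,
#'   distance.
#' @export
interval_closest <- function(a, b) {
  assert_track(a); assert_track(b)
  empty <- data.table(a_chrom = character(), a_start = integer(),
                      a_end = integer(), a_name = character(),
                      b_start = integer(), b_end = integer(),
                      b_name = character(), distance = integer())
  if (!nrow(a)) return(empty)
  out <- vector("list", length(unique(a$chrom)))
  i <- 0L
  for (ch in unique(a$chrom)) {
    ax <- a[chrom == ch]
    bx <- b[chrom == ch]
    i <- i + 1L
    if (!nrow(bx)) {
      out[[i]] <- data.table(a_chrom = ch, a_start = ax$start,
                             a_end = ax$end, a_name = ax$name,
                             b_start = NA_integer_, b_end = NA_integer_,
                             b_name = NA_character_, distance = NA_integer_)
      next
    }
    out[[i]] <- closest_one_chrom(ax, bx, ch)
  }
  res <- rbindlist(out, use.names = TRUE)
  setorder(res, a_chrom, a_start, a_end)
  res[]
}

# closest for one chromosome; bx sorted by (start, end)
closest_one_chrom <- function(ax, bx, ch) {
  nb <- nrow(bx)
  bs <- bx$start; be <- bx$end
  # running max of ends, and index achieving it (smallest start on ties)
  cme <- cummax(be)
  upd <- be == cme & c(TRUE, be[-1L] > cme[-nb])
  cmi <- cummax(ifelse(upd, seq_len(nb), 0L))
  # minimal-start b index per distinct end value (for bookended ties)
  endtab <- data.table(end = be, start = bs, i = seq_len(nb))
  endmin <- endtab[, .(i = i[which.min(start)]), by = end]
  setorder(endmin, end)

  n <- nrow(ax)
  res_bi <- integer(n); res_d <- integer(n)
  for (k in seq_len(n)) {
    s <- ax$start[k]; e <- ax$end[k]
    # overlap: any b with start < e and end > s
    lo <- findInterval(e - 1L, bs)      # last b with start <= e-1 (start < e)
    ov_bi <- 0L
    if (lo >= 1L && cme[lo] > s) {
      # some b among 1..lo ends beyond s -> overlap; find smallest start
      ov_bi <- match(TRUE, be[seq_len(lo)] > s)
    }
    if (ov_bi > 0L) {
      # a bookended left interval (end == s) also has distance 0 and may
      # have the smaller start
      pos <- findInterval(s, endmin$end)
      if (pos >= 1L && endmin$end[pos] == s &&
          bs[endmin$i[pos]] < bs[ov_bi])
        ov_bi <- endmin$i[pos]
      res_bi[k] <- ov_bi; res_d[k] <- 0L
      next
    }
    # left candidate: all b in 1..idx have end <= s (no overlap found)
    idx <- findInterval(s, bs)
    dl <- if (idx >= 1L) s - cme[idx] else NA_integer_
    bl <- if (idx >= 1L) cmi[idx] else NA_integer_
    # right candidate: first b with start >= e
    j <- findInterval(e - 1L, bs) + 1L
    dr <- if (j <= nb) bs[j] - e else NA_integer_
    br <- if (j <= nb) j else NA_integer_
    if (is.na(dr) || (!is.na(dl) && dl <= dr)) {
      res_bi[k] <- bl; res_d[k] <- dl
    } else {
      res_bi[k] <- br; res_d[k] <- dr
    }
  }
  data.table(a_chrom = ch, a_start = ax$start, a_end = ax$end,
             a_name = ax$name,
             b_start = bs[res_bi], b_end = be[res_bi],
             b_name = bx$name[res_bi], distance = pmax(res_d, 0L))
}

#' Merge intervals within a gap
#'
#' Intervals of `a` separated by a gap of at most `gap` bp (gap =
#' later start - earlier end; overlapping or bookended intervals have
#' gap <= 0) are unioned into single intervals. The result is sorted and
#' non-overlapping; the operation is idempotent.
#'
#' @param a an `interval_track`.
#' @param gap non-negative integer; `gap = 0` merges only overlapping or
#'   bookended intervals.
#' @return an `interval_track` with columns chrom/start/end (name of merged
#'   runs collapses to "."), plus `n_merged` = number of source intervals.
#' @export
interval_merge <- function(a, gap = 0L) {
  assert_track(a)
  if (gap < 0L) stop("gap must be non-negative")
  if (!nrow(a))
    return(interval_track(a[0L], track_name = track_name(a)))
  dt <- as.data.table(a)[, .(chrom, start, end)]
  setorder(dt, chrom, start, end)
  dt[, cummax_end := cummax(end), by = chrom]
  dt[, newgrp := c(TRUE, start[-1L] - cummax_end[-.N] > gap), by = chrom]
  dt[, grp := cumsum(newgrp)]
  m <- dt[, .(chrom = chrom[1L], start = min(start), end = max(end),
              name = ".", score = as.numeric(.N), strand = "."), by = grp]
  out <- interval_track(m[, !"grp"], track_name = track_name(a))
  setnames(out, "score", "score")  # score carries n_merged
  out
}

# ---- BED I/O ---------------------------------------------------------------

#' Read a BED3/BED6 file
#'
#' Tab-separated, no header; `track`/`browser`/`#` lines are skipped.
#' Zero-length or malformed intervals are an error (malformed BED should
#' surface early, not be dropped).
#'
#' @param path file path.
#' @param track_name label for the resulting track (default: file base name).
#' @param genome optional named chromosome-length vector.
#' @return an `interval_track`.
#' @export
read_bed <- function(path, track_name = NULL,
                     genome = NULL) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  if (is.null(track_name))
    track_name <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines))
    return(interval_track(data.table(chrom = character(), start = integer(),
                                     end = integer()),
                          track_name = track_name, genome = genome))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3L))
    stop("BED line(s) with fewer than 3 fields in ", path)
  dt <- data.table(
    chrom = vapply(parts, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    name = ifelse(ncol >= 4L, vapply(parts, function(p) p[4L], ""), "."),
    score = suppressWarnings(
      as.numeric(ifelse(ncol >= 5L, vapply(parts, function(p) p[5L], ""),
                        NA_character_))),
    strand = ifelse(ncol >= 6L, vapply(parts, function(p) p[6L], ""), "."))
  if (any(is.na(dt$start) | is.na(dt$end)))
    stop("non-numeric BED coordinates in ", path)
  interval_track(dt, track_name = track_name, genome = genome)
}

#' Write a track as BED6
#'
#' @param a an `interval_track`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(a, path) {
  assert_track(a)
  dt <- as.data.table(a)[, .(chrom, start, end, name,
                             score = fifelse(is.na(score), 0, score),
                             strand)]
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chrom-sizes file
#'
#' Two tab-separated columns: chromosome name, length.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "len"))
  if (any(dt$len <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(as.integer(dt$len), as.character(dt$chrom))
}

#' Write a chrom-sizes file
#' @param genome named integer vector of chromosome lengths.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_chrom_sizes <- function(genome, path) {
  fwrite(data.table(chrom = names(genome), len = as.integer(genome)),
         path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
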