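# Independent brute-force oracles used by the property and acceptance
# tests. These deliberately share no code path with the package: all-pairs
# loops, per-base masks, graph components, hypergeometric enumeration.

library(data.table)

random_track <- function(n, chroms = c("chr1", "chr2"), maxlen = 100000L,
                         max_w = 2000L) {
  ch <- sample(chroms, n, TRUE)
  w <- sample.int(max_w, n, TRUE)
  s <- sapply(w, function(wi) sample.int(maxlen - wi - 1L, 1L))
  interval_track(data.table(chrom = ch, start = s, end = s + w,
                            name = sprintf("iv%03d", seq_len(n))))
}

norm_iv <- function(dt) {
  d <- as.data.table(dt)[, .(chrom, start, end)]
  setorder(d, chrom, start, end)
  d
}

# all-pairs truncated-overlap pieces
oracle_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s < e) out[[length(out) + 1L]] <-
        data.table(chrom = a$chrom[i], start = s, end = e)
  }
  if (!length(out)) return(data.table(chrom = character(),
                                      start = integer(), end = integer()))
  norm_iv(rbindlist(out))
}

# per-base boolean mask (coordinates must fit in `maxlen`)
oracle_subtract <- function(a, b, maxlen = 100000L) {
  out <- list()
  for (ch in unique(a$chrom)) {
    mask <- rep(FALSE, maxlen)
    for (j in which(b$chrom == ch))
      mask[(b$start[j] + 1L):b$end[j]] <- TRUE
    for (i in which(a$chrom == ch)) {
      idx <- (a$start[i] + 1L):a$end[i]
      keep <- idx[!mask[idx]]
      if (!length(keep)) next
      brk <- c(0L, which(diff(keep) > 1L), length(keep))
      for (k in seq_len(length(brk) - 1L))
        out[[length(out) + 1L]] <- data.table(
          chrom = ch, start = keep[brk[k] + 1L] - 1L,
          end = keep[brk[k + 1L]])
    }
  }
  if (!length(out)) return(data.table(chrom = character(),
                                      start = integer(), end = integer()))
  norm_iv(rbindlist(out))
}

# exhaustive min-over-all-pairs closest with smaller-start tie-break
oracle_closest <- function(a, b) {
  res <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    j <- which(b$chrom == a$chrom[i])
    if (!length(j)) {
      res[[i]] <- data.table(a_chrom = a$chrom[i], a_start = a$start[i],
                             a_end = a$end[i], dist = NA_integer_,
                             b_start = NA_integer_)
      next
    }
    d <- pmax(pmax(b$start[j] - a$end[i], a$start[i] - b$end[j]), 0L)
    best <- j[d == min(d)]
    best <- best[which.min(b$start[best])]
    res[[i]] <- data.table(a_chrom = a$chrom[i], a_start = a$start[i],
                           a_end = a$end[i], dist = min(d),
                           b_start = b$start[best])
  }
  out <- rbindlist(res)
  setorder(out, a_chrom, a_start, a_end)
  out
}

# connected components of the pairwise gap<=g graph
oracle_merge <- function(a, gap) {
  out <- list()
  for (ch in unique(a$chrom)) {
    x <- as.data.table(a)[chrom == ch]
    n <- nrow(x)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            max(x$start[i], x$start[j]) -
              min(x$end[i], x$end[j]) <= gap) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp))
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, start = min(x$start[comp == cc]),
        end = max(x$end[comp == cc]))
  }
  norm_iv(rbindlist(out))
}

# independent quadrant counting
oracle_qcr <- function(x, y) {
  q <- character(length(x))
  q[x > 0 & y > 0] <- "I"; q[x < 0 & y > 0] <- "II"
  q[x < 0 & y < 0] <- "III"; q[x > 0 & y < 0] <- "IV"
  n <- sum(q != "")
  (sum(q == "I") + sum(q == "III") - sum(q == "II") - sum(q == "IV")) / n
}

# two-sided Fisher p by hypergeometric-tail enumeration
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0L, c1 - r2):min(r1, c1)
  ps <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# single-linkage clustering + ambiguity + extension rules
oracle_tiles <- function(dmcpgs, merge_gap = 500L, min_size = 100L) {
  out <- list(); n_amb <- 0L
  for (ch in unique(dmcpgs$chrom)) {
    x <- as.data.table(dmcpgs)[chrom == ch]
    n <- nrow(x)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n))
        if (comp[i] != comp[j] &&
            abs(x$pos[i] - x$pos[j]) <= merge_gap) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      mem <- x[comp == cc]
      if (length(unique(sign(mem$meth_diff))) > 1L) {
        n_amb <- n_amb + 1L
        next
      }
      s <- min(mem$pos) - 1L; e <- max(mem$pos)
      w <- e - s
      if (w < min_size) {
        g <- ceiling((min_size - w) / 2)
        s <- s - g; e <- e + g
        if (e - s > min_size) e <- e - 1L
        if (s < 0L) { e <- e - s; s <- 0L }
      }
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, start = as.integer(s), end = as.integer(e),
        n_dmcpgs = nrow(mem), mean_diff = mean(mem$meth_diff))
    }
  }
  tiles <- if (length(out)) rbindlist(out) else
    data.table(chrom = character(), start = integer(), end = integer(),
               n_dmcpgs = integer(), mean_diff = numeric())
  setorder(tiles, chrom, start, end)
  list(tiles = tiles, n_ambiguous_removed = n_amb)
}

track_bases_oracle <- function(tr, maxlen = 100000L) {
  tot <- 0
  for (ch in unique(tr$chrom)) {
    mask <- rep(FALSE, maxlen)
    for (i in which(tr$chrom == ch)) mask[(tr$start[i] + 1L):tr$end[i]] <- TRUE
    tot <- tot + sum(mask)
  }
  tot
}

# ---- vectorized oracles for acceptance-scale inputs ------------------------
# Still independent of the engine: explicit all-pairs expansion and graph
# components (igraph), no foverlaps/cummax.

all_pairs <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    out[[ch]] <- data.table(i = rep(ia, each = length(ib)),
                            j = rep(ib, times = length(ia)))
  }
  rbindlist(out)
}

oracle_intersect_fast <- function(a, b) {
  p <- all_pairs(a, b)
  if (!nrow(p)) return(data.table(chrom = character(), start = integer(),
                                  end = integer()))
  s <- pmax(a$start[p$i], b$start[p$j])
  e <- pmin(a$end[p$i], b$end[p$j])
  keep <- s < e
  norm_iv(data.table(chrom = a$chrom[p$i][keep], start = s[keep],
                     end = e[keep]))
}

oracle_closest_fast <- function(a, b) {
  res <- data.table(a_chrom = a$chrom, a_start = a$start, a_end = a$end,
                    dist = NA_integer_, b_start = NA_integer_)
  p <- all_pairs(a, b)
  if (nrow(p)) {
    d <- pmax(pmax(b$start[p$j] - a$end[p$i],
                   a$start[p$i] - b$end[p$j]), 0L)
    p[, dd := d][, bs := b$start[j]]
    setorder(p, i, dd, bs)
    best <- p[!duplicated(i)]
    res$dist[best$i] <- best$dd
    res$b_start[best$i] <- best$bs
  }
  setorder(res, a_chrom, a_start, a_end)
  res
}

oracle_merge_fast <- function(a, gap) {
  adt <- as.data.table(a)
  p <- all_pairs(adt, adt)
  d <- pmax(pmax(adt$start[p$j] - adt$end[p$i],
                 adt$start[p$i] - adt$end[p$j]), 0L)
  g <- igraph::graph_from_edgelist(as.matrix(p[d <= gap, .(i, j)]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(adt) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  adt[, cc := comp]
  norm_iv(adt[, .(start = min(start), end = max(end)),
              by = .(chrom, cc)][, .(chrom, start, end)])
}

oracle_tiles_fast <- function(dmcpgs, merge_gap = 500L, min_size = 100L) {
  x <- as.data.table(dmcpgs)
  x2 <- x[, .(chrom, start = pos, end = pos)]
  p <- all_pairs(x2, x2)
  d <- abs(x2$start[p$j] - x2$start[p$i])
  g <- igraph::graph_from_edgelist(as.matrix(p[d <= merge_gap, .(i, j)]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(x2) - igraph::vcount(g)))
  x[, cc := igraph::components(g)$membership]
  n_amb <- 0L
  out <- list()
  for (cc_ in unique(x$cc)) {
    mem <- x[cc == cc_]
    if (length(unique(sign(mem$meth_diff))) > 1L) {
      n_amb <- n_amb + 1L; next
    }
    s <- min(mem$pos) - 1L; e <- max(mem$pos)
    if (e - s < min_size) {
      grow <- ceiling((min_size - (e - s)) / 2)
      s <- s - grow; e <- e + grow
      if (e - s > min_size) e <- e - 1L
      if (s < 0L) { e <- e - s; s <- 0L }
    }
    out[[length(out) + 1L]] <- data.table(
      chrom = mem$chrom[1L], start = as.integer(s), end = as.integer(e),
      n_dmcpgs = nrow(mem), mean_diff = mean(mem$meth_diff))
  }
  tiles <- if (length(out)) rbindlist(out) else
    data.table(chrom = character(), start = integer(), end = integer(),
               n_dmcpgs = integer(), mean_diff = numeric())
  setorder(tiles, chrom, start, end)
  list(tiles = tiles, n_ambiguous_removed = n_amb)
}
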