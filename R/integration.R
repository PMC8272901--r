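utils::globalVariables(c(
  "log2_fc", "fdr", "gol", "lol", "mol", "observed", "background",
  "n_q1", "n_q2", "n_q3", "n_q4", "fraction_inverse"
))

#' Read a differentially-expressed-gene table
#'
#' Tab-separated with header; column names are configurable to cover the
#' two source dialects (fibroblast tables filtered by FDR, cardiac tables
#' by raw p).
#'
#' @param path file path.
#' @param cols named list mapping the canonical names `gene_id`, `log2_fc`,
#'   `p_value`, `fdr` to the file's column names; entries absent from the
#'   file may be omitted (`fdr` is optional).
#' @return data.table with canonical columns.
#' @export
read_degs <- function(path,
                      cols = list(gene_id = "gene_id", log2_fc = "log2_fc",
                                  p_value = "p_value", fdr = "fdr")) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "log2_fc", "p_value")
  for (k in need)
    if (!cols[[k]] %in% names(dt))
      stop("DEG file lacks column ", cols[[k]])
  out <- data.table(gene_id = as.character(dt[[cols$gene_id]]),
                    log2_fc = as.numeric(dt[[cols$log2_fc]]),
                    p_value = as.numeric(dt[[cols$p_value]]))
  out[, fdr := if (!is.null(cols$fdr) && cols$fdr %in% names(dt))
    as.numeric(dt[[cols$fdr]]) else NA_real_]
  out[]
}

#' Filter DEG tables by their source rule
#'
#' @param degs data.table from [read_degs()].
#' @param fdr_max keep records with `fdr <= fdr_max` (fibroblast rule);
#'   NULL to skip.
#' @param p_max keep records with `p_value <= p_max` (cardiac rule);
#'   NULL to skip.
#' @return filtered data.table.
#' @export
filter_degs <- function(degs, fdr_max = NULL, p_max = NULL) {
  dt <- as.data.table(degs)
  if (!is.null(fdr_max)) dt <- dt[!is.na(fdr) & fdr <= fdr_max]
  if (!is.null(p_max)) dt <- dt[p_value <= p_max]
  dt[]
}

#' Conserved DEGs across fibroblast and cardiac sets
#'
#' Genes present in both pre-filtered lists.
#'
#' @param fib,cardiac filtered DEG data.tables.
#' @return character vector of shared gene ids.
#' @export
filter_and_intersect_degs <- function(fib, cardiac) {
  sort(intersect(unique(fib$gene_id), unique(cardiac$gene_id)))
}

#' Quadrant count ratio
#'
#' For points on the signed (x = methylation change, y = expression
#' change) plane, QCR = (nQI + nQIII - nQII - nQIV) / N, where QI is
#' (+,+), QII (-,+), QIII (-,-), QIV (+,-). Points on an axis (either
#' coordinate zero) are excluded from the counts and from N. +1 means
#' perfect concordance, -1 perfect inverse association.
#'
#' @param x,y numeric vectors (or `x` a two-column matrix/data.frame).
#' @return list of class `qcr_result`: n_q1..n_q4, n_total, qcr
#'   (NA when every point lies on an axis).
#' @export
qcr <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.data.frame(x)
    if (ncol(m) < 2L) stop("need two coordinates")
    y <- m[[2L]]; x <- m[[1L]]
  }
  if (!length(x)) stop("qcr: empty input")
  keep <- x != 0 & y != 0
  x <- x[keep]; y <- y[keep]
  n1 <- sum(x > 0 & y > 0); n2 <- sum(x < 0 & y > 0)
  n3 <- sum(x < 0 & y < 0); n4 <- sum(x > 0 & y < 0)
  n <- n1 + n2 + n3 + n4
  structure(list(n_q1 = n1, n_q2 = n2, n_q3 = n3, n_q4 = n4,
                 n_total = n,
                 qcr = if (n) (n1 + n3 - n2 - n4) / n else NA_real_),
            class = "qcr_result")
}

#' @export
print.qcr_result <- function(x, ...) {
  cat(sprintf("QCR = %.4f over %d points (QI %d, QII %d, QIII %d, QIV %d)\n",
              x$qcr, x$n_total, x$n_q1, x$n_q2, x$n_q3, x$n_q4))
  invisible(x)
}

#' Methylation-expression direction concordance
#'
#' Each (tile, associated DEG) pair becomes a point (tile `mean_diff`,
#' gene `log2_fc`); genes associated with several tiles contribute one
#' point per pair. Returns the four combinatorial group fractions, the
#' QCR, and the fraction of pairs in the inverse quadrants (+/- and -/+).
#'
#' @param tiles tile data.table with `mean_diff` (a `tile_id` column is
#'   added if absent, numbering rows -- must match the ids used in
#'   `gene_assoc`).
#' @param gene_assoc data.table (tile_id, gene_id) from
#'   [great_associate()] or an enhancer/promoter-restricted subset.
#' @param degs DEG data.table (gene_id, log2_fc), already filtered.
#' @return list: `pairs` (tile_id, gene_id, meth_diff, log2_fc, group),
#'   `fractions` (named numeric over "+/+", "+/-", "-/+", "-/-"),
#'   `qcr` (a `qcr_result`), `fraction_inverse`.
#' @export
direction_concordance <- function(tiles, gene_assoc, degs) {
  t <- copy(as.data.table(tiles))
  if (!"tile_id" %in% names(t)) t[, tile_id := .I]
  d <- as.data.table(degs)[, .(gene_id, log2_fc)]
  pr <- merge(as.data.table(gene_assoc), t[, .(tile_id, mean_diff)],
              by = "tile_id")
  pr <- merge(pr, d, by = "gene_id")
  pr <- pr[mean_diff != 0 & log2_fc != 0]
  pr[, grp := paste0(fifelse(mean_diff > 0, "+", "-"), "/",
                     fifelse(log2_fc > 0, "+", "-"))]
  lv <- c("+/+", "+/-", "-/+", "-/-")
  counts <- vapply(lv, function(g) sum(pr$grp == g), 0L)
  n <- nrow(pr)
  q <- if (n) qcr(pr$mean_diff, pr$log2_fc) else
    structure(list(n_q1 = 0L, n_q2 = 0L, n_q3 = 0L, n_q4 = 0L,
                   n_total = 0L, qcr = NA_real_), class = "qcr_result")
  list(pairs = pr[, .(tile_id, gene_id, meth_diff = mean_diff, log2_fc,
                      group = grp)],
       fractions = if (n) counts / n else counts * NA_real_,
       qcr = q,
       fraction_inverse = if (n) (counts[["+/-"]] + counts[["-/+"]]) / n
                          else NA_real_)
}

#' LAD redistribution (GoL / LoL / MoL)
#'
#' Gain of LAD (GoL): lamina-associated regions present in diseased (DCM)
#' tissue but absent in controls = subtract(dcm, ctrl). Loss of LAD (LoL):
#' present in controls but absent in disease = subtract(ctrl, dcm).
#' Maintenance of LAD (MoL): present in both = intersect. Input tracks are
#' unioned (overlapping/bookended intervals merged) first so the base
#' counts satisfy |GoL| + |MoL| = |DCM| and |LoL| + |MoL| = |control|.
#'
#' @param dcm_lads,ctrl_lads `interval_track` objects.
#' @return list of class `lad_redistribution`: gol, lol, mol tracks.
#' @export
lad_redistribute <- function(dcm_lads, ctrl_lads) {
  assert_track(dcm_lads); assert_track(ctrl_lads)
  dcm <- interval_merge(dcm_lads, 0L)
  ctl <- interval_merge(ctrl_lads, 0L)
  gol <- interval_subtract(dcm, ctl)
  lol <- interval_subtract(ctl, dcm)
  mol <- interval_intersect(dcm, ctl)
  setattr(gol, "track_name", "GoL")
  setattr(lol, "track_name", "LoL")
  setattr(mol, "track_name", "MoL")
  structure(list(gol = gol, lol = lol, mol = mol),
            class = "lad_redistribution")
}

#' @export
print.lad_redistribution <- function(x, ...) {
  cat(sprintf("LAD redistribution: GoL %d (%g bp), LoL %d (%g bp), MoL %d (%g bp)\n",
              nrow(x$gol), interval_bases(x$gol),
              nrow(x$lol), interval_bases(x$lol),
              nrow(x$mol), interval_bases(x$mol)))
  invisible(x)
}

#' Cross-cell-type conservation filter for redistributed LADs
#'
#' GoL intervals are kept only when they do NOT overlap any fibroblast
#' LAD; LoL and MoL intervals are kept only when they DO overlap a
#' fibroblast LAD (>= 1 bp).
#'
#' @param redist a `lad_redistribution`.
#' @param fib_lads fibroblast LAD `interval_track`.
#' @return a filtered `lad_redistribution`.
#' @export
conserve_across_celltypes <- function(redist, fib_lads) {
  stopifnot(inherits(redist, "lad_redistribution"))
  assert_track(fib_lads)
  keep_track <- function(tr, want_overlap) {
    hit <- tiles_found_in(tr, fib_lads)
    out <- interval_track(as.data.table(tr)[if (want_overlap) hit else !hit],
                          track_name = track_name(tr))
    out
  }
  structure(list(gol = keep_track(redist$gol, FALSE),
                 lol = keep_track(redist$lol, TRUE),
                 mol = keep_track(redist$mol, TRUE)),
            class = "lad_redistribution")
}

#' DEG position relative to redistributed LADs
#'
#' Per focal gene: a direct-overlap category (gene body overlapping a GoL,
#' LoL or MoL, precedence in that order) or "distal", plus the distance to
#' the nearest redistributed/maintained LAD. Also builds the 2x2
#' within-window odds ratio comparing the focal genes against a background
#' gene set (default: all other genes in the supplied model) for falling
#' within `window` bp of the nearest LAD.
#'
#' @param deg_genes gene-model rows for the focal genes.
#' @param redist a `lad_redistribution`.
#' @param window distance window in bp (default 2e6).
#' @param background_genes gene-model rows used as OR background; defaults
#'   to NULL (no OR computed) -- pass the full gene model to use its
#'   complement.
#' @return list: `per_gene` (gene_id, category, distance), `or` (one-row
#'   [odds_ratio()]-style data.table or NULL).
#' @export
deg_lad_distance <- function(deg_genes, redist, window = 2e6,
                             background_genes = NULL) {
  stopifnot(inherits(redist, "lad_redistribution"))
  all_lads <- rbindlist(lapply(redist, as.data.table), use.names = TRUE)
  if (!nrow(all_lads)) stop("empty LAD tracks")
  all_tr <- interval_track(all_lads, track_name = "redistributed")
  gene_cat <- function(g) {
    gt <- interval_track(as.data.table(g)[, .(chrom, start, end,
                                              name = gene_id)],
                         track_name = "genes")
    in_gol <- tiles_found_in(gt, redist$gol)
    in_lol <- tiles_found_in(gt, redist$lol)
    in_mol <- tiles_found_in(gt, redist$mol)
    cl <- interval_closest(gt, all_tr)
    m <- match(paste0(g$chrom, ":", g$start, "-", g$end),
               paste0(cl$a_chrom, ":", cl$a_start, "-", cl$a_end))
    dist <- cl$distance[m]
    cat <- ifelse(in_gol, "within_GoL",
                  ifelse(in_lol, "within_LoL",
                         ifelse(in_mol, "within_MoL", "distal")))
    data.table(gene_id = g$gene_id, category = cat, distance = dist)
  }
  focal <- gene_cat(as.data.table(deg_genes))
  or <- NULL
  if (!is.null(background_genes)) {
    bgg <- as.data.table(background_genes)
    bgg <- bgg[!gene_id %in% deg_genes$gene_id]
    bg <- gene_cat(bgg)
    a <- sum(focal$distance <= window, na.rm = TRUE)
    b <- nrow(focal) - a
    c_ <- sum(bg$distance <= window, na.rm = TRUE)
    d <- nrow(bg) - c_
    orv <- (a / c_) / (b / d)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L,
                                   byrow = TRUE))$p.value
    or <- data.table(context = sprintf("within_%gbp_of_LAD", window),
                     a = a, b = b, c = c_, d = d, odds_ratio = orv,
                     log_or = log10(orv), p_value = p,
                     undefined_margin = !is.finite(orv))
  }
  list(per_gene = focal, or = or)
}

# nearest-target distance for every query site (bp between cytosine
# positions; 0 when a query position is itself a target)
nearest_site_distance <- function(query, target) {
  q <- as.data.table(query)[, .(chrom, pos)]
  t <- as.data.table(target)[, .(chrom, pos)]
  out <- rep(NA_real_, nrow(q))
  for (ch in unique(q$chrom)) {
    qi <- which(q$chrom == ch)
    tp <- sort(t[chrom == ch, pos])
    if (!length(tp)) next
    qp <- q$pos[qi]
    idx <- findInterval(qp, tp)
    left <- ifelse(idx >= 1L, qp - tp[pmax(idx, 1L)], Inf)
    right <- ifelse(idx < length(tp), tp[pmin(idx + 1L, length(tp))] - qp,
                    Inf)
    out[qi] <- pmin(left, right)
  }
  out
}

#' Epimutation-hotspot proximity test
#'
#' Observed statistic: for each query CpG, the distance to the nearest
#' target CpG. Background: the same computation between two uniform random
#' samples (without replacement, seeded) -- one of size `|query_cpgs|`
#' drawn from `query_background`, one of size `|target_cpgs|` drawn from
#' `target_background` -- i.e. both categories are resampled from the
#' captured-CpG pools, which keeps the two distance samples independent.
#' In `density` mode the two distance samples are compared with a Wilcoxon
#' rank-sum test; in `binned` mode observed vs background counts per
#' distance bin are compared with one-tailed (greater) Fisher exact tests.
#'
#' @param query_cpgs,target_cpgs data.tables (chrom, pos).
#' @param target_background data.table (chrom, pos); must contain at least
#'   `nrow(target_cpgs)` sites.
#' @param query_background data.table (chrom, pos) the query surrogate is
#'   drawn from; defaults to `target_background`.
#' @param mode "density" (Wilcoxon) or "binned" (per-bin Fisher).
#' @param bins bin edges in bp for binned mode (right-open; an `Inf` final
#'   edge is appended if absent). Default c(0, 1e3, 5e3, 1e4, 5e4, Inf).
#' @param seed integer seed for the background draw.
#' @param n_draws average the background over this many draws (default 1,
#'   the matched-sampling convention; distances of all draws are pooled).
#' @return list of class `proximity_result`: observed_distances,
#'   background_distances, mode, p_value (density) or bin table with
#'   per-bin p (binned), seed.
#' @export
hotspot_proximity <- function(query_cpgs, target_cpgs, target_background,
                              mode = c("density", "binned"), bins = NULL,
                              seed = 1L, n_draws = 1L,
                              query_background = NULL) {
  mode <- match.arg(mode)
  q <- unique(as.data.table(query_cpgs)[, .(chrom, pos)])
  t <- unique(as.data.table(target_cpgs)[, .(chrom, pos)])
  bg <- unique(as.data.table(target_background)[, .(chrom, pos)])
  qbg <- if (is.null(query_background)) bg else
    unique(as.data.table(query_background)[, .(chrom, pos)])
  if (!nrow(q) || !nrow(t)) stop("empty CpG sets")
  if (nrow(bg) < nrow(t))
    stop("target background smaller than target set")
  if (nrow(qbg) < nrow(q))
    stop("query background smaller than query set")
  obs <- nearest_site_distance(q, t)
  set.seed(seed)
  bgd <- unlist(lapply(seq_len(n_draws), function(i) {
    qs <- qbg[sample.int(nrow(qbg), nrow(q))]
    ts <- bg[sample.int(nrow(bg), nrow(t))]
    nearest_site_distance(qs, ts)
  }))
  obs <- obs[is.finite(obs)]; bgd <- bgd[is.finite(bgd)]
  res <- list(observed_distances = obs, background_distances = bgd,
              mode = mode, seed = seed)
  if (mode == "density") {
    res$test <- "wilcoxon_rank_sum"
    # ties are expected in distance data; normal approximation with tie
    # correction is what wilcox.test falls back to
    res$p_value <- suppressWarnings(stats::wilcox.test(obs, bgd)$p.value)
  } else {
    if (is.null(bins)) bins <- c(0, 1e3, 5e3, 1e4, 5e4, Inf)
    if (is.finite(bins[length(bins)])) bins <- c(bins, Inf)
    res$test <- "fisher_binned"
    res$bin_edges <- bins
    tab <- lapply(seq_len(length(bins) - 1L), function(i) {
      lo <- bins[i]; hi <- bins[i + 1L]
      a <- sum(obs >= lo & obs < hi); b <- length(obs) - a
      c_ <- sum(bgd >= lo & bgd < hi); d <- length(bgd) - c_
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                              alternative = "greater")$p.value
      data.table(bin_lo = lo, bin_hi = hi, n_observed = a,
                 n_background = c_, p_value = p)
    })
    res$bins <- rbindlist(tab)
  }
  structure(res, class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "proximity_result (%s): median observed %.1f vs background %.1f bp\n",
    x$test, stats::median(x$observed_distances),
    stats::median(x$background_distances)))
  if (!is.null(x$p_value)) cat(sprintf("  Wilcoxon p = %.3g\n", x$p_value))
  invisible(x)
}

#' Write a proximity result
#'
#' Writes a TSV of distances (set, distance) and a JSON sidecar with the
#' test, p-value(s), bins and seed.
#'
#' @param x a `proximity_result`.
#' @param tsv_path,json_path output paths.
#' @return invisibly `tsv_path`.
#' @export
write_proximity_result <- function(x, tsv_path, json_path) {
  dt <- rbindlist(list(
    data.table(set = "observed", distance = x$observed_distances),
    data.table(set = "background", distance = x$background_distances)))
  fwrite(dt, tsv_path, sep = "\t", quote = FALSE)
  meta <- list(test = x$test, mode = x$mode, seed = x$seed)
  if (!is.null(x$p_value)) meta$p_value <- x$p_value
  if (!is.null(x$bins)) meta$bins <- x$bins
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}
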