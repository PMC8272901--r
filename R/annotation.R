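utils::globalVariables(c(
  "gene_id", "tss", "exon_starts", "exon_ends", "feature", "context",
  "log_or", "odds_ratio_", "a_name", "b_name", "dist_signed", "bin",
  "basal_start", "basal_end", "dom_start", "dom_end", "a_start", "a_end",
  "b_start", "b_end"
))

#' Read gene models
#'
#' Tab-separated with header `gene_id, chrom, strand, start, end,
#' exon_starts, exon_ends`; coordinates 0-based half-open, exon bounds
#' comma-separated lists within [start, end). The TSS boundary is `start`
#' for + strand genes and `end` for - strand genes.
#'
#' @param path file path.
#' @return data.table of gene models with a `tss` (boundary) column.
#' @export
read_gene_models <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("gene_id", "chrom", "strand",
                                              "exon_starts", "exon_ends")))
  req <- c("gene_id", "chrom", "strand", "start", "end",
           "exon_starts", "exon_ends")
  if (!all(req %in% names(dt)))
    stop("gene model file needs columns: ", paste(req, collapse = ", "))
  if (any(!dt$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (any(dt$start >= dt$end)) stop("gene with start >= end")
  dt[, tss := fifelse(strand == "+", start, end)]
  setorder(dt, chrom, start, end)
  dt[]
}

#' Write gene models
#' @param genes data.table as produced by [read_gene_models()] or the
#'   simulator.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_gene_models <- function(genes, path) {
  fwrite(as.data.table(genes)[, .(gene_id, chrom, strand, start, end,
                                  exon_starts, exon_ends)],
         path, sep = "\t", quote = FALSE)
  invisible(path)
}

parse_exons <- function(genes) {
  n <- vapply(strsplit(genes$exon_starts, ","), length, 0L)
  data.table(
    chrom = rep(genes$chrom, n),
    start = as.integer(unlist(strsplit(genes$exon_starts, ","))),
    end = as.integer(unlist(strsplit(genes$exon_ends, ","))),
    name = rep(genes$gene_id, n))
}

#' Promoter track from gene models
#'
#' Per gene, the strand-aware interval of `upstream` bp abutting the TSS:
#' `[tss - upstream, tss)` for + strand genes, `[tss, tss + upstream)` for
#' - strand genes (TSS as 0-based boundary), clipped at coordinate 0.
#'
#' @param genes gene-model data.table (see [read_gene_models()]).
#' @param upstream promoter size in bp (default 2000).
#' @return an `interval_track` named "promoters".
#' @export
define_promoters <- function(genes, upstream = 2000L) {
  g <- as.data.table(genes)
  dt <- data.table(
    chrom = g$chrom,
    start = fifelse(g$strand == "+", pmax(g$tss - upstream, 0L), g$tss),
    end = fifelse(g$strand == "+", g$tss, g$tss + upstream),
    name = g$gene_id, score = NA_real_, strand = g$strand)
  dt <- dt[start < end]
  interval_track(dt, track_name = "promoters")
}

#' Feature tracks from gene models
#'
#' @param genes gene-model data.table.
#' @param promoter_upstream promoter size in bp.
#' @return list of `interval_track`s: promoters, exons, gene_bodies.
#' @export
gene_feature_tracks <- function(genes, promoter_upstream = 2000L) {
  g <- as.data.table(genes)
  list(promoters = define_promoters(g, promoter_upstream),
       exons = interval_track(parse_exons(g), track_name = "exons"),
       gene_bodies = interval_track(
         g[, .(chrom, start, end, name = gene_id)],
         track_name = "gene_bodies"))
}

sites_as_track <- function(sites, track_name = "sites") {
  s <- as.data.table(sites)
  interval_track(s[, .(chrom, start = pos - 1L, end = pos,
                       name = paste0(chrom, ":", pos))],
                 track_name = track_name)
}

#' Assign each CpG site to one genomic feature
#'
#' Precedence promoter > exon > intron > intergenic: a site in both a
#' promoter and an exon is "promoter"; "intron" is inside a gene body but
#' not in an exon; "intergenic" is outside all gene bodies and promoters.
#'
#' @param sites data.table with `chrom`, `pos` (1-based CpG positions).
#' @param features list from [gene_feature_tracks()].
#' @return character vector of labels, one per site.
#' @export
assign_feature <- function(sites, features) {
  s <- as.data.table(sites)[, .(chrom, pos)]
  st <- sites_as_track(s)   # sorted by coordinate
  in_prom <- tiles_found_in(st, features$promoters)
  in_exon <- tiles_found_in(st, features$exons)
  in_body <- tiles_found_in(st, features$gene_bodies)
  lab <- ifelse(in_prom, "promoter",
                ifelse(in_exon, "exon",
                       ifelse(in_body, "intron", "intergenic")))
  # map back to the caller's site order
  lab[match(paste0(s$chrom, ":", s$pos - 1L),
            paste0(st$chrom, ":", st$start))]
}

#' Odds-ratio enrichment of a CpG set in a genomic context
#'
#' Builds the 2x2 table a = focal CpGs in context, b = focal CpGs outside
#' the context, c = non-focal background CpGs in context, d = non-focal
#' background CpGs outside (the background rows are counted over
#' `background` minus `dm_cpgs`). OR = (a/c)/(b/d); `log_or` is log10(OR).
#' Significance is two-sided Fisher's exact by default.
#'
#' @param dm_cpgs data.table (chrom, pos) of focal CpGs; must be a subset
#'   of `background`.
#' @param background data.table (chrom, pos) of all captured CpGs.
#' @param context an `interval_track`.
#' @param alternative passed to [stats::fisher.test()] ("two.sided"
#'   default).
#' @return one-row data.table: context, a, b, c, d, odds_ratio, log_or,
#'   p_value, undefined_margin (TRUE when a margin is zero and the OR is
#'   not finite).
#' @export
odds_ratio <- function(dm_cpgs, background, context,
                       alternative = "two.sided") {
  dm <- unique(as.data.table(dm_cpgs)[, .(chrom, pos)])
  bg <- unique(as.data.table(background)[, .(chrom, pos)])
  setkey(bg, chrom, pos); setkey(dm, chrom, pos)
  if (nrow(dm[!bg])) stop("dm_cpgs must be a subset of background")
  rest <- bg[!dm]
  in_ctx <- function(s) tiles_found_in(sites_as_track(s), context)
  a <- sum(in_ctx(dm)); b <- nrow(dm) - a
  c_ <- sum(in_ctx(rest)); d <- nrow(rest) - c_
  or <- (a / c_) / (b / d)
  undef <- !is.finite(or)
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                          alternative = alternative)$p.value
  data.table(context = track_name(context), a = a, b = b, c = c_, d = d,
             odds_ratio = or, log_or = log10(or), p_value = p,
             undefined_margin = undef)
}

#' Signed distance of CpGs to the nearest TSS
#'
#' Distance from each site to the nearest TSS over all genes (nearest by
#' absolute distance), signed by the gene's orientation: positive
#' downstream of the TSS, negative upstream. A site exactly at the TSS
#' base has distance 0 (downstream by convention).
#'
#' @param sites data.table (chrom, pos).
#' @param genes gene-model data.table.
#' @return numeric vector of signed distances (NA when the site's
#'   chromosome has no gene).
#' @export
tss_signed_distance <- function(sites, genes) {
  s <- as.data.table(sites)[, .(chrom, pos)]
  g <- as.data.table(genes)
  # TSS base in 0-based coords: start for +, end-1 for -
  tssb <- data.table(chrom = g$chrom,
                     start = fifelse(g$strand == "+", g$tss, g$tss - 1L),
                     strand = g$strand)
  tssb[, end := start + 1L]
  tsst <- interval_track(tssb[, .(chrom, start, end, name = strand)],
                         track_name = "tss")
  cl <- interval_closest(sites_as_track(s), tsst)
  # interval_closest returns rows sorted by a coords; map back
  key <- paste0(s$chrom, ":", s$pos - 1L)
  m <- match(key, paste0(cl$a_chrom, ":", cl$a_start))
  cl <- cl[m]
  raw <- (s$pos - 1L) - cl$b_start   # positive = to the right of TSS base
  fifelse(cl$b_name == "+", as.numeric(raw), as.numeric(-raw))
}

#' TSS-distance-bin enrichment
#'
#' One odds-ratio per signed distance bin: CpGs are binned by signed
#' distance to the nearest TSS (negative upstream, positive downstream)
#' using edges `bins_kb` mirrored around 0. Downstream bins are
#' `[lo, hi)` kb and upstream bins `(-hi, -lo]` kb, so a CpG exactly at a
#' TSS falls in the first downstream bin.
#'
#' @param dm_cpgs,background CpG site tables (chrom, pos); dm_cpgs must be
#'   a subset of background.
#' @param genes gene-model data.table.
#' @param bins_kb strictly increasing non-negative edges in kb
#'   (default c(0, 1, 5, 10, 50)).
#' @return data.table of [odds_ratio()] rows, one per signed bin, with
#'   columns bin (label) and side.
#' @export
tss_distance_bins <- function(dm_cpgs, background, genes,
                              bins_kb = c(0, 1, 5, 10, 50)) {
  if (!nrow(as.data.table(genes))) stop("empty gene set")
  if (is.unsorted(bins_kb, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  dm <- unique(as.data.table(dm_cpgs)[, .(chrom, pos)])
  bg <- unique(as.data.table(background)[, .(chrom, pos)])
  setkey(bg, chrom, pos); setkey(dm, chrom, pos)
  if (nrow(dm[!bg])) stop("dm_cpgs must be a subset of background")
  d_bg <- tss_signed_distance(bg, genes)
  idx <- bg[dm, which = TRUE]
  dm_flag <- rep(FALSE, nrow(bg)); dm_flag[idx] <- TRUE

  edges <- bins_kb * 1000
  out <- list()
  for (i in seq_len(length(edges) - 1L)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    for (side in c("downstream", "upstream")) {
      # a CpG exactly at a TSS (distance 0) is downstream-only
      inbin <- if (side == "downstream") d_bg >= lo & d_bg < hi
               else d_bg <= -lo & d_bg > -hi & d_bg < 0
      inbin[is.na(inbin)] <- FALSE
      a <- sum(inbin & dm_flag); b <- sum(dm_flag) - a
      c_ <- sum(inbin & !dm_flag); d <- sum(!dm_flag) - c_
      or <- (a / c_) / (b / d)
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L,
                                     byrow = TRUE))$p.value
      lab <- sprintf("%s%g-%gkb", if (side == "upstream") "-" else "+",
                     bins_kb[i], bins_kb[i + 1L])
      out[[length(out) + 1L]] <-
        data.table(bin = lab, side = side, a = a, b = b, c = c_, d = d,
                   odds_ratio = or, log_or = log10(or), p_value = p,
                   undefined_margin = !is.finite(or))
    }
  }
  rbindlist(out)
}

#' Basal-plus-extension regulatory domains
#'
#' Per gene, the basal domain is `proximal_up` bp upstream to
#' `proximal_down` bp downstream of the TSS (strand-aware). Each side of
#' the basal domain is then extended to the nearest non-overlapping
#' neighboring basal-domain boundary or by `distal_max` bp, whichever is
#' closer, clipped at 0 (and at the chromosome length when `genome` is
#' given). A domain is never smaller than its basal domain.
#'
#' @param genes gene-model data.table.
#' @param proximal_up,proximal_down basal extents in bp (defaults 5000 and
#'   1000).
#' @param distal_max maximum extension in bp (default 1e6).
#' @param genome optional named chromosome-length vector.
#' @return data.table: gene_id, chrom, strand, basal_start, basal_end,
#'   dom_start, dom_end.
#' @export
regulatory_domains <- function(genes, proximal_up = 5000L,
                               proximal_down = 1000L, distal_max = 1000000L,
                               genome = NULL) {
  g <- as.data.table(genes)
  g[, basal_start := fifelse(strand == "+",
                             pmax(tss - proximal_up, 0L),
                             pmax(tss - proximal_down, 0L))]
  g[, basal_end := fifelse(strand == "+",
                           tss + proximal_down, tss + proximal_up)]
  res <- g[, {
    bs <- basal_start; be <- basal_end
    n <- .N
    ds <- integer(n); de <- integer(n)
    clen <- if (!is.null(genome) && chrom[1L] %in% names(genome))
      genome[[chrom[1L]]] else NA_integer_
    for (k in seq_len(n)) {
      others_e <- be[-k]; others_s <- bs[-k]
      lb <- others_e[others_e <= bs[k]]
      left <- max(c(bs[k] - distal_max, 0L, if (length(lb)) max(lb)))
      rb <- others_s[others_s >= be[k]]
      right <- min(c(be[k] + distal_max,
                     if (!is.na(clen)) clen else NULL,
                     if (length(rb)) min(rb)))
      ds[k] <- min(left, bs[k]); de[k] <- max(right, be[k])
    }
    .(gene_id = gene_id, strand = strand, tss = tss,
      basal_start = bs, basal_end = be,
      dom_start = ds, dom_end = de)
  }, by = chrom]
  setorder(res, chrom, dom_start)
  res[]
}

#' Associate DMR tiles to genes (basal-plus-extension rule)
#'
#' A tile associates with every gene whose regulatory domain (see
#' [regulatory_domains()]) it overlaps by >= 1 bp.
#'
#' @param tiles tile data.table (chrom, start, end; a `tile_id` column is
#'   added if absent, numbering rows).
#' @inheritParams regulatory_domains
#' @return data.table (tile_id, gene_id) association pairs.
#' @export
great_associate <- function(tiles, genes, proximal_up = 5000L,
                            proximal_down = 1000L, distal_max = 1000000L,
                            genome = NULL) {
  t <- copy(as.data.table(tiles))
  if (!"tile_id" %in% names(t)) t[, tile_id := .I]
  doms <- regulatory_domains(genes, proximal_up, proximal_down,
                             distal_max, genome)
  if (!nrow(t) || !nrow(doms))
    return(data.table(tile_id = integer(), gene_id = character()))
  b <- doms[, .(chrom, start = dom_start, end = dom_end, gene_id)]
  setkey(b, chrom, start, end)
  a <- t[, .(chrom, start, end, tile_id)]
  ov <- foverlaps(a, b, by.x = c("chrom", "start", "end"),
                  type = "any", nomatch = NULL)
  ov <- ov[pmin(i.end, end) - pmax(i.start, start) > 0L]
  unique(ov[, .(tile_id, gene_id)])[order(tile_id, gene_id)]
}

#' Write odds-ratio results
#' @param or_table data.table of [odds_ratio()] rows.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_or_results <- function(or_table, path) {
  fwrite(or_table, path, sep = "\t", quote = FALSE)
  invisible(path)
}
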