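toy_genes <- function() {
  data.table(
    gene_id = c("gPlus", "gMinus"), chrom = "chr1",
    strand = c("+", "-"), start = c(10000L, 40000L),
    end = c(20000L, 50000L),
    exon_starts = c("10000,15000", "40000,48000"),
    exon_ends = c("11000,16000", "42000,50000"),
    tss = c(10000L, 50000L))
}

test_that("promoters are strand-aware, 2 kb, abutting the TSS", {
  g <- toy_genes()
  pr <- define_promoters(g)
  plus <- as.data.table(pr)[name == "gPlus"]
  minus <- as.data.table(pr)[name == "gMinus"]
  expect_identical(c(plus$start, plus$end), c(8000L, 10000L))
  expect_identical(c(minus$start, minus$end), c(50000L, 52000L))
  # random genes: width <= upstream, promoter abuts its TSS
  set.seed(14)
  rg <- data.table(gene_id = sprintf("g%02d", 1:50), chrom = "chr1",
                   strand = sample(c("+", "-"), 50, TRUE),
                   start = st <- sample.int(100000L, 50),
                   end = st + 1000L)
  rg[, tss := fifelse(strand == "+", start, end)]
  rp <- as.data.table(define_promoters(rg))
  expect_true(all(rp$end - rp$start <= 2000L))
  m <- match(rp$name, rg$gene_id)
  expect_true(all(ifelse(rg$strand[m] == "+", rp$end == rg$tss[m],
                         rp$start == rg$tss[m])))
})

test_that("assign_feature follows promoter > exon > intron > intergenic", {
  g <- toy_genes()
  feats <- gene_feature_tracks(g)
  sites <- data.table(
    chrom = "chr1",
    pos = c(9000L,    # promoter of gPlus
            10500L,   # exon 1 of gPlus
            12000L,   # intron of gPlus
            30000L,   # intergenic
            50500L,   # promoter of gMinus
            49000L))  # exon of gMinus
  expect_identical(assign_feature(sites, feats),
                   c("promoter", "exon", "intron", "intergenic",
                     "promoter", "exon"))
  # overlapping promoter+exon resolves to promoter: gene at 8000-9000
  g2 <- rbind(g, data.table(gene_id = "gOv", chrom = "chr1", strand = "+",
                            start = 8000L, end = 9500L,
                            exon_starts = "8000", exon_ends = "9500",
                            tss = 8000L))
  expect_identical(
    assign_feature(data.table(chrom = "chr1", pos = 8500L),
                   gene_feature_tracks(g2)), "promoter")
})

test_that("assign_feature fractions match a per-base mask oracle", {
  g <- toy_genes()
  feats <- gene_feature_tracks(g)
  L <- 100000L
  lab <- rep("intergenic", L)
  mark <- function(track, value) {
    for (i in seq_len(nrow(track))) {
      idx <- (track$start[i] + 1L):min(track$end[i], L)
      lab[idx][lab[idx] == "intergenic" |
                 (value == "promoter")] <<- value
    }
  }
  # paint lowest precedence first, promoter may override anything
  body <- as.data.table(feats$gene_bodies)
  for (i in seq_len(nrow(body))) lab[(body$start[i] + 1L):body$end[i]] <- "intron"
  ex <- as.data.table(feats$exons)
  for (i in seq_len(nrow(ex))) lab[(ex$start[i] + 1L):ex$end[i]] <- "exon"
  prm <- as.data.table(feats$promoters)
  for (i in seq_len(nrow(prm))) lab[(prm$start[i] + 1L):prm$end[i]] <- "promoter"
  set.seed(88)
  pos <- sample.int(L - 1L, 5000L)
  got <- assign_feature(data.table(chrom = "chr1", pos = pos), feats)
  expect_identical(got, lab[pos])
})

test_that("odds_ratio matches the formula example and flags degenerates", {
  set.seed(31)
  bg <- data.table(chrom = "chr1", pos = sort(sample.int(100000L, 1000L)))
  dm <- bg[1:100]
  # context holding 30 of the dm and 100 of the rest -> a=30,b=70,c=100,d=800
  ctx_sites <- rbind(dm[1:30], bg[101:200])
  ctx <- interval_track(ctx_sites[, .(chrom, start = pos - 1L, end = pos)],
                        track_name = "ctx")
  r <- odds_ratio(dm, bg, ctx)
  expect_identical(c(r$a, r$b, r$c, r$d), c(30L, 70L, 100L, 800L))
  expect_equal(r$odds_ratio, (30 / 100) / (70 / 800), tolerance = 1e-12)
  expect_equal(r$log_or, 0.5351, tolerance = 1e-3)
  expect_equal(r$p_value, oracle_fisher_p(30, 70, 100, 800),
               tolerance = 1e-10)
  # context covering every background site -> undefined margins
  all_ctx <- interval_track(data.table(chrom = "chr1", start = 0L,
                                       end = 100001L), track_name = "all")
  expect_true(odds_ratio(dm, bg, all_ctx)$undefined_margin)
  expect_error(odds_ratio(data.table(chrom = "chr9", pos = 1L), bg, ctx),
               "subset")
})

test_that("odds_ratio p equals hypergeometric enumeration, OR inverts", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(40:200, 1)
    bg <- data.table(chrom = "chr1",
                     pos = sort(sample.int(50000L, n)))
    dm <- bg[sample.int(n, sample(5:(n - 5), 1))]
    ctx_n <- sample(3:(n - 3), 1)
    ctx_sites <- bg[sample.int(n, ctx_n)]
    ctx <- interval_track(ctx_sites[, .(chrom, start = pos - 1L,
                                        end = pos)], track_name = "c")
    r <- odds_ratio(dm, bg, ctx)
    expect_lt(abs(r$p_value - oracle_fisher_p(r$a, r$b, r$c, r$d)), 1e-10)
    # complement swap inverts the odds ratio
    comp <- bg[!dm, on = c("chrom", "pos")]
    r2 <- odds_ratio(comp, bg, ctx)
    if (!r$undefined_margin && !r2$undefined_margin)
      expect_equal(r2$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-9)
  }
})

test_that("tss distance bins respect boundaries and orientation", {
  g <- toy_genes()  # TSS boundaries at 10000 (+) and 50000 (-)
  # + strand gene: 3 kb upstream = pos 7001 (0-based 7000)
  d <- tss_signed_distance(data.table(chrom = "chr1",
                                      pos = c(7001L, 10001L, 12001L)), g)
  expect_equal(d[1], -3000)
  expect_equal(d[2], 0)       # exactly at the TSS base
  expect_equal(d[3], 2000)    # downstream, inside gene
  # - strand gene: TSS base at 0-based 49999; upstream = larger coords
  d2 <- tss_signed_distance(data.table(chrom = "chr1", pos = 53000L), g)
  expect_equal(d2, -3000)
  bg <- data.table(chrom = "chr1",
                   pos = c(7001L, 10001L, 12001L, 53000L, 80000L))
  tb <- tss_distance_bins(bg[c(1, 2)], bg, g)
  at_tss <- tb[bin == "+0-1kb"]
  expect_identical(at_tss$a, 1L)            # the TSS site, downstream only
  up <- tb[bin == "-1-5kb"]
  expect_identical(up$a, 1L)                # the 3 kb upstream site
  expect_identical(sum(tb[side == "upstream" & bin == "-0-1kb", a]), 0L)
  expect_error(tss_distance_bins(bg, bg, g[0L]), "empty gene set")
  expect_error(tss_distance_bins(bg, bg, g, bins_kb = c(5, 1)),
               "strictly increasing")
})

test_that("tss bin geometry matches closed form for one gene", {
  g <- data.table(gene_id = "g", chrom = "chr1", strand = "+",
                  start = 500000L, end = 520000L, exon_starts = "500000",
                  exon_ends = "520000", tss = 500000L)
  set.seed(4)
  bg <- data.table(chrom = "chr1", pos = sample.int(1000000L, 20000L))
  d <- tss_signed_distance(bg, g)
  # uniform positions: expected fraction in each signed bin ~ width/1e6
  for (b in list(c(0, 1000), c(1000, 5000), c(5000, 10000))) {
    frac_dn <- mean(d >= b[1] & d < b[2])
    frac_up <- mean(d < 0 & d <= -b[1] & d > -b[2])
    expect_equal(frac_dn, (b[2] - b[1]) / 1e6, tolerance = 0.25)
    expect_equal(frac_up, (b[2] - b[1]) / 1e6, tolerance = 0.25)
  }
})

test_that("regulatory domains follow the basal-plus-extension rule", {
  # single gene: basal +- distal_max
  g1 <- data.table(gene_id = "g", chrom = "chr1", strand = "+",
                   start = 2000000L, end = 2010000L,
                   exon_starts = "2000000", exon_ends = "2010000",
                   tss = 2000000L)
  d1 <- regulatory_domains(g1)
  expect_identical(d1$basal_start, 2000000L - 5000L)
  expect_identical(d1$basal_end, 2000000L + 1000L)
  expect_identical(d1$dom_start, d1$basal_start - 1000000L)
  expect_identical(d1$dom_end, d1$basal_end + 1000000L)
  # two genes 100 kb apart: extensions stop at each other's basal domain
  g2 <- rbind(g1, data.table(gene_id = "g2", chrom = "chr1", strand = "+",
                             start = 2100000L, end = 2110000L,
                             exon_starts = "2100000",
                             exon_ends = "2110000", tss = 2100000L))
  d2 <- regulatory_domains(g2)
  expect_identical(d2[gene_id == "g", dom_end],
                   d2[gene_id == "g2", basal_start])
  expect_identical(d2[gene_id == "g2", dom_start],
                   d2[gene_id == "g", basal_end])
})

test_that("regulatory domains match an independent boundary oracle", {
  set.seed(23)
  for (rep in 1:4) {
    n <- 12L
    tsspos <- sort(sample(seq(100000L, 8000000L, by = 50000L), n))
    g <- data.table(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                    strand = sample(c("+", "-"), n, TRUE))
    g[, start := tsspos]; g[, end := tsspos + 10000L]
    g[, `:=`(exon_starts = as.character(start),
             exon_ends = as.character(end))]
    g[, tss := fifelse(strand == "+", start, end)]
    doms <- regulatory_domains(g)
    # oracle: explicit scan over other genes' basal boundaries
    for (i in seq_len(nrow(doms))) {
      bs <- doms$basal_start[i]; be <- doms$basal_end[i]
      oth_e <- doms$basal_end[-i]; oth_s <- doms$basal_start[-i]
      lo <- suppressWarnings(max(oth_e[oth_e <= bs]))
      hi <- suppressWarnings(min(oth_s[oth_s >= be]))
      expect_identical(doms$dom_start[i],
                       as.integer(max(bs - 1000000L, 0L,
                                      if (is.finite(lo)) lo else 0L)))
      expect_identical(doms$dom_end[i],
                       as.integer(min(be + 1000000L,
                                      if (is.finite(hi)) hi else Inf)))
      # never overlap another gene's basal domain
      expect_true(all(doms$dom_start[i] >= oth_e | doms$dom_end[i] <= oth_s |
                        (oth_s >= bs & oth_e <= be)))
    }
  }
})

test_that("great_associate links tiles to overlapping domains only", {
  g <- data.table(gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
                  start = c(1000000L, 5000000L),
                  end = c(1010000L, 5010000L),
                  exon_starts = c("1000000", "5000000"),
                  exon_ends = c("1010000", "5010000"),
                  tss = c(1000000L, 5000000L))
  tiles <- data.table(chrom = "chr1",
                      start = c(900000L,     # in gA's domain
                                3000000L,    # between domains (gap)
                                4200000L),   # in gB's distal extension
                      end = c(900500L, 3000500L, 4200500L))
  a <- great_associate(tiles, g)
  expect_identical(a[tile_id == 1L, gene_id], "gA")
  expect_identical(nrow(a[tile_id == 2L]), 0L)
  expect_identical(a[tile_id == 3L, gene_id], "gB")
})

test_that("gene model files round-trip", {
  f <- tempfile()
  write_gene_models(toy_genes(), f)
  back <- read_gene_models(f)
  expect_identical(back$gene_id, toy_genes()$gene_id)
  expect_identical(back$tss, toy_genes()$tss)
})
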